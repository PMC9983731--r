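make_crops <- function(nutrient = "N") {
  crop_table(data.frame(
    crop = rep(c("corn", "soy", "hay"), each = 2),
    year = rep(2000:2001, 3),
    yield = c(10, 10, 20, 20, 30, 30),
    content = rep(c(1, 0.5, 2), each = 2),
    is_n_fixing = rep(c(FALSE, TRUE, TRUE), each = 2)),
    nutrient = nutrient)
}

test_that("crop uptake is yield times content summed over crops", {
  one <- crop_table(data.frame(crop = "corn", year = 2000, yield = 100,
                               content = 0.5, is_n_fixing = FALSE), "N")
  expect_equal(compute_crop_uptake(one)$value, 50)

  zero <- crop_table(data.frame(crop = "corn", year = 2000, yield = 0,
                                content = 0.5, is_n_fixing = FALSE), "N")
  expect_equal(compute_crop_uptake(zero)$value, 0)

  # 10*1 + 20*0.5 + 30*2 = 80
  expect_equal(compute_crop_uptake(make_crops())$value, c(80, 80))
})

test_that("N fixation equals harvest-N removal of fixing crops only", {
  crops <- make_crops()
  # fixing crops: soy (20*0.5) + hay (30*2) = 70
  expect_equal(compute_n_fixation(crops)$value, c(70, 70))

  none <- crop_table(data.frame(crop = "corn", year = 2000:2001,
                                yield = c(5, 6), content = 1,
                                is_n_fixing = FALSE), "N")
  expect_equal(compute_n_fixation(none)$value, c(0, 0))

  solo <- crop_table(data.frame(crop = "soy", year = 2000, yield = 12,
                                content = 0.25, is_n_fixing = TRUE), "N")
  expect_equal(compute_n_fixation(solo)$value,
               compute_crop_uptake(solo)$value)

  expect_error(compute_n_fixation(make_crops("P")), "nitrogen")
})

test_that("gaseous N outputs follow the 1% and 1.7x rules", {
  f <- annual_series(2000:2001, c(600, 0))
  m <- annual_series(2000:2001, c(400, 0))
  g <- compute_n_gaseous_outputs(f, m)
  expect_equal(g$n2o$value, c(10, 0))
  expect_equal(g$n2$value, c(17, 0))
  # total gaseous output: 0.01 * 1000 * (1 + 1.7) = 27
  expect_equal(g$n2o$value[1] + g$n2$value[1], 27)
  # ratio is exactly 1.7 wherever n2o > 0
  pos <- g$n2o$value > 0
  expect_equal(g$n2$value[pos] / g$n2o$value[pos], rep(1.7, sum(pos)))
})

test_that("the N balance follows inputs-minus-outputs with default constants", {
  comp <- balance_components(data.frame(
    year = 2000, fertilizer = 500, manure = 300, wastewater = 10,
    fixation = 200, atmospheric_deposition_oxidized = 100,
    crop_uptake = 600), "N")
  # (500+300+10+200+100) - (600 + 8 + 13.6 + 114) = 374.4
  expect_equal(compute_balance(comp)$value, 374.4)

  # reduced deposition is carried but never summed
  comp2 <- balance_components(cbind(as.data.frame(comp),
                                    atmospheric_deposition_reduced = 500), "N")
  expect_equal(compute_balance(comp2)$value, 374.4)

  # explicit components override the defaults
  comp3 <- balance_components(data.frame(
    year = 2000, fertilizer = 500, manure = 300, wastewater = 10,
    fixation = 200, atmospheric_deposition_oxidized = 100,
    crop_uptake = 600, n2o_emission = 8, n2_emission = 13.6,
    river_emission = 50), "N")
  expect_equal(compute_balance(comp3)$value, 438.4)

  # inputs equal outputs exactly -> 0
  comp4 <- balance_components(data.frame(
    year = 2000, fertilizer = 500, manure = 300, wastewater = 10,
    fixation = 200, atmospheric_deposition_oxidized = 100,
    crop_uptake = 974.4), "N")
  expect_equal(compute_balance(comp4)$value, 0)
})

test_that("the P balance defaults weathering to 7.16", {
  comp <- balance_components(data.frame(
    year = 2000:2002, fertilizer = 0, manure = 0, wastewater = 0,
    crop_uptake = 0), "P")
  expect_equal(compute_balance(comp)$value, rep(7.16, 3))
})

test_that("balance conserves mass and is monotone in its components", {
  set.seed(42)
  yrs <- 1990:1999
  df <- data.frame(year = yrs,
                   fertilizer = runif(10, 100, 2000),
                   manure = runif(10, 100, 2000),
                   wastewater = runif(10, 0, 50),
                   fixation = runif(10, 100, 2000),
                   atmospheric_deposition_oxidized = runif(10, 50, 600),
                   crop_uptake = runif(10, 500, 4000))
  comp <- balance_components(df, "N")
  bal <- compute_balance(comp, quiet = TRUE)
  inputs <- with(df, fertilizer + manure + wastewater + fixation +
                   atmospheric_deposition_oxidized)
  n2o <- 0.01 * (df$fertilizer + df$manure)
  outputs <- df$crop_uptake + n2o + 1.7 * n2o + 114
  expect_equal(bal$value + outputs - inputs, rep(0, 10))

  # finite-difference monotonicity: up in each input, down in each output
  for (cc in c("fertilizer", "manure", "wastewater", "fixation",
               "atmospheric_deposition_oxidized")) {
    df2 <- df
    df2[[cc]] <- df2[[cc]] + 10
    expect_true(all(compute_balance(balance_components(df2, "N"),
                                    quiet = TRUE)$value > bal$value),
                info = cc)
  }
  df2 <- df
  df2$crop_uptake <- df2$crop_uptake + 10
  expect_true(all(compute_balance(balance_components(df2, "N"),
                                  quiet = TRUE)$value < bal$value))
})

test_that("the 19%-of-delivery riverine emission path is available", {
  comp <- balance_components(data.frame(
    year = 2000, fertilizer = 1000, manure = 0, wastewater = 0,
    fixation = 0, atmospheric_deposition_oxidized = 0,
    crop_uptake = 500), "N")
  # delivery = 1000 - (500 + 10 + 17) = 473; emission = 0.19*473 = 89.87
  bal <- compute_balance(comp, river_emission_rate = 0.19, quiet = TRUE)
  expect_equal(bal$value, 473 - 0.19 * 473)
})

test_that("component tables are validated", {
  expect_error(balance_components(
    data.frame(year = c(2000, 2002), fertilizer = 1), "N"), "gaps")
  expect_error(balance_components(
    data.frame(year = 2000, fertilizer = -1), "N"), "negative")
  expect_error(balance_components(
    data.frame(year = 2000, weathering = 1), "N"), "other nutrient")
  expect_error(balance_components(
    data.frame(year = 2000, fixation = 1), "P"), "other nutrient")
  expect_error(compute_balance(balance_components(
    data.frame(year = 2000, fertilizer = 1, manure = 1), "N")),
    "missing N component")
  expect_message(compute_balance(balance_components(
    data.frame(year = 2000, fertilizer = 0, manure = 0, wastewater = 0,
               fixation = 0, atmospheric_deposition_oxidized = 0,
               crop_uptake = 0), "N")), "negative")
  # farm/nonfarm fertilizer split is summed on construction
  comp <- balance_components(data.frame(
    year = 2000, fertilizer_farm = 300, fertilizer_nonfarm = 200,
    manure = 0, wastewater = 0, fixation = 0,
    atmospheric_deposition_oxidized = 0, crop_uptake = 0), "N")
  expect_equal(comp$fertilizer, 500)
})
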