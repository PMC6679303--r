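test_that("thermal-time phenology accumulates and caps at maturity", {
  crop <- crop_params(TSUM1 = 1000, TSUM2 = 800, TBASEM = 5)
  st <- init_crop_state(crop, base_soil)

  # daily mean equal to the base temperature leaves development unchanged
  st2 <- update_phenology(st, crop, make_wd(tmin = 0, tmax = 10))
  expect_identical(st2$dvs, st$dvs)
  expect_identical(st2$tsum, st$tsum)

  # constant 20 degC mean, TBASEM 0: dvs reaches exactly 1 on day 50
  crop0 <- crop_params(TSUM1 = 1000, TSUM2 = 800, TBASEM = 0)
  st <- init_crop_state(crop0, base_soil)
  wd <- make_wd(tmin = 15, tmax = 25)
  for (d in 1:49) st <- update_phenology(st, crop0, wd)
  expect_lt(st$dvs, 1)
  st <- update_phenology(st, crop0, wd)
  expect_equal(st$dvs, 1, tolerance = 1e-12)

  # dvs is non-decreasing and capped at 2 (maturity)
  prev <- st$dvs
  for (d in 1:200) {
    st <- update_phenology(st, crop0, wd)
    expect_gte(st$dvs, prev)
    prev <- st$dvs
  }
  expect_equal(st$dvs, 2)
})

test_that("leaf cohorts age, senesce past SPAN, and stall below TBASE", {
  crop <- crop_params(SPAN = 20, TBASE = 2)
  st <- init_crop_state(crop, base_soil)
  st$lv <- c(100, 50); st$lvage <- c(20.001, 1); st$sla <- c(0.002, 0.002)
  st$wlv <- 150; st$lai <- sum(st$lv * st$sla)

  # cold day: nothing ages (an over-aged cohort still dies, ages do not move)
  young <- st
  young$lvage <- c(15, 1)
  cold <- update_leaves(young, crop, make_wd(tmin = -4, tmax = 2), 0)
  expect_equal(cold$lvage, young$lvage)
  expect_equal(cold$lai, young$lai)

  # warm day: the over-aged cohort dies and LAI drops by weight * sla
  warm <- update_leaves(st, crop, make_wd(tmin = 10, tmax = 20), 0)
  expect_length(warm$lv, 1)
  expect_equal(warm$wlv, 50)
  expect_equal(warm$lai, 50 * 0.002)

  expect_error(update_leaves(st, crop, make_wd(), -1), "negative")
})

test_that("juvenile canopy expansion is capped at the exponential rate", {
  # RGRLAI * dTeff = 0.005 * 10 = 0.05 with TBASE 0 and Tmean 10
  crop <- crop_params(RGRLAI = 0.005, TBASE = 0, SPAN = 40)
  st <- init_crop_state(crop, base_soil)
  sla <- pw_lookup(crop$SLATB, 0)
  st$lv <- 0.1 / sla; st$lvage <- 1; st$sla <- sla
  st$wlv <- st$lv; st$lai <- 0.1
  out <- update_leaves(st, crop, make_wd(tmin = 5, tmax = 15),
                       new_leaf_dw = 1e6)
  expect_lte(out$lai, 0.1 * exp(0.05) + 1e-10)
  expect_equal(out$lai, 0.1 * exp(0.05), tolerance = 1e-8)
})

test_that("soil water balance closes and respects physical bounds", {
  soil <- base_soil
  st <- init_crop_state(base_crop, soil)

  # zero-flux day below field capacity leaves moisture unchanged
  st$sm <- soil$SMFCF - 0.05
  out <- update_soil_water(st, soil, make_wd(rain = 0), 0, 0)
  expect_equal(out$state$sm, soil$SMFCF - 0.05)

  # heavy rain saturates the bucket and produces runoff
  out <- update_soil_water(st, soil, make_wd(rain = 500), 0, 0)
  expect_equal(out$state$sm, soil$SM0)
  expect_gt(out$fluxes$runoff, 0)

  # every random day closes the balance identically
  set.seed(11)
  for (i in 1:200) {
    st$sm <- runif(1, soil$SMW, soil$SM0)
    wd <- make_wd(rain = rexp(1, 1 / 5) * rbinom(1, 1, 0.4),
                  irrigation = 50 * rbinom(1, 1, 0.05))
    out <- update_soil_water(st, soil, wd, runif(1, 0, 0.3), runif(1, 0, 0.6))
    f <- out$fluxes
    resid <- f$infil - f$e_act - f$t_act - f$percolation - f$runoff - f$dW
    expect_lt(abs(resid), 1e-9)
    expect_gte(out$state$sm, soil$SMW)
    expect_lte(out$state$sm, soil$SM0)
  }

  expect_error(update_soil_water(st, soil, make_wd(), -0.1, 0), ">= 0")
})

test_that("growth needs canopy, light and water", {
  st <- init_crop_state(base_crop, base_soil)
  st$lv <- numeric(0); st$lvage <- numeric(0); st$sla <- numeric(0)
  st$lai <- 0; st$wlv <- 0
  # no canopy -> no interception -> no growth
  g <- daily_growth(st, base_crop, make_wd(radiation = 20), 1)
  expect_equal(g$new_leaf_dw, 0)
  expect_equal(g$state$wso, 0)

  # full stress -> no new biomass
  st2 <- init_crop_state(base_crop, base_soil)
  g0 <- daily_growth(st2, base_crop, make_wd(radiation = 20), 0)
  expect_equal(g0$state$tagp, st2$tagp)
  expect_equal(g0$new_leaf_dw, 0)

  # past maturity growth stops entirely
  st2$dvs <- 2
  gm <- daily_growth(st2, base_crop, make_wd(radiation = 20), 1)
  expect_identical(gm$state$wso, st2$wso)
  expect_error(daily_growth(st2, base_crop, make_wd(), 1.2), "water_stress")
})

test_that("advance_day is deterministic and keeps mass and moisture invariants", {
  st1 <- init_crop_state(base_crop, base_soil)
  st2 <- init_crop_state(base_crop, base_soil)
  for (i in 1:60) {
    wd <- list(tmin = season_weather$tmin[i], tmax = season_weather$tmax[i],
               rain = season_weather$rain[i],
               irrigation = season_weather$irrigation[i],
               radiation = season_weather$radiation[i])
    st1 <- advance_day(st1, base_crop, base_soil, wd)
    st2 <- advance_day(st2, base_crop, base_soil, wd)
    expect_identical(st1, st2)
    expect_equal(st1$tagp, st1$wlv + st1$wst + st1$wso, tolerance = 1e-10)
    expect_gte(st1$sm, base_soil$SMW)
    expect_lte(st1$sm, base_soil$SM0)
    expect_gte(min(st1$wlv, st1$wst, st1$wso, st1$wrt), 0)
  }
})

test_that("a watered season never yields less than the same season dried out", {
  for (s in 1:10) {
    wx <- generate_weather(base_climate, "2016-10-10", 255, seed = 100 + s)
    dry <- wx
    dry$rain <- 0
    dry$irrigation <- 0
    y_wet <- run_season(base_crop, base_soil, wx)$yield_kg_ha
    y_dry <- run_season(base_crop, base_soil, dry)$yield_kg_ha
    expect_gte(y_wet, y_dry)
  }
})

test_that("run_season initialises from TDWI and WAV and records the full window", {
  # no seed biomass: the canopy never forms and yield is zero
  res0 <- run_season(crop_params(TDWI = 0), base_soil, season_weather)
  expect_equal(max(res0$trajectory$lai), 0)
  expect_equal(res0$yield_kg_ha, 0)

  # initial available water at (SMFCF - SMW) * RD puts sm exactly at SMFCF
  soil <- soil_params(WAV = (base_soil$SMFCF - base_soil$SMW) * base_soil$RD)
  st <- init_crop_state(base_crop, soil)
  expect_equal(st$sm, soil$SMFCF)

  res <- run_season(base_crop, base_soil, season_weather)
  expect_equal(nrow(res$trajectory), nrow(season_weather))
  expect_true(all(res$trajectory$sm >= base_soil$SMW - 1e-12))
  expect_true(all(res$trajectory$sm <= base_soil$SM0 + 1e-12))
  expect_true(all(diff(res$trajectory$dvs) >= 0))
  expect_true(all(diff(res$trajectory$wso) >= -1e-9))

  expect_error(run_season(base_crop, base_soil, season_weather,
                          sowing_day = "2015-01-01"), "sowing")
})

test_that("parameter constructors reject inconsistent inputs", {
  expect_error(soil_params(SMW = 0.3, SMFCF = 0.2), "SMW < SMFCF")
  expect_error(soil_params(WAV = 1e4), "WAV")
  expect_error(crop_params(SPAN = -1), "non-negative|SPAN")
  bad_fltb <- list(c(0, 0.9), c(2, 0.9))
  expect_error(crop_params(FLTB = bad_fltb), "sum to 1")
  expect_error(pw_table(list(c(1, 0), c(1, 1))), "increasing")
})
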