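test_that("ensemble building perturbs exactly the requested targets", {
  cfg <- scheme_config("open_loop", seed = 31)
  members <- build_ensemble(base_crop, base_soil, cfg)
  expect_length(members, 50)

  tdwi <- vapply(members, function(m) m$crop$TDWI, 0)
  expect_gt(sd(tdwi), 0)
  # soil ordering survives perturbation in every member
  for (m in members) {
    expect_true(m$soil$SMW < m$soil$SMFCF)
    expect_true(m$soil$SMFCF < m$soil$SM0)
    expect_lt(m$soil$SM0, 1)
    expect_lte(m$soil$WAV, (m$soil$SM0 - m$soil$SMW) * m$soil$RD)
  }
  # unperturbed parameters stay at base values
  expect_true(all(vapply(members, function(m) m$crop$TSUM1, 0) ==
                    base_crop$TSUM1))

  # zero spread: members identical to base
  cfg0 <- scheme_config("open_loop", ensemble_size = 5,
                        perturbations = data.frame(
                          target = c("TDWI", "WAV"), rel_sd = 0),
                        seed = 31)
  m0 <- build_ensemble(base_crop, base_soil, cfg0)
  expect_true(all(vapply(m0, function(m) m$crop$TDWI, 0) == base_crop$TDWI))
  expect_true(all(vapply(m0, function(m) m$soil$WAV, 0) == base_soil$WAV))

  # reproducible: same config, same members
  m1 <- build_ensemble(base_crop, base_soil, cfg)
  expect_identical(members[[7]], m1[[7]])

  # sampling check of the relative spread at large Ne
  cfgN <- scheme_config("open_loop", ensemble_size = 10000,
                        perturbations = data.frame(target = "TDWI",
                                                   rel_sd = 0.10),
                        seed = 2)
  mN <- build_ensemble(base_crop, base_soil, cfgN)
  tdwiN <- vapply(mN, function(m) m$crop$TDWI, 0)
  expect_equal(sd(tdwiN) / mean(tdwiN), 0.10, tolerance = 0.05)

  expect_error(build_ensemble(base_crop, base_soil,
                              scheme_config(perturbations = data.frame(
                                target = "NOPE", rel_sd = 0.1))),
               "unknown perturbation target")
})

test_that("observation variance follows the stated relative-error rule", {
  expect_equal(observation_variance(list(value = 4.0, rel_error = 0.10)), 0.16)
  expect_equal(sqrt(observation_variance(list(value = 0.20, rel_error = 0.35))),
               0.07)
  expect_equal(observation_variance(list(value = 0, rel_error = 0.35)), 0)
})

test_that("state reconciliation keeps the crop state self-consistent", {
  st <- init_crop_state(base_crop, base_soil)
  for (i in 1:120) {
    wd <- list(tmin = season_weather$tmin[i], tmax = season_weather$tmax[i],
               rain = season_weather$rain[i],
               irrigation = season_weather$irrigation[i],
               radiation = season_weather$radiation[i])
    st <- advance_day(st, base_crop, base_soil, wd)
  }

  # identity update leaves the state numerically unchanged
  same <- reconcile_state(st, c(LAI = st$lai, SM = st$sm),
                          base_crop, base_soil)
  expect_equal(same$lv, st$lv)
  expect_equal(same$sm, st$sm)
  expect_equal(same$tagp, st$tagp)

  # halving LAI halves every cohort and the leaf pool
  half <- reconcile_state(st, c(LAI = st$lai / 2, SM = st$sm),
                          base_crop, base_soil)
  expect_equal(half$lv, st$lv / 2)
  expect_equal(half$wlv, st$wlv / 2)
  expect_equal(half$lai, st$lai / 2)
  expect_equal(half$tagp, half$wlv + half$wst + half$wso)
  expect_equal(half$lai, sum(half$lv * half$sla))

  # nonphysical targets are clamped to the physical ranges
  cl <- reconcile_state(st, c(LAI = -2, SM = 0.9), base_crop, base_soil)
  expect_equal(cl$lai, 0)
  expect_equal(cl$sm, base_soil$SM0)

  # an empty canopy regrows one fresh cohort when the filter demands leaf area
  bare <- st
  bare$lv <- numeric(0); bare$lvage <- numeric(0); bare$sla <- numeric(0)
  bare$lai <- 0; bare$wlv <- 0
  re <- reconcile_state(bare, c(LAI = 0.5, SM = st$sm),
                        base_crop, base_soil)
  expect_length(re$lv, 1)
  expect_equal(re$lai, 0.5)
  expect_equal(re$lvage, 0)
})

test_that("schemes assimilate exactly their own observation streams", {
  wx <- short_weather(n = 75, seed = 19)
  plan <- observation_plan(
    lai_dates = as.Date(c("2017-03-20", "2017-04-10", "2017-05-01")),
    sm_dates = as.Date(c("2017-03-25", "2017-04-10", "2017-05-05")))
  tw <- generate_twin(base_crop, base_soil, wx, plan, seed = 5)

  ol <- run_scheme(scheme_config("open_loop", ensemble_size = 8, seed = 77),
                   base_crop, base_soil, wx, tw$observations)
  expect_equal(nrow(ol$diagnostics), 0)

  # joint with no observations reproduces the open loop exactly
  j0 <- run_scheme(scheme_config("joint", ensemble_size = 8, seed = 77),
                   base_crop, base_soil, wx, tw$observations[0, ])
  expect_identical(j0$yields, ol$yields)
  expect_identical(j0$trajectory$lai, ol$trajectory$lai)

  # LAI-only never touches SM records
  la <- run_scheme(scheme_config("lai", ensemble_size = 8, seed = 77),
                   base_crop, base_soil, wx, tw$observations)
  expect_true(all(la$diagnostics$variable == "LAI"))
  expect_equal(nrow(la$diagnostics), 3)

  # joint stacks same-date LAI and SM into one analysis event
  jt <- run_scheme(scheme_config("joint", ensemble_size = 8, seed = 77),
                   base_crop, base_soil, wx, tw$observations)
  ev_apr10 <- jt$diagnostics[jt$diagnostics$date == as.Date("2017-04-10"), ]
  expect_setequal(ev_apr10$variable, c("LAI", "SM"))
  expect_equal(length(unique(ev_apr10$event)), 1)

  # observations outside the weather window are refused
  bad <- data.frame(date = as.Date("2018-01-01"), variable = "LAI",
                    value = 1, rel_error = 0.1)
  expect_error(run_scheme(scheme_config("lai", ensemble_size = 8), base_crop,
                          base_soil, wx, bad), "outside")

  # bitwise reproducibility of a full assimilation run
  jt2 <- run_scheme(scheme_config("joint", ensemble_size = 8, seed = 77),
                    base_crop, base_soil, wx, tw$observations)
  expect_identical(jt$yields, jt2$yields)
  expect_identical(jt$diagnostics, jt2$diagnostics)
})

test_that("assimilating the ensemble's own mean stays close to the open loop", {
  wx <- short_weather(n = 75, seed = 23)
  cfg_ol <- scheme_config("open_loop", ensemble_size = 12, seed = 55)
  ol <- run_scheme(cfg_ol, base_crop, base_soil, wx)
  dates <- as.Date(c("2017-04-01", "2017-04-20", "2017-05-05"))
  self_obs <- data.frame(
    date = rep(dates, 2),
    variable = rep(c("LAI", "SM"), each = 3),
    value = c(ol$trajectory$lai[match(dates, ol$trajectory$date)],
              ol$trajectory$sm[match(dates, ol$trajectory$date)]),
    rel_error = 1e-6)
  da <- run_scheme(scheme_config("joint", ensemble_size = 12, seed = 55),
                   base_crop, base_soil, wx, self_obs)
  rel_dev <- abs(da$trajectory$lai - ol$trajectory$lai) /
    pmax(ol$trajectory$lai, 0.5)
  expect_lt(max(rel_dev), 0.05)
  expect_lt(abs(da$yield_mean - ol$yield_mean) / ol$yield_mean, 0.05)
})

test_that("assimilating LAI improves the tracked LAI in a twin experiment", {
  errs <- vapply(1:5, function(s) {
    ex <- run_twin_experiment(700 + s, ensemble_size = 20,
                              schemes = c("open_loop", "lai"))
    tt <- ex$truth$trajectory
    dates <- ex$observations$date[ex$observations$variable == "LAI"]
    idx <- match(dates, tt$date)
    ol_err <- mean(abs(ex$results$open_loop$trajectory$lai[idx] -
                         tt$lai[idx]))
    da_err <- mean(abs(ex$results$lai$trajectory$lai[idx] - tt$lai[idx]))
    c(ol = ol_err, da = da_err)
  }, c(ol = 0, da = 0))
  expect_lt(median(errs["da", ]), median(errs["ol", ]))
})
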