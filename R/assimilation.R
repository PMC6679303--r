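#' Assimilation experiment configuration
#'
#' One experiment definition: which scheme runs, the ensemble size, which
#' parameters/initial values are perturbed and by how much, the observation
#' relative errors, and the master seed. Ensemble size 50 and 10%
#' perturbations of TDWI, WAV, RGRLAI, SPAN, SMFCF and SM0 are the study
#' defaults.
#'
#' @param scheme one of `"open_loop"`, `"lai"`, `"sm"`, `"joint"`.
#' @param ensemble_size number of members (>= 2).
#' @param perturbations data.frame `target,rel_sd`; targets must be fields of
#'   the crop or soil parameter sets.
#' @param obs_rel_error named vector of default relative observation errors.
#' @param obs_var_floor named vector of observation-variance floors per
#'   variable. Relative errors make R proportional to the observed value
#'   squared, so a near-zero retrieval would claim near-perfect certainty and
#'   the gain would slam the whole ensemble onto it; the floors (s.d. 0.1 for
#'   LAI, 0.04 cm3 cm-3 for SM, below the absolute noise floor of optical LAI
#'   and C-band SM retrievals) keep such an observation informative but not
#'   dictatorial.
#' @param seed master integer seed; split internally into independent streams
#'   for ensemble generation and observation perturbation so different
#'   schemes share identical ensembles.
#' @param sowing_day sowing date (or `NULL` for the first weather day).
#' @return a `scheme_config` list.
#' @export
scheme_config <- function(scheme = c("open_loop", "lai", "sm", "joint"),
                          ensemble_size = 50,
                          perturbations = default_perturbations(),
                          obs_rel_error = c(LAI = 0.10, SM = 0.35),
                          obs_var_floor = c(LAI = 0.01, SM = 1.6e-3),
                          seed = 1L,
                          sowing_day = NULL) {
  scheme <- match.arg(scheme)
  if (ensemble_size < 2) stop("ensemble_size must be >= 2")
  if (any(perturbations$rel_sd < 0)) stop("rel_sd must be >= 0")
  if (any(obs_rel_error < 0)) stop("obs_rel_error must be >= 0")
  if (any(obs_var_floor < 0)) stop("obs_var_floor must be >= 0")
  structure(list(scheme = scheme, ensemble_size = as.integer(ensemble_size),
                 perturbations = perturbations,
                 obs_rel_error = obs_rel_error,
                 obs_var_floor = obs_var_floor,
                 seed = as.integer(seed), sowing_day = sowing_day),
            class = "scheme_config")
}

#' Default perturbation specification
#'
#' The two perturbed initial values (TDWI, WAV), the two LAI-sensitive
#' parameters (RGRLAI, SPAN) and the two SM-sensitive parameters
#' (SMFCF, SM0), each with Gaussian relative s.d. 0.10.
#'
#' @return data.frame `target,rel_sd`.
#' @export
default_perturbations <- function() {
  data.frame(target = c("TDWI", "WAV", "RGRLAI", "SPAN", "SMFCF", "SM0"),
             rel_sd = 0.10)
}

# deterministic per-purpose sub-seeds from one master seed
derive_seeds <- function(master, n = 6L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

#' Build a perturbed parameter ensemble
#'
#' Draws `ensemble_size` members around the base crop/soil parameter sets.
#' Each perturbed target is `N(base, (rel_sd * base)^2)`, redrawn (up to 100
#' times) until positive and, for the soil retention triplet, ordered
#' `SMW < SMFCF < SM0 < 1` within each member; `WAV` is kept inside its
#' feasible range. Seeded and reproducible: the same config gives the same
#' members regardless of scheme.
#'
#' @param base_crop,base_soil base parameter sets.
#' @param config a [scheme_config()].
#' @return list of members, each `list(crop, soil, state)` with the state
#'   initialised by [init_crop_state()].
#' @export
build_ensemble <- function(base_crop, base_soil, config) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[1])
  pert <- config$perturbations
  members <- vector("list", config$ensemble_size)
  for (i in seq_len(config$ensemble_size)) {
    cp <- base_crop
    sp <- base_soil
    for (j in seq_len(nrow(pert))) {
      tg <- pert$target[j]
      sd_j <- pert$rel_sd[j]
      if (tg %in% names(cp)) {
        cp[[tg]] <- truncated_gauss(cp[[tg]], sd_j * cp[[tg]])
      } else if (tg %in% names(sp)) {
        sp[[tg]] <- truncated_gauss(sp[[tg]], sd_j * sp[[tg]])
      } else {
        stop("unknown perturbation target: ", tg)
      }
    }
    # keep the retention ordering and WAV feasibility per member
    tries <- 0L
    while (!(sp$SMW < sp$SMFCF && sp$SMFCF < sp$SM0 && sp$SM0 < 1)) {
      tries <- tries + 1L
      if (tries > 100L) stop("soil retention ordering failed after 100 redraws")
      if ("SMFCF" %in% pert$target) {
        sp$SMFCF <- truncated_gauss(base_soil$SMFCF,
                                    pert$rel_sd[pert$target == "SMFCF"] *
                                      base_soil$SMFCF)
      }
      if ("SM0" %in% pert$target) {
        sp$SM0 <- truncated_gauss(base_soil$SM0,
                                  pert$rel_sd[pert$target == "SM0"] *
                                    base_soil$SM0)
      }
    }
    sp$WAV <- min(sp$WAV, (sp$SM0 - sp$SMW) * sp$RD)
    members[[i]] <- list(crop = cp, soil = sp,
                         state = init_crop_state(cp, sp))
  }
  members
}

#' Observation error variance
#'
#' The observation error is stated as a relative magnitude, so the variance
#' is `(rel_error * value)^2`. A zero value gives zero variance here; where
#' the variance enters the filter's innovation covariance a floor of 1e-6 is
#' applied (see [run_scheme()]) so the gain stays computable.
#'
#' @param rec one observation record (list or one-row data.frame with
#'   `value` and `rel_error`).
#' @return the error variance.
#' @export
observation_variance <- function(rec) {
  (rec$rel_error * rec$value)^2
}

.OBS_VAR_FLOOR <- 1e-6

#' Push a filter update back into the full crop state
#'
#' The filter only updates the `(LAI, SM)` subvector; the rest of the crop
#' state must follow consistently. SM is overwritten (clamped to the
#' member's `[SMW, SM0]`); leaf cohorts are rescaled multiplicatively by
#' `LAI_new / LAI_old` so `sum(lv * sla)` equals the updated LAI, with `wlv`
#' and `tagp` adjusted. If the canopy was empty and the update demands leaf
#' area, one fresh cohort is created at the current specific leaf area.
#'
#' @param member_state a `crop_state`.
#' @param updated named vector with elements `LAI` and `SM`.
#' @param crop,soil the member's parameter sets.
#' @return the reconciled `crop_state`.
#' @export
reconcile_state <- function(member_state, updated, crop, soil) {
  st <- member_state
  st$sm <- min(soil$SM0, max(soil$SMW, updated[["SM"]]))
  lai_new <- max(0, updated[["LAI"]])
  lai_old <- st$lai
  if (lai_old > 0) {
    f <- lai_new / lai_old
    st$lv <- st$lv * f
  } else if (lai_new > 0) {
    sla <- pw_lookup(crop$SLATB, st$dvs)
    st$lv <- lai_new / sla
    st$lvage <- 0
    st$sla <- sla
  }
  st$wlv <- sum(st$lv)
  st$lai <- sum(st$lv * st$sla)
  st$tagp <- st$wlv + st$wst + st$wso
  st
}

#' Run one assimilation scheme over a season
#'
#' Propagates the ensemble day by day through the crop model; at each
#' observation date matching the scheme (LAI records for `"lai"`, SM records
#' for `"sm"`, both for `"joint"`, none for `"open_loop"`), performs one
#' perturbed-observation EnKF analysis on the stacked `(LAI, SM)` state —
#' observations sharing a date form one observation vector with diagonal R —
#' and reconciles every member. No process noise is added (model structural
#' and input uncertainty are taken as zero); ensemble spread comes from the
#' parameter/initial-condition perturbations.
#'
#' @param config a [scheme_config()].
#' @param crop,soil base parameter sets.
#' @param weather weather data.frame covering the season.
#' @param observations data.frame `date,variable,value,rel_error` (may be
#'   empty or NULL; `rel_error` defaulted from the config).
#' @return an `assim_result`: `scheme`, `trajectory` (daily ensemble mean and
#'   s.d. of LAI and SM, plus the base-parameter open-loop run `lai_base`,
#'   `sm_base`), `diagnostics` (one row per analysis event and variable:
#'   `event,date,variable,prior_mean,prior_var,gain,post_mean,post_var`),
#'   `yields` (per member), `yield_mean`, `yield_sd`, and `truth`-comparable
#'   metadata (`dates`).
#' @export
run_scheme <- function(config, crop, soil, weather, observations = NULL) {
  weather <- validate_weather(weather)
  sowing <- if (is.null(config$sowing_day)) weather$date[1] else
    as.Date(config$sowing_day)
  wx <- weather[weather$date >= sowing, , drop = FALSE]
  if (!nrow(wx)) stop("weather window empty from the sowing day")
  obs <- observations
  keep_vars <- switch(config$scheme,
                      open_loop = character(0),
                      lai = "LAI", sm = "SM", joint = c("LAI", "SM"))
  if (is.null(obs) || !nrow(obs)) {
    obs <- data.frame(date = as.Date(character(0)), variable = character(0),
                      value = numeric(0), rel_error = numeric(0))
  }
  obs$date <- as.Date(obs$date)
  if (nrow(obs) && is.null(obs$rel_error)) {
    obs$rel_error <- config$obs_rel_error[obs$variable]
  }
  obs <- obs[obs$variable %in% keep_vars, , drop = FALSE]
  if (nrow(obs) && (min(obs$date) < wx$date[1] || max(obs$date) > wx$date[nrow(wx)])) {
    stop("observation date outside the simulated weather window")
  }
  seeds <- derive_seeds(config$seed)
  members <- build_ensemble(crop, soil, config)
  ne <- length(members)
  n_days <- nrow(wx)
  lai_mean <- lai_sd <- sm_mean <- sm_sd <- numeric(n_days)
  diag_rows <- list()
  event <- 0L
  obs_by_date <- if (nrow(obs)) split(obs, obs$date) else list()
  tminv <- wx$tmin; tmaxv <- wx$tmax; rainv <- wx$rain
  irrv <- wx$irrigation; radv <- wx$radiation; dates <- wx$date
  date_keys <- as.character(dates)
  for (i in seq_len(n_days)) {
    wd <- list(tmin = tminv[i], tmax = tmaxv[i], rain = rainv[i],
               irrigation = irrv[i], radiation = radv[i])
    for (k in seq_len(ne)) {
      members[[k]]$state <- advance_day(members[[k]]$state,
                                        members[[k]]$crop,
                                        members[[k]]$soil, wd)
    }
    todays <- obs_by_date[[date_keys[i]]]
    if (!is.null(todays)) {
      event <- event + 1L
      X <- cbind(LAI = vapply(members, function(m) m$state$lai, 0),
                 SM = vapply(members, function(m) m$state$sm, 0))
      floors <- config$obs_var_floor[todays$variable]
      floors[is.na(floors)] <- .OBS_VAR_FLOOR
      vars <- pmax(vapply(seq_len(nrow(todays)), function(j)
        observation_variance(todays[j, ]), 0), floors, .OBS_VAR_FLOOR)
      ov <- obs_vector(todays$value, todays$variable, vars)
      Xa <- enkf_analysis(X, ov, rng_seed = seeds[2] %% 900000000L + event,
                          diagnostics = TRUE)
      dg <- attr(Xa, "diagnostics")
      for (k in seq_len(ne)) {
        members[[k]]$state <- reconcile_state(
          members[[k]]$state, Xa[k, ], members[[k]]$crop, members[[k]]$soil)
      }
      for (v in todays$variable) {
        gv <- dg$gain[v, todays$variable == v, drop = TRUE][1]
        diag_rows[[length(diag_rows) + 1L]] <- data.frame(
          event = event, date = dates[i], variable = v,
          prior_mean = dg$prior_mean[[v]], prior_var = dg$prior_var[[v]],
          gain = gv, post_mean = dg$post_mean[[v]],
          post_var = dg$post_var[[v]])
      }
    }
    lai_k <- vapply(members, function(m) m$state$lai, 0)
    sm_k <- vapply(members, function(m) m$state$sm, 0)
    lai_mean[i] <- mean(lai_k); lai_sd[i] <- stats::sd(lai_k)
    sm_mean[i] <- mean(sm_k); sm_sd[i] <- stats::sd(sm_k)
  }
  base_run <- run_season(crop, soil, wx)
  yields <- vapply(members, function(m) m$state$wso, 0)
  res <- list(
    scheme = config$scheme,
    trajectory = data.frame(
      day = seq_len(n_days) - 1L, date = dates,
      lai = lai_mean, lai_sd = lai_sd, sm = sm_mean, sm_sd = sm_sd,
      lai_base = base_run$trajectory$lai, sm_base = base_run$trajectory$sm),
    diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows) else
      data.frame(event = integer(0), date = as.Date(character(0)),
                 variable = character(0), prior_mean = numeric(0),
                 prior_var = numeric(0), gain = numeric(0),
                 post_mean = numeric(0), post_var = numeric(0)),
    yields = yields,
    yield_mean = mean(yields),
    yield_sd = stats::sd(yields),
    yield_base = base_run$yield_kg_ha,
    config = config)
  class(res) <- "assim_result"
  res
}

#' @export
print.assim_result <- function(x, ...) {
  cat(sprintf("Assimilation scheme '%s': %d members, %d analysis events\n",
              x$scheme, x$config$ensemble_size,
              length(unique(x$diagnostics$event))))
  cat(sprintf("  yield %.0f +/- %.0f kg/ha (base run %.0f)\n",
              x$yield_mean, x$yield_sd, x$yield_base))
  invisible(x)
}

#' Write per-event filter diagnostics to CSV
#'
#' Columns `event,date,variable,prior_mean,prior_var,gain,post_mean,post_var`.
#'
#' @param result an `assim_result`.
#' @param path output CSV path.
#' @export
write_diagnostics_csv <- function(result, path) {
  utils::write.csv(result$diagnostics, path, row.names = FALSE, quote = FALSE)
}
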