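#' Initial crop state
#'
#' Builds the state at sowing/emergence. The initial dry weight `TDWI` is
#' split 50% roots, 30% leaves, 20% stems; the leaf share forms one cohort of
#' age zero with the current specific leaf area. Initial soil moisture comes
#' from the initial available water: `sm = SMW + WAV / RD`.
#'
#' @param crop a [crop_params()] set.
#' @param soil a [soil_params()] set.
#' @return a `crop_state` list with components `dvs`, `tsum`, leaf cohort
#'   vectors (`lv` weights, `lvage` ages, `sla`), `lai`, biomass pools
#'   (`wlv`, `wst`, `wso`, `wrt`, `tagp`), `sm` and `day_index`.
#' @export
init_crop_state <- function(crop, soil) {
  wlv <- 0.30 * crop$TDWI
  wst <- 0.20 * crop$TDWI
  wrt <- 0.50 * crop$TDWI
  sla0 <- pw_lookup(crop$SLATB, 0)
  has_leaf <- wlv > 0
  st <- list(
    dvs = 0, tsum = 0, day_index = 0L,
    lv = if (has_leaf) wlv else numeric(0),
    lvage = if (has_leaf) 0 else numeric(0),
    sla = if (has_leaf) sla0 else numeric(0),
    lai = wlv * sla0,
    wlv = wlv, wst = wst, wso = 0, wrt = wrt,
    tagp = wlv + wst,
    sm = min(soil$SM0, soil$SMW + soil$WAV / soil$RD)
  )
  class(st) <- "crop_state"
  st
}

#' Advance phenological development by one day
#'
#' Thermal time accumulates as `max(0, Tmean - TBASEM)`; development stage is
#' `tsum / TSUM1` before anthesis and `1 + (tsum - TSUM1) / TSUM2` after,
#' capped at 2 (maturity). DVS is 0 at emergence, 1 at anthesis, 2 at
#' maturity.
#'
#' @param state a `crop_state`.
#' @param crop crop parameters.
#' @param wd one weather row (list or one-row data.frame).
#' @return updated state.
#' @export
update_phenology <- function(state, crop, wd) {
  tmean <- (wd$tmin + wd$tmax) / 2
  state$tsum <- state$tsum + max(0, tmean - crop$TBASEM)
  dvs <- if (state$tsum < crop$TSUM1) {
    state$tsum / crop$TSUM1
  } else {
    1 + (state$tsum - crop$TSUM1) / crop$TSUM2
  }
  state$dvs <- min(2, dvs)
  state
}

#' Age, senesce and grow leaf cohorts
#'
#' Cohorts age by `max(0, Tmean - TBASE) / (35 - TBASE)` physiological days,
#' so a leaf held at 35 degC lives exactly `SPAN` days; cohorts older than
#' `SPAN` die and their weight leaves the canopy. Hard frost kills a fraction
#' of every cohort, rising linearly from 0 at `frost_tcrit` to total loss
#' `frost_trange` degrees below it — winter wheat canopies thin over winter
#' and regrow in spring. New leaf mass enters as a fresh cohort at the
#' current specific leaf area. Throughout the vegetative expansion phase
#' (DVS < 1 and LAI < 6) canopy growth is capped at the exponential rate
#' `lai * (exp(RGRLAI * dTeff) - 1)`, so `RGRLAI` governs regrowth whenever
#' the canopy is small; beyond that window growth is source-limited only.
#'
#' @param state a `crop_state`.
#' @param crop crop parameters.
#' @param wd one weather row.
#' @param new_leaf_dw newly partitioned leaf dry matter (kg ha-1 d-1).
#' @return updated state with `lai = sum(lv * sla)` restored.
#' @export
update_leaves <- function(state, crop, wd, new_leaf_dw) {
  if (new_leaf_dw < 0) stop("negative leaf growth: partitioning bug upstream")
  tmean <- (wd$tmin + wd$tmax) / 2
  teff <- max(0, tmean - crop$TBASE)
  if (length(state$lv)) {
    if (wd$tmin < crop$frost_tcrit) {
      kill <- min(1, (crop$frost_tcrit - wd$tmin) / crop$frost_trange)
      state$lv <- state$lv * (1 - kill)
    }
    state$lvage <- state$lvage + teff / (35 - crop$TBASE)
    keep <- state$lvage <= crop$SPAN
    if (!all(keep)) {
      state$lv <- state$lv[keep]
      state$lvage <- state$lvage[keep]
      state$sla <- state$sla[keep]
    }
  }
  lai_cur <- sum(state$lv * state$sla)
  if (new_leaf_dw > 0) {
    sla_new <- pw_lookup(crop$SLATB, state$dvs)
    expansion <- state$dvs < 1 && lai_cur < 6
    if (expansion && lai_cur > 0) {
      dlai_max <- lai_cur * expm1(crop$RGRLAI * teff)
      new_leaf_dw <- min(new_leaf_dw, dlai_max / sla_new)
    }
    state$lv <- c(state$lv, new_leaf_dw)
    state$lvage <- c(state$lvage, 0)
    state$sla <- c(state$sla, sla_new)
  }
  state$wlv <- sum(state$lv)
  state$lai <- sum(state$lv * state$sla)
  state$tagp <- state$wlv + state$wst + state$wso
  state
}

#' One-day root-zone water balance
#'
#' Single free-draining bucket of depth `RD`. Inputs are rain and irrigation;
#' losses are actual soil evaporation and transpiration (demand reduced by a
#' moisture factor linear between the wilting point and the critical point
#' `SMW + 0.5 (SMFCF - SMW)`), percolation above field capacity limited by
#' `KSUB`, and surface runoff of any excess above saturation. Every term is
#' returned so the balance closes identically.
#'
#' @param state a `crop_state`.
#' @param soil soil parameters.
#' @param wd one weather row.
#' @param evap_demand potential soil evaporation (cm d-1).
#' @param transp_demand potential transpiration (cm d-1).
#' @return list with `state` (updated `sm`) and `fluxes` (cm): `infil`,
#'   `e_act`, `t_act`, `percolation`, `runoff`, `dW`.
#' @export
update_soil_water <- function(state, soil, wd, evap_demand, transp_demand) {
  if (evap_demand < 0 || transp_demand < 0) stop("ET demands must be >= 0")
  w0 <- state$sm * soil$RD
  infil <- (wd$rain + wd$irrigation) / 10  # mm -> cm
  smcr <- soil$SMW + 0.5 * (soil$SMFCF - soil$SMW)
  red <- min(1, max(0, (state$sm - soil$SMW) / (smcr - soil$SMW)))
  e_act <- evap_demand * red
  t_act <- transp_demand * red
  # never extract below wilting point
  extractable <- max(0, w0 - soil$SMW * soil$RD) + infil
  tot <- e_act + t_act
  if (tot > extractable && tot > 0) {
    scale <- extractable / tot
    e_act <- e_act * scale
    t_act <- t_act * scale
  }
  w1 <- w0 + infil - e_act - t_act
  percolation <- min(soil$KSUB, max(0, w1 - soil$SMFCF * soil$RD))
  w2 <- w1 - percolation
  runoff <- max(0, w2 - soil$SM0 * soil$RD)
  w3 <- w2 - runoff
  state$sm <- min(soil$SM0, max(soil$SMW, w3 / soil$RD))
  list(state = state,
       fluxes = list(infil = infil, e_act = e_act, t_act = t_act,
                     percolation = percolation, runoff = runoff,
                     dW = w3 - w0))
}

#' Daily biomass growth and partitioning
#'
#' Gross assimilation follows a light-use-efficiency form:
#' `LUE * radiation * (1 - exp(-k_ext * LAI)) * water_stress`, scaled by the
#' `TMPFTB` temperature response of the daily mean. Maintenance
#' respiration (per-pool coefficients at 25 degC, Q10 = 2) is subtracted;
#' the non-negative remainder goes first to roots (`FRTB`), the shoot share
#' to leaves/stems/storage organs by the DVS-indexed fractions. Growth stops
#' at maturity (DVS >= 2); the storage pool never shrinks.
#'
#' @param state a `crop_state`.
#' @param crop crop parameters.
#' @param wd one weather row.
#' @param water_stress transpiration ratio in `[0, 1]`.
#' @return list with `state` (stem/storage/root pools updated) and
#'   `new_leaf_dw`, the leaf dry-matter increment consumed by
#'   [update_leaves()].
#' @export
daily_growth <- function(state, crop, wd, water_stress) {
  if (water_stress < 0 || water_stress > 1) {
    stop("water_stress must lie in [0, 1]")
  }
  if (state$dvs >= 2) return(list(state = state, new_leaf_dw = 0))
  tmean <- (wd$tmin + wd$tmax) / 2
  gross <- crop$LUE * wd$radiation * (1 - exp(-crop$k_ext * state$lai)) *
    water_stress * pw_lookup(crop$TMPFTB, tmean)
  rm25 <- crop$rm_coef[["lv"]] * state$wlv + crop$rm_coef[["st"]] * state$wst +
    crop$rm_coef[["so"]] * state$wso + crop$rm_coef[["rt"]] * state$wrt
  maint <- rm25 * 2^((tmean - 25) / 10)
  net <- max(0, gross - maint)
  fr <- pw_lookup(crop$FRTB, state$dvs)
  shoot <- net * (1 - fr)
  state$wrt <- state$wrt + net * fr
  state$wst <- state$wst + shoot * pw_lookup(crop$FSTB, state$dvs)
  state$wso <- state$wso + shoot * pw_lookup(crop$FOTB, state$dvs)
  state$tagp <- state$wlv + state$wst + state$wso
  list(state = state, new_leaf_dw = shoot * pw_lookup(crop$FLTB, state$dvs))
}

#' Potential evapotranspiration (cm d-1)
#'
#' Temperature-radiation (Hargreaves-type) reference ET from the day's mean
#' temperature and incoming global radiation, so wind and humidity inputs
#' remain optional. The swap-in point for a Penman-Monteith implementation is
#' this function.
#'
#' @param wd one weather row.
#' @return potential ET in cm d-1.
#' @export
potential_et <- function(wd) {
  tmean <- (wd$tmin + wd$tmax) / 2
  et0_mm <- 0.0135 * (tmean + 17.8) * wd$radiation / 2.45
  max(0, et0_mm) / 10
}

#' Advance the full crop state by one day
#'
#' Composes, in order: potential ET, the soil water balance (splitting ET
#' demand into soil evaporation and transpiration by canopy cover),
#' the water-stress factor `T_actual / T_potential`, biomass growth, leaf
#' dynamics, and phenology. Pure function: identical inputs give identical
#' outputs.
#'
#' @param state a `crop_state`.
#' @param crop crop parameters.
#' @param soil soil parameters.
#' @param wd one weather row.
#' @param return_fluxes also return the day's water fluxes.
#' @return updated state, or `list(state, fluxes)` if `return_fluxes`.
#' @export
advance_day <- function(state, crop, soil, wd, return_fluxes = FALSE) {
  et0 <- potential_et(wd)
  cover <- 1 - exp(-crop$k_ext * state$lai)
  epot <- et0 * (1 - cover)
  tpot <- et0 * cover
  sw <- update_soil_water(state, soil, wd, epot, tpot)
  state <- sw$state
  stress <- if (tpot > 0) sw$fluxes$t_act / tpot else 1
  g <- daily_growth(state, crop, wd, stress)
  state <- update_leaves(g$state, crop, wd, g$new_leaf_dw)
  state <- update_phenology(state, crop, wd)
  state$day_index <- state$day_index + 1L
  if (return_fluxes) list(state = state, fluxes = sw$fluxes) else state
}

#' Run a full growing season
#'
#' Integrates the simulator from sowing over the supplied weather window and
#' records the daily trajectory. Yield is the storage-organ weight at
#' maturity (DVS = 2) or at the last simulated day.
#'
#' @param crop crop parameters.
#' @param soil soil parameters.
#' @param weather validated weather data.frame covering the season.
#' @param sowing_day first simulated day (Date); defaults to the first
#'   weather date.
#' @return a `season_result` list: `trajectory` data.frame
#'   (`day,date,dvs,lai,sm,tagp,wso`), `yield_kg_ha`, `maturity_day`
#'   (Date or `NA`), `final_state`, and the accumulated `water_balance`.
#' @export
run_season <- function(crop, soil, weather, sowing_day = NULL) {
  weather <- validate_weather(weather)
  if (is.null(sowing_day)) sowing_day <- weather$date[1]
  sowing_day <- as.Date(sowing_day)
  idx <- which(weather$date >= sowing_day)
  if (!length(idx) || weather$date[idx[1]] != sowing_day) {
    stop("weather series does not cover the sowing day")
  }
  wx <- weather[idx, , drop = FALSE]
  n <- nrow(wx)
  state <- init_crop_state(crop, soil)
  dvs_v <- lai_v <- sm_v <- tagp_v <- wso_v <- numeric(n)
  bal <- c(infil = 0, e_act = 0, t_act = 0, percolation = 0, runoff = 0)
  w_start <- state$sm * soil$RD
  maturity_day <- as.Date(NA)
  dates <- wx$date
  tminv <- wx$tmin; tmaxv <- wx$tmax; rainv <- wx$rain
  irrv <- wx$irrigation; radv <- wx$radiation
  for (i in seq_len(n)) {
    wd <- list(tmin = tminv[i], tmax = tmaxv[i], rain = rainv[i],
               irrigation = irrv[i], radiation = radv[i])
    out <- advance_day(state, crop, soil, wd, return_fluxes = TRUE)
    state <- out$state
    f <- out$fluxes
    bal <- bal + c(f$infil, f$e_act, f$t_act, f$percolation, f$runoff)
    dvs_v[i] <- state$dvs; lai_v[i] <- state$lai
    sm_v[i] <- state$sm; tagp_v[i] <- state$tagp
    wso_v[i] <- state$wso
    if (is.na(maturity_day) && state$dvs >= 2) maturity_day <- dates[i]
  }
  traj <- data.frame(day = seq_len(n) - 1L, date = dates,
                     dvs = dvs_v, lai = lai_v, sm = sm_v,
                     tagp = tagp_v, wso = wso_v)
  res <- list(trajectory = traj,
              yield_kg_ha = state$wso,
              maturity_day = maturity_day,
              final_state = state,
              water_balance = c(bal, dW = state$sm * soil$RD - w_start))
  class(res) <- "season_result"
  res
}

#' @export
print.season_result <- function(x, ...) {
  cat("Season simulation:", nrow(x$trajectory), "days\n")
  cat(sprintf("  yield: %.0f kg/ha   max LAI: %.2f   maturity: %s\n",
              x$yield_kg_ha, max(x$trajectory$lai),
              ifelse(is.na(x$maturity_day), "not reached",
                     as.character(x$maturity_day))))
  invisible(x)
}

#' Write a season trajectory CSV
#'
#' @param result a `season_result`.
#' @param path output path (`day,date,dvs,lai,sm,tagp,wso`).
#' @export
write_trajectory_csv <- function(result, path) {
  utils::write.csv(result$trajectory, path, row.names = FALSE, quote = FALSE)
}
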