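#' Climate specification for the weather generator
#'
#' Describes a semi-humid temperate climate with a sinusoidal temperature
#' cycle, a first-order wet/dry rainfall occurrence process with exponential
#' wet-day depths, beta-distributed sunshine fractions converted to radiation
#' through the Angstrom formula, and fixed irrigation events (dry winters in
#' the emulated region make spring irrigation routine). Defaults emulate a
#' North China Plain winter wheat environment: annual mean temperature about
#' 12.5 degC and roughly 650 mm annual rainfall concentrated in summer.
#'
#' @param latitude site latitude (deg N).
#' @param t_mean annual mean temperature (degC).
#' @param t_amplitude seasonal half-range (degC).
#' @param t_phase_doy day-of-year of the temperature minimum.
#' @param t_noise_sd day-to-day temperature noise s.d. (degC).
#' @param diurnal_range mean tmax - tmin (degC).
#' @param wet_prob monthly wet-day probabilities (Jan..Dec).
#' @param wet_depth monthly mean wet-day rainfall (mm).
#' @param irrigation data.frame `date,mm` of irrigation events (may be empty).
#' @param angstrom_a,angstrom_b Angstrom coefficients (a, b > 0, a + b <= 1).
#' @param sunshine_shape1,sunshine_shape2 beta parameters of the daily
#'   sunshine fraction n/N.
#' @return a `climate_spec` list.
#' @export
climate_spec <- function(latitude = 37.7,
                         t_mean = 12.5, t_amplitude = 14.5,
                         t_phase_doy = 15, t_noise_sd = 2,
                         diurnal_range = 10,
                         wet_prob = c(0.08, 0.08, 0.10, 0.12, 0.15, 0.20,
                                      0.40, 0.40, 0.25, 0.15, 0.08, 0.06),
                         wet_depth = c(2, 3, 5, 8, 10, 12,
                                       14, 14, 10, 8, 4, 2),
                         irrigation = data.frame(
                           date = as.Date(c("2017-03-05", "2017-04-15",
                                            "2017-05-10")),
                           mm = c(70, 70, 60)),
                         angstrom_a = 0.25, angstrom_b = 0.50,
                         sunshine_shape1 = 3, sunshine_shape2 = 2) {
  stopifnot(length(wet_prob) == 12, length(wet_depth) == 12,
            all(wet_prob >= 0 & wet_prob <= 1), all(wet_depth >= 0),
            angstrom_a > 0, angstrom_b > 0, angstrom_a + angstrom_b <= 1)
  structure(list(latitude = latitude, t_mean = t_mean,
                 t_amplitude = t_amplitude, t_phase_doy = t_phase_doy,
                 t_noise_sd = t_noise_sd, diurnal_range = diurnal_range,
                 wet_prob = wet_prob, wet_depth = wet_depth,
                 irrigation = irrigation,
                 angstrom_a = angstrom_a, angstrom_b = angstrom_b,
                 sunshine_shape1 = sunshine_shape1,
                 sunshine_shape2 = sunshine_shape2),
            class = "climate_spec")
}

#' Solar radiation from sunshine hours (Angstrom formula)
#'
#' FAO-56 form `Rs = (a + b n/N) Ra` with extraterrestrial radiation `Ra` and
#' daylength `N` from standard solar geometry (solar constant
#' 0.0820 MJ m-2 min-1).
#'
#' @param sunshine_hours bright sunshine duration n (h), `0 <= n <= N`.
#' @param latitude site latitude (deg).
#' @param doy day of year (1-366).
#' @param a,b Angstrom coefficients (defaults 0.25 and 0.50).
#' @return incoming solar radiation (MJ m-2 d-1).
#' @export
angstrom_radiation <- function(sunshine_hours, latitude, doy,
                               a = 0.25, b = 0.50) {
  geo <- solar_geometry(latitude, doy)
  if (any(sunshine_hours < 0) || any(sunshine_hours > geo$daylength + 1e-9)) {
    stop("sunshine hours must lie in [0, daylength]")
  }
  (a + b * sunshine_hours / geo$daylength) * geo$ra
}

#' Extraterrestrial radiation and daylength
#'
#' @param latitude site latitude (deg).
#' @param doy day of year.
#' @return list with `ra` (MJ m-2 d-1) and `daylength` (h).
#' @export
solar_geometry <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(1, pmax(-1, x)))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(ra = pmax(0, ra), daylength = 24 / pi * ws)
}

#' Generate a daily weather series
#'
#' Seeded, reproducible draw from a [climate_spec()]: sinusoidal mean
#' temperature plus Gaussian noise, tmax >= tmin enforced, Bernoulli wet days
#' with exponential depths, beta sunshine fractions converted by
#' [angstrom_radiation()], and the spec's irrigation events inserted verbatim.
#'
#' @param spec a [climate_spec()].
#' @param start first date (Date or string).
#' @param n_days number of days (>= 1).
#' @param seed integer seed.
#' @return validated weather data.frame (`date,tmin,tmax,rain,irrigation,
#'   sunshine_hours,radiation,wind`).
#' @export
generate_weather <- function(spec, start, n_days, seed) {
  stopifnot(n_days >= 1)
  set.seed(seed)
  dates <- as.Date(start) + seq_len(n_days) - 1L
  doy <- as.integer(strftime(dates, "%j"))
  month <- as.integer(strftime(dates, "%m"))
  # temperature minimum at t_phase_doy
  tbar <- spec$t_mean - spec$t_amplitude *
    cos(2 * pi * (doy - spec$t_phase_doy) / 365)
  noise <- stats::rnorm(n_days, 0, spec$t_noise_sd)
  half <- spec$diurnal_range / 2
  tmin <- tbar + noise - half
  tmax <- tbar + noise + half
  wet <- stats::runif(n_days) < spec$wet_prob[month]
  rain <- ifelse(wet, stats::rexp(n_days, 1) * spec$wet_depth[month], 0)
  sun_frac <- stats::rbeta(n_days, spec$sunshine_shape1, spec$sunshine_shape2)
  geo <- solar_geometry(spec$latitude, doy)
  sunshine_hours <- sun_frac * geo$daylength
  radiation <- angstrom_radiation(sunshine_hours, spec$latitude, doy,
                                  spec$angstrom_a, spec$angstrom_b)
  irrigation <- numeric(n_days)
  if (!is.null(spec$irrigation) && nrow(spec$irrigation)) {
    idx <- match(as.Date(spec$irrigation$date), dates)
    ok <- !is.na(idx)
    irrigation[idx[ok]] <- spec$irrigation$mm[ok]
  }
  wx <- data.frame(date = dates, tmin = tmin, tmax = tmax, rain = rain,
                   irrigation = irrigation, sunshine_hours = sunshine_hours,
                   radiation = radiation, wind = 2)
  validate_weather(wx)
}

#' Observation plan for twin experiments
#'
#' Default cadence mirrors a Sentinel-style acquisition calendar for a
#' 2016/17-type season: 7 LAI dates and 8 SM dates between late February and
#' late May, with relative errors of 10% (LAI) and 35% (SM).
#'
#' @param lai_dates LAI observation dates.
#' @param sm_dates SM observation dates.
#' @param rel_errors named vector `c(LAI = , SM = )` of relative errors.
#' @param sm_bias additive bias injected into SM observations
#'   (cm3 cm-3; emulates a surface-probe vs root-zone mismatch).
#' @return an `observation_plan` list.
#' @export
observation_plan <- function(lai_dates = as.Date(c("2017-02-27", "2017-03-09",
                                                   "2017-03-29", "2017-04-18",
                                                   "2017-04-28", "2017-05-18",
                                                   "2017-05-28")),
                             sm_dates = as.Date(c("2017-02-25", "2017-03-09",
                                                  "2017-03-21", "2017-04-02",
                                                  "2017-04-14", "2017-04-26",
                                                  "2017-05-08", "2017-05-20")),
                             rel_errors = c(LAI = 0.10, SM = 0.35),
                             sm_bias = 0) {
  stopifnot(all(rel_errors >= 0))
  structure(list(lai_dates = as.Date(lai_dates), sm_dates = as.Date(sm_dates),
                 rel_errors = rel_errors, sm_bias = sm_bias),
            class = "observation_plan")
}

#' Generate a twin-experiment truth and its noisy observations
#'
#' Runs the simulator on the supplied parameters to obtain the truth
#' trajectory, then samples observations at the plan's dates with
#' multiplicative Gaussian noise, `obs = truth * (1 + e)`,
#' `e ~ N(0, rel_error^2)`, clamped at zero (errors are stated as relative
#' percentages, hence multiplicative). An optional additive SM bias emulates
#' the surface-probe vs root-zone mismatch.
#'
#' @param crop,soil truth parameter sets.
#' @param weather weather data.frame covering the plan dates.
#' @param plan an [observation_plan()].
#' @param seed integer seed for the observation noise.
#' @return list with `truth` (a `season_result`) and `observations`
#'   (data.frame `date,variable,value,rel_error`, sorted by date).
#' @export
generate_twin <- function(crop, soil, weather, plan, seed) {
  truth <- run_season(crop, soil, weather)
  traj <- truth$trajectory
  bad <- c(plan$lai_dates, plan$sm_dates)[
    !(c(plan$lai_dates, plan$sm_dates) %in% traj$date)]
  if (length(bad)) {
    stop("observation dates outside the simulated window: ",
         paste(bad, collapse = ", "))
  }
  set.seed(seed)
  sample_obs <- function(dates, variable, values, rel) {
    eps <- stats::rnorm(length(dates), 0, rel)
    data.frame(date = dates, variable = variable,
               value = pmax(0, values * (1 + eps)), rel_error = rel)
  }
  lai_vals <- traj$lai[match(plan$lai_dates, traj$date)]
  sm_vals <- traj$sm[match(plan$sm_dates, traj$date)]
  obs <- rbind(
    sample_obs(plan$lai_dates, "LAI", lai_vals, plan$rel_errors[["LAI"]]),
    sample_obs(plan$sm_dates, "SM", sm_vals, plan$rel_errors[["SM"]]))
  obs$value[obs$variable == "SM"] <-
    pmax(0, obs$value[obs$variable == "SM"] + plan$sm_bias)
  obs <- obs[order(obs$date, obs$variable), ]
  rownames(obs) <- NULL
  list(truth = truth, observations = obs)
}

#' Regional grid specification
#'
#' @param n_rows,n_cols grid dimensions.
#' @param threshold wheat-fraction threshold; cells are simulated only when
#'   their fraction strictly exceeds it.
#' @param jitter data.frame `target,rel_sd` of per-cell parameter jitter
#'   (targets from the perturbable set, see [build_ensemble()]).
#' @return a `region_spec` list.
#' @export
region_spec <- function(n_rows = 20, n_cols = 20, threshold = 0.40,
                        jitter = data.frame(
                          target = c("TDWI", "WAV"),
                          rel_sd = c(0.10, 0.10))) {
  structure(list(n_rows = n_rows, n_cols = n_cols, threshold = threshold,
                 jitter = jitter), class = "region_spec")
}

#' Generate a synthetic regional grid
#'
#' Draws a wheat fraction `U(0, 1)` per cell, jitters the base parameters
#' per cell, and produces truth trajectories and noisy observations for every
#' cell above the threshold (all cells share one weather realisation, as a
#' region small against the synoptic scale would).
#'
#' @param spec a [region_spec()].
#' @param crop,soil base parameter sets.
#' @param climate a [climate_spec()].
#' @param plan an [observation_plan()].
#' @param start,n_days weather window passed to [generate_weather()].
#' @param seed integer seed.
#' @return list with `cells` (data.frame `cell_id,row,col,wheat_fraction,
#'   included`), `weather`, and per-cell lists `params` and `observations`
#'   (NULL for excluded cells).
#' @export
generate_region <- function(spec, crop, soil, climate, plan,
                            start, n_days, seed) {
  set.seed(seed)
  n <- spec$n_rows * spec$n_cols
  cells <- data.frame(
    cell_id = seq_len(n),
    row = rep(seq_len(spec$n_rows), each = spec$n_cols),
    col = rep(seq_len(spec$n_cols), times = spec$n_rows),
    wheat_fraction = stats::runif(n))
  cells$included <- cells$wheat_fraction > spec$threshold
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L + n)
  weather <- generate_weather(climate, start, n_days, sub_seeds[1])
  params <- vector("list", n)
  observations <- vector("list", n)
  jit <- spec$jitter
  for (i in seq_len(n)) {
    if (!cells$included[i]) next
    set.seed(sub_seeds[2L + i])
    cp <- crop; sp <- soil
    if (!is.null(jit) && nrow(jit)) {
      for (j in seq_len(nrow(jit))) {
        tg <- jit$target[j]
        draw <- function(base) truncated_gauss(base, jit$rel_sd[j] * base)
        if (tg %in% names(cp)) cp[[tg]] <- draw(cp[[tg]])
        else if (tg %in% names(sp)) sp[[tg]] <- draw(sp[[tg]])
        else stop("unknown jitter target: ", tg)
      }
      sp$WAV <- min(sp$WAV, (sp$SM0 - sp$SMW) * sp$RD)
      validate_soil_params(sp)
    }
    twin <- generate_twin(cp, sp, weather, plan,
                          seed = sub_seeds[2L + i] %% 1000000L + 1L)
    params[[i]] <- list(crop = cp, soil = sp)
    observations[[i]] <- twin$observations
  }
  list(cells = cells, weather = weather, params = params,
       observations = observations, spec = spec)
}

# positive truncated Gaussian draw (redraws; used for parameter jitter)
truncated_gauss <- function(mean, sd, lower = 0, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
  stop("truncated Gaussian draw failed after ", max_tries,
       " tries (spec too wide)")
}

#' Read / write observation CSVs
#'
#' Observation files carry `date,variable,value,rel_error`; `rel_error` may
#' be omitted and supplied from a default map.
#'
#' @param path CSV path.
#' @param default_rel_errors named vector used where the file has no
#'   `rel_error` column.
#' @return data.frame `date,variable,value,rel_error` sorted by date.
#' @export
read_observations_csv <- function(path,
                                  default_rel_errors = c(LAI = 0.10,
                                                         SM = 0.35)) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  obs$date <- as.Date(obs$date)
  if (is.null(obs$rel_error)) {
    obs$rel_error <- default_rel_errors[obs$variable]
  }
  if (any(obs$value < 0)) stop("observation values must be >= 0")
  if (any(obs$variable == "SM" & obs$value >= 1)) {
    stop("volumetric SM observations must be < 1")
  }
  obs <- obs[order(obs$date, obs$variable), ]
  rownames(obs) <- NULL
  obs
}

#' @rdname read_observations_csv
#' @param obs observation data.frame.
#' @export
write_observations_csv <- function(obs, path) {
  utils::write.csv(obs[c("date", "variable", "value", "rel_error")],
                   path, row.names = FALSE, quote = FALSE)
}
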