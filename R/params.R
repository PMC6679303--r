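#' Piecewise-linear lookup table
#'
#' DVS-indexed tables (specific leaf area, partitioning fractions) are stored
#' as knot lists `[[dvs, value], ...]` and evaluated by linear interpolation
#' with flat extrapolation beyond the outer knots.
#'
#' @param knots two-column matrix or list of `c(x, y)` pairs, x strictly
#'   increasing.
#' @return object of class `pw_table`, callable through [pw_lookup()].
#' @export
pw_table <- function(knots) {
  if (is.list(knots)) knots <- do.call(rbind, lapply(knots, as.numeric))
  knots <- as.matrix(knots)
  if (ncol(knots) != 2L) stop("knots must have two columns (x, value)")
  if (is.unsorted(knots[, 1L], strictly = TRUE)) {
    stop("table knots must have strictly increasing x")
  }
  structure(list(x = knots[, 1L], y = knots[, 2L]), class = "pw_table")
}

#' Evaluate a piecewise-linear table
#'
#' @param tab a [pw_table()].
#' @param x numeric vector of evaluation points.
#' @return interpolated values, constant beyond the outer knots.
#' @export
pw_lookup <- function(tab, x) {
  xs <- tab$x
  ys <- tab$y
  n <- length(xs)
  if (length(x) == 1L) {
    if (x <= xs[1L]) return(ys[1L])
    if (x >= xs[n]) return(ys[n])
    i <- findInterval(x, xs)
    return(ys[i] + (ys[i + 1L] - ys[i]) * (x - xs[i]) / (xs[i + 1L] - xs[i]))
  }
  xc <- pmin(pmax(x, xs[1L]), xs[n])
  i <- findInterval(xc, xs, all.inside = TRUE)
  ys[i] + (ys[i + 1L] - ys[i]) * (xc - xs[i]) / (xs[i + 1L] - xs[i])
}

# default DVS-indexed tables for a generic winter wheat cultivar.
# Shoot partition fractions (leaf/stem/storage) share knot positions so each
# linear segment sums to one exactly.
.default_slatb <- list(c(0, 0.00212), c(0.5, 0.00212), c(2, 0.00175))
.default_fltb  <- list(c(0, 0.65), c(0.25, 0.70), c(0.50, 0.50),
                       c(0.65, 0.30), c(0.95, 0.00), c(1.00, 0.00), c(2, 0))
.default_fstb  <- list(c(0, 0.35), c(0.25, 0.30), c(0.50, 0.50),
                       c(0.65, 0.70), c(0.95, 0.85), c(1.00, 0.00), c(2, 0))
.default_fotb  <- list(c(0, 0.00), c(0.25, 0.00), c(0.50, 0.00),
                       c(0.65, 0.00), c(0.95, 0.15), c(1.00, 1.00), c(2, 1))
.default_frtb  <- list(c(0, 0.50), c(0.10, 0.50), c(0.20, 0.40),
                       c(0.35, 0.22), c(0.50, 0.13), c(0.70, 0.07),
                       c(0.90, 0.03), c(1.20, 0.00), c(2, 0))
# assimilation response to daily mean temperature (fraction of potential);
# keeps the canopy dormant through a North China Plain winter
.default_tmpftb <- list(c(0, 0.01), c(10, 0.60), c(15, 1.00), c(35, 1.00))

#' Crop parameter set
#'
#' Builds the parameter set of the wheat growth simulator. Defaults describe a
#' generic winter wheat cultivar; every value is configuration, not a fitted
#' constant.
#'
#' @param TDWI initial total crop dry weight at emergence (kg ha-1).
#' @param RGRLAI maximum relative LAI increase during the juvenile
#'   (exponential) phase (per degree-day above `TBASE`).
#' @param SPAN maximum leaf lifespan at 35 degC (days).
#' @param TBASE lower threshold temperature for leaf ageing (degC).
#' @param SLATB specific leaf area vs DVS (ha kg-1), knot list.
#' @param TSUM1,TSUM2 thermal time emergence to anthesis and anthesis to
#'   maturity (degC day).
#' @param TBASEM base temperature for phenological development (degC).
#' @param FLTB,FSTB,FOTB shoot partitioning fractions to leaves, stems and
#'   storage organs vs DVS; must sum to 1 at every knot.
#' @param FRTB fraction of net growth sent to roots vs DVS.
#' @param k_ext canopy light extinction coefficient (dimensionless).
#' @param LUE light-use efficiency, kg dry matter ha-1 per MJ m-2 of
#'   intercepted global radiation.
#' @param TMPFTB reduction factor of gross assimilation vs daily mean
#'   temperature (degC), knot list.
#' @param rm_coef maintenance respiration coefficients at 25 degC for
#'   leaves/stems/storage/roots (kg kg-1 d-1); Q10 = 2.
#' @param frost_tcrit daily minimum temperature (degC) below which leaf
#'   cohorts start to be killed by frost.
#' @param frost_trange temperature span (degC) over which frost kill rises
#'   from 0 to complete loss of the canopy.
#' @return a `crop_params` list.
#' @export
crop_params <- function(TDWI = 210, RGRLAI = 0.00817, SPAN = 31.3,
                        TBASE = 0, SLATB = .default_slatb,
                        TSUM1 = 1100, TSUM2 = 900, TBASEM = 0,
                        FLTB = .default_fltb, FSTB = .default_fstb,
                        FOTB = .default_fotb, FRTB = .default_frtb,
                        k_ext = 0.6, LUE = 22,
                        TMPFTB = .default_tmpftb,
                        rm_coef = c(lv = 0.03, st = 0.015,
                                    so = 0.01, rt = 0.015),
                        frost_tcrit = -10, frost_trange = 15) {
  as_tab <- function(x) if (inherits(x, "pw_table")) x else pw_table(x)
  p <- list(TDWI = TDWI, RGRLAI = RGRLAI, SPAN = SPAN, TBASE = TBASE,
            SLATB = as_tab(SLATB), TSUM1 = TSUM1, TSUM2 = TSUM2,
            TBASEM = TBASEM, FLTB = as_tab(FLTB), FSTB = as_tab(FSTB),
            FOTB = as_tab(FOTB), FRTB = as_tab(FRTB),
            k_ext = k_ext, LUE = LUE, TMPFTB = as_tab(TMPFTB),
            rm_coef = rm_coef,
            frost_tcrit = frost_tcrit, frost_trange = frost_trange)
  class(p) <- "crop_params"
  validate_crop_params(p)
  p
}

validate_crop_params <- function(p) {
  pos <- c("TDWI", "RGRLAI", "SPAN", "TSUM1", "TSUM2", "k_ext", "LUE")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop(sprintf("crop parameter %s must be a non-negative scalar", nm))
    }
  }
  if (p$SPAN <= 0) stop("SPAN must be > 0")
  if (p$TBASE >= 35) stop("TBASE must be below the 35 degC reference")
  knots <- sort(unique(c(p$FLTB$x, p$FSTB$x, p$FOTB$x)))
  fr <- pw_lookup(p$FLTB, knots) + pw_lookup(p$FSTB, knots) +
    pw_lookup(p$FOTB, knots)
  if (any(abs(fr - 1) > 1e-8)) {
    stop("shoot partition fractions FLTB + FSTB + FOTB must sum to 1 at every knot")
  }
  frac_tabs <- list(FLTB = p$FLTB, FSTB = p$FSTB, FOTB = p$FOTB, FRTB = p$FRTB)
  for (nm in names(frac_tabs)) {
    y <- frac_tabs[[nm]]$y
    if (any(y < 0 | y > 1)) stop(sprintf("%s fractions must lie in [0, 1]", nm))
  }
  invisible(p)
}

#' Soil parameter set
#'
#' One-layer free-draining water-balance parameters for the root zone.
#'
#' @param SM0 saturated volumetric water content (cm3 cm-3).
#' @param SMFCF field capacity (cm3 cm-3).
#' @param SMW wilting point (cm3 cm-3).
#' @param RD rooting depth (cm), fixed over the season.
#' @param WAV initial plant-available water in the root zone (cm).
#' @param KSUB maximum percolation rate below the root zone (cm d-1).
#' @return a `soil_params` list.
#' @export
soil_params <- function(SM0 = 0.46, SMFCF = 0.36, SMW = 0.12,
                        RD = 60, WAV = 10, KSUB = 10) {
  p <- list(SM0 = SM0, SMFCF = SMFCF, SMW = SMW, RD = RD,
            WAV = WAV, KSUB = KSUB)
  class(p) <- "soil_params"
  validate_soil_params(p)
  p
}

validate_soil_params <- function(p) {
  if (!(p$SMW > 0 && p$SMW < p$SMFCF && p$SMFCF < p$SM0 && p$SM0 < 1)) {
    stop("soil retention must satisfy 0 < SMW < SMFCF < SM0 < 1")
  }
  if (p$RD <= 0) stop("rooting depth RD must be > 0")
  if (p$KSUB < 0) stop("KSUB must be >= 0")
  if (p$WAV < 0 || p$WAV > (p$SM0 - p$SMW) * p$RD) {
    stop("WAV must lie in [0, (SM0 - SMW) * RD]")
  }
  invisible(p)
}

#' Read crop/soil parameters from JSON or YAML
#'
#' Files carry keys named exactly as the [crop_params()] / [soil_params()]
#' arguments; piecewise tables are `[[dvs, value], ...]` knot lists. Keys not
#' present keep their defaults.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @param what `"crop"` or `"soil"`.
#' @return a `crop_params` or `soil_params` object.
#' @export
read_params <- function(path, what = c("crop", "soil")) {
  what <- match.arg(what)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  }
  ctor <- if (what == "crop") crop_params else soil_params
  keep <- intersect(names(vals), names(formals(ctor)))
  do.call(ctor, vals[keep])
}
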