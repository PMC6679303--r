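#' Validate a daily weather table
#'
#' The simulator consumes a data.frame with one row per calendar day and
#' columns `date` (Date), `tmin`, `tmax` (degC), `rain`, `irrigation`
#' (mm d-1), `radiation` (MJ m-2 d-1) and optionally `wind` (m s-1).
#'
#' @param wx data.frame of daily weather.
#' @return the validated data.frame (invisibly usable), with `irrigation`
#'   defaulted to 0 and dates coerced to `Date`.
#' @export
validate_weather <- function(wx) {
  req <- c("date", "tmin", "tmax", "rain", "radiation")
  miss <- setdiff(req, names(wx))
  if (length(miss)) stop("weather table missing columns: ",
                         paste(miss, collapse = ", "))
  wx$date <- as.Date(wx$date)
  if (is.null(wx$irrigation)) wx$irrigation <- 0
  wx$irrigation[is.na(wx$irrigation)] <- 0
  if (anyNA(wx[req])) stop("weather table contains missing values")
  if (any(wx$tmax < wx$tmin)) stop("weather invariant violated: tmax < tmin")
  if (any(wx$rain < 0) || any(wx$irrigation < 0) || any(wx$radiation < 0)) {
    stop("rain, irrigation and radiation must be non-negative")
  }
  if (is.unsorted(wx$date, strictly = TRUE)) {
    stop("weather dates must be strictly increasing")
  }
  wx
}

#' Read a weather CSV
#'
#' Expects header `date,tmin,tmax,rain,irrigation,sunshine_hours,radiation,wind`.
#' Rows may give either `radiation` directly or `sunshine_hours`, which are
#' converted with the Angstrom formula ([angstrom_radiation()]).
#'
#' @param path CSV file path.
#' @param latitude site latitude in degrees, needed when any row supplies
#'   sunshine hours instead of radiation.
#' @param angstrom_a,angstrom_b Angstrom coefficients for the conversion.
#' @return validated weather data.frame.
#' @export
read_weather_csv <- function(path, latitude = NULL,
                             angstrom_a = 0.25, angstrom_b = 0.50) {
  wx <- utils::read.csv(path, stringsAsFactors = FALSE)
  wx$date <- as.Date(wx$date)
  no_rad <- is.null(wx$radiation) | is.na(wx$radiation)
  if (any(no_rad)) {
    if (is.null(wx$sunshine_hours) || any(is.na(wx$sunshine_hours[no_rad]))) {
      stop("each weather row needs radiation or sunshine_hours")
    }
    if (is.null(latitude)) stop("latitude required to convert sunshine hours")
    doy <- as.integer(strftime(wx$date[no_rad], "%j"))
    if (is.null(wx$radiation)) wx$radiation <- NA_real_
    wx$radiation[no_rad] <- angstrom_radiation(
      wx$sunshine_hours[no_rad], latitude, doy, angstrom_a, angstrom_b)
  }
  validate_weather(wx)
}

#' Write a weather CSV
#'
#' @param wx weather data.frame.
#' @param path output path.
#' @export
write_weather_csv <- function(wx, path) {
  cols <- c("date", "tmin", "tmax", "rain", "irrigation",
            "sunshine_hours", "radiation", "wind")
  for (nm in setdiff(cols, names(wx))) wx[[nm]] <- NA
  utils::write.csv(wx[cols], path, row.names = FALSE, quote = FALSE)
}
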