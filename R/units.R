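# Unit conversions shared across the package. Powers are stored in watts,
# gains linear, RCS in m^2; decibel forms exist only at the interface.

#' Speed of light used throughout the package
#'
#' Fixed at 2.998e8 m/s. All wavelength/frequency conversions use this value.
#' @export
speed_of_light <- function() 2.998e8

#' Convert power in watts to dBm
#'
#' @param watts power in watts; must be strictly positive (0 W has no
#'   decibel representation).
#' @return power in dBm (decibels referenced to 1 mW).
#' @examples
#' watts_to_dbm(1e-3)   # 0 dBm
#' watts_to_dbm(3.98e-11)  # about -74 dBm
#' @export
watts_to_dbm <- function(watts) {
  stopifnot(is.numeric(watts), all(watts > 0))
  10 * log10(watts / 1e-3)
}

#' Convert power in dBm to watts
#'
#' @param dbm power in dBm.
#' @return power in watts.
#' @export
dbm_to_watts <- function(dbm) {
  stopifnot(is.numeric(dbm), all(is.finite(dbm)))
  1e-3 * 10^(dbm / 10)
}

#' Convert power in watts to dBW
#' @param watts power in watts, strictly positive.
#' @return power in dBW.
#' @export
watts_to_dbw <- function(watts) {
  stopifnot(is.numeric(watts), all(watts > 0))
  10 * log10(watts)
}

#' Convert a decibel quantity to a linear ratio
#' @param db value in decibels (e.g. antenna gain in dBi).
#' @return linear ratio.
#' @export
db_to_linear <- function(db) 10^(db / 10)

#' Convert a linear ratio to decibels
#' @param x linear ratio, strictly positive.
#' @return value in decibels.
#' @export
linear_to_db <- function(x) {
  stopifnot(all(x > 0))
  10 * log10(x)
}

#' Convert a radar cross section from cm^2 to m^2
#' @param cm2 RCS in cm^2 (the unit used when reporting).
#' @return RCS in m^2 (the unit used internally).
#' @export
cm2_to_m2 <- function(cm2) cm2 * 1e-4

#' Convert a radar cross section from m^2 to cm^2
#' @param m2 RCS in m^2.
#' @return RCS in cm^2.
#' @export
m2_to_cm2 <- function(m2) m2 * 1e4
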