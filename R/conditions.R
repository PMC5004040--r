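# Culture-condition factor space: seven factors, canonical column order.

#' Culture-condition factors
#'
#' The seven culture factors of the Phellinus liquid-fermentation experiments,
#' in canonical order: inoculum size (volume fraction, stored as a fraction in
#' (0, 1] even though data files and reports use percent), medium pH, initial
#' liquid volume (mL), temperature (deg C), seed (starter culture) age (days),
#' fermentation time (days) and shaker rotation speed (r/min).
#'
#' @return Character vector of the seven canonical factor names.
#' @export
culture_factors <- function() {
  c("inoculum", "ph", "volume", "temperature", "seed_age",
    "ferm_time", "rotation")
}

# pretty units, used by print methods and the CLI
factor_units <- c(
  inoculum = "%", ph = "", volume = "mL", temperature = "degC",
  seed_age = "d", ferm_time = "d", rotation = "r/min"
)

#' Construct a culture condition
#'
#' @param inoculum Inoculum size as a fraction in (0, 1] (0.05 = 5 %).
#' @param ph Medium pH in (0, 14].
#' @param volume Initial liquid volume in mL.
#' @param temperature Temperature in degrees Celsius.
#' @param seed_age Seed-culture age in days.
#' @param ferm_time Fermentation time in days.
#' @param rotation Rotation speed in revolutions per minute.
#'
#' @return One-row data frame with the seven factor columns in canonical
#'   order.
#' @examples
#' culture_condition(0.12, 5.8, 100, 28, 9, 9, 150)
#' @export
culture_condition <- function(inoculum, ph, volume, temperature,
                              seed_age, ferm_time, rotation) {
  cc <- data.frame(
    inoculum = inoculum, ph = ph, volume = volume,
    temperature = temperature, seed_age = seed_age,
    ferm_time = ferm_time, rotation = rotation
  )
  validate_conditions(cc)
  cc
}

validate_conditions <- function(cc, where = "condition") {
  miss <- setdiff(culture_factors(), names(cc))
  if (length(miss))
    stop(where, ": missing factor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(cc[culture_factors()])
  if (!is.numeric(m))
    stop(where, ": non-numeric factor values", call. = FALSE)
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(where, ": non-finite or non-positive value in row ", bad[1L, 1L],
         ", factor '", culture_factors()[bad[1L, 2L]], "'", call. = FALSE)
  if (any(cc$inoculum > 1))
    stop(where, ": inoculum must be a fraction in (0, 1]; row ",
         which(cc$inoculum > 1)[1L], call. = FALSE)
  if (any(cc$ph > 14))
    stop(where, ": pH outside (0, 14]; row ", which(cc$ph > 14)[1L],
         call. = FALSE)
  invisible(cc)
}

#' Factor bounds for filtering and optimization
#'
#' Returns the closed per-factor intervals used both to select regression
#' records and as the feasible box for optimization. The `"corrected"` preset
#' reads the published inoculum filter as 5--12 % (the printed data contain no
#' inoculum below 2 % and the reported optimum is 12 %, reachable only under
#' this reading); the `"literal"` preset keeps it at 0.5--1.2 %.
#'
#' @param preset `"corrected"` (default) or `"literal"`.
#' @return Object of class `factor_bounds`: a data frame with columns
#'   `factor`, `lo`, `hi` (one row per factor, canonical order).
#' @examples
#' factor_bounds()
#' factor_bounds("literal")
#' @export
factor_bounds <- function(preset = c("corrected", "literal")) {
  preset <- match.arg(preset)
  ino <- if (preset == "corrected") c(0.05, 0.12) else c(0.005, 0.012)
  b <- data.frame(
    factor = culture_factors(),
    lo = c(ino[1], 5, 60, 25, 4, 6, 140),
    hi = c(ino[2], 7, 100, 30, 9, 12, 200)
  )
  class(b) <- c("factor_bounds", "data.frame")
  attr(b, "preset") <- preset
  b
}

#' Build custom factor bounds
#'
#' @param lo,hi Named numeric vectors (names = [culture_factors()]) of lower
#'   and upper interval endpoints, in each factor's units.
#' @return A `factor_bounds` object.
#' @export
make_bounds <- function(lo, hi) {
  fac <- culture_factors()
  lo <- lo[fac]; hi <- hi[fac]
  if (anyNA(lo) || anyNA(hi))
    stop("lo and hi must both name all seven factors", call. = FALSE)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite with lo < hi for every factor", call. = FALSE)
  b <- data.frame(factor = fac, lo = unname(lo), hi = unname(hi))
  class(b) <- c("factor_bounds", "data.frame")
  attr(b, "preset") <- "custom"
  b
}

#' @export
print.factor_bounds <- function(x, ...) {
  cat("Factor bounds (", attr(x, "preset"), " preset)\n", sep = "")
  shown <- x
  shown$units <- unname(factor_units[x$factor])
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
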