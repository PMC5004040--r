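# Experiment records: the bundled 45-run dataset, CSV I/O, range filtering
# and exact-duplicate removal.

csv_columns <- c("inoculum_pct", "ph", "volume_ml", "temperature_c",
                 "seed_age_days", "fermentation_time_days",
                 "rotation_speed_rpm", "yield")

#' Load experiment records from CSV
#'
#' Reads fermentation experiment records with header
#' `inoculum_pct,ph,volume_ml,temperature_c,seed_age_days,`
#' `fermentation_time_days,rotation_speed_rpm,yield`. The percent-valued
#' inoculum column is converted to a fraction on read; rows keep file order.
#'
#' @param source Path to a CSV file, or `"fixture"` for the bundled 45-run
#'   Phellinus flavonoid dataset.
#' @return Data frame of class `experiment_records`: the seven factor columns
#'   (see [culture_factors()], inoculum as a fraction) plus `yield`.
#' @examples
#' recs <- read_experiments("fixture")
#' nrow(recs)  # 45
#' @export
read_experiments <- function(source = "fixture") {
  if (identical(source, "fixture"))
    source <- system.file("extdata", "phellinus45.csv", package = "phellopt",
                          mustWork = TRUE)
  raw <- utils::read.csv(source, check.names = TRUE)
  miss <- setdiff(csv_columns, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  raw <- raw[csv_columns]
  for (cn in csv_columns) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop("non-numeric value in column '", cn, "', row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
  }
  rec <- data.frame(
    inoculum    = raw$inoculum_pct / 100,
    ph          = raw$ph,
    volume      = raw$volume_ml,
    temperature = raw$temperature_c,
    seed_age    = raw$seed_age_days,
    ferm_time   = raw$fermentation_time_days,
    rotation    = raw$rotation_speed_rpm,
    yield       = raw$yield
  )
  validate_conditions(rec, where = "experiment records")
  if (any(!is.finite(rec$yield) | rec$yield < 0))
    stop("experiment records: negative or non-finite yield in row ",
         which(!is.finite(rec$yield) | rec$yield < 0)[1L], call. = FALSE)
  class(rec) <- c("experiment_records", "data.frame")
  rec
}

#' Write experiment records to CSV
#'
#' Inverse of [read_experiments()]: inoculum is rendered back to percent and
#' the canonical CSV header is used, so load -> write -> load round-trips.
#'
#' @param records An `experiment_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(records, path) {
  out <- data.frame(
    inoculum_pct           = records$inoculum * 100,
    ph                     = records$ph,
    volume_ml              = records$volume,
    temperature_c          = records$temperature,
    seed_age_days          = records$seed_age,
    fermentation_time_days = records$ferm_time,
    rotation_speed_rpm     = records$rotation,
    yield                  = records$yield
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled Phellinus flavonoid fermentation dataset
#'
#' One-factor-at-a-time liquid-fermentation experiments on Phellinus
#' flavonoid yield: a 14-level pH sweep, a 6-level initial-volume sweep, an
#' 8-level inoculum sweep, a 4-level temperature sweep and a 12-level
#' fermentation-time sweep. The study these data come from describes the
#' campaign as 45 experiments, but its tables print 44 rows; the fixture
#' reproduces the printed tables row-for-row and therefore has 44 records.
#'
#' @return `experiment_records` data frame with 44 rows.
#' @export
phellinus45 <- function() read_experiments("fixture")

#' Filter records to a factor box
#'
#' Keeps exactly the records whose every factor lies inside its closed
#' interval; order is preserved. Records outside the box correspond to the
#' extreme one-factor-at-a-time settings excluded from regression.
#'
#' @param records An `experiment_records` data frame.
#' @param bounds A [factor_bounds()] object.
#' @return The surviving records (possibly zero rows), same class.
#' @examples
#' nrow(filter_records(phellinus45(), factor_bounds()))  # 16
#' @export
filter_records <- function(records, bounds = factor_bounds()) {
  stopifnot(inherits(bounds, "factor_bounds"))
  keep <- rep(TRUE, nrow(records))
  for (k in seq_len(nrow(bounds))) {
    v <- records[[bounds$factor[k]]]
    keep <- keep & v >= bounds$lo[k] & v <= bounds$hi[k]
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop exact duplicate records
#'
#' Removes rows whose condition *and* yield exactly equal an earlier row
#' (first occurrence kept). Rows with equal conditions but different yields
#' are biological replicates and are retained.
#'
#' @param records An `experiment_records` data frame.
#' @return Deduplicated records, original order.
#' @export
dedup_records <- function(records) {
  out <- records[!duplicated(records[c(culture_factors(), "yield")]), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_records <- function(x, ...) {
  cat("Phellinus fermentation records: ", nrow(x), " experiment(s)\n",
      sep = "")
  shown <- as.data.frame(x)
  shown$inoculum <- paste0(format(shown$inoculum * 100), "%")
  print(utils::head(shown, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}
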