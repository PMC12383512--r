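.LOGBOOK_COLS <- c("date", "lat", "lon", "species", "catch_t", "hauls",
                   "effort_days", "vessel_id", "vessel_length_m")

#' Read and write logbook CSV files
#'
#' The logbook dialect has header \code{date,lat,lon,species,catch_t,hauls,
#' effort_days,vessel_id,vessel_length_m}, ISO-8601 dates and decimal
#' degrees.
#'
#' @param records Logbook data.frame.
#' @param path File path.
#' @return \code{readLogbook}: the validated data.frame.
#' @export
writeLogbook <- function(records, path) {
  miss <- setdiff(.LOGBOOK_COLS, names(records))
  if (length(miss)) stop("logbook lacks column(s): ", paste(miss, collapse = ", "))
  write.csv(records[, .LOGBOOK_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLogbook
#' @export
readLogbook <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.LOGBOOK_COLS, names(rec))
  if (length(miss)) stop("logbook lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(as.Date(rec$date, format = "%Y-%m-%d"))) stop("logbook contains unparseable dates")
  rec
}

#' Write a validation report to JSON and tidy CSV
#'
#' @param report A \linkS4class{ValidationReport}.
#' @param stem Output path stem; writes \code{<stem>.json} and
#'   \code{<stem>.csv}.
#' @return Invisibly, the two paths.
#' @export
writeValidationReport <- function(report, stem) {
  js <- list(iterations = report@iterations,
             note = "p-values are descriptive: holdout replicates share training data",
             summary = report@summary, r2 = report@r2)
  if (nrow(report@effort)) js$effort <- report@effort
  jsonlite::write_json(js, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  long <- rbind(
    data.frame(month = report@r2$month, iteration = report@r2$iteration,
               model = "ssSDM", r2 = report@r2$r2_ss),
    data.frame(month = report@r2$month, iteration = report@r2$iteration,
               model = "icSDM", r2 = report@r2$r2_ic))
  write.csv(long, paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(c(paste0(stem, ".json"), paste0(stem, ".csv")))
}

#' Write a correlation report to CSV matrices and JSON
#'
#' @param report A \linkS4class{CorrelationReport}.
#' @param stem Output path stem.
#' @return Invisibly, the written paths.
#' @export
writeCorrelationReport <- function(report, stem) {
  write.csv(report@cross, paste0(stem, "_cross.csv"), row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(report@withinA), paste0(stem, "_withinA.csv"), quote = FALSE)
  write.csv(as.data.frame(report@withinB), paste0(stem, "_withinB.csv"), quote = FALSE)
  jsonlite::write_json(
    list(speciesA = report@speciesA, speciesB = report@speciesB,
         months = report@months, cross = report@cross,
         withinA = report@withinA, withinB = report@withinB),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  invisible(paste0(stem, c("_cross.csv", "_withinA.csv", "_withinB.csv", ".json")))
}
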