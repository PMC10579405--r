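#' Read and write tidy time-series tables
#'
#' The canonical on-disk schema is a tidy long CSV with columns `time_h`,
#' `variable`, `compartment` (planktonic / attached / total), `value` and
#' `units`, optionally preceded by `replicate`. Files open with provenance
#' comment lines (`# mucodyn ...`) recording the package version and, when
#' given, the seed; `read_timeseries()` skips them. Validation rejects
#' missing columns, non-finite values and negative densities, naming the
#' offending rows.
#'
#' @param ts tidy time-series data.frame.
#' @param path file path.
#' @param seed optional integer recorded in the provenance header.
#' @return `read_timeseries()` returns the validated data.frame.
#' @export
write_timeseries <- function(ts, path, seed = NULL) {
  need <- c("time_h", "variable", "compartment", "value", "units")
  miss <- setdiff(need, names(ts))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# mucodyn ", as.character(utils::packageVersion("mucodyn")),
           " tidy time series"),
    if (!is.null(seed)) paste0("# seed: ", seed)), con)
  utils::write.csv(ts, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  ts <- utils::read.csv(path, comment.char = "#")
  need <- c("time_h", "variable", "compartment", "value", "units")
  miss <- setdiff(need, names(ts))
  if (length(miss))
    stop("schema violation: missing column(s) ", paste(miss, collapse = ", "))
  bad_comp <- !ts$compartment %in% c("planktonic", "attached", "total")
  if (any(bad_comp))
    stop("schema violation: unknown compartment in row(s) ",
         paste(utils::head(which(bad_comp), 5), collapse = ", "))
  dens <- ts$units == "cells/ul"
  bad <- dens & (!is.finite(ts$value) | ts$value < 0)
  if (any(bad))
    stop("schema violation: negative or non-finite density in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  ts
}

#' Read and write event tables
#'
#' Flow-cytometry events are exchanged as CSV with the four channel columns
#' (`FSC`, `SSC`, `FL_SG`, `FL_PI`); additional columns (`truth_label`,
#' `sample_id`, `dilution`, `acquisition_volume_ul`, ...) are preserved.
#' Channel aliases can be mapped to the canonical names on read.
#'
#' @param events event data.frame.
#' @param path file path.
#' @param channel_map optional named character vector mapping file column
#'   names to canonical channel names, e.g.
#'   `c("FSC-H" = "FSC", "FL1-H" = "FL_SG")`.
#' @return `read_events()` returns the validated event data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, channel_map = NULL) {
  ev <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(channel_map)) {
    hit <- names(ev) %in% names(channel_map)
    names(ev)[hit] <- channel_map[names(ev)[hit]]
  }
  names(ev) <- make.names(names(ev))
  chans <- intersect(c("FSC", "SSC", "FL_SG", "FL_PI"), names(ev))
  if (length(chans) < 2)
    stop("schema violation: fewer than 2 recognised channel columns")
  for (ch in chans) {
    bad <- !is.finite(ev[[ch]])
    if (any(bad))
      stop("schema violation: non-finite ", ch, " in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if ("dilution" %in% names(ev) && any(ev$dilution <= 0))
    stop("schema violation: dilution must be > 0")
  ev
}
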