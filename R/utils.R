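# Internal helpers: error conditions, clock, sequence utilities.

af_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "annoforge_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

af_bounds_error     <- function(msg, ...) af_error("af_bounds_error", msg, ...)
af_validation_error <- function(msg, ...) af_error("af_validation_error", msg, ...)
af_permission_error <- function(msg, ...) af_error("af_permission_error", msg, ...)
af_format_error     <- function(msg, ...) af_error("af_format_error", msg, ...)
af_not_found_error  <- function(msg, ...) af_error("af_not_found_error", msg, ...)
af_usage_error      <- function(msg, ...) af_error("af_usage_error", msg, ...)

af_notice <- function(...) message("annoforge: ", ...)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of a plain character string (A/C/G/T/N).
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Clock used for history timestamps.  timestamp_mode "real" reads the wall
# clock; "logical" derives a deterministic ISO-8601 instant from a counter so
# replayed sessions are byte-identical.
af_timestamp <- function(config, counter) {
  mode <- config$timestamp_mode %||% "real"
  if (identical(mode, "logical")) {
    format(as.POSIXct("2000-01-01 00:00:00", tz = "UTC") + counter,
           "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  } else {
    format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
}

# Coalesce sorted exon intervals: merge overlapping or bookended (gap 0)
# intervals.  `exons` is a data.frame(start, end), 0-based half-open.
coalesce_exons <- function(exons) {
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  if (nrow(exons) <= 1L) {
    rownames(exons) <- NULL
    return(exons)
  }
  out_start <- exons$start[1L]
  out_end <- exons$end[1L]
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(exons))[-1L]) {
    if (exons$start[i] <= out_end) {
      out_end <- max(out_end, exons$end[i])
    } else {
      starts <- c(starts, out_start)
      ends <- c(ends, out_end)
      out_start <- exons$start[i]
      out_end <- exons$end[i]
    }
  }
  starts <- c(starts, out_start)
  ends <- c(ends, out_end)
  data.frame(start = starts, end = ends)
}
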