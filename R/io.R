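#' Construct a CGM trace
#'
#' A light container for one subject's ordered glucose readings at a
#' fixed sampling period. `segments` records the lengths of contiguous
#' runs: recording gaps detected by [read_cgm()] split a trace into
#' segments so that lagged statistics never bridge a gap.
#'
#' @param values glucose concentrations in mg/dL, positive and finite,
#'   length >= 2.
#' @param period_seconds sampling period in seconds (default 300).
#' @param subject opaque subject label.
#' @param segments integer run lengths summing to `length(values)`.
#' @return an object of class `cgm_trace`.
#' @examples
#' cgm_trace(c(69.9, 70, 180, 53.9))
#' @export
cgm_trace <- function(values, period_seconds = 300, subject = "subject",
                      segments = length(values)) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("'values' must be a numeric vector of length >= 2", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("invalid glucose value at index ", bad[1],
         " (must be positive and finite)", call. = FALSE)
  samples_per_day(period_seconds)
  if (sum(segments) != length(values) || any(segments < 1))
    stop("'segments' must be positive run lengths summing to length(values)",
         call. = FALSE)
  structure(list(values = as.numeric(values),
                 period_seconds = period_seconds,
                 subject = as.character(subject),
                 segments = as.integer(segments)),
            class = "cgm_trace")
}

#' @export
print.cgm_trace <- function(x, ...) {
  cat(sprintf("CGM trace '%s': %d samples at %gs period (%d segment%s)\n",
              x$subject, length(x$values), x$period_seconds,
              length(x$segments), if (length(x$segments) > 1) "s" else ""))
  invisible(x)
}

MGDL_PER_MMOLL <- 18.016

#' Read a cohort of CGM traces from a delimited text file
#'
#' Expects a header with a glucose column and, optionally, subject and
#' ISO-8601 timestamp columns. Values in mmol/L are converted to mg/dL
#' (factor 18.016). When timestamps are present, consecutive readings
#' more than `1.5 *` the sampling period apart mark a recording gap and
#' the trace is split into contiguous segments (reported via `message`);
#' without timestamps the samples are taken as contiguous.
#'
#' @param path path to a delimited text file.
#' @param glucose_col,subject_col,time_col column names; `subject_col`
#'   and `time_col` are used only if present in the file.
#' @param units `"mg/dL"` (default) or `"mmol/L"`.
#' @param period_seconds sampling period in seconds (default 300).
#' @param sep field separator (default comma).
#' @return a list of [cgm_trace()] objects, one per subject.
#' @export
read_cgm <- function(path, glucose_col = "glucose",
                     subject_col = "subject_id", time_col = "timestamp",
                     units = c("mg/dL", "mmol/L"), period_seconds = 300,
                     sep = ",") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!glucose_col %in% names(df))
    stop("missing glucose column '", glucose_col, "' in ", path,
         call. = FALSE)
  g <- suppressWarnings(as.numeric(df[[glucose_col]]))
  bad <- which(is.na(g) | !is.finite(g) | g <= 0)
  if (length(bad))
    stop("unparseable or non-positive glucose at data row ", bad[1],
         call. = FALSE)
  if (units == "mmol/L") g <- g * MGDL_PER_MMOLL
  subj <- if (subject_col %in% names(df)) as.character(df[[subject_col]])
          else rep("subject", length(g))
  times <- if (time_col %in% names(df)) {
    tt <- as.POSIXct(df[[time_col]], tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    if (anyNA(tt))
      stop("unparseable timestamp at data row ", which(is.na(tt))[1],
           call. = FALSE)
    tt
  } else NULL
  lapply(split(seq_along(g), factor(subj, levels = unique(subj))),
         function(idx) {
    segs <- length(idx)
    if (!is.null(times)) {
      tsub <- times[idx]
      if (any(diff(as.numeric(tsub)) <= 0))
        stop("non-increasing timestamps for subject '", subj[idx[1]], "'",
             call. = FALSE)
      gap_after <- which(diff(as.numeric(tsub)) > 1.5 * period_seconds)
      if (length(gap_after)) {
        segs <- diff(c(0L, gap_after, length(idx)))
        message(sprintf("subject '%s': %d recording gap(s), split into %d segments",
                        subj[idx[1]], length(gap_after), length(segs)))
      }
    }
    cgm_trace(g[idx], period_seconds = period_seconds,
              subject = subj[idx[1]], segments = segs)
  })
}
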