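#' Glycemic ranges
#'
#' A glycemic range is a half-open glucose interval `[lower, upper)` in
#' mg/dL whose indicator dichotomizes a CGM trace. Named presets follow the
#' standard clinical cut-points:
#' \describe{
#'   \item{`"tbr"`}{time below range, glucose < 70 mg/dL}
#'   \item{`"l2h"`}{level 2 hypoglycemia, glucose < 54 mg/dL}
#'   \item{`"tir"`}{time in range, 70 <= glucose < 180 mg/dL}
#'   \item{`"tar"`}{time above range, glucose >= 180 mg/dL}
#' }
#' A reading exactly at a bound belongs to the side where the bound is
#' inclusive: the TBR indicator is strictly `glucose < 70`.
#'
#' @param x a preset name, an existing `glycemic_range`, or a numeric
#'   `c(lower, upper)` pair (use `-Inf`/`Inf` for unbounded sides).
#' @return an object of class `glycemic_range` with fields `lower`,
#'   `upper`, `label`.
#' @examples
#' glycemic_range("tbr")
#' glycemic_range(c(54, 70))
#' @export
glycemic_range <- function(x = "tbr") {
  if (inherits(x, "glycemic_range")) return(x)
  presets <- list(tbr = c(-Inf, 70), l2h = c(-Inf, 54),
                  tir = c(70, 180), tar = c(180, Inf))
  if (is.character(x)) {
    key <- match.arg(tolower(x), names(presets))
    b <- presets[[key]]
    label <- toupper(key)
  } else if (is.numeric(x) && length(x) == 2L) {
    b <- as.numeric(x)
    label <- sprintf("[%s, %s)", format(b[1]), format(b[2]))
  } else {
    stop("'x' must be a preset name or a c(lower, upper) pair", call. = FALSE)
  }
  if (is.na(b[1]) || is.na(b[2]) || b[1] >= b[2])
    stop("glycemic range requires lower < upper", call. = FALSE)
  structure(list(lower = b[1], upper = b[2], label = label),
            class = "glycemic_range")
}

#' @export
print.glycemic_range <- function(x, ...) {
  cat(sprintf("Glycemic range %s: %s <= glucose < %s mg/dL\n",
              x$label, format(x$lower), format(x$upper)))
  invisible(x)
}

#' Dichotomize a CGM trace against a glycemic range
#'
#' Maps glucose readings to the binary indicator `h_k = 1` when
#' `lower <= g_k < upper`, 0 otherwise (for TBR: 1 when `g_k < 70` mg/dL).
#'
#' @param x numeric glucose vector in mg/dL, or a [cgm_trace()].
#' @param range a [glycemic_range()] or preset name (default `"tbr"`).
#' @return an integer 0/1 vector of the same length; for a `cgm_trace`
#'   input the `segments` attribute (contiguous-run lengths) is carried
#'   over.
#' @examples
#' dichotomize(c(69.9, 70, 180, 53.9), "tbr")  # 1 0 0 1
#' dichotomize(c(69.9, 70, 180, 53.9), "l2h")  # 0 0 0 1
#' @export
dichotomize <- function(x, range = "tbr") {
  range <- glycemic_range(range)
  segments <- NULL
  if (inherits(x, "cgm_trace")) {
    segments <- x$segments
    x <- x$values
  }
  if (!is.numeric(x) || length(x) == 0L)
    stop("glucose input must be a non-empty numeric vector", call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite glucose value at index ", bad[1], call. = FALSE)
  bits <- as.integer(x >= range$lower & x < range$upper)
  if (!is.null(segments)) attr(bits, "segments") <- segments
  bits
}

#' Fraction of time spent in a glycemic metric
#'
#' The prefix-mean estimator `t(n)`: the mean of the first `n` indicator
#' values. Over the full trace this is the clinical TBR/TIR/TAR value and
#' the whole-trial estimate of `p_h`.
#'
#' @param bits 0/1 indicator vector (from [dichotomize()]).
#' @param n prefix length; defaults to the full length.
#' @return a fraction in `[0, 1]`.
#' @examples
#' time_in_metric(c(1, 0, 0, 1))      # 0.5
#' time_in_metric(c(1, 0, 0, 1), 1)   # 1
#' @export
time_in_metric <- function(bits, n = length(bits)) {
  bits <- check_bits(bits)
  if (length(n) != 1L || !is.finite(n) || n < 1 || n > length(bits) ||
      n != floor(n))
    stop("'n' must be an integer in [1, length(bits)]", call. = FALSE)
  mean(bits[seq_len(n)])
}

check_bits <- function(bits) {
  if (is.logical(bits)) bits <- as.integer(bits)
  if (!is.numeric(bits) || length(bits) == 0L || anyNA(bits) ||
      !all(bits %in% c(0, 1)))
    stop("expected a non-empty 0/1 indicator vector", call. = FALSE)
  bits
}
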