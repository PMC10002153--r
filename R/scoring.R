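#' Third-molar maturity index
#'
#' `I3M = (a + b) / c`: the summed open-apex widths over the tooth height.
#' The index is dimensionless, so the pixel scale of the crop cancels.
#'
#' @param m An `i3m_measurement` (or any list with `a_px`, `b_px`, `c_px`).
#' @return The I3M ratio.
#' @export
compute_i3m <- function(m) {
  if (!is.finite(m$c_px) || m$c_px <= 0) {
    abort_invalid_measurement("tooth height c must be positive")
  }
  (m$a_px + m$b_px) / m$c_px
}

#' Minor/adult decision from an I3M score
#'
#' A subject is classified adult (>= 18 years) iff `i3m < threshold`, minor
#' otherwise. The boundary case `i3m == threshold` classifies as minor: the
#' conservative direction in a safeguarding context. The 0.08 default cut-off
#' is the standard discrimination threshold for mandibular third molars; it
#' is exposed so population-specific cut-offs can be used.
#'
#' @param i3m Non-negative I3M score.
#' @param threshold Positive decision cut-off.
#' @return `"adult"` or `"minor"`.
#' @export
classify_age <- function(i3m, threshold = 0.08) {
  stopifnot(threshold > 0)
  if (any(!is.finite(i3m)) || any(i3m < 0)) {
    abort_invalid_measurement("I3M must be finite and non-negative")
  }
  ifelse(i3m < threshold, "adult", "minor")
}

#' Score a measurement and take the decision
#'
#' @param measurement An `i3m_measurement`.
#' @param threshold Decision cut-off (see [classify_age()]).
#' @return Object of class `i3m_result` with `i3m`, `threshold`, `decision`
#'   and the underlying `measurement`.
#' @export
i3m_result <- function(measurement, threshold = 0.08) {
  score <- compute_i3m(measurement)
  structure(list(i3m = score, threshold = threshold,
                 decision = classify_age(score, threshold),
                 measurement = measurement),
            class = "i3m_result")
}

#' @export
print.i3m_result <- function(x, ...) {
  cat(sprintf("<i3m_result %s> I3M = %.4f (threshold %.3f) -> %s\n",
              x$measurement$method, x$i3m, x$threshold, x$decision))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.i3m_measurement <- function(x, ...) {
  tibble::tibble(method = x$method, a_px = x$a_px, b_px = x$b_px,
                 c_px = x$c_px, i3m = compute_i3m(x))
}

#' @export
tidy.i3m_result <- function(x, ...) {
  dplyr::mutate(tidy(x$measurement), threshold = x$threshold,
                decision = x$decision)
}
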