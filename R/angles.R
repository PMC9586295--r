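#' Wrap an angle into (-pi, pi]
#'
#' Maps any finite angle onto the principal interval `(-pi, pi]`, the interval
#' used throughout the package for swimming headings. The upper endpoint is
#' closed so that `wrap_angle(pi) == pi` and `wrap_angle(-pi) == pi`.
#'
#' @param a numeric vector of angles (rad); must be finite.
#' @return numeric vector of the same length, congruent to `a` modulo `2*pi`,
#'   each element in `(-pi, pi]`.
#' @examples
#' wrap_angle(c(0, pi + 0.1, -3 * pi))
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a))) {
    stop("wrap_angle(): input angles must be finite numeric values")
  }
  a - 2 * pi * ceiling((a - pi) / (2 * pi))
}
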