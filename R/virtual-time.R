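#' Virtual time
#'
#' Virtual time is measured in seconds from the start of a round (round start
#' is 0) on a fixed tick grid. All scripted times, injected-action times and
#' engine transitions are quantized to the grid so that replay is exactly
#' deterministic.
#'
#' @param t numeric vector of times in seconds.
#' @param tick grid resolution in seconds (default 0.1).
#' @return `vt_quantize()` returns `t` snapped to the nearest grid point.
#' @examples
#' vt_quantize(1.2499)
#' vt_eq(0.30000000001, 0.3)
#' @export
vt_quantize <- function(t, tick = 0.1) {
  stopifnot(is.numeric(t), all(t >= 0 | is.infinite(t)))
  ifelse(is.infinite(t), t, round(round(t / tick) * tick, 9))
}

#' @rdname vt_quantize
#' @param a,b times to compare.
#' @return `vt_eq()` returns TRUE where `a` and `b` fall on the same tick.
#' @export
vt_eq <- function(a, b, tick = 0.1) {
  abs(a - b) < tick / 2
}

# smallest grid multiple of `unit` that is >= t
vt_ceil <- function(t, unit) round(ceiling(round(t / unit, 9)) * unit, 9)
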