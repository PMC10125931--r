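#' Exponential speed-accuracy curve
#'
#' The classic exponential-approach-to-a-limit description of the
#' speed--accuracy trade-off (Wickelgren, 1977): below the x-offset `delta`
#' responding is mere guessing and PC stays at 50% (two response
#' alternatives); beyond it, `PC = (lam/2) * (1 - exp(-gamma * (rt_bar -
#' delta))) + 50`, rising towards the asymptote `lam/2 + 50`.  The curve is
#' continuous at `rt_bar = delta` and monotone non-decreasing.
#'
#' Time units follow the caller (e.g. seconds with `delta = 0.20`); no hidden
#' conversion is applied, so `rt_bar` and `delta`/`gamma` must share a unit.
#'
#' @param rt_bar Mean RT value(s) at which to evaluate the curve.
#' @param delta x-offset (same time unit as `rt_bar`).
#' @param gamma Steepness (> 0, per time unit).
#' @param lam PC-asymptote span in percentage points, in `[0, 100]`; the
#'   asymptote itself is `lam/2 + 50`.
#' @return PC in percent, same length as `rt_bar`.
#' @examples
#' wickelgren_pc(c(0.1, 0.3, 2), delta = 0.20, gamma = 5, lam = 95)
#' @export
wickelgren_pc <- function(rt_bar, delta, gamma, lam) {
  stopifnot(is.numeric(rt_bar), all(is.finite(rt_bar)),
            length(delta) == 1L, is.finite(delta),
            length(gamma) == 1L, is.finite(gamma), gamma > 0,
            length(lam) == 1L, is.finite(lam), lam >= 0, lam <= 100)
  ifelse(rt_bar < delta, 50,
         (lam / 2) * (1 - exp(-gamma * (rt_bar - delta))) + 50)
}
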