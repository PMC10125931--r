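#' Diffusion-trial parameter set
#'
#' Bundles the parameters of a single two-boundary Wiener diffusion trial:
#' evidence accumulates from `start` with drift `v` and noise scale `sigma`
#' until it reaches the upper boundary `a` (a correct response) or the lower
#' boundary at 0 (an error).  The non-decision time `t_er` (encoding and motor
#' time) is added to the decision time to give the response time.
#'
#' Time is in milliseconds throughout; evidence units are arbitrary (only the
#' ratios `v*a/sigma^2` and `a^2/sigma^2` matter for behavior).
#'
#' @param v Drift rate (evidence units per ms).
#' @param a Threshold separation (evidence units); must be positive.
#' @param start Starting activation, strictly between 0 and `a`.  Defaults to
#'   the unbiased midpoint `a/2`.
#' @param sigma Diffusion noise scale (evidence units per sqrt-ms).  Default 4.
#' @param t_er Non-decision time in ms, non-negative.  Default 0.
#'
#' @return An object of class `diffusion_params`.
#' @seealso [simulate_trials()], [analytic_accuracy()], [analytic_mean_dt()]
#' @examples
#' p <- diffusion_params(v = 0.25, a = 125, t_er = 300)
#' analytic_accuracy(p)
#' @export
diffusion_params <- function(v, a, start = a / 2, sigma = 4, t_er = 0) {
  for (nm in c("v", "a", "start", "sigma", "t_er")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("invalid parameter: `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (a <= 0) stop("invalid parameter: `a` must be > 0", call. = FALSE)
  if (start <= 0 || start >= a) {
    stop("invalid parameter: `start` must lie strictly between 0 and `a`",
         call. = FALSE)
  }
  if (sigma <= 0) stop("invalid parameter: `sigma` must be > 0", call. = FALSE)
  if (t_er < 0) stop("invalid parameter: `t_er` must be >= 0", call. = FALSE)
  structure(list(v = v, a = a, start = start, sigma = sigma, t_er = t_er),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf(
    "<diffusion_params> v = %g, a = %g, start = %g, sigma = %g, t_er = %g ms\n",
    x$v, x$a, x$start, x$sigma, x$t_er))
  invisible(x)
}

as_diffusion_params <- function(params) {
  if (inherits(params, "diffusion_params")) return(params)
  do.call(diffusion_params, as.list(params))
}

#' Simulate diffusion trials
#'
#' First-passage simulation of the two-boundary Wiener process by
#' Euler--Maruyama discretization with step `dt`:
#' `X <- X + v*dt + sigma*sqrt(dt)*N(0,1)`, absorbed at `>= a` (correct) or
#' `<= 0` (error).  The returned `rt` is the absorption step times `dt` plus
#' `t_er`, so every `rt` strictly exceeds `t_er`.
#'
#' Randomness comes from R's global RNG: call `set.seed()` beforehand for
#' reproducibility.  `simulate_trials(params, n)` consumes the stream exactly
#' as `n` successive [simulate_trial()] calls would.
#'
#' @param params A [diffusion_params()] object (or a list coercible to one).
#' @param n Number of trials.
#' @param dt Integration step in ms.  Default 1.  The discretization induces a
#'   small positive bias in decision time and accuracy that shrinks with
#'   `sqrt(dt)`; see the package vignette.
#' @param max_steps Maximum number of steps before a trial is abandoned.
#'   Default 20000 (i.e. 20 s at `dt = 1`), effectively unreachable at typical
#'   parameters.
#' @param on_max What to do with unabsorbed trials: `"error"` (default) stops;
#'   `"drop"` removes them and records the count in the `n_dropped` attribute
#'   (used by the study harness).
#'
#' @return A data.frame with columns `rt` (ms) and `correct` (logical), one
#'   row per completed trial.
#' @examples
#' set.seed(1)
#' trials <- simulate_trials(diffusion_params(0.25, 125, t_er = 300), 1000)
#' mean(trials$correct)  # close to analytic_accuracy()
#' @export
simulate_trials <- function(params, n, dt = 1, max_steps = 20000L,
                            on_max = c("error", "drop")) {
  params <- as_diffusion_params(params)
  on_max <- match.arg(on_max)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, is.finite(n))
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0, is.finite(dt))
  res <- wiener_trials_cpp(as.integer(n), params$v, params$a, params$start,
                           params$sigma, params$t_er, dt,
                           as.integer(max_steps))
  out <- data.frame(rt = res$rt, correct = res$correct)
  bad <- is.na(out$rt)
  if (any(bad)) {
    if (on_max == "error") {
      stop("max-duration error: ", sum(bad), " trial(s) not absorbed within ",
           max_steps, " steps", call. = FALSE)
    }
    out <- out[!bad, , drop = FALSE]
    row.names(out) <- NULL
  }
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Simulate a single diffusion trial
#'
#' @inheritParams simulate_trials
#' @return A list with elements `rt` (ms) and `correct` (logical).
#' @export
simulate_trial <- function(params, dt = 1, max_steps = 20000L) {
  res <- simulate_trials(params, 1L, dt = dt, max_steps = max_steps,
                         on_max = "error")
  list(rt = res$rt[1L], correct = res$correct[1L])
}

#' Closed-form accuracy of the Wiener diffusion
#'
#' Probability of absorption at the upper (correct) boundary for the
#' continuous-time process:
#' `P = (1 - exp(-2*v*start/sigma^2)) / (1 - exp(-2*v*a/sigma^2))`,
#' with the limit `start/a` as `v -> 0`.  Serves as the validation oracle for
#' the simulator.
#'
#' @inheritParams simulate_trials
#' @return Probability of a correct response.
#' @examples
#' analytic_accuracy(diffusion_params(0.25, 125))  # ~0.876
#' @export
analytic_accuracy <- function(params) {
  params <- as_diffusion_params(params)
  if (params$v == 0) return(params$start / params$a)
  s2 <- params$sigma^2
  # -expm1 for numerical stability at small exponents
  (-expm1(-2 * params$v * params$start / s2)) /
    (-expm1(-2 * params$v * params$a / s2))
}

#' Closed-form mean decision time of the Wiener diffusion
#'
#' Mean first-passage time (either boundary) for the unbiased starting point
#' `start = a/2`: `(a/(2v)) * tanh(v*a/(2*sigma^2))` for `v != 0`, and
#' `a^2/(4*sigma^2)` at `v = 0`.  Decision time only; add `t_er` for the mean
#' response time.  Only the midpoint start is supported.
#'
#' @inheritParams simulate_trials
#' @return Mean decision time in ms.
#' @examples
#' analytic_mean_dt(diffusion_params(0.25, 125))  # ~187.9 ms
#' @export
analytic_mean_dt <- function(params) {
  params <- as_diffusion_params(params)
  if (abs(params$start - params$a / 2) > 1e-9 * params$a) {
    stop("not implemented: analytic_mean_dt requires start = a/2",
         call. = FALSE)
  }
  s2 <- params$sigma^2
  if (params$v == 0) return(params$a^2 / (4 * s2))
  (params$a / (2 * params$v)) * tanh(params$v * params$a / (2 * s2))
}
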