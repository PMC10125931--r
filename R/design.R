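#' Two-condition within-participants design specification
#'
#' Describes how a simulated experiment is generated: one focal diffusion
#' parameter (drift rate or threshold separation) takes baseline values
#' `mu[1]` and `mu[2]` in the two conditions and is perturbed per participant
#' and per participant-by-condition cell,
#' `mu_ij = mu_j + eps_i_between + eps_ij_within`, with
#' `eps_between ~ N(0, sigma_b2)` shared by both conditions of a participant
#' (stable individual differences) and `eps_within ~ N(0, sigma_w2)` drawn
#' independently per cell (the participant-by-condition error term).  The
#' non-decision time is drawn once per participant from
#' `N(t_er_mean, t_er_sd^2)` and shared across conditions, adding
#' between-participant spread to mean RT.
#'
#' The implied between-condition correlation of the focal parameter across
#' participants is [theoretical_correlation()]`(sigma_b2, sigma_w2)`.
#'
#' @param focal Which diffusion parameter carries the manipulation:
#'   `"drift"` (a genuine difficulty/ability effect) or `"threshold"` (a pure
#'   speed--accuracy trade-off effect).
#' @param mu Length-2 numeric: baseline focal-parameter value in conditions 1
#'   and 2.
#' @param fixed Value of the non-focal parameter (threshold separation when
#'   `focal = "drift"`, drift rate when `focal = "threshold"`).
#' @param sigma_b2 Between-participants variance of the focal parameter.
#' @param sigma_w2 Within (participant-by-condition) variance of the focal
#'   parameter.
#' @param t_er_mean,t_er_sd Mean and SD (ms) of the per-participant
#'   non-decision time.  Defaults 300 and 20.
#' @param sigma Diffusion noise scale.  Default 4.
#' @param n_participants Participants per experiment.  Default 20.
#' @param n_trials Trials per participant-by-condition cell.  Default 1000.
#'
#' @return An object of class `design_spec`.
#' @seealso [design_drift_effect()], [design_sat_effect()], [design_null()]
#' @export
design_spec <- function(focal = c("drift", "threshold"), mu, fixed,
                        sigma_b2, sigma_w2, t_er_mean = 300, t_er_sd = 20,
                        sigma = 4, n_participants = 20L, n_trials = 1000L) {
  focal <- match.arg(focal)
  stopifnot(is.numeric(mu), length(mu) == 2L, all(is.finite(mu)),
            is.numeric(fixed), length(fixed) == 1L, is.finite(fixed),
            is.numeric(sigma_b2), length(sigma_b2) == 1L, sigma_b2 >= 0,
            is.numeric(sigma_w2), length(sigma_w2) == 1L, sigma_w2 >= 0,
            t_er_mean >= 0, t_er_sd >= 0, sigma > 0)
  n_participants <- as.integer(n_participants)
  n_trials <- as.integer(n_trials)
  if (n_participants < 2L) stop("need n_participants >= 2", call. = FALSE)
  if (n_trials < 1L) stop("need n_trials >= 1", call. = FALSE)
  structure(list(focal = focal, mu = as.numeric(mu), fixed = fixed,
                 sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
                 t_er_mean = t_er_mean, t_er_sd = t_er_sd, sigma = sigma,
                 n_participants = n_participants, n_trials = n_trials),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<design_spec> focal = %s (mu = %g vs %g, fixed = %g)\n",
           "  sigma_b2 = %g, sigma_w2 = %g (r = %.3g), t_er ~ N(%g, %g^2)\n",
           "  %d participants x 2 conditions x %d trials\n"),
    x$focal, x$mu[1], x$mu[2], x$fixed, x$sigma_b2, x$sigma_w2,
    if (x$sigma_b2 + x$sigma_w2 > 0)
      theoretical_correlation(x$sigma_b2, x$sigma_w2) else NA_real_,
    x$t_er_mean, x$t_er_sd, x$n_participants, x$n_trials))
  invisible(x)
}

#' Reference designs: drift effect, SAT effect, null
#'
#' Pre-configured [design_spec()]s for the standard validation conditions.
#' `design_drift_effect()` induces a genuine difficulty effect by varying the
#' drift rate (v = 0.246 vs 0.254 at a = 125, variance components 0.01^2 and
#' 0.005^2); `design_sat_effect()` induces a pure speed--accuracy trade-off by
#' varying the threshold separation (a = 120 vs 130 at v = 0.25, variance
#' components 20^2 and 10^2); `design_null()` keeps the threshold identical in
#' both conditions (type-I-error calibration).  Both variance-component pairs
#' imply a between-condition parameter correlation of .80.
#'
#' @param v,a Focal/fixed diffusion parameters; length 2 for the varied one.
#' @param sigma_b2,sigma_w2 Variance components of the focal parameter.
#' @param ... Passed on to [design_spec()] (e.g. `n_participants`,
#'   `n_trials`, `t_er_sd`).
#' @return A `design_spec`.
#' @examples
#' design_sat_effect()
#' design_sat_effect(a = c(110, 130), v = 0.35)  # a stronger SAT manipulation
#' @export
design_drift_effect <- function(v = c(0.246, 0.254), a = 125,
                                sigma_b2 = 0.01^2, sigma_w2 = 0.005^2, ...) {
  design_spec("drift", mu = v, fixed = a,
              sigma_b2 = sigma_b2, sigma_w2 = sigma_w2, ...)
}

#' @rdname design_drift_effect
#' @export
design_sat_effect <- function(a = c(120, 130), v = 0.25,
                              sigma_b2 = 20^2, sigma_w2 = 10^2, ...) {
  design_spec("threshold", mu = a, fixed = v,
              sigma_b2 = sigma_b2, sigma_w2 = sigma_w2, ...)
}

#' @rdname design_drift_effect
#' @export
design_null <- function(a = c(125, 125), v = 0.25,
                        sigma_b2 = 20^2, sigma_w2 = 10^2, ...) {
  design_spec("threshold", mu = a, fixed = v,
              sigma_b2 = sigma_b2, sigma_w2 = sigma_w2, ...)
}

#' Theoretical between-condition correlation of the focal parameter
#'
#' With a shared between-participant perturbation of variance `sigma_b2` and
#' independent per-cell perturbations of variance `sigma_w2`, the correlation
#' of the realized parameter between the two conditions across participants is
#' `sigma_b2 / (sigma_b2 + sigma_w2)`.
#'
#' @param sigma_b2 Between-participants variance (>= 0).
#' @param sigma_w2 Within (participant-by-condition) variance (>= 0).
#' @return The correlation in `[0, 1]`.
#' @examples
#' theoretical_correlation(20^2, 10^2)  # 0.8
#' @export
theoretical_correlation <- function(sigma_b2, sigma_w2) {
  stopifnot(is.numeric(sigma_b2), is.numeric(sigma_w2),
            all(sigma_b2 >= 0), all(sigma_w2 >= 0))
  if (any(sigma_b2 + sigma_w2 == 0)) {
    stop("undefined correlation: sigma_b2 and sigma_w2 are both zero",
         call. = FALSE)
  }
  sigma_b2 / (sigma_b2 + sigma_w2)
}

# Redraw-until-valid normal draw; invalid realizations (non-positive focal
# parameter, negative t_er) have negligible probability at realistic
# parameters but would break the simulator.
redraw_valid <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  tries <- 0L
  while (any(bad <- x <= lower)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    tries <- tries + 1L
    if (tries > 1000L) stop("could not draw valid parameters", call. = FALSE)
  }
  x
}

#' Draw realized per-cell parameters for one experiment
#'
#' Realizes `mu_ij = mu_j + eps_i_between + eps_ij_within` for every
#' participant-by-condition cell plus one non-decision time per participant.
#' Realizations that would be invalid for the diffusion (focal parameter
#' <= 0, `t_er` < 0) are redrawn cell-wise, which leaves the marginal
#' essentially Gaussian at realistic settings.  Uses R's global RNG.
#'
#' @param spec A [design_spec()].
#' @return A data.frame with columns `participant`, `condition`, `mu`
#'   (realized focal parameter) and `t_er` (ms; identical across a
#'   participant's conditions), ordered by participant then condition.
#' @examples
#' set.seed(1)
#' draw_parameters(design_sat_effect(n_participants = 4))
#' @export
draw_parameters <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  np <- spec$n_participants
  eps_b <- rnorm(np, 0, sqrt(spec$sigma_b2))
  t_er <- redraw_valid(np, spec$t_er_mean, spec$t_er_sd, lower = -1e-12)
  # per-cell within perturbation; redraw a cell if mu_ij would be <= 0
  mu <- matrix(NA_real_, np, 2L)
  for (j in 1:2) {
    base <- spec$mu[j] + eps_b
    eps_w <- rnorm(np, 0, sqrt(spec$sigma_w2))
    mu_j <- base + eps_w
    tries <- 0L
    while (any(bad <- mu_j <= 0)) {
      mu_j[bad] <- base[bad] + rnorm(sum(bad), 0, sqrt(spec$sigma_w2))
      tries <- tries + 1L
      if (tries > 1000L) stop("could not draw valid parameters", call. = FALSE)
    }
    mu[, j] <- mu_j
  }
  data.frame(participant = rep(seq_len(np), each = 2L),
             condition = rep(1:2, times = np),
             mu = as.vector(t(mu)),
             t_er = rep(t_er, each = 2L))
}

#' Generate one simulated experiment
#'
#' Draws per-cell parameters (unless `draws` is supplied) and simulates
#' `n_trials` diffusion trials per participant-by-condition cell, assembling
#' drift and threshold from the focal/fixed values with starting point `a/2`.
#'
#' @param spec A [design_spec()].
#' @param draws Optional result of [draw_parameters()] for `spec`; drawn
#'   fresh when `NULL`.
#' @param dt,max_steps Passed to [simulate_trials()].
#' @param on_max `"drop"` (default; unabsorbed trials are removed and counted
#'   in the `n_dropped` attribute) or `"error"`.
#' @return A trial table: data.frame with columns `participant`, `condition`,
#'   `rt` (ms) and `correct` (logical), `n_trials` rows per cell (minus
#'   drops), with attributes `draws` and `n_dropped`.
#' @examples
#' set.seed(1)
#' trials <- generate_experiment(design_sat_effect(n_participants = 2,
#'                                                 n_trials = 10))
#' head(trials)
#' @export
generate_experiment <- function(spec, draws = NULL, dt = 1,
                                max_steps = 20000L,
                                on_max = c("drop", "error")) {
  stopifnot(inherits(spec, "design_spec"))
  on_max <- match.arg(on_max)
  if (is.null(draws)) draws <- draw_parameters(spec)
  ncell <- nrow(draws)
  rts <- vector("list", ncell)
  cors <- vector("list", ncell)
  ns <- integer(ncell)
  dropped <- 0L
  for (k in seq_len(ncell)) {
    if (spec$focal == "drift") {
      v <- draws$mu[k]; a <- spec$fixed
    } else {
      v <- spec$fixed; a <- draws$mu[k]
    }
    p <- diffusion_params(v = v, a = a, start = a / 2, sigma = spec$sigma,
                          t_er = draws$t_er[k])
    cell <- simulate_trials(p, spec$n_trials, dt = dt, max_steps = max_steps,
                            on_max = on_max)
    dropped <- dropped + attr(cell, "n_dropped")
    rts[[k]] <- cell$rt
    cors[[k]] <- cell$correct
    ns[k] <- nrow(cell)
  }
  out <- data.frame(participant = rep(draws$participant, ns),
                    condition = rep(draws$condition, ns),
                    rt = unlist(rts, use.names = FALSE),
                    correct = unlist(cors, use.names = FALSE))
  attr(out, "draws") <- draws
  attr(out, "n_dropped") <- dropped
  out
}
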