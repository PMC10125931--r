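#' Monte-Carlo study configuration
#'
#' Bundles everything [run_study()] needs: the design, the number of
#' simulated experiments, the significance level, which measures to score,
#' and the master seed.  Per-experiment sub-seeds are derived
#' deterministically from the master seed, so any experiment is reproducible
#' in isolation and results do not depend on execution order.
#'
#' @param design A [design_spec()].
#' @param n_experiments Number of simulated experiments.  Default 200, which
#'   keeps a full study at desk scale; increase for tighter Monte-Carlo
#'   error.
#' @param alpha Significance level for the paired t tests.  Default .05.
#' @param measures Character vector out of [measure_names()].
#' @param seed Master integer seed.
#' @param dt,max_steps Passed to the trial simulator.
#' @return An object of class `study_config`.
#' @export
study_config <- function(design, n_experiments = 200L, alpha = 0.05,
                         measures = c("mean_rt", "pc", "bis", "lisas",
                                      "lisas_cond", "lisas_bis"),
                         seed = 1L, dt = 1, max_steps = 20000L) {
  stopifnot(inherits(design, "design_spec"))
  n_experiments <- as.integer(n_experiments)
  if (n_experiments < 1L) stop("need n_experiments >= 1", call. = FALSE)
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  bad <- setdiff(measures, measure_names())
  if (length(bad)) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(list(design = design, n_experiments = n_experiments,
                 alpha = alpha, measures = measures, seed = seed,
                 dt = dt, max_steps = as.integer(max_steps)),
            class = "study_config")
}

#' Run a Monte-Carlo validation study
#'
#' Repeats generate -> aggregate -> measure -> paired t test
#' `n_experiments` times and summarizes, per measure: the mean of the two
#' condition means, the mean effect size `d_z`, the percentage of
#' significant t tests at `alpha`, and the mean (plus range) of the
#' between-condition correlation across participants.  The correlation of
#' the realized focal diffusion parameter between conditions is summarized
#' as well, for comparison with its theoretical value
#' [theoretical_correlation()].
#'
#' Experiments in which a measure is degenerate (e.g. a zero-variance
#' difference) are logged, excluded and counted in `n_excluded`; at
#' realistic parameters none occur.
#'
#' @param config A [study_config()].
#' @param progress Print a progress line every `progress` experiments;
#'   `0` (default) is silent.
#' @return An object of class `study_summary`: list with `summary` (one row
#'   per measure: `measure`, `mean_1`, `mean_2`, `mean_dz`,
#'   `pct_significant`, `mean_r`, `min_r`, `max_r`), `param_correlation`
#'   (mean/min/max of the focal-parameter correlation),
#'   `details` (per experiment x measure: `experiment`, `measure`, `mean_1`,
#'   `mean_2`, `t`, `p`, `dz`, `r`), `n_excluded`, `n_dropped_trials`,
#'   `config`.
#' @examples
#' cfg <- study_config(design_sat_effect(n_participants = 6, n_trials = 50),
#'                     n_experiments = 5, seed = 42)
#' run_study(cfg)
#' @export
run_study <- function(config, progress = 0L) {
  stopifnot(inherits(config, "study_config"))
  nexp <- config$n_experiments
  nm <- length(config$measures)
  set.seed(config$seed)
  exp_seeds <- sample.int(.Machine$integer.max - 1L, nexp)

  det <- vector("list", nexp)
  r_mu <- rep(NA_real_, nexp)
  n_excluded <- 0L
  n_dropped <- 0L
  for (k in seq_len(nexp)) {
    set.seed(exp_seeds[k])
    res <- tryCatch(
      run_one_experiment(config),
      error = function(e) {
        message("experiment ", k, " excluded: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      n_excluded <- n_excluded + 1L
      next
    }
    res$details$experiment <- k
    det[[k]] <- res$details
    r_mu[k] <- res$r_mu
    n_dropped <- n_dropped + res$n_dropped
    if (progress > 0L && k %% progress == 0L) {
      message("experiment ", k, "/", nexp)
    }
  }
  details <- do.call(rbind, det)
  if (is.null(details)) stop("all experiments degenerate", call. = FALSE)
  row.names(details) <- NULL
  details <- details[, c("experiment", "measure", "mean_1", "mean_2",
                         "t", "p", "dz", "r")]

  safe_stat <- function(x, f) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) NA_real_ else f(x)
  }
  summarize_measure <- function(d) {
    data.frame(measure = d$measure[1L],
               mean_1 = mean(d$mean_1), mean_2 = mean(d$mean_2),
               mean_dz = mean(d$dz),
               pct_significant = percent_significant(d$p, config$alpha),
               mean_r = safe_stat(d$r, mean),
               min_r = safe_stat(d$r, min),
               max_r = safe_stat(d$r, max))
  }
  summary <- do.call(rbind, lapply(split(details, details$measure),
                                   summarize_measure))
  summary <- summary[match(config$measures, summary$measure), , drop = FALSE]
  row.names(summary) <- NULL

  structure(list(summary = summary,
                 param_correlation = c(mean = safe_stat(r_mu, mean),
                                       min = safe_stat(r_mu, min),
                                       max = safe_stat(r_mu, max)),
                 details = details,
                 n_excluded = n_excluded,
                 n_dropped_trials = n_dropped,
                 config = config),
            class = "study_summary")
}

run_one_experiment <- function(config) {
  spec <- config$design
  draws <- draw_parameters(spec)
  trials <- generate_experiment(spec, draws = draws, dt = config$dt,
                                max_steps = config$max_steps, on_max = "drop")
  cells <- aggregate_trials(trials)
  scored <- compute_measures(cells, config$measures)
  wide_mu <- split_by_condition(draws, "mu")
  r_mu <- suppressWarnings(stats::cor(wide_mu$x1, wide_mu$x2))

  rows <- lapply(config$measures, function(m) {
    w <- split_by_condition(scored, m)
    pt <- paired_t(w$x1, w$x2)
    r <- if (stats::sd(w$x1) == 0 || stats::sd(w$x2) == 0) NA_real_
         else stats::cor(w$x1, w$x2)
    data.frame(measure = m, mean_1 = mean(w$x1), mean_2 = mean(w$x2),
               t = pt$t, p = pt$p, dz = pt$dz, r = r)
  })
  list(details = do.call(rbind, rows), r_mu = r_mu,
       n_dropped = attr(trials, "n_dropped"))
}

#' @export
print.study_summary <- function(x, digits = 3, ...) {
  cfg <- x$config
  d <- cfg$design
  cat(sprintf("Monte-Carlo study: %d experiments, %s design (mu = %g vs %g)\n",
              cfg$n_experiments, d$focal, d$mu[1], d$mu[2]))
  cat(sprintf("  %d participants, %d trials/condition, alpha = %g, seed = %d\n",
              d$n_participants, d$n_trials, cfg$alpha, cfg$seed))
  s <- x$summary
  out <- data.frame(measure = s$measure,
                    mean_1 = signif(s$mean_1, digits + 2),
                    mean_2 = signif(s$mean_2, digits + 2),
                    mean_dz = round(s$mean_dz, 2),
                    pct_significant = round(s$pct_significant, 1),
                    mean_r = round(s$mean_r, 3))
  print(out, row.names = FALSE)
  cat(sprintf("focal-parameter correlation: mean %.3f [%.3f; %.3f]\n",
              x$param_correlation["mean"], x$param_correlation["min"],
              x$param_correlation["max"]))
  if (x$n_excluded > 0L) {
    cat("excluded degenerate experiments:", x$n_excluded, "\n")
  }
  invisible(x)
}

#' Write and read study outputs
#'
#' `write_study_summary()` writes `summary.csv` (the per-measure table),
#' `summary.json` (the same table plus a configuration echo, the master
#' seed, the focal-parameter correlation and exclusion counts) and, when
#' details are present, `details.csv` with the per-experiment results.
#'
#' @param x A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_summary <- function(x, dir) {
  stopifnot(inherits(x, "study_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(summary_csv = file.path(dir, "summary.csv"),
             summary_json = file.path(dir, "summary.json"),
             details_csv = file.path(dir, "details.csv"))
  utils::write.csv(x$summary, paths["summary_csv"], row.names = FALSE)
  cfg <- x$config
  payload <- list(
    config = list(design = unclass(cfg$design),
                  n_experiments = cfg$n_experiments, alpha = cfg$alpha,
                  measures = cfg$measures, seed = cfg$seed, dt = cfg$dt,
                  max_steps = cfg$max_steps),
    param_correlation = as.list(x$param_correlation),
    n_excluded = x$n_excluded,
    n_dropped_trials = x$n_dropped_trials,
    summary = x$summary)
  jsonlite::write_json(payload, paths["summary_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(x$details, paths["details_csv"], row.names = FALSE)
  invisible(paths)
}

#' Trial-table CSV round-trip
#'
#' Writes/reads the trial-table schema `participant,condition,rt,correct`
#' (participant and condition as integers, `rt` as float ms with full
#' precision, `correct` as 0/1).  A write followed by a read reproduces the
#' table bit-identically.
#'
#' @param trials A trial table as produced by [generate_experiment()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   trial table.
#' @export
write_trials <- function(trials, path) {
  need <- c("participant", "condition", "rt", "correct")
  stopifnot(all(need %in% names(trials)))
  out <- data.frame(participant = as.integer(trials$participant),
                    condition = as.integer(trials$condition),
                    rt = sprintf("%.17g", trials$rt),
                    correct = as.integer(trials$correct))
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write trial table to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop("trial table not found: '", path, "'", call. = FALSE)
  }
  out <- utils::read.csv(path, colClasses = c(participant = "integer",
                                              condition = "integer",
                                              rt = "numeric",
                                              correct = "integer"))
  out$correct <- as.logical(out$correct)
  out
}

#' Serialize a design or study configuration to JSON
#'
#' @param config A [design_spec()] or [study_config()].
#' @param path File path ending in `.json`.
#' @return `write_config()` returns `path` invisibly; `read_design()` a
#'   `design_spec`; `read_study_config()` a `study_config`.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "study_config")) {
    payload <- list(type = "study_config",
                    design = unclass(config$design),
                    n_experiments = config$n_experiments,
                    alpha = config$alpha, measures = config$measures,
                    seed = config$seed, dt = config$dt,
                    max_steps = config$max_steps)
  } else if (inherits(config, "design_spec")) {
    payload <- c(list(type = "design_spec"), unclass(config))
  } else {
    stop("config must be a design_spec or study_config", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design_spec(focal = x$focal, mu = x$mu, fixed = x$fixed,
              sigma_b2 = x$sigma_b2, sigma_w2 = x$sigma_w2,
              t_er_mean = x$t_er_mean, t_er_sd = x$t_er_sd,
              sigma = x$sigma, n_participants = x$n_participants,
              n_trials = x$n_trials)
}

#' @rdname write_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- design_spec(focal = x$design$focal, mu = x$design$mu,
                        fixed = x$design$fixed, sigma_b2 = x$design$sigma_b2,
                        sigma_w2 = x$design$sigma_w2,
                        t_er_mean = x$design$t_er_mean,
                        t_er_sd = x$design$t_er_sd, sigma = x$design$sigma,
                        n_participants = x$design$n_participants,
                        n_trials = x$design$n_trials)
  study_config(design, n_experiments = x$n_experiments, alpha = x$alpha,
               measures = x$measures, seed = x$seed, dt = x$dt,
               max_steps = x$max_steps)
}
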