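#' Aggregate a trial table into participant-by-condition cells
#'
#' Reduces trial-level data to the cell statistics every combined
#' speed--accuracy measure is built from: the mean RT over correct trials,
#' the proportion correct over all trials, and trial-level SDs of RT and of
#' the 0/1 error indicator, computed both pooled over all of a participant's
#' trials (used by LISAS) and within each cell (used by the condition-wise
#' LISAS variant).
#'
#' @param trials A trial table: data.frame with columns `participant`,
#'   `condition`, `rt` and `correct` (logical or 0/1).  Every cell needs at
#'   least one trial and at least one correct trial.
#' @param rt_sd_trials Which trials enter the RT SDs: `"correct"` (default)
#'   or `"all"` (sensitivity option).
#' @param sd_method `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).  Applies to all trial-level SDs.
#' @return A data.frame of class `cell_stats`, one row per
#'   participant-by-condition cell ordered by participant then condition,
#'   with columns `participant`, `condition`, `n`, `n_correct`, `mean_rt`,
#'   `pc`, `pe`, `sum_rt` (sum of all trial RTs, for the Rate Correct Score),
#'   `sd_rt_participant`, `sd_e_participant` (pooled over the participant's
#'   conditions), `sd_rt_cell` and `sd_e_cell` (within the cell).
#' @examples
#' trials <- data.frame(participant = 1, condition = 1,
#'                      rt = c(400, 500, 600), correct = c(TRUE, TRUE, FALSE))
#' aggregate_trials(trials)
#' @export
aggregate_trials <- function(trials, rt_sd_trials = c("correct", "all"),
                             sd_method = c("sample", "population")) {
  rt_sd_trials <- match.arg(rt_sd_trials)
  sd_method <- match.arg(sd_method)
  need <- c("participant", "condition", "rt", "correct")
  if (!all(need %in% names(trials))) {
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sdfun <- trial_sd_fun(sd_method)
  correct <- as.logical(trials$correct)
  if (anyNA(correct) || anyNA(trials$rt)) {
    stop("trial table contains missing values", call. = FALSE)
  }

  idx <- split(seq_len(nrow(trials)),
               list(participant = trials$participant,
                    condition = trials$condition), drop = TRUE)
  cells <- lapply(idx, function(i) {
    rt <- trials$rt[i]
    ok <- correct[i]
    if (sum(ok) == 0L) {
      stop(sprintf(
        "aggregation error: no correct trials in cell participant %s, condition %s",
        trials$participant[i[1L]], trials$condition[i[1L]]), call. = FALSE)
    }
    rt_for_sd <- if (rt_sd_trials == "correct") rt[ok] else rt
    data.frame(participant = trials$participant[i[1L]],
               condition = trials$condition[i[1L]],
               n = length(i), n_correct = sum(ok),
               mean_rt = mean(rt[ok]),
               pc = mean(ok), pe = mean(!ok),
               sum_rt = sum(rt),
               sd_rt_cell = sdfun(rt_for_sd),
               sd_e_cell = sdfun(as.numeric(!ok)))
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$participant, out$condition), , drop = FALSE]
  row.names(out) <- NULL

  # per-participant pooled trial SDs (across all of that participant's trials)
  pid <- split(seq_len(nrow(trials)), trials$participant, drop = TRUE)
  pooled <- lapply(pid, function(i) {
    rt <- trials$rt[i]
    ok <- correct[i]
    rt_for_sd <- if (rt_sd_trials == "correct") rt[ok] else rt
    c(sd_rt = sdfun(rt_for_sd), sd_e = sdfun(as.numeric(!ok)))
  })
  pm <- do.call(rbind, pooled)
  m <- match(as.character(out$participant), names(pid))
  out$sd_rt_participant <- pm[m, "sd_rt"]
  out$sd_e_participant <- pm[m, "sd_e"]
  out <- out[, c("participant", "condition", "n", "n_correct", "mean_rt",
                 "pc", "pe", "sum_rt", "sd_rt_participant",
                 "sd_e_participant", "sd_rt_cell", "sd_e_cell")]
  class(out) <- c("cell_stats", "data.frame")
  out
}

trial_sd_fun <- function(sd_method) {
  if (sd_method == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    function(x) if (length(x) < 2L) 0 else stats::sd(x)
  }
}

#' Standardization context for BIS
#'
#' Grand means and across-cell SDs of the aggregated constituents (mean RT
#' and PC) over a standardization scope, by default all
#' participant-by-condition cells of one experiment.  BIS standardizes with
#' the variance of these aggregated data points -- the ones that enter a
#' t test or ANOVA -- not with trial-level variance; that choice is what
#' makes BIS attenuate speed--accuracy trade-offs.
#'
#' @param cells A [aggregate_trials()] result (or any data.frame with
#'   `mean_rt` and `pc` columns) spanning the standardization scope.
#' @param sd_method `"sample"` (default) or `"population"` SD across cells.
#' @return A list of class `measure_context`: `grand_mean_rt`, `sd_mean_rt`,
#'   `grand_mean_pc`, `sd_pc`, `grand_mean_pe`, `sd_pe` (`sd_pe == sd_pc`),
#'   `n_cells`.
#' @export
measure_context <- function(cells, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  stopifnot(all(c("mean_rt", "pc") %in% names(cells)))
  sdfun <- trial_sd_fun(sd_method)
  structure(list(grand_mean_rt = mean(cells$mean_rt),
                 sd_mean_rt = sdfun(cells$mean_rt),
                 grand_mean_pc = mean(cells$pc),
                 sd_pc = sdfun(cells$pc),
                 grand_mean_pe = mean(1 - cells$pc),
                 sd_pe = sdfun(cells$pc),
                 n_cells = nrow(cells)),
            class = "measure_context")
}

resolve_context <- function(cells, context) {
  if (is.null(context)) context <- measure_context(cells)
  stopifnot(inherits(context, "measure_context"))
  context
}

#' Balanced Integration Score (BIS)
#'
#' `BIS_ij = z(PC_ij) - z(mean RT_ij)`, each constituent z-standardized with
#' the mean and SD across the aggregated cells of the standardization scope
#' (see [measure_context()]).  Higher values mean better (faster and/or more
#' accurate) performance; the scores sum to zero over the scope and are
#' invariant to positive affine transformations of RT or PC applied uniformly
#' to all cells.
#'
#' @param cells A [aggregate_trials()] result.
#' @param context A [measure_context()]; computed from `cells` when `NULL`.
#'   Supply one standardization scope per group if scores must be equated
#'   across participant groups.
#' @return Numeric vector of per-cell scores, aligned with `cells` rows.
#' @references Liesefeld, H. R., Fu, X., & Zimmer, H. D. (2015); Liesefeld,
#'   H. R., & Janczyk, M. (2019). Combining speed and accuracy to control for
#'   speed-accuracy trade-offs. Behavior Research Methods.
#' @export
bis <- function(cells, context = NULL) {
  context <- resolve_context(cells, context)
  if (context$sd_mean_rt <= 0 || context$sd_pc <= 0) {
    stop("degenerate-variance error: across-cell SD of mean RT and PC must be > 0",
         call. = FALSE)
  }
  (cells$pc - context$grand_mean_pc) / context$sd_pc -
    (cells$mean_rt - context$grand_mean_rt) / context$sd_mean_rt
}

#' RT-scaled Balanced Integration Score
#'
#' Linear rescaling of [bis()] to the millisecond scale of mean RT:
#' `grand_mean_rt - sd_mean_rt * BIS_ij`.  Lower values mean better
#' performance (like an error-corrected RT); the cell mean equals the grand
#' mean RT and paired contrasts equal those of BIS with the sign flipped.
#'
#' @inheritParams bis
#' @return Numeric vector of per-cell scores (ms scale).
#' @export
bis_rt_scaled <- function(cells, context = NULL) {
  context <- resolve_context(cells, context)
  context$grand_mean_rt - context$sd_mean_rt * bis(cells, context)
}

#' Linear Integrated Speed-Accuracy Score (LISAS)
#'
#' `LISAS_ij = mean RT_ij + (S_i^RT / S_i^E) * PE_ij`, where `S_i^RT` and
#' `S_i^E` are participant i's trial-level SDs of (correct-trial) RT and of
#' the 0/1 error indicator, pooled over all of that participant's conditions.
#' RT-scaled; lower is better.  When a participant commits no errors at all
#' (`S_i^E = 0`), the error term is taken as 0, the limit of the formula, so
#' the score equals mean RT.
#'
#' `lisas_cond()` is the condition-wise variant with both SDs computed within
#' each participant-by-condition cell instead of pooled.
#'
#' @param cells A [aggregate_trials()] result.
#' @return Numeric vector of per-cell scores (ms scale).
#' @references Vandierendonck, A. (2017). A comparison of methods to combine
#'   speed and accuracy measures of performance. Behavior Research Methods.
#' @export
lisas <- function(cells) {
  stopifnot(all(c("mean_rt", "pe", "sd_rt_participant", "sd_e_participant")
                %in% names(cells)))
  lisas_score(cells$mean_rt, cells$pe,
              cells$sd_rt_participant, cells$sd_e_participant)
}

#' @rdname lisas
#' @export
lisas_cond <- function(cells) {
  stopifnot(all(c("mean_rt", "pe", "sd_rt_cell", "sd_e_cell")
                %in% names(cells)))
  lisas_score(cells$mean_rt, cells$pe, cells$sd_rt_cell, cells$sd_e_cell)
}

lisas_score <- function(mean_rt, pe, sd_rt, sd_e) {
  scale <- ifelse(sd_e > 0, sd_rt / pmax(sd_e, .Machine$double.xmin), 0)
  mean_rt + scale * pe
}

#' LISAS with BIS's standardization variance
#'
#' `LISAS^BIS_ij = mean RT_ij + (S^meanRT / S^PE) * PE_ij`, i.e. the LISAS
#' form with the trial-level SD ratio replaced by the ratio of across-cell
#' SDs of the aggregated data (the SDs BIS standardizes with).  This variant
#' is an affine transform of BIS -- `lisas_bis = bis_rt_scaled + C` with a
#' per-experiment constant `C` -- so it inherits BIS's attenuation of
#' speed--accuracy trade-offs while staying on the RT scale.
#'
#' @inheritParams bis
#' @return Numeric vector of per-cell scores (ms scale).
#' @export
lisas_bis <- function(cells, context = NULL) {
  context <- resolve_context(cells, context)
  if (context$sd_pe <= 0) {
    stop("degenerate-variance error: across-cell SD of PE must be > 0",
         call. = FALSE)
  }
  cells$mean_rt + (context$sd_mean_rt / context$sd_pe) * cells$pe
}

#' Baseline combined measures: IES and RCS
#'
#' The Inverse Efficiency Score `IES_ij = mean RT_ij / PC_ij` (ms; lower is
#' better) and the Rate Correct Score `RCS_ij = n_correct / sum of all trial
#' RTs in the cell` (correct responses per ms; higher is better).
#'
#' @param cells A [aggregate_trials()] result.
#' @return Numeric vector of per-cell scores.
#' @export
ies <- function(cells) {
  if (any(cells$pc <= 0)) {
    stop("undefined IES: cell with pc = 0", call. = FALSE)
  }
  cells$mean_rt / cells$pc
}

#' @rdname ies
#' @export
rcs <- function(cells) {
  if (any(cells$sum_rt <= 0)) {
    stop("undefined RCS: cell with non-positive total RT", call. = FALSE)
  }
  cells$n_correct / cells$sum_rt
}

measure_registry <- function() {
  list(
    mean_rt       = function(cells, context) cells$mean_rt,
    pc            = function(cells, context) cells$pc,
    bis           = function(cells, context) bis(cells, context),
    bis_rt_scaled = function(cells, context) bis_rt_scaled(cells, context),
    lisas         = function(cells, context) lisas(cells),
    lisas_cond    = function(cells, context) lisas_cond(cells),
    lisas_bis     = function(cells, context) lisas_bis(cells, context),
    ies           = function(cells, context) ies(cells),
    rcs           = function(cells, context) rcs(cells)
  )
}

#' Available performance measures
#'
#' @return Character vector of measure names accepted by
#'   [compute_measures()] and [study_config()].
#' @export
measure_names <- function() names(measure_registry())

#' Compute all requested measures for a cell table
#'
#' Appends one column per measure to the aggregated cell table.  `mean_rt`
#' and `pc` are passed through as measures in their own right so that the
#' study harness can score them alongside the combined measures.
#'
#' @param cells A [aggregate_trials()] result.
#' @param measures Character vector out of [measure_names()].
#' @param context Standardization scope for the BIS-family measures; computed
#'   from `cells` when `NULL`.
#' @return `cells` with one appended numeric column per requested measure.
#' @examples
#' set.seed(1)
#' trials <- generate_experiment(design_sat_effect(n_participants = 4,
#'                                                 n_trials = 100))
#' head(compute_measures(aggregate_trials(trials)))
#' @export
compute_measures <- function(cells, measures = measure_names(),
                             context = NULL) {
  reg <- measure_registry()
  bad <- setdiff(measures, names(reg))
  if (length(bad)) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  context <- resolve_context(cells, context)
  for (m in measures) cells[[m]] <- reg[[m]](cells, context)
  cells
}
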