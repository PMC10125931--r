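# Independent brute-force oracles, deliberately coded with plain loops and
# straight transcriptions of the formulas so they share no code with the
# package implementations they check.

# z-standardize with the sample SD across the supplied values
oracle_z <- function(x) (x - mean(x)) / sd(x)

oracle_bis <- function(mean_rt, pc) oracle_z(pc) - oracle_z(mean_rt)

oracle_bis_rt_scaled <- function(mean_rt, pc) {
  mean(mean_rt) - sd(mean_rt) * oracle_bis(mean_rt, pc)
}

oracle_lisas_bis <- function(mean_rt, pc) {
  pe <- 1 - pc
  mean_rt + (sd(mean_rt) / sd(pe)) * pe
}

# LISAS and friends computed directly from a raw trial table, one cell at a
# time, pooled SDs by explicit subsetting per participant.
oracle_lisas_from_trials <- function(trials, condition_wise = FALSE) {
  trials$correct <- as.logical(trials$correct)
  out <- NULL
  for (p in sort(unique(trials$participant))) {
    tp <- trials[trials$participant == p, ]
    s_rt_pooled <- sd(tp$rt[tp$correct])
    s_e_pooled <- sd(as.numeric(!tp$correct))
    for (j in sort(unique(tp$condition))) {
      cell <- tp[tp$condition == j, ]
      mean_rt <- mean(cell$rt[cell$correct])
      pe <- mean(!cell$correct)
      if (condition_wise) {
        s_rt <- sd(cell$rt[cell$correct])
        s_e <- sd(as.numeric(!cell$correct))
      } else {
        s_rt <- s_rt_pooled
        s_e <- s_e_pooled
      }
      score <- if (is.na(s_e) || s_e == 0) mean_rt else mean_rt + s_rt / s_e * pe
      out <- rbind(out, data.frame(participant = p, condition = j,
                                   score = score))
    }
  }
  out$score
}

# Euler first-passage bias correction: each absorbing boundary effectively
# moves outward by beta = zeta(1/2)/sqrt(2*pi) * sigma * sqrt(dt) when first
# passage is monitored only on the dt grid (Broadie, Glasserman & Kou, 1997).
# Evaluating the continuous-time formulas at the widened geometry gives a
# closed-form oracle for what the discretized simulator should produce.
euler_boundary_shift <- function(sigma, dt) 0.5826 * sigma * sqrt(dt)

euler_corrected_params <- function(params, dt) {
  beta <- euler_boundary_shift(params$sigma, dt)
  diffusion_params(v = params$v, a = params$a + 2 * beta,
                   start = params$start + beta, sigma = params$sigma,
                   t_er = params$t_er)
}

# quick paired-t helper for tests that only need the t statistic
oracle_paired_t <- function(x1, x2) {
  d <- x1 - x2
  mean(d) / (sd(d) / sqrt(length(d)))
}

# small random trial table with at least one correct trial per cell
random_trial_table <- function(n_participants = 4, n_trials = 30,
                               p_correct = 0.85) {
  grid <- expand.grid(participant = seq_len(n_participants), condition = 1:2)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    correct <- c(TRUE, runif(n_trials - 1) < p_correct)
    data.frame(participant = grid$participant[k],
               condition = grid$condition[k],
               rt = round(rlnorm(n_trials, log(450), 0.3), 3),
               correct = correct)
  })
  do.call(rbind, rows)
}
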