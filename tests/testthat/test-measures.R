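# Aggregation and the combined speed-accuracy measures.

toy_trials <- data.frame(
  participant = rep(1:2, each = 6),
  condition = rep(rep(1:2, each = 3), times = 2),
  rt = c(400, 500, 600, 450, 550, 650, 420, 520, 620, 470, 570, 670),
  correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
              TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))

test_that("aggregation reproduces hand-computed cell statistics", {
  cells <- aggregate_trials(toy_trials)
  c11 <- cells[cells$participant == 1 & cells$condition == 1, ]
  expect_equal(c11$mean_rt, 450)      # mean of the two correct RTs 400, 500
  expect_equal(c11$pc, 2 / 3)
  expect_equal(c11$pe, 1 / 3)
  expect_equal(c11$n, 3L)
  expect_equal(c11$n_correct, 2L)
  expect_equal(c11$sum_rt, 1500)
  expect_equal(c11$sd_e_cell, sd(c(0, 0, 1)))
  expect_equal(c11$sd_rt_cell, sd(c(400, 500)))
  # participant-pooled SDs use all of participant 1's trials
  p1_correct_rts <- c(400, 500, 450, 550, 650)
  expect_equal(c11$sd_rt_participant, sd(p1_correct_rts))
  expect_equal(c11$sd_e_participant, sd(c(0, 0, 1, 0, 0, 0)))
})

test_that("population SD convention gives sd_e_cell = sqrt(pe*(1-pe))", {
  cells <- aggregate_trials(toy_trials, sd_method = "population")
  expect_equal(cells$sd_e_cell, sqrt(cells$pe * (1 - cells$pe)))
})

test_that("aggregation is order-free and errors on cells without correct trials", {
  set.seed(10)
  shuffled <- toy_trials[sample(nrow(toy_trials)), ]
  expect_equal(aggregate_trials(shuffled), aggregate_trials(toy_trials))
  bad <- toy_trials
  bad$correct[bad$participant == 2 & bad$condition == 2] <- FALSE
  expect_error(aggregate_trials(bad), "participant 2, condition 2")
})

test_that("BIS matches the frozen hand-standardized example", {
  cells <- data.frame(participant = c(1, 1, 2, 2), condition = c(1, 2, 1, 2),
                      mean_rt = c(500, 520, 480, 540),
                      pc = c(0.90, 0.85, 0.95, 0.80))
  # z-scores computed by hand: rt deviations (-10,10,-30,30)/25.8199,
  # pc deviations (.025,-.025,.075,-.075)/.0645497
  expect_equal(bis(cells),
               c(0.7745967, -0.7745967, 2.3237900, -2.3237900),
               tolerance = 1e-6)
})

test_that("BIS sums to zero and is invariant to affine transforms of its inputs", {
  set.seed(42)
  for (rep in 1:5) {
    trials <- random_trial_table()
    cells <- aggregate_trials(trials)
    b <- bis(cells)
    expect_equal(sum(b), 0, tolerance = 1e-10)
    rescaled <- cells
    rescaled$mean_rt <- 2 * cells$mean_rt + 100
    expect_equal(bis(rescaled), b, tolerance = 1e-10)
    repc <- cells
    repc$pc <- 0.5 * cells$pc + 0.1
    expect_equal(bis(repc), b, tolerance = 1e-10)
  }
})

test_that("standardizing PC or PE gives the same BIS", {
  set.seed(13)
  cells <- aggregate_trials(random_trial_table())
  ctx <- measure_context(cells)
  z_pe <- ((1 - cells$pc) - ctx$grand_mean_pe) / ctx$sd_pe
  z_rt <- (cells$mean_rt - ctx$grand_mean_rt) / ctx$sd_mean_rt
  expect_equal(bis(cells), -z_pe - z_rt, tolerance = 1e-12)
})

test_that("BIS errors on degenerate across-cell variance", {
  flat <- data.frame(mean_rt = c(500, 500), pc = c(0.9, 0.8))
  expect_error(bis(flat), "degenerate-variance")
  flat2 <- data.frame(mean_rt = c(500, 510), pc = c(0.9, 0.9))
  expect_error(bis(flat2), "degenerate-variance")
})

test_that("RT-scaled BIS is the documented affine image of BIS", {
  set.seed(14)
  cells <- aggregate_trials(random_trial_table())
  b <- bis(cells)
  brs <- bis_rt_scaled(cells)
  expect_equal(mean(brs), mean(cells$mean_rt), tolerance = 1e-10)
  expect_equal(cor(brs, b), -1, tolerance = 1e-12)
  # paired t flips sign exactly under the affine map
  w_b <- list(x1 = b[cells$condition == 1], x2 = b[cells$condition == 2])
  w_s <- list(x1 = brs[cells$condition == 1], x2 = brs[cells$condition == 2])
  expect_equal(paired_t(w_s$x1, w_s$x2)$t, -paired_t(w_b$x1, w_b$x2)$t,
               tolerance = 1e-9)
})

test_that("LISAS matches hand arithmetic and the zero-error convention", {
  cells <- data.frame(mean_rt = c(450, 500), pe = c(1 / 3, 0),
                      sd_rt_participant = c(100, 80),
                      sd_e_participant = c(0.5, 0))
  expect_equal(lisas(cells), c(450 + 200 / 3, 500))
  cellwise <- data.frame(mean_rt = c(450, 500), pe = c(1 / 3, 0),
                         sd_rt_cell = c(100, 80), sd_e_cell = c(0.5, 0))
  expect_equal(lisas_cond(cellwise), c(450 + 200 / 3, 500))
})

test_that("LISAS variants agree with the brute-force trial-table oracle", {
  set.seed(77)
  for (rep in 1:5) {
    trials <- random_trial_table(n_participants = 5, n_trials = 40)
    cells <- aggregate_trials(trials)
    expect_equal(lisas(cells), oracle_lisas_from_trials(trials),
                 tolerance = 1e-10)
    expect_equal(lisas_cond(cells),
                 oracle_lisas_from_trials(trials, condition_wise = TRUE),
                 tolerance = 1e-10)
    expect_equal(bis(cells), oracle_bis(cells$mean_rt, cells$pc),
                 tolerance = 1e-10)
    expect_equal(bis_rt_scaled(cells),
                 oracle_bis_rt_scaled(cells$mean_rt, cells$pc),
                 tolerance = 1e-10)
    expect_equal(lisas_bis(cells),
                 oracle_lisas_bis(cells$mean_rt, cells$pc),
                 tolerance = 1e-10)
  }
})

test_that("lisas_cond coincides with lisas when cell SDs equal pooled SDs", {
  cells <- data.frame(mean_rt = c(450, 470), pe = c(0.1, 0.2),
                      sd_rt_participant = c(90, 90),
                      sd_e_participant = c(0.3, 0.3),
                      sd_rt_cell = c(90, 90), sd_e_cell = c(0.3, 0.3))
  expect_equal(lisas(cells), lisas_cond(cells))
})

test_that("LISAS^BIS differs from RT-scaled BIS by a per-experiment constant", {
  set.seed(15)
  for (rep in 1:5) {
    cells <- aggregate_trials(random_trial_table())
    gap <- lisas_bis(cells) - bis_rt_scaled(cells)
    expect_lt(diff(range(gap)), 1e-9)
    # the constant is S^RT/S^PE * (1 - grand mean PC)
    ctx <- measure_context(cells)
    expect_equal(gap[1],
                 ctx$sd_mean_rt / ctx$sd_pe * (1 - ctx$grand_mean_pc),
                 tolerance = 1e-9)
  }
})

test_that("LISAS^BIS reduces to mean-RT contrasts when PE is constant", {
  cells <- data.frame(mean_rt = c(500, 540, 480, 520), pc = rep(0.9, 4),
                      pe = rep(0.1, 4))
  ctx <- measure_context(data.frame(mean_rt = cells$mean_rt,
                                    pc = c(0.9, 0.89, 0.91, 0.9)))
  lb <- lisas_bis(cells, ctx)
  expect_equal(diff(lb), diff(cells$mean_rt))
})

test_that("LISAS is not invariant to uniform RT rescaling (unlike BIS)", {
  set.seed(16)
  trials <- random_trial_table()
  cells <- aggregate_trials(trials)
  trials2 <- trials
  trials2$rt <- 2 * trials$rt + 100
  cells2 <- aggregate_trials(trials2)
  l1 <- lisas(cells); l2 <- lisas(cells2)
  # contrasts between cells are NOT preserved under the affine map
  expect_false(isTRUE(all.equal(l2 - mean(l2), l1 - mean(l1))))
  expect_equal(bis(cells2), bis(cells), tolerance = 1e-10)
})

test_that("IES and RCS behave as defined", {
  cells <- data.frame(mean_rt = c(500, 480), pc = c(1, 0.8),
                      n_correct = c(2L, 4L), sum_rt = c(1000, 2400))
  expect_equal(ies(cells), c(500, 600))
  expect_equal(rcs(cells), c(0.002, 4 / 2400))
  expect_error(ies(data.frame(mean_rt = 500, pc = 0)), "undefined IES")
  # strictly decreasing in pc at fixed mean RT
  pcs <- seq(0.5, 1, by = 0.1)
  vals <- ies(data.frame(mean_rt = 500, pc = pcs))
  expect_true(all(diff(vals) < 0))
})

test_that("compute_measures appends the requested columns", {
  set.seed(17)
  cells <- aggregate_trials(random_trial_table())
  scored <- compute_measures(cells)
  expect_true(all(measure_names() %in% names(scored)))
  expect_equal(scored$bis, bis(cells))
  expect_error(compute_measures(cells, "nope"), "unknown measure")
})
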