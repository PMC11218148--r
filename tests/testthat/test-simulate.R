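test_that("generator is deterministic: same config and seed, identical bytes", {
  cfg <- simulate_config(n_probes = 300, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$sheet, s2$sheet)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(s1$beta, f1)
  write_beta_matrix(s2$beta, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_cohort(simulate_config(n_probes = 300, seed = 78))
  expect_false(identical(s1$beta, s3$beta))
})

test_that("default design reproduces the serial-passaging study layout", {
  sim <- small_sim()
  sh <- sim$sheet
  expect_equal(sum(sh$cohort == "train"), 39)
  expect_equal(sum(sh$cohort == "test"), 26)
  tr <- table(sh$passage[sh$cohort == "train"])
  expect_equal(unname(tr[c("10", "12", "14")]), rep(6L, 3), ignore_attr = TRUE)
  expect_equal(unname(tr[c("16", "18", "20")]), rep(7L, 3), ignore_attr = TRUE)
  expect_equal(nrow(sim$truth$probes), 23 + 19)
  expect_equal(sum(sim$truth$probes$direction == "hypo"), 23)
  expect_equal(sum(sim$truth$probes$direction == "hyper"), 19)
  expect_true(all(sim$truth$probes$probe_id %in% rownames(sim$beta)))
})

test_that("drift amplitude is calibrated to 0.2 between P10 and P20", {
  sim <- simulate_cohort(simulate_config(n_probes = 3000, n_extra = 18,
                                         seed = 13))
  sh <- sim$sheet
  tr <- sh$cohort == "train"
  b <- sim$beta[sim$truth$probes$probe_id, ]
  m20 <- rowMeans(b[, sh$sample_id[tr & sh$passage == 20], drop = FALSE])
  m10 <- rowMeans(b[, sh$sample_id[tr & sh$passage == 10], drop = FALSE])
  expect_lt(abs(mean(abs(m20 - m10)) - 0.2), 0.02)
})

test_that("background probes stay near their drawn baselines", {
  sim <- small_sim()
  sh <- sim$sheet
  bg <- setdiff(rownames(sim$beta), sim$truth$probes$probe_id)
  b <- sim$beta[bg, ]
  m <- rowMeans(b)
  # background probes are flat, so P10 and P20 means agree within 3 joint
  # SEs of the Beta(mu k, (1 - mu) k) observation noise
  tr <- sh$cohort == "train"
  m10 <- rowMeans(b[, sh$sample_id[tr & sh$passage == 10]])
  m20 <- rowMeans(b[, sh$sample_id[tr & sh$passage == 20]])
  se_d <- sqrt(m * (1 - m) / 201 * (1 / 6 + 1 / 7))
  expect_gt(mean(abs(m20 - m10) <= 3 * se_d), 0.99)
})

test_that("full deceleration freezes the mean trajectory at the onset", {
  expect_equal(effective_passage(9:20, 1, 9), rep(9, 12))
  expect_equal(effective_passage(9:20, 0, 9), 9:20)
  expect_equal(effective_passage(c(8, 9, 15), 0.5, 9), c(8, 9, 12))
  cfg <- simulate_config(n_probes = 800, seed = 23, cohorts = list(
    sim_cohort("train", c("10" = 6, "12" = 6, "14" = 6,
                          "16" = 7, "18" = 7, "20" = 7)),
    sim_cohort("frozen", c("10" = 6, "14" = 6, "20" = 6),
               deceleration = 1, onset = 9, treatment = "frozen")))
  sim <- simulate_cohort(cfg)
  sh <- sim$sheet
  tr <- sh$cohort == "train"
  dm <- suppressMessages(screen_dmps(sim$beta[, sh$sample_id[tr]],
                                     sh[tr, ], 1e-9))
  m <- fit_clock(sim$beta[dm$probe_id, sh$sample_id[tr]], sh[tr, ],
                 seed = 23)
  fz <- sh$cohort == "frozen"
  pr <- predict_passage(m, sim$beta[, sh$sample_id[fz]], sh[fz, ])
  by_p <- tapply(pr$predicted_passage,
                 sh$passage[match(pr$sample_id, sh$sample_id)], mean)
  # frozen ageing: predicted passage flat across actual passages
  expect_lt(max(by_p) - min(by_p), 1)
})

test_that("immortalised cohorts drift slower and are underestimated", {
  cfg <- simulate_config(n_probes = 1500, seed = 31)
  sim <- simulate_cohort(cfg)
  sh <- sim$sheet
  tr <- sh$cohort == "train"
  dm <- suppressMessages(screen_dmps(sim$beta[, sh$sample_id[tr]],
                                     sh[tr, ], 1e-11))
  m <- fit_clock(sim$beta[dm$probe_id, sh$sample_id[tr]], sh[tr, ],
                 seed = 31)

  # r = 1 is a no-op: cohort statistically identical to an untreated one
  s_r1 <- simulate_immortalised(cfg, immortalisation = 12, residual_drift = 1)
  pr1 <- predict_passage(m, s_r1$beta, s_r1$sheet)
  expect_lt(evaluate_predictions(pr1)$rmse, 1)

  # r = 0.4 after P12: prediction keeps rising but underestimates, worse
  # with passage
  s_r04 <- simulate_immortalised(cfg, immortalisation = 12,
                                 residual_drift = 0.4)
  pr04 <- predict_passage(m, s_r04$beta, s_r04$sheet)
  shi <- s_r04$sheet
  agg <- tapply(pr04$predicted_passage,
                shi$passage[match(pr04$sample_id, shi$sample_id)], mean)
  expect_true(all(diff(agg) > 0))
  dl <- tapply(pr04$delta,
               shi$passage[match(pr04$sample_id, shi$sample_id)], mean)
  high <- as.numeric(names(dl)) > 12
  expect_true(all(dl[high] < 0))
  expect_true(all(diff(dl[as.numeric(names(dl)) >= 12]) < 0))

  # r = 0: predictions plateau at the clock's estimate of the
  # immortalisation passage
  s_r0 <- simulate_immortalised(cfg, immortalisation = 12,
                                residual_drift = 0)
  pr0 <- predict_passage(m, s_r0$beta, s_r0$sheet)
  late <- s_r0$sheet$passage[match(pr0$sample_id, s_r0$sheet$sample_id)] >= 12
  expect_lt(abs(mean(pr0$predicted_passage[late]) - 12), 1)
})

test_that("null generator produces no screenable drift", {
  cfg <- simulate_config(n_probes = 2000, n_hypo = 0, n_hyper = 0,
                         drift_total = 0, seed = 3,
                         cohorts = list(sim_cohort("train", c(
                           "10" = 6, "12" = 6, "14" = 6,
                           "16" = 7, "18" = 7, "20" = 7))))
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$truth$probes), 0)
  dm <- suppressMessages(screen_dmps(sim$beta, sim$sheet, 1e-11))
  expect_equal(nrow(dm), 0)
})

test_that("config invariants are enforced", {
  expect_error(simulate_config(n_probes = 10, n_hypo = 20, n_hyper = 19))
  expect_error(sim_cohort("x", c("10" = 3), deceleration = 1.5))
  expect_error(sim_cohort("x", c("10" = 3), residual_drift = -0.1))
})
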