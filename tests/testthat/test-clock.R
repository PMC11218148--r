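# seeded 20 x 10 regression instance on the beta scale
enet_instance <- function(seed = 99, n = 20, p = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- (x - min(x)) / (max(x) - min(x))
  colnames(x) <- sprintf("cg%02d", seq_len(p))
  y <- round(runif(n, 9, 20))
  beta <- t(x)
  colnames(beta) <- sprintf("S%02d", seq_len(n))
  list(beta = beta, x = x, y = y,
       sheet = data.frame(sample_id = colnames(beta), passage = y))
}

full_weights <- function(model, probes) {
  w <- stats::setNames(numeric(length(probes)), probes)
  w[names(model$weights)] <- model$weights
  w
}

test_that("fixed-lambda fit matches the coordinate-descent oracle", {
  inst <- enet_instance()
  lam <- 0.05
  m <- fit_clock(inst$beta, inst$sheet, alpha = 0.5, lambda = lam)
  or <- enet_coordinate_descent(inst$x, inst$y, 0.5, lam, tol = 1e-12)
  expect_true(or$converged)
  w <- full_weights(m, rownames(inst$beta))
  o_fit <- enet_objective(inst$x, inst$y, m$intercept, w, 0.5, lam)
  o_cd <- enet_objective(inst$x, inst$y, or$intercept, or$coef, 0.5, lam)
  expect_lt(abs(o_fit - o_cd), 1e-8)
  expect_lt(enet_kkt_residual(inst$x, inst$y, m$intercept, w, 0.5, lam), 1e-6)
})

test_that("lambda above lambda_max gives the null model exactly", {
  inst <- enet_instance()
  lmax <- enet_lambda_max(inst$x, inst$y, 0.5)
  m <- fit_clock(inst$beta, inst$sheet, alpha = 0.5, lambda = lmax * 1.001)
  expect_length(m$weights, 0)
  expect_equal(m$intercept, mean(inst$y), tolerance = 1e-12)
  # the oracle agrees that lambda_max zeroes everything
  or <- enet_coordinate_descent(inst$x, inst$y, 0.5, lmax * 1.001)
  expect_true(all(or$coef == 0))
})

test_that("single predictor at vanishing lambda recovers the OLS slope", {
  inst <- enet_instance(seed = 4)
  b1 <- inst$beta[1, , drop = FALSE]
  m <- fit_clock(b1, inst$sheet, alpha = 0.5, lambda = 1e-10)
  ols <- stats::coef(stats::lm(inst$y ~ inst$x[, 1]))
  expect_equal(unname(m$weights), unname(ols[2]), tolerance = 1e-6)
})

test_that("returned fit is locally optimal against a perturbation cloud", {
  inst <- enet_instance(seed = 17)
  lam <- 0.08
  m <- fit_clock(inst$beta, inst$sheet, alpha = 0.5, lambda = lam)
  w <- full_weights(m, rownames(inst$beta))
  o0 <- enet_objective(inst$x, inst$y, m$intercept, w, 0.5, lam)
  set.seed(1)
  cloud <- vapply(seq_len(1000), function(k) {
    enet_objective(inst$x, inst$y,
                   m$intercept + rnorm(1, 0, 0.01),
                   w + rnorm(length(w), 0, 0.01), 0.5, lam)
  }, numeric(1))
  expect_gte(min(cloud), o0)
})

test_that("cross-validated fit is deterministic given the seed", {
  sim <- small_sim()
  sh <- sim$sheet
  tr <- sh$cohort == "train"
  b <- sim$beta[, sh$sample_id[tr]]
  dm <- suppressMessages(screen_dmps(b, sh[tr, ], 1e-9))
  m1 <- fit_clock(b[dm$probe_id, ], sh[tr, ], seed = 7)
  m2 <- fit_clock(b[dm$probe_id, ], sh[tr, ], seed = 7)
  expect_identical(m1, m2)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_clock_model(m1, f1)
  write_clock_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("prediction is the stated affine map and ignores non-clock CpGs", {
  m <- structure(list(intercept = 15, weights = numeric(0), cv = NULL,
                      training_meta = list()), class = "passage_clock")
  b <- toy_beta(4, 3)
  pr <- predict_passage(m, b)
  expect_equal(pr$predicted_passage, rep(15, 3))

  m$weights <- c(cg00001 = 2, cg00003 = -1)
  pr2 <- predict_passage(m, b)
  expect_equal(pr2$predicted_passage,
               15 + 2 * b["cg00001", ] - b["cg00003", ],
               ignore_attr = TRUE)
  # adding unrelated probes leaves predictions unchanged
  extra <- toy_beta(50, 3, seed = 9)
  rownames(extra) <- sprintf("cgX%04d", 1:50)
  pr3 <- predict_passage(m, rbind(b, extra))
  expect_equal(pr3$predicted_passage, pr2$predicted_passage)
  # linearity in beta at the clock probes
  b_half <- b
  b_half[c("cg00001", "cg00003"), ] <- b[c("cg00001", "cg00003"), ] / 2
  pr4 <- predict_passage(m, b_half)
  expect_equal(pr4$predicted_passage - 15, (pr2$predicted_passage - 15) / 2)
})

test_that("missing clock probes are a hard error naming the IDs", {
  m <- structure(list(intercept = 0, weights = c(cgABSENT = 1), cv = NULL,
                      training_meta = list()), class = "passage_clock")
  expect_error(predict_passage(m, toy_beta(3, 2)), "cgABSENT")
  m2 <- structure(list(intercept = 0, weights = c(cg00001 = 1), cv = NULL,
                       training_meta = list()), class = "passage_clock")
  b <- toy_beta(3, 2)
  b["cg00001", 1] <- NA
  expect_error(predict_passage(m2, b), "missing values.*cg00001")
})

test_that("evaluation metrics match hand computation and flag degeneracy", {
  pr <- data.frame(sample_id = c("a", "b", "c"),
                   predicted_passage = c(10, 12, 14),
                   actual_passage = c(11, 12, 13))
  pr$delta <- pr$predicted_passage - pr$actual_passage
  ev <- evaluate_predictions(pr)
  expect_equal(ev$rmse, sqrt(2 / 3))
  expect_equal(ev$spearman_rho, 1)

  pr2 <- pr
  pr2$predicted_passage <- pr2$actual_passage
  ev2 <- evaluate_predictions(pr2)
  expect_equal(ev2$rmse, 0)
  expect_equal(ev2$spearman_rho, 1)

  pr3 <- pr
  pr3$predicted_passage <- rep(12, 3)
  ev3 <- evaluate_predictions(pr3)
  expect_false(ev3$rho_defined)
  expect_equal(ev3$rmse, sqrt(mean(c(1, 0, 1))))

  expect_error(evaluate_predictions(pr[1:2, ]), ">= 3")
})

test_that("clock trained on simulated cohort predicts the held-out cohort", {
  sim <- small_sim()
  sh <- sim$sheet
  tr <- sh$cohort == "train"
  b <- sim$beta[, sh$sample_id[tr]]
  dm <- suppressMessages(screen_dmps(b, sh[tr, ], 1e-11))
  m <- fit_clock(b[dm$probe_id, ], sh[tr, ], seed = 7, threshold = 1e-11)
  te <- sh$cohort == "test"
  pr <- predict_passage(m, sim$beta[, sh$sample_id[te]], sh[te, ])
  expect_gte(mean(abs(pr$delta) <= 1), 0.9)
  ev <- evaluate_predictions(pr)
  expect_lte(ev$rmse, 1)
  expect_gte(ev$spearman_rho, 0.95)
  # selected truth CpGs carry weights whose sign matches the drift direction
  truth <- sim$truth$probes
  sel <- intersect(names(m$weights), truth$probe_id)
  expect_gt(length(sel), 0)
  agree <- sign(m$weights[sel]) ==
    sign(truth$slope[match(sel, truth$probe_id)])
  expect_gte(mean(agree), 0.9)
})

test_that("deceleration readout is null for identical cohorts and detects d", {
  sched <- c("16" = 7, "18" = 7, "20" = 7)
  cfg <- simulate_config(n_probes = 1500, seed = 19, cohorts = list(
    sim_cohort("train", c("10" = 6, "12" = 6, "14" = 6,
                          "16" = 7, "18" = 7, "20" = 7)),
    sim_cohort("ctrl", sched),
    sim_cohort("ctrl2", sched, treatment = "sham"),
    sim_cohort("drugA", sched, deceleration = 0.3, onset = 9,
               treatment = "drugA")))
  sim <- simulate_cohort(cfg)
  sh <- sim$sheet
  tr <- sh$cohort == "train"
  dm <- suppressMessages(screen_dmps(sim$beta[, sh$sample_id[tr]],
                                     sh[tr, ], 1e-11))
  m <- fit_clock(sim$beta[dm$probe_id, sh$sample_id[tr]], sh[tr, ], seed = 19)
  oth <- !tr
  pr <- predict_passage(m, sim$beta[, sh$sample_id[oth]], sh[oth, ])

  # sham arm drawn from the same process: effect within 2 SE of zero
  null_cmp <- compute_acceleration(pr, sh[oth, ], "sham", "vehicle")
  expect_lt(abs(null_cmp$overall_effect), 2 * null_cmp$overall_se)

  # decelerated arm: negative at P16/18/20, monotonically more negative
  cmp <- compute_acceleration(pr, sh[oth, ], "drugA", "vehicle")
  expect_true(all(cmp$table$effect < 0))
  expect_true(all(diff(cmp$table$effect) < 0))

  # cumulative-PD axis gives the same overall story
  cmp_pd <- compute_acceleration(pr, sh[oth, ], "drugA", "vehicle",
                                 x_axis = "cumulative_pd", n_bins = 3)
  expect_lt(cmp_pd$overall_effect, 0)

  expect_error(compute_acceleration(pr, sh[oth, ], "nosuchdrug", "vehicle"),
               "nosuchdrug")
})
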