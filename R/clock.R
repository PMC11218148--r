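#' Fit a methylation passage clock by elastic-net regression
#'
#' Fits passage number on the beta values of pre-screened CpGs by elastic-net
#' regression, minimising
#' \deqn{\frac{1}{2n}\sum_i (p_i - w_0 - x_i^T w)^2 +
#'       \lambda\left[\alpha \|w\|_1 + \frac{1-\alpha}{2}\|w\|_2^2\right],}
#' with predictors standardised internally (mean 0, variance 1 computed with
#' the 1/n convention) and coefficients reported back on the original beta
#' scale. The penalty weight \eqn{\lambda} is chosen by seeded k-fold
#' cross-validation (folds stratified by passage level) unless a fixed
#' `lambda` is supplied. Only CpGs with non-zero weight are retained in the
#' returned model — the fitted clock is a sparse linear predictor
#' \eqn{\hat p = w_0 + \sum_j w_j \beta_j}.
#'
#' @param beta beta matrix restricted to the screened CpGs (probes x samples),
#'   complete (no missing values).
#' @param sheet sample sheet with a passage for every sample of `beta`.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (1 = lasso,
#'   0 = ridge); default 0.5.
#' @param n_folds number of cross-validation folds (default 10; must not
#'   exceed the sample count).
#' @param lambda optional fixed penalty; when supplied, cross-validation is
#'   skipped and the model is fitted at exactly this value.
#' @param lambda_rule `"min"` (default) selects the CV-error-minimising
#'   lambda; `"1se"` the largest lambda within one standard error of it.
#' @param seed integer seed controlling fold assignment; identical inputs and
#'   seed give a bit-identical model.
#' @param threshold the screening threshold that produced `beta`, recorded in
#'   the model's provenance (optional).
#' @return an object of class `passage_clock`: a list with elements
#'   `intercept`, `weights` (named numeric vector of non-zero CpG
#'   coefficients), `training_meta` (alpha, lambda, lambda_rule, screening
#'   threshold, fold count, seed, sample count, passage range) and `cv`
#'   (the cross-validation curve, or `NULL` for fixed-lambda fits).
#'   Methods: [print()], [summary()], [coef()], [predict.passage_clock()],
#'   [plot.passage_clock()].
#' @seealso [screen_dmps()] to select input CpGs, [predict_passage()],
#'   [evaluate_predictions()], [compute_acceleration()].
#' @export
fit_clock <- function(beta, sheet, alpha = 0.5, n_folds = 10, lambda = NULL,
                      lambda_rule = c("min", "1se"), seed = 1,
                      threshold = NA_real_) {
  lambda_rule <- match.arg(lambda_rule)
  beta <- as_beta_matrix(beta)
  if (anyNA(beta)) stop("clock predictors must be complete", call. = FALSE)
  sheet <- as_sample_sheet(sheet)
  sheet <- match_sheet(beta, sheet)
  y <- as.numeric(sheet$passage)
  x <- t(beta)
  n <- nrow(x)
  if (is.null(lambda) && n < n_folds)
    stop(sprintf("fewer samples (%d) than folds (%d)", n, n_folds),
         call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)

  const <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping %d constant predictor column(s)", sum(const)),
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 1) stop("no usable predictors", call. = FALSE)

  if (ncol(x) == 1) {
    fitted1 <- fit_enet_single(x, y, alpha, lambda, n_folds, seed, lambda_rule)
    lambda_used <- fitted1$lambda
    w_full <- fitted1$coef
    intercept <- fitted1$intercept
    cv_tab <- fitted1$cv
  } else if (!is.null(lambda)) {
    # glmnet standardises y internally for gaussian fits; reparameterise
    # (lambda, alpha) on that scale so the fit minimises the objective
    # 1/(2n)||y - w0 - Xw||^2 + lambda [a||w~||_1 + (1-a)/2 ||w~||_2^2]
    # at exactly the requested lambda.
    ym <- mean(y)
    sy <- sqrt(mean((y - ym)^2))
    if (sy == 0) {
      intercept <- ym
      w_full <- numeric(ncol(x))
    } else {
      lam_l1 <- lambda * alpha / sy
      lam_l2 <- lambda * (1 - alpha)
      lt <- lam_l1 + lam_l2
      at <- if (lt > 0) lam_l1 / lt else alpha
      fit <- glmnet::glmnet(x, y / sy, family = "gaussian", alpha = at,
                            standardize = TRUE, thresh = 1e-14, maxit = 1e7)
      cf <- as.matrix(glmnet::coef.glmnet(fit, s = lt, exact = TRUE,
                                          x = x, y = y / sy, alpha = at))
      intercept <- sy * cf[1, 1]
      w_full <- sy * cf[-1, 1]
      if (all(w_full == 0)) intercept <- ym   # null model analytically
    }
    lambda_used <- lambda
    cv_tab <- NULL
  } else {
    foldid <- stratified_folds(y, n_folds, seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = alpha,
                               foldid = foldid, standardize = TRUE,
                               thresh = 1e-10)
    lambda_used <- if (lambda_rule == "min") cvfit$lambda.min
                   else cvfit$lambda.1se
    cf <- as.matrix(glmnet::coef.glmnet(cvfit, s = lambda_used))
    intercept <- cf[1, 1]
    w_full <- cf[-1, 1]
    cv_tab <- data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                         cvsd = cvfit$cvsd, nzero = as.integer(cvfit$nzero))
  }

  names(w_full) <- colnames(x)
  weights <- w_full[w_full != 0]
  structure(list(
    intercept = unname(intercept),
    weights = weights,
    cv = cv_tab,
    training_meta = list(
      alpha = alpha, lambda = unname(lambda_used), lambda_rule = lambda_rule,
      screening_threshold = threshold, n_folds = n_folds, seed = seed,
      n_training_samples = n,
      passage_range = range(sheet$passage),
      n_candidate_probes = nrow(beta))
  ), class = "passage_clock")
}

# single-predictor elastic net in closed form on the standardised scale:
# b = soft(cor, lambda*alpha) / (1 + lambda*(1-alpha))
fit_enet_single <- function(x, y, alpha, lambda, n_folds, seed, lambda_rule) {
  solve_at <- function(xv, yv, lam) {
    m <- mean(xv); s <- sqrt(mean((xv - m)^2))
    z <- (xv - m) / s
    r <- mean(z * (yv - mean(yv)))
    bt <- sign(r) * max(abs(r) - lam * alpha, 0) / (1 + lam * (1 - alpha))
    b <- bt / s
    c(intercept = mean(yv) - b * m, coef = b)
  }
  cv_tab <- NULL
  if (is.null(lambda)) {
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    lmax <- abs(mean(((x - m) / s) * (y - mean(y)))) / max(alpha, 1e-3)
    grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
    foldid <- stratified_folds(y, n_folds, seed)
    err <- sapply(grid, function(lam) {
      se <- unlist(lapply(unique(foldid), function(f) {
        tr <- foldid != f
        cf <- solve_at(x[tr], y[tr], lam)
        (y[!tr] - cf[1] - cf[2] * x[!tr])^2
      }))
      c(mean(se), stats::sd(se) / sqrt(length(se)))
    })
    cvm <- err[1, ]
    best <- which.min(cvm)
    lambda <- if (lambda_rule == "min") grid[best]
              else max(grid[cvm <= cvm[best] + err[2, best]])
    cv_tab <- data.frame(lambda = grid, cvm = cvm, cvsd = err[2, ],
                         nzero = NA_integer_)
  }
  cf <- solve_at(as.numeric(x), y, lambda)
  list(intercept = cf[1], coef = cf[2], lambda = lambda, cv = cv_tab)
}

# seeded fold assignment, stratified by passage level where group sizes allow
stratified_folds <- function(y, n_folds, seed) {
  n <- length(y)
  set.seed(seed)
  foldid <- integer(n)
  cycle <- rep_len(seq_len(n_folds), n)
  pos <- 1
  for (lev in sort(unique(y))) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- cycle[pos:(pos + length(idx) - 1)]
    pos <- pos + length(idx)
  }
  foldid
}

#' Predict passage from a fitted clock
#'
#' Applies a `passage_clock` to a beta matrix:
#' \eqn{\hat p = w_0 + \sum_j w_j \beta_j} per sample. Every clock CpG must be
#' present and non-missing — absent probes are a hard error (no imputation),
#' since silently skipping weights would bias predictions on mismatched
#' platforms.
#'
#' @param model a `passage_clock`.
#' @param beta beta matrix containing at least the clock CpGs.
#' @param sheet optional sample sheet; when it carries passages, the
#'   deceleration readout `delta = predicted - actual` is filled in.
#' @return data.frame with columns `sample_id`, `predicted_passage`, and when
#'   actual passages are available `actual_passage` and `delta`.
#' @export
predict_passage <- function(model, beta, sheet = NULL) {
  stopifnot(inherits(model, "passage_clock"))
  beta <- as_beta_matrix(beta)
  probes <- names(model$weights)
  miss <- setdiff(probes, rownames(beta))
  if (length(miss) > 0)
    stop("clock CpG(s) absent from beta matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sub <- beta[probes, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- unique(rownames(which(is.na(sub), arr.ind = TRUE)))
    stop("missing values for clock CpG(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  yhat <- model$intercept +
    if (length(probes) > 0) as.numeric(crossprod(sub, model$weights)) else 0
  out <- data.frame(sample_id = colnames(beta), predicted_passage = yhat,
                    stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    sheet <- as_sample_sheet(sheet, require_passage = FALSE)
    actual <- sheet$passage[match(out$sample_id, sheet$sample_id)]
    out$actual_passage <- actual
    out$delta <- out$predicted_passage - as.numeric(actual)
  }
  out
}

#' @rdname predict_passage
#' @param object a `passage_clock`.
#' @param ... unused.
#' @export
predict.passage_clock <- function(object, beta, sheet = NULL, ...) {
  predict_passage(object, beta, sheet)
}

#' Accuracy metrics for passage predictions
#'
#' Computes the clock's headline metrics: root mean square error of predicted
#' vs actual passage, and Spearman's rank correlation (average ranks) with the
#' asymptotic t-approximation p-value. A constant prediction or passage vector
#' leaves rho undefined (`rho_defined = FALSE`).
#'
#' @param predictions data.frame from [predict_passage()] with
#'   `actual_passage` filled for at least 3 samples.
#' @return object of class `clock_eval`: list with `rmse`, `spearman_rho`,
#'   `spearman_p`, `n`, `rho_defined`.
#' @export
evaluate_predictions <- function(predictions) {
  ok <- !is.na(predictions$actual_passage)
  yhat <- predictions$predicted_passage[ok]
  y <- as.numeric(predictions$actual_passage[ok])
  n <- length(y)
  if (n < 3) stop("need >= 3 predictions with actual passage", call. = FALSE)
  rmse <- sqrt(mean((yhat - y)^2))
  defined <- stats::sd(yhat) > 0 && stats::sd(y) > 0
  if (defined) {
    rho <- stats::cor(yhat, y, method = "spearman")
    if (abs(rho) < 1) {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      pval <- 2 * stats::pt(-abs(tstat), n - 2)
    } else pval <- 2 * stats::pt(-Inf, n - 2) + .Machine$double.xmin
  } else {
    rho <- NA_real_; pval <- NA_real_
  }
  structure(list(rmse = rmse, spearman_rho = rho, spearman_p = pval,
                 n = n, rho_defined = defined), class = "clock_eval")
}

#' @export
print.clock_eval <- function(x, ...) {
  cat(sprintf("Clock evaluation on %d samples\n", x$n))
  cat(sprintf("  RMSE:          %.4f passages\n", x$rmse))
  if (x$rho_defined)
    cat(sprintf("  Spearman rho:  %.4f (p = %.3g)\n",
                x$spearman_rho, x$spearman_p))
  else cat("  Spearman rho:  undefined (constant ranks)\n")
  invisible(x)
}

#' Deceleration readout: compare predicted-minus-actual passage by cohort
#'
#' Groups the deceleration readout `delta = predicted - actual passage` by
#' passage level (or by cumulative-population-doubling bins) and cohort, and
#' reports per-level cohort means, their difference (`effect = mean delta of
#' treatment - mean delta of control`), and the overall mean effect. A
#' negative effect means the treated cohort's methylation drift lags the
#' control's — clock deceleration, the anti-ageing readout.
#'
#' @param predictions data.frame from [predict_passage()] including `delta`.
#' @param sheet sample sheet carrying `treatment` (and `cumulative_pd` when
#'   that axis is requested).
#' @param treatment_label,control_label values of `sheet$treatment` defining
#'   the two cohorts.
#' @param x_axis group by `"passage"` (default) or by `"cumulative_pd"` bins.
#' @param n_bins number of equal-width bins for the cumulative-PD axis.
#' @return object of class `cohort_comparison`: list with `table` (per-level
#'   means, counts and effects), `overall_effect`, `overall_se`, and the
#'   labels compared.
#' @export
compute_acceleration <- function(predictions, sheet, treatment_label,
                                 control_label,
                                 x_axis = c("passage", "cumulative_pd"),
                                 n_bins = 6) {
  x_axis <- match.arg(x_axis)
  sheet <- as_sample_sheet(sheet, require_passage = FALSE)
  if (!"treatment" %in% names(sheet))
    stop("sample sheet has no treatment column", call. = FALSE)
  for (lab in c(treatment_label, control_label))
    if (!lab %in% sheet$treatment)
      stop("treatment label not present in sample sheet: ", lab,
           call. = FALSE)
  df <- merge(predictions, sheet[, intersect(
    c("sample_id", "passage", "treatment", "cumulative_pd"), names(sheet))],
    by = "sample_id")
  df <- df[df$treatment %in% c(treatment_label, control_label), ]
  if (anyNA(df$delta))
    stop("predictions lack delta; supply a sheet with passages to predict",
         call. = FALSE)
  if (x_axis == "passage") {
    df$level <- as.numeric(df$actual_passage)
  } else {
    if (!"cumulative_pd" %in% names(df) || anyNA(df$cumulative_pd))
      stop("cumulative_pd required for the cumulative_pd axis", call. = FALSE)
    br <- seq(min(df$cumulative_pd), max(df$cumulative_pd),
              length.out = n_bins + 1)
    bin <- cut(df$cumulative_pd, breaks = br, include.lowest = TRUE)
    df$level <- ((br[-length(br)] + br[-1]) / 2)[as.integer(bin)]
  }
  levs <- sort(unique(df$level))
  rows <- lapply(levs, function(lv) {
    dt <- df$delta[df$level == lv & df$treatment == treatment_label]
    dc <- df$delta[df$level == lv & df$treatment == control_label]
    data.frame(level = lv, n_treatment = length(dt), n_control = length(dc),
               mean_delta_treatment = if (length(dt)) mean(dt) else NA_real_,
               mean_delta_control = if (length(dc)) mean(dc) else NA_real_,
               effect = if (length(dt) && length(dc)) mean(dt) - mean(dc)
                        else NA_real_,
               var_treatment = if (length(dt) > 1) stats::var(dt) else NA_real_,
               var_control = if (length(dc) > 1) stats::var(dc) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$effect)
  overall <- mean(tab$effect[ok])
  sev <- (tab$var_treatment / tab$n_treatment +
          tab$var_control / tab$n_control)[ok]
  overall_se <- if (all(!is.na(sev)) && sum(ok) > 0)
    sqrt(sum(sev)) / sum(ok) else NA_real_
  structure(list(table = tab, overall_effect = overall,
                 overall_se = overall_se,
                 treatment = treatment_label, control = control_label,
                 x_axis = x_axis),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Clock deceleration readout: %s vs %s (by %s)\n",
              x$treatment, x$control, x$x_axis))
  print(x$table[, c("level", "n_treatment", "n_control",
                    "mean_delta_treatment", "mean_delta_control", "effect")],
        row.names = FALSE, digits = 4)
  cat(sprintf("Overall effect: %.4f passages", x$overall_effect))
  if (!is.na(x$overall_se)) cat(sprintf(" (SE %.4f)", x$overall_se))
  cat("\n")
  invisible(x)
}

#' @export
print.passage_clock <- function(x, ...) {
  m <- x$training_meta
  cat(sprintf("Passage clock: %d CpG(s), intercept %.4f\n",
              length(x$weights), x$intercept))
  cat(sprintf("  alpha %.2f, lambda %.6g (%s rule), %d training samples, passages %d-%d\n",
              m$alpha, m$lambda, m$lambda_rule, m$n_training_samples,
              m$passage_range[1], m$passage_range[2]))
  invisible(x)
}

#' @export
summary.passage_clock <- function(object, ...) {
  print(object)
  w <- object$weights
  cat(sprintf("  %d CpGs with positive weight (hypermethylating), %d negative (hypomethylating)\n",
              sum(w > 0), sum(w < 0)))
  if (length(w) > 0) {
    top <- w[order(-abs(w))][seq_len(min(10, length(w)))]
    cat("  largest |weight| CpGs:\n")
    for (i in seq_along(top))
      cat(sprintf("    %-12s %+ .4f\n", names(top)[i], top[i]))
  }
  invisible(object)
}

#' @export
coef.passage_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Plot predicted against actual passage
#'
#' @param x a `passage_clock`.
#' @param beta beta matrix of samples to score.
#' @param sheet sample sheet with actual passages.
#' @param ... passed to [graphics::plot()].
#' @export
plot.passage_clock <- function(x, beta, sheet, ...) {
  pr <- predict_passage(x, beta, sheet)
  graphics::plot(pr$actual_passage, pr$predicted_passage,
                 xlab = "actual passage", ylab = "predicted passage", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(pr)
}
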