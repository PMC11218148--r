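#' Screen CpGs whose methylation drifts with passage
#'
#' Each CpG is regressed on passage number by ordinary least squares,
#' `beta ~ a + b * passage`, on the beta scale (no M-value transform). The
#' two-sided t-test on the slope (n - 2 degrees of freedom) gives the per-probe
#' p-value; probes below the significance threshold are the differentially
#' methylated positions (DMPs) passed on to clock fitting. Exact linear fits
#' (zero residual sum of squares) are flagged and assigned p = 0 with an
#' infinite t statistic so ordering stays deterministic.
#'
#' @param betas numeric vector of beta values for one probe (one per sample).
#' @param passages integer vector of passages, same length, not all equal.
#' @return `fit_passage_regression()` returns a one-row data.frame with
#'   columns `slope` (delta-beta per passage), `intercept` (beta at passage
#'   0), `t_stat`, `p_value`, `direction` (`"hypo"` if slope < 0 else
#'   `"hyper"`) and `perfect_fit`.
#' @examples
#' fit_passage_regression(c(0.50, 0.46, 0.42), c(10, 12, 14))
#' @export
fit_passage_regression <- function(betas, passages) {
  res <- passage_ols(matrix(betas, nrow = 1), passages)
  res$probe_id <- NULL
  res
}

# Vectorised closed-form OLS of each matrix row on passage.
# Returns data.frame(probe_id, slope, intercept, t_stat, p_value, direction,
# perfect_fit). RSS below `eps` (absolute, beta^2 units) counts as an exact
# fit; constant responses get slope 0, t 0, p 1.
passage_ols <- function(beta, passages, eps = 1e-24) {
  n <- length(passages)
  if (n < 3) stop("need at least 3 samples for the passage regression",
                  call. = FALSE)
  if (ncol(beta) != n)
    stop("beta columns and passages differ in length", call. = FALSE)
  p <- as.numeric(passages)
  if (length(unique(p)) < 2)
    stop("degenerate design: all passages identical", call. = FALSE)
  pc <- p - mean(p)
  sxx <- sum(pc^2)
  rm_ <- rowMeans(beta)
  bc <- beta - rm_                         # centred rows: stable tss/rss
  sxy <- as.numeric(bc %*% pc)
  slope <- sxy / sxx
  intercept <- rm_ - slope * mean(p)
  tss <- rowSums(bc^2)
  rss <- pmax(tss - slope^2 * sxx, 0)
  df <- n - 2
  constant <- tss < eps
  perfect <- !constant & rss < eps
  se <- sqrt(rss / df / sxx)
  t_stat <- ifelse(se > 0, slope / se, 0)
  p_value <- 2 * stats::pt(-abs(t_stat), df)
  t_stat[constant] <- 0
  p_value[constant] <- 1
  t_stat[perfect] <- sign(slope[perfect]) * Inf
  p_value[perfect] <- 0
  data.frame(
    probe_id = if (is.null(rownames(beta))) rep(NA_character_, nrow(beta))
               else rownames(beta),
    slope = slope, intercept = intercept, t_stat = t_stat,
    p_value = p_value,
    direction = ifelse(slope < 0, "hypo", "hyper"),
    perfect_fit = perfect,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname fit_passage_regression
#' @param beta complete beta matrix (probes x samples).
#' @param sheet sample sheet covering every sample of `beta`, with passages.
#' @param threshold significance threshold tau; probes with p_value <
#'   `threshold` are returned. Default 1e-11.
#' @return `screen_dmps()` returns a data.frame of per-probe results for
#'   probes passing the threshold, sorted by ascending p-value with ties
#'   broken by probe ID.
#' @export
screen_dmps <- function(beta, sheet, threshold = 1e-11) {
  beta <- as_beta_matrix(beta)
  if (anyNA(beta))
    stop("beta matrix has missing values; run drop_incomplete_probes() first",
         call. = FALSE)
  sheet <- as_sample_sheet(sheet)
  sheet <- match_sheet(beta, sheet)
  res <- passage_ols(beta, sheet$passage)
  res <- res[res$p_value < threshold, , drop = FALSE]
  res <- res[order(res$p_value, res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  message(sprintf("screen: %d DMP(s) at p < %g (%d hypo, %d hyper)",
                  nrow(res), threshold,
                  sum(res$direction == "hypo"),
                  sum(res$direction == "hyper")))
  res
}

#' @rdname fit_passage_regression
#' @param grid candidate thresholds, evaluated from the laxest down; the
#'   threshold minimising leave-one-out RMSE of predicted passage wins, ties
#'   broken toward the most stringent (smallest) value.
#' @param alpha,n_folds,lambda_rule,seed clock-fitting parameters used inside
#'   each leave-one-out fold (see [fit_clock()]).
#' @return `select_threshold_loo()` returns a list with `threshold` (selected
#'   tau) and `table` (data.frame of threshold, loo_rmse, feasible).
#' @export
select_threshold_loo <- function(beta, sheet,
                                 grid = c(1e-5, 1e-7, 1e-9, 1e-11, 1e-13),
                                 alpha = 0.5, n_folds = 5,
                                 lambda_rule = "min", seed = 1) {
  beta <- as_beta_matrix(beta)
  sheet <- as_sample_sheet(sheet)
  sheet <- match_sheet(beta, sheet)
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  grid <- sort(grid, decreasing = TRUE)
  n <- ncol(beta)
  if (n < 5) stop("need >= 5 samples for leave-one-out selection",
                  call. = FALSE)
  rmse <- numeric(length(grid))
  feasible <- logical(length(grid))
  for (k in seq_along(grid)) {
    tau <- grid[k]
    sq_err <- numeric(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      b_tr <- beta[, -i, drop = FALSE]
      s_tr <- sheet[-i, , drop = FALSE]
      dmps <- suppressMessages(screen_dmps(b_tr, s_tr, threshold = tau))
      if (nrow(dmps) == 0) { ok <- FALSE; break }
      fit <- fit_clock(b_tr[dmps$probe_id, , drop = FALSE], s_tr,
                       alpha = alpha, n_folds = min(n_folds, n - 1),
                       lambda_rule = lambda_rule, seed = seed + i)
      pr <- predict_passage(fit, beta[, i, drop = FALSE],
                            sheet[i, , drop = FALSE])
      sq_err[i] <- (pr$predicted_passage - pr$actual_passage)^2
    }
    feasible[k] <- ok
    rmse[k] <- if (ok) sqrt(mean(sq_err)) else Inf
  }
  best <- which(rmse == min(rmse))
  best <- best[which.min(grid[best])]   # ties -> most stringent tau
  list(threshold = grid[best],
       table = data.frame(threshold = grid, loo_rmse = rmse,
                          feasible = feasible))
}
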