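#' Reference elastic-net solver (cyclic coordinate descent)
#'
#' A plain-R cyclic coordinate-descent solver for the gaussian elastic net,
#' kept deliberately independent of the fitting engine used by [fit_clock()]
#' so that fits can be verified against it: same objective,
#' \eqn{\frac{1}{2n}\|y - w_0 - Xw\|^2 + \lambda[\alpha\|\tilde w\|_1 +
#' \frac{1-\alpha}{2}\|\tilde w\|_2^2]}, with the penalty applied on the
#' internally standardised scale (\eqn{\tilde w_j = w_j s_j}, \eqn{s_j} the
#' 1/n-convention standard deviation of column j) and coefficients returned on
#' the original scale. Run to tight convergence it serves as a numerical
#' oracle: [enet_objective()] evaluates the objective at any candidate
#' solution and [enet_kkt_residual()] measures the worst violation of the
#' subgradient optimality conditions.
#'
#' @param x design matrix (samples x predictors).
#' @param y numeric response.
#' @param alpha elastic-net mixing in \[0, 1\].
#' @param lambda penalty weight, >= 0.
#' @param tol convergence tolerance on the maximum standardised-coefficient
#'   change per sweep (default 1e-12).
#' @param max_iter sweep cap.
#' @return list with `intercept`, `coef` (original scale, named), `n_iter`,
#'   and `converged`.
#' @export
enet_coordinate_descent <- function(x, y, alpha, lambda, tol = 1e-12,
                                    max_iter = 100000L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x)
  z0 <- sweep(x, 2, xm)
  xs <- sqrt(colMeans(z0^2))
  xs[xs == 0] <- 1              # constant columns stay at coefficient 0
  z <- sweep(z0, 2, xs, "/")
  yc <- y - mean(y)
  b <- numeric(p)
  r <- yc                        # residual of the centred problem
  denom <- 1 + lambda * (1 - alpha)
  thr <- lambda * alpha
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      bj <- b[j]
      rho <- sum(z[, j] * r) / n + bj      # (1/n) z_j' (r + z_j b_j); var(z_j)=1
      bn <- sign(rho) * max(abs(rho) - thr, 0) / denom
      if (bn != bj) {
        r <- r - z[, j] * (bn - bj)
        b[j] <- bn
        delta_max <- max(delta_max, abs(bn - bj))
      }
    }
    if (delta_max < tol) { converged <- TRUE; break }
  }
  coef <- b / xs
  names(coef) <- colnames(x)
  list(intercept = mean(y) - sum(coef * xm), coef = coef,
       n_iter = it, converged = converged)
}

#' @rdname enet_coordinate_descent
#' @param intercept,coef a candidate solution on the original scale.
#' @return `enet_objective()` returns the penalised objective value.
#' @export
enet_objective <- function(x, y, intercept, coef, alpha, lambda) {
  x <- as.matrix(x)
  n <- nrow(x)
  xs <- sqrt(colMeans(sweep(x, 2, colMeans(x))^2))
  xs[xs == 0] <- 1
  bt <- coef * xs
  resid <- y - intercept - as.numeric(x %*% coef)
  sum(resid^2) / (2 * n) +
    lambda * (alpha * sum(abs(bt)) + (1 - alpha) / 2 * sum(bt^2))
}

#' @rdname enet_coordinate_descent
#' @return `enet_kkt_residual()` returns the maximum violation of the
#'   stationarity conditions over the intercept and all coordinates (0 at an
#'   exact optimum).
#' @export
enet_kkt_residual <- function(x, y, intercept, coef, alpha, lambda) {
  x <- as.matrix(x)
  n <- nrow(x)
  xm <- colMeans(x)
  z0 <- sweep(x, 2, xm)
  xs <- sqrt(colMeans(z0^2))
  xs[xs == 0] <- 1
  z <- sweep(z0, 2, xs, "/")
  bt <- coef * xs
  resid <- y - intercept - as.numeric(x %*% coef)
  g <- -as.numeric(crossprod(z, resid)) / n + lambda * (1 - alpha) * bt
  viol <- ifelse(bt != 0,
                 abs(g + lambda * alpha * sign(bt)),
                 pmax(abs(g) - lambda * alpha, 0))
  max(c(viol, abs(mean(resid))))
}

#' @rdname enet_coordinate_descent
#' @return `enet_lambda_max()` returns the smallest lambda at which every
#'   coefficient is zero, `max_j |(1/n) \sum_i z_ij (y_i - mean(y))| / alpha`.
#' @export
enet_lambda_max <- function(x, y, alpha) {
  x <- as.matrix(x)
  n <- nrow(x)
  xm <- colMeans(x)
  z0 <- sweep(x, 2, xm)
  xs <- sqrt(colMeans(z0^2))
  xs[xs == 0] <- 1
  z <- sweep(z0, 2, xs, "/")
  max(abs(as.numeric(crossprod(z, y - mean(y)))) / n) / max(alpha, 1e-3)
}
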