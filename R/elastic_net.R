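#' Fit an elastic net by cyclic coordinate descent
#'
#' Minimizes, over intercept `b0` and coefficients `beta`,
#' \deqn{\frac{1}{2n}\sum_i (y_i - b_0 - x_i\cdot\beta)^2 +
#'       \lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' via cyclic coordinate descent with soft-thresholding (the glmnet
#' parameterization). `alpha = 1` is the lasso, `alpha = 0` ridge,
#' `lambda = 0` ordinary least squares. Predictors are **not** standardized
#' internally by default — the clock's features are already min-max scaled
#' to \[0, 1\]; set `standardize = TRUE` for sensitivity analyses (the fit is
#' computed on scaled columns and coefficients are mapped back).
#'
#' The solver warm-starts along an internally built descending lambda path
#' ending at the requested `lambda`, which makes small-lambda fits both fast
#' and stable. Convergence is declared when the largest single-coefficient
#' change in a sweep (intercept included) drops below `tol`.
#'
#' @param X numeric matrix, samples x predictors (column names kept).
#' @param y numeric response vector.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda penalty strength >= 0.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter maximum sweeps per lambda.
#' @param standardize standardize predictors internally? Default `FALSE`.
#' @return list of class `elnet_fit` with `b0`, `beta` (named, dense),
#'   `alpha`, `lambda`, `sweeps`.
#' @export
elastic_net_fit <- function(X, y, alpha = 0.5, lambda, tol = 1e-7,
                            max_iter = 100000L, standardize = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  alpha <- check_number(alpha, "alpha", 0, 1)
  lambda <- check_number(lambda, "lambda", 0)
  if (nrow(X) != length(y)) stop_("nrow(X) != length(y)")
  if (nrow(X) < 2L) stop_("need at least two observations")
  if (check_flag(standardize, "standardize")) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    if (any(sdev == 0)) stop_("cannot standardize constant predictor column(s)")
    Xs <- scale(X, center = mu, scale = sdev)
    f <- elastic_net_fit(Xs, y, alpha, lambda, tol, max_iter, standardize = FALSE)
    ## y ~ b0s + Xs bs  =  (b0s - sum(bs * mu / sd)) + X (bs / sd)
    beta <- f$beta / sdev
    f$b0 <- f$b0 - sum(beta * mu)
    f$beta <- setNames(beta, colnames(X))
    return(f)
  }
  lam_path <- elnet_warm_path(X, y, alpha, lambda)
  fit <- elnet_path_cpp(X, y, alpha, lam_path, tol, as.integer(max_iter),
                        0, numeric(ncol(X)))
  last <- length(lam_path)
  if (!fit$converged[last]) {
    cond <- structure(class = c("elnet_nonconvergence", "error", "condition"),
                      list(message = sprintf(
                        "coordinate descent did not converge in %d sweeps (max coefficient change %.3g > tol %.3g)",
                        max_iter, fit$max_delta[last], tol),
                        call = sys.call(-1),
                        b0 = fit$b0[last], beta = fit$beta[, last],
                        max_delta = fit$max_delta[last]))
    stop(cond)
  }
  structure(list(b0 = fit$b0[last],
                 beta = setNames(fit$beta[, last], colnames(X)),
                 alpha = alpha, lambda = lambda,
                 sweeps = sum(fit$sweeps)),
            class = "elnet_fit")
}

## descending geometric warm-start path from lambda_max down to the target.
elnet_warm_path <- function(X, y, alpha, lambda, length_out = 25L) {
  lam_max <- elnet_lambda_max(X, y, alpha)
  if (lambda >= lam_max) return(lambda)
  lo <- max(lambda, lam_max * 1e-6)
  path <- exp(seq(log(lam_max), log(lo), length.out = length_out))
  c(path, lambda)
}

## smallest lambda with an all-zero solution (at alpha; floored for ridge).
## The 1e-9 cushion keeps the solution exactly zero at the path head even
## when BLAS and sequential summation round the gradient differently.
elnet_lambda_max <- function(X, y, alpha) {
  n <- nrow(X)
  (1 + 1e-9) * max(abs(crossprod(X, y - mean(y)) / n)) / max(alpha, 0.001)
}

#' Karush-Kuhn-Tucker residuals of an elastic-net fit
#'
#' Returns per-coefficient `rho_j = (1/n) sum_i x_ij r_i` (partial gradients
#' at the solution). At an exact optimum, `|rho_j| <= lambda * alpha` for
#' every zero coefficient and `rho_j = lambda * alpha * sign(beta_j) +
#' lambda * (1 - alpha) * beta_j` for nonzero ones.
#'
#' @param fit an `elnet_fit`.
#' @param X,y the training data the fit was computed on.
#' @return named numeric vector of `rho_j`.
#' @export
elnet_kkt <- function(fit, X, y) {
  r <- y - fit$b0 - as.numeric(as.matrix(X) %*% fit$beta)
  drop(crossprod(as.matrix(X), r)) / nrow(X)
}

#' @export
print.elnet_fit <- function(x, ...) {
  cat(sprintf("Elastic-net fit: alpha=%g lambda=%g, %d/%d nonzero coefficients, intercept %.4g\n",
              x$alpha, x$lambda, sum(x$beta != 0), length(x$beta), x$b0))
  invisible(x)
}

#' Select the elastic-net penalty by k-fold cross-validation
#'
#' Builds a path of `nlambda` values log-spaced from the smallest lambda
#' with an all-zero solution (`lambda_max = max_j |(1/n) sum_i x_ij (y_i -
#' mean(y))| / max(alpha, 0.001)`) down to `lambda_min_ratio * lambda_max`,
#' assigns folds deterministically from `seed`, fits the whole path on each
#' training fold with warm starts, and scores held-out squared (`"mse"`) or
#' absolute (`"mae"`) error. `lambda_min` minimizes the mean criterion;
#' `lambda_1se` is the largest lambda within one standard error of that
#' minimum (the conservative choice).
#'
#' @param X samples x predictors matrix.
#' @param y response vector.
#' @param alpha elastic-net mixing parameter.
#' @param k number of folds (>= 2).
#' @param criterion `"mse"` (default) or `"mae"`.
#' @param seed integer seed controlling the fold assignment.
#' @param nlambda path length, default 100.
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`,
#'   default 1e-4.
#' @param rule which lambda `$chosen` points at: `"min"` (default) or `"1se"`.
#' @param tol,max_iter solver controls.
#' @return list of class `diage_cv`: `lambda` (path), `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `chosen`, `folds`, plus settings.
#' @export
cv_select_lambda <- function(X, y, alpha = 0.5, k = 10L, criterion = c("mse", "mae"),
                             seed = 1L, nlambda = 100L, lambda_min_ratio = 1e-4,
                             rule = c("min", "1se"), tol = 1e-5, max_iter = 100000L) {
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  k <- check_count(k, "k", 2L)
  if (n < k) stop_("fewer samples (%d) than folds (%d)", n, k)
  lam_max <- elnet_lambda_max(X, y, alpha)
  if (lam_max <= 0) lam_max <- 1e-3   # y exactly constant: degenerate but legal
  lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = nlambda))
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  errs <- matrix(NA_real_, k, nlambda)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- elnet_path_cpp(X[tr, , drop = FALSE], y[tr], alpha, lambda,
                          tol, as.integer(max_iter), 0, numeric(ncol(X)))
    pred <- X[!tr, , drop = FALSE] %*% fit$beta +
      matrix(fit$b0, sum(!tr), nlambda, byrow = TRUE)
    res <- pred - y[!tr]
    errs[f, ] <- if (criterion == "mse") colMeans(res^2) else colMeans(abs(res))
  }
  cvm <- colMeans(errs)
  cvsd <- apply(errs, 2, sd) / sqrt(k)
  i_min <- which.min(cvm)
  ok <- cvm <= cvm[i_min] + cvsd[i_min]
  i_1se <- which(ok)[1L]        # path is descending, so first = largest lambda
  out <- list(lambda = lambda, cvm = cvm, cvsd = cvsd,
              lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
              chosen = if (rule == "min") lambda[i_min] else lambda[i_1se],
              rule = rule, criterion = criterion, alpha = alpha,
              k = k, seed = seed, folds = folds)
  structure(out, class = "diage_cv")
}

#' @export
print.diage_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d lambdas (alpha=%g, %s): lambda_min=%.4g, lambda_1se=%.4g, chosen=%.4g (%s)\n",
              x$k, length(x$lambda), x$alpha, x$criterion,
              x$lambda_min, x$lambda_1se, x$chosen, x$rule))
  invisible(x)
}
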