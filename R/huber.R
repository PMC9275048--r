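# Huber M-estimator linear regression by iteratively reweighted least
# squares. This is the statistical engine behind the differential
# gene-gene interaction test.

#' Huber M-estimator fit (matrix interface)
#'
#' Minimises the Huber rho of the residuals by IRLS. The residual scale
#' is the MAD (consistency factor 1.4826, centered at zero) re-estimated
#' at every iteration; iteration stops when the maximum relative
#' coefficient change drops below \code{tol} or after \code{max_iter}
#' iterations. Standard errors use the classical M-estimator asymptotic
#' formula \eqn{\hat\sigma^2 \, \kappa \, (X'X)^{-1}} with
#' \eqn{\kappa = n/(n-p) \cdot \overline{\psi^2} / (\overline{\psi'})^2},
#' multiplied by the square of Huber's small-sample correction
#' \eqn{1 + p \, \mathrm{var}(\psi') / (n \, \overline{\psi'}^2)}.
#'
#' With \code{k = Inf} every observation gets weight one and the fit is
#' ordinary least squares.
#'
#' @param y numeric response vector
#' @param X numeric design matrix (including the intercept column);
#'   \code{nrow(X) == length(y)} and \code{length(y) >= ncol(X) + 1}
#' @param k Huber tuning constant (default 1.345, 95\% Gaussian
#'   efficiency)
#' @param tol convergence tolerance on the relative coefficient change
#' @param max_iter iteration cap
#' @return object of class \code{huber_fit}: coefficients, scale,
#'   standard errors, covariance matrix, residuals, fitted values,
#'   robustness weights, iteration count, convergence and zero-scale
#'   flags
#' @export
huber_fit <- function(y, X, k = 1.345, tol = 1e-8, max_iter = 50L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n)
    stop_deggnet("nrow(X) must equal length(y)")
  if (n < p + 1)
    stop_deggnet(sprintf("too few observations: n = %d for %d coefficients",
                         n, p), "deggnet_validation")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_deggnet(sprintf("design is rank deficient; collinear column(s): %s",
                         paste(dropped, collapse = ", ")),
                 "deggnet_rank")
  }
  beta <- qr.coef(qrX, y)
  scale_floor <- 1e3 * .Machine$double.eps * max(1, stats::sd(y))
  zero_scale <- FALSE
  converged <- FALSE
  iter <- 0L
  s <- NA_real_
  repeat {
    r <- y - drop(X %*% beta)
    s <- 1.4826 * stats::median(abs(r))
    if (s < scale_floor) {
      # (near-)exact fit: residual scale degenerates, keep the current
      # (least-squares) solution and flag it
      s <- scale_floor
      zero_scale <- TRUE
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    u <- abs(r) / s
    w <- ifelse(u <= k, 1, k / u)
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), y * sw)
    rel <- max(abs(beta_new - beta) / pmax(abs(beta_new), 1e-10))
    beta <- beta_new
    if (rel < tol) { converged <- TRUE; break }
  }
  r <- y - drop(X %*% beta)
  u <- r / s
  psi <- pmin(k, pmax(-k, u))
  psi_prime <- as.numeric(abs(u) <= k)
  mean_dpsi <- mean(psi_prime)
  if (mean_dpsi <= 0) mean_dpsi <- 1 / n  # pathological: all gross outliers
  # Huber's small-sample correction guards against anti-conservative
  # standard errors at cohort-sized n
  correction <- 1 + p * stats::var(psi_prime) / (n * mean_dpsi^2)
  kappa <- correction^2 * (n / (n - p)) * mean(psi^2) / mean_dpsi^2
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  vcov <- s^2 * kappa * XtX_inv
  se <- sqrt(diag(vcov))
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    scale = s,
    standard_errors = se,
    vcov = vcov,
    residuals = r,
    fitted = drop(X %*% beta),
    weights = if (zero_scale) rep(1, n) else ifelse(abs(u) <= k, 1, k / abs(u)),
    iterations = iter,
    converged = converged,
    zero_scale = zero_scale,
    df.residual = n - p,
    k = k
  ), class = "huber_fit")
}

#' Huber robust linear model (formula interface)
#'
#' Formula front end to [huber_fit()], in the style of \code{lm}.
#'
#' @param formula model formula
#' @param data data.frame
#' @param ... passed to [huber_fit()] (\code{k}, \code{tol},
#'   \code{max_iter})
#' @return object of class \code{c("huber_lm", "huber_fit")}
#' @examples
#' d <- data.frame(x = 1:20, y = 2 * (1:20) + rnorm(20, sd = 0.1))
#' fit <- huber_lm(y ~ x, d)
#' coef(fit)
#' @export
huber_lm <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- huber_fit(y, X, ...)
  fit$terms <- attr(mf, "terms")
  fit$xlevels <- stats::.getXlevels(attr(mf, "terms"), mf)
  fit$call <- match.call()
  class(fit) <- c("huber_lm", class(fit))
  fit
}

#' @export
print.huber_fit <- function(x, ...) {
  cat("Huber M-estimator linear fit",
      if (x$zero_scale) "(exact fit; scale floored)" else "", "\n")
  cat(sprintf("  scale: %.4g | iterations: %d | converged: %s\n",
              x$scale, x$iterations, x$converged))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.huber_fit <- function(object, ...) object$coefficients

#' @export
residuals.huber_fit <- function(object, ...) object$residuals

#' @export
fitted.huber_fit <- function(object, ...) object$fitted

#' @export
vcov.huber_fit <- function(object, ...) object$vcov

#' @export
summary.huber_fit <- function(object, ...) {
  z <- object$coefficients / object$standard_errors
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$standard_errors,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, scale = object$scale,
              iterations = object$iterations,
              converged = object$converged,
              df.residual = object$df.residual)
  class(out) <- "summary.huber_fit"
  out
}

#' @export
print.summary.huber_fit <- function(x, ...) {
  cat("Huber M-estimator linear fit\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Robust residual scale: %.4g on %d degrees of freedom (%d IRLS iterations)\n",
              x$scale, x$df.residual, x$iterations))
  invisible(x)
}

#' @export
predict.huber_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}
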