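#' Least-squares engine
#'
#' Ordinary least squares on an explicit design matrix (intercept included by
#' the caller). Standard errors from sigma^2 (X'X)^-1 with sigma^2 =
#' RSS / df_residual; two-sided t p-values.
#'
#' @param x numeric design matrix with named columns.
#' @param y numeric response.
#' @return a \code{fitResult} list: coefficients, se, statistic (t), p, vcov,
#'   n, df_residual, r_squared, fitted, residuals, rss.
#' @export
olsFit <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("design and response lengths differ")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  n <- nrow(x); p <- ncol(x)
  df <- n - p
  if (df <= 0) stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")")
  coef <- qr.coef(qrx, y)
  fitted <- drop(x %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / df
  xtxinv <- chol2inv(qr.R(qrx))
  dimnames(xtxinv) <- list(colnames(x), colnames(x))
  vcov <- sigma2 * xtxinv
  se <- sqrt(diag(vcov))
  tstat <- coef / se
  pvals <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = coef, se = se, statistic = tstat, p = pvals,
                 vcov = vcov, n = n, df_residual = df,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 fitted = fitted, residuals = res, rss = rss,
                 family = "gaussian"),
            class = "fitResult")
}

#' Logistic-regression engine
#'
#' Maximum likelihood by iteratively reweighted least squares
#' (\code{stats::glm.fit}) on an explicit design matrix. Wald standard errors
#' from the inverse Fisher information at the optimum; odds ratios as
#' exp(coef) with 95% intervals exp(coef +/- 1.959964 se). Non-convergence
#' and complete separation raise explicit errors.
#'
#' @param x numeric design matrix with named columns (include the intercept).
#' @param y binary 0/1 response.
#' @return a \code{fitResult} list: coefficients, se, statistic (Wald z), p,
#'   vcov, n, df_residual, log_likelihood, fitted, or, ci_low, ci_high.
#' @export
logisticFit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (nrow(x) != length(y)) stop("design and response lengths differ")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged) stop("logistic fit did not converge in 100 iterations")
  mu <- fit$fitted.values
  coef <- fit$coefficients
  if (max(abs(coef)) > 15 && (min(mu) < 1e-8 || max(mu) > 1 - 1e-8))
    stop("complete separation detected in logistic fit")
  w <- mu * (1 - mu)
  info <- crossprod(x * sqrt(w))
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vcov))
  z <- coef / se
  pvals <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  structure(list(coefficients = coef, se = se, statistic = z, p = pvals,
                 vcov = vcov, n = nrow(x), df_residual = nrow(x) - ncol(x),
                 log_likelihood = ll, fitted = mu,
                 or = exp(coef),
                 ci_low = exp(coef - Z975 * se),
                 ci_high = exp(coef + Z975 * se),
                 family = "binomial"),
            class = "fitResult")
}

#' @export
print.fitResult <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, df = %d\n", x$family, x$n, x$df_residual))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    statistic = x$statistic, p = x$p)
  print(tab, digits = 4)
  invisible(x)
}

# Build a design matrix from a cohort data.frame: intercept, optional focal
# column(s), covariates with sex expanded to the female indicator.
designMatrix <- function(data, covars, focal = NULL) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  if (!is.null(focal)) for (nm in names(focal)) cols[[nm]] <- focal[[nm]]
  for (cv in covars) {
    if (cv == "sex") cols[["sexfemale"]] <- as.numeric(data$sex == "female")
    else cols[[cv]] <- data[[cv]]
  }
  do.call(cbind, cols)
}

# Complete-case row index over the named columns plus optional extra vectors.
completeRows <- function(data, cols, ...) {
  ok <- rep(TRUE, nrow(data))
  for (cl in cols) ok <- ok & !is.na(data[[cl]])
  for (v in list(...)) ok <- ok & !is.na(v)
  which(ok)
}
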