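#' Regression-based multivariable MR
#'
#' Weighted least squares of SNP-outcome effects on the J x K matrix of
#' SNP-exposure effects without an intercept, weights 1/sy^2. Each
#' coefficient is an exposure's direct effect on the outcome conditional
#' on the other exposures. Standard errors carry a multiplicative
#' dispersion factor max(1, RSS / (J - K)); p-values are two-sided normal.
#' With K = 1 the estimator reproduces the fixed-effect univariable IVW
#' point estimate exactly (and the random-effects SE, since the dispersion
#' rule matches).
#'
#' @param h A [harmonize]d set with K >= 1 exposures and J > K SNPs.
#' @return An object of class `mvmr_result`: list with `exposure_names`,
#'   `betas`, `ses`, `pvals`, `or_`, `ci_low`, `ci_high`, `nsnp`, `rss`.
#' @export
mvmr_ivw <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  X <- h$bx
  K <- ncol(X); J <- nrow(X)
  if (J <= K)
    stop(sprintf("insufficient instruments: %d SNPs for %d exposures (need J > K)",
                 J, K), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < K) {
    bad <- h$exposure_names[qrX$pivot[(qrX$rank + 1):K]]
    stop("collinear or degenerate exposure effects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- 1 / h$sy^2
  fit <- stats::lm.wfit(X, h$by, w)
  rss <- sum(w * fit$residuals^2)
  disp <- max(1, rss / (J - K))
  cov_unscaled <- solve(crossprod(X * sqrt(w)))
  ses <- sqrt(diag(cov_unscaled) * disp)
  betas <- fit$coefficients
  pvals <- 2 * stats::pnorm(abs(betas / ses), lower.tail = FALSE)
  z <- stats::qnorm(0.975)
  structure(list(
    exposure_names = h$exposure_names,
    betas = unname(betas), ses = unname(ses), pvals = unname(pvals),
    or_ = exp(unname(betas)),
    ci_low = unname(betas - z * ses), ci_high = unname(betas + z * ses),
    nsnp = J, rss = rss
  ), class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR: %d SNPs, %d exposures\n",
              x$nsnp, length(x$exposure_names)))
  print(data.frame(exposure = x$exposure_names, beta = x$betas, se = x$ses,
                   or_ = x$or_, pval = x$pvals))
  invisible(x)
}

#' Extract one exposure's row from a multivariable MR fit
#'
#' @param fit An `mvmr_result`.
#' @param exposure Name of the exposure to extract.
#' @return List with `beta`, `se`, `pval`, `or_`.
#' @export
mvmr_coef <- function(fit, exposure) {
  stopifnot(inherits(fit, "mvmr_result"))
  i <- match(exposure, fit$exposure_names)
  if (is.na(i)) stop("exposure not in fit: ", exposure, call. = FALSE)
  list(beta = fit$betas[i], se = fit$ses[i], pval = fit$pvals[i],
       or_ = fit$or_[i])
}
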