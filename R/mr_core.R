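#' @keywords internal
mr_result <- function(method, nsnp, beta, se, pval,
                      egger_intercept = NULL, egger_intercept_se = NULL,
                      egger_intercept_p = NULL,
                      q_stat = NULL, q_df = NULL, q_p = NULL) {
  structure(list(
    method = method, nsnp = nsnp, beta = beta, se = se, pval = pval,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    or_ = exp(beta),
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    q_stat = q_stat, q_df = q_df, q_p = q_p
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$nsnp))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], OR = %.3f, p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$or_, x$pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  if (!is.null(x$q_stat))
    cat(sprintf("  Cochran Q = %.2f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_p))
  invisible(x)
}

#' Single-SNP Wald ratio
#'
#' Ratio estimate by/bx with the first-order standard error sy/|bx|
#' (exposure-side uncertainty ignored; appropriate when instruments are
#' strong, F > 10).
#'
#' @param bx SNP-exposure effect (nonzero).
#' @param by SNP-outcome effect.
#' @param sy Standard error of `by` (positive).
#' @return List with `ratio` and `se`.
#' @export
wald_ratio <- function(bx, by, sy) {
  if (bx == 0) stop("Wald ratio undefined for bx = 0", call. = FALSE)
  if (sy <= 0) stop("`sy` must be positive", call. = FALSE)
  list(ratio = by / bx, se = sy / abs(bx))
}

#' Inverse-variance-weighted estimator
#'
#' Combines per-SNP Wald ratios with weights bx^2 / sy^2, equivalent to
#' weighted regression of the outcome effects on the exposure effects
#' through the origin. The multiplicative random-effects model (default)
#' inflates the fixed-effect SE by sqrt(max(1, Q / (J - 1))), where Q is
#' Cochran's heterogeneity statistic; it is never anti-conservative
#' relative to the fixed-effect model. With a single SNP the estimate
#' reduces to the Wald ratio.
#'
#' @param h A [harmonize]d set with one exposure.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_result` with heterogeneity (`q_stat`, `q_df`, `q_p`)
#'   fields when J >= 2.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  u <- .univariable(h)
  J <- length(u$by)
  if (J == 1L) {
    wr <- wald_ratio(u$bx, u$by, u$sy)
    p <- 2 * stats::pnorm(abs(wr$ratio / wr$se), lower.tail = FALSE)
    return(mr_result("wald", 1L, wr$ratio, wr$se, p))
  }
  if (all(u$sy == 0)) stop("all outcome SEs are zero", call. = FALSE)
  w <- u$bx^2 / u$sy^2
  beta <- sum(u$bx * u$by / u$sy^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  # Q = sum_j w_j (by_j/bx_j - beta)^2 == sum_j (by_j - beta*bx_j)^2 / sy_j^2
  q <- sum((u$by - beta * u$bx)^2 / u$sy^2)
  q_df <- J - 1L
  se <- if (model == "random") se_fixed * sqrt(max(1, q / q_df)) else se_fixed
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  mr_result(paste0("ivw_", model), J, beta, se, p,
            q_stat = q, q_df = q_df,
            q_p = stats::pchisq(q, q_df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights 1/sy^2, after orienting every SNP so the exposure
#' effect is non-negative (Egger regression is not orientation-invariant,
#' so a fixed convention is applied). The intercept estimates the average
#' directional pleiotropy; the slope is the pleiotropy-adjusted causal
#' effect. Standard errors carry a multiplicative dispersion factor
#' max(1, RSS / (J - 2)); inference uses the t distribution with J - 2
#' degrees of freedom.
#'
#' @param h A [harmonize]d set with one exposure and J >= 3 SNPs.
#' @return An `mr_result` with `egger_intercept*` fields populated.
#' @export
mr_egger <- function(h) {
  u <- .univariable(h)
  J <- length(u$by)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(u$bx); flip[flip == 0] <- 1
  bx <- u$bx * flip; by <- u$by * flip
  if (stats::var(bx) == 0)
    stop("exposure effects are constant; Egger fit is singular", call. = FALSE)
  w <- 1 / u$sy^2
  X <- cbind(intercept = 1, slope = bx)
  fit <- stats::lm.wfit(X, by, w)
  rss <- sum(w * fit$residuals^2)
  disp <- max(1, rss / (J - 2))
  cov_unscaled <- solve(crossprod(X * sqrt(w)))
  ses <- sqrt(diag(cov_unscaled) * disp)
  tval <- fit$coefficients / ses
  pv <- 2 * stats::pt(abs(tval), df = J - 2, lower.tail = FALSE)
  q <- rss
  mr_result("egger", J,
            beta = unname(fit$coefficients[2L]), se = unname(ses[2L]),
            pval = unname(pv[2L]),
            egger_intercept = unname(fit$coefficients[1L]),
            egger_intercept_se = unname(ses[1L]),
            egger_intercept_p = unname(pv[1L]),
            q_stat = q, q_df = J - 2L,
            q_p = stats::pchisq(q, J - 2L, lower.tail = FALSE))
}

# weighted median of `x` with weights `w` by linear interpolation of the
# cumulative standardized weight p_j = (cumsum(w) - w/2) / sum(w)
.weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1L]) return(x[1L])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

.median_estimator <- function(h, weighted, n_boot = 1000L, seed = 1L) {
  u <- .univariable(h)
  J <- length(u$by)
  if (J < 3L) stop("median estimators require at least 3 instruments",
                   call. = FALSE)
  ratios <- u$by / u$bx
  weights <- if (weighted) u$bx^2 / u$sy^2 else rep(1 / J, J)
  est <- .weighted_median_point(ratios, weights)
  # parametric bootstrap for the SE: resample summary effects from their
  # sampling distributions and re-evaluate the median
  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(seed)
  bvals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx_b <- stats::rnorm(J, u$bx, u$sx)
    by_b <- stats::rnorm(J, u$by, u$sy)
    r_b <- by_b / bx_b
    w_b <- if (weighted) bx_b^2 / u$sy^2 else rep(1 / J, J)
    bvals[b] <- .weighted_median_point(r_b, w_b)
  }
  se <- stats::sd(bvals)
  p <- if (se > 0) 2 * stats::pnorm(abs(est / se), lower.tail = FALSE) else
    as.numeric(est == 0)
  mr_result(if (weighted) "weighted_median" else "simple_median",
            J, est, se, max(p, .Machine$double.xmin))
}

# save/restore global RNG state so seeded bootstraps do not perturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Simple and weighted median estimators
#'
#' The median of the per-SNP Wald ratios, using equal weights (simple) or
#' inverse-variance weights bx^2/sy^2 (weighted), evaluated by linear
#' interpolation of the cumulative standardized weight at 0.5. The
#' weighted median is consistent when less than half the total weight lies
#' on invalid instruments. Standard errors come from a seeded parametric
#' bootstrap that resamples both exposure and outcome effects from their
#' sampling distributions.
#'
#' @param h A [harmonize]d set with one exposure and J >= 3 SNPs.
#' @param n_boot Number of bootstrap draws.
#' @param seed Seed for the bootstrap (the caller's RNG state is
#'   preserved).
#' @return An `mr_result`.
#' @export
mr_simple_median <- function(h, n_boot = 1000L, seed = 1L)
  .median_estimator(h, weighted = FALSE, n_boot = n_boot, seed = seed)

#' @rdname mr_simple_median
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = 1L)
  .median_estimator(h, weighted = TRUE, n_boot = n_boot, seed = seed)

#' Single-SNP analysis
#'
#' One Wald-ratio row per SNP. SNPs with a zero exposure effect have an
#' undefined ratio and are excluded with a reason.
#'
#' @param h A [harmonize]d set with one exposure.
#' @return data.frame with columns `snp`, `ratio`, `se`, `pval` and
#'   attribute `excluded` (data.frame of snp/reason).
#' @export
single_snp_analysis <- function(h) {
  u <- .univariable(h)
  ok <- u$bx != 0
  out <- data.frame(snp = u$snp[ok],
                    ratio = u$by[ok] / u$bx[ok],
                    se = u$sy[ok] / abs(u$bx[ok]),
                    stringsAsFactors = FALSE)
  out$pval <- 2 * stats::pnorm(abs(out$ratio / out$se), lower.tail = FALSE)
  attr(out, "excluded") <- data.frame(
    snp = u$snp[!ok], reason = rep("zero exposure effect", sum(!ok)),
    stringsAsFactors = FALSE)
  out
}

#' Leave-one-out analysis
#'
#' Re-estimates the IVW effect excluding each SNP in turn; a row whose
#' estimate departs markedly from the full-set estimate points to an
#' influential (possibly pleiotropic) variant.
#'
#' @param h A [harmonize]d set with one exposure and J >= 3 SNPs.
#' @param model IVW model, as in [mr_ivw()].
#' @return data.frame with columns `left_out_snp`, `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  u <- .univariable(h)
  J <- length(u$by)
  if (J < 3L) stop("leave-one-out requires at least 3 instruments",
                   call. = FALSE)
  rows <- lapply(seq_len(J), function(j) {
    hj <- h
    hj$snp_ids <- h$snp_ids[-j]
    hj$bx <- h$bx[-j, , drop = FALSE]; hj$sx <- h$sx[-j, , drop = FALSE]
    hj$by <- h$by[-j]; hj$sy <- h$sy[-j]
    fit <- mr_ivw(hj, model = model)
    data.frame(left_out_snp = u$snp[j], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
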