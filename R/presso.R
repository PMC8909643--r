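#' MR-PRESSO: global, outlier and distortion tests
#'
#' Simulation-based pleiotropy residual sum of squares test. The observed
#' statistic is RSS = sum_j (by_j - b(-j) * bx_j)^2 / sy_j^2 where b(-j)
#' is the leave-one-out IVW estimate. A parametric null is built by
#' drawing by*_j ~ Normal(b(-j) * bx_j, sy_j^2) `nsim` times and
#' recomputing the statistic; the global p-value is the add-one-smoothed
#' exceedance probability, so it is bounded below by 1/(nsim + 1). The
#' outlier test compares each SNP's observed squared standardized residual
#' to its own simulated distribution (Bonferroni-adjusted across SNPs);
#' the distortion test measures the relative change in the IVW estimate
#' after removing flagged outliers against random outlier re-assignments.
#'
#' @param h A [harmonize]d set with one exposure and J >= 4 SNPs.
#' @param nsim Number of simulated null datasets (>= 100).
#' @param seed Integer seed for the simulation generator (caller RNG state
#'   is preserved).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (and for running it at all after the global
#'   test).
#' @return An object of class `presso_result`: list with `global_rss`,
#'   `global_p`, `outliers` (data.frame snp/outlier_p, the
#'   Bonferroni-adjusted p), `flagged` (snp ids below `outlier_alpha`),
#'   `corrected` (IVW [mr_result] on the non-flagged subset, or NULL),
#'   `distortion` (relative change in estimate) and `distortion_p`,
#'   `nsim`, `seed`.
#' @export
mr_presso <- function(h, nsim = 1000L, seed = 1L, outlier_alpha = 0.05) {
  u <- .univariable(h)
  J <- length(u$by)
  if (J < 4L) stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  if (nsim < 100L) stop("`nsim` must be at least 100", call. = FALSE)

  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(seed)

  bx <- u$bx; by <- u$by; sy <- u$sy
  w <- 1 / sy^2
  sxx <- sum(bx^2 * w); sxy <- sum(bx * by * w)
  loo_den <- sxx - bx^2 * w
  b_loo <- (sxy - bx * by * w) / loo_den
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  # parametric null: J x nsim matrix of simulated outcome effects with the
  # per-SNP leave-one-out expectation, statistic recomputed identically
  mu <- b_loo * bx
  by_sim <- matrix(stats::rnorm(J * nsim, mean = mu, sd = sy), J, nsim)
  sxy_sim <- colSums(bx * by_sim * w)
  b_loo_sim <- (matrix(sxy_sim, J, nsim, byrow = TRUE) -
                  (bx * w) * by_sim) / loo_den
  res_sim <- w * (by_sim - b_loo_sim * bx)^2
  rss_sim <- colSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nsim + 1)

  outliers <- data.frame(snp = u$snp,
                         outlier_p = NA_real_,
                         stringsAsFactors = FALSE)
  flagged <- character(0)
  corrected <- NULL
  distortion <- NA_real_
  distortion_p <- NA_real_

  if (global_p < outlier_alpha) {
    p_raw <- (1 + rowSums(res_sim >= res_obs)) / (nsim + 1)
    outliers$outlier_p <- pmin(1, p_raw * J)
    flagged <- u$snp[outliers$outlier_p < outlier_alpha]
    if (length(flagged) && length(flagged) <= J - 2L) {
      keep <- !(u$snp %in% flagged)
      h_keep <- .subset_harmonized(h, keep)
      corrected <- mr_ivw(h_keep)
      beta_all <- mr_ivw(h)$beta
      distortion <- (beta_all - corrected$beta) / corrected$beta
      # null for the distortion: re-assign the outlier labels to randomly
      # chosen non-outlier SNPs and recompute the relative change, so the
      # null reflects removing unremarkable SNPs of the same count
      n_out <- length(flagged)
      nonout_idx <- which(keep)
      d_sim <- numeric(nsim)
      for (s in seq_len(nsim)) {
        drop_idx <- sample(nonout_idx, min(n_out, length(nonout_idx) - 2L))
        hs <- .subset_harmonized(h, setdiff(seq_len(J), drop_idx))
        beta_s <- mr_ivw(hs)$beta
        d_sim[s] <- (beta_all - beta_s) / beta_s
      }
      distortion_p <- (1 + sum(abs(d_sim) >= abs(distortion))) / (nsim + 1)
    } else if (length(flagged) > J - 2L) {
      stop("all but <2 SNPs flagged as outliers; corrected estimate undefined",
           call. = FALSE)
    }
  }

  structure(list(global_rss = rss_obs, global_p = global_p,
                 outliers = outliers, flagged = flagged,
                 corrected = corrected, distortion = distortion,
                 distortion_p = distortion_p, nsim = nsim, seed = seed),
            class = "presso_result")
}

# subset a harmonized set to an index/logical vector of SNPs
.subset_harmonized <- function(h, idx) {
  h$snp_ids <- h$snp_ids[idx]
  h$bx <- h$bx[idx, , drop = FALSE]
  h$sx <- h$sx[idx, , drop = FALSE]
  h$eafx <- h$eafx[idx, , drop = FALSE]
  h$by <- h$by[idx]; h$sy <- h$sy[idx]; h$eafy <- h$eafy[idx]
  h
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO (nsim = %d, seed = %d)\n", x$nsim, x$seed))
  cat(sprintf("  global RSS = %.3f, p = %.4g\n", x$global_rss, x$global_p))
  if (length(x$flagged)) {
    cat(sprintf("  outliers: %s\n", paste(x$flagged, collapse = ", ")))
    cat(sprintf("  corrected beta = %.4f, distortion = %.2f%%, p = %.4g\n",
                x$corrected$beta, 100 * x$distortion, x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}
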