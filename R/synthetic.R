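#' Generative truth for a two-sample mediation simulation
#'
#' Parameters of an explicit exposure -> mediator(s) -> outcome structural
#' model on the summary-statistic level. Exposure instruments receive
#' per-SNP effects gamma_j = |Normal(0, gamma_sd^2)| — effect alleles are
#' labeled exposure-increasing, the convention of published instrument
#' tables, which gives directional pleiotropy a well-defined sign; each
#' mediator also
#' gets its own instruments (effects kappa ~ Normal(0, kappa_sd^2)) so the
#' multivariable design matrix has full rank. True effects are
#' * mediator m, SNP j: alpha_m * gamma_j (exposure instruments) or
#'   kappa_j (that mediator's own instruments), 0 otherwise;
#' * outcome, SNP j: gamma_j * beta_d + sum_m (SNP j's mediator-m effect) *
#'   beta_m\[m\] + theta_j, where theta_j ~ Normal(pleiotropy_mean,
#'   pleiotropy_sd^2) for the invalid fraction of exposure instruments and
#'   0 otherwise.
#' Observed effects add Normal(0, se^2) sampling noise per trait, with the
#' SE scales standing in for 1/sqrt(N); p-values follow from z-scores.
#'
#' Defaults emulate a well-powered two-sample design: 143 exposure
#' instruments (the scale of a modern type 2 diabetes instrument set) with
#' a typical F-statistic in the 25-100 range, 50 instruments per mediator,
#' and a mediated share of two thirds of the total effect
#' (alpha = 0.5, beta_m = 0.4, beta_d = 0.1).
#'
#' @param J_exposure Number of exposure instruments.
#' @param J_mediator Number of instruments per mediator.
#' @param gamma_sd SD of true per-SNP exposure effects (log-odds scale).
#' @param kappa_sd SD of true per-SNP mediator-specific effects (SD scale).
#' @param alpha Exposure -> mediator effect(s), SD per log-odds; one value
#'   per mediator.
#' @param beta_m Mediator -> outcome direct effect(s), log-odds per SD;
#'   same length as `alpha`.
#' @param beta_d Exposure -> outcome direct effect, log-odds per log-odds.
#' @param pleiotropy_mean,pleiotropy_sd Law of the direct SNP -> outcome
#'   (horizontal pleiotropy) effects on invalid exposure instruments.
#' @param invalid_fraction Share of exposure instruments carrying
#'   pleiotropy, in \[0, 1\].
#' @param se_x,se_m,se_y Sampling-error scales of the exposure, mediator
#'   and outcome summary statistics, standing in for 1/sqrt(N): the
#'   defaults correspond to a continuous-trait mediator GWAS of roughly
#'   450,000 participants (se_m ~ 1/sqrt(450000)) and consortium-scale
#'   binary-trait GWAS for the exposure and outcome.
#' @param n_x,n_m,n_y Nominal GWAS sample sizes written into the tables.
#' @param mediator_names Labels; default M1, M2, ...
#' @param seed Integer seed.
#' @return An object of class `mediation_truth` (a list of the above plus
#'   `M`, the number of mediators).
#' @export
mediation_truth <- function(J_exposure = 143L, J_mediator = 50L,
                            gamma_sd = 0.04, kappa_sd = 0.03,
                            alpha = 0.5, beta_m = 0.4, beta_d = 0.1,
                            pleiotropy_mean = 0, pleiotropy_sd = 0,
                            invalid_fraction = 0,
                            se_x = 0.004, se_m = 0.0015, se_y = 0.01,
                            n_x = 475000, n_m = 450000, n_y = 180000,
                            mediator_names = NULL, seed = 1L) {
  stopifnot(J_exposure >= 1L, J_mediator >= 1L,
            gamma_sd >= 0, kappa_sd >= 0,
            length(alpha) == length(beta_m),
            pleiotropy_sd >= 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            se_x > 0, se_m > 0, se_y > 0)
  M <- length(alpha)
  if (is.null(mediator_names)) mediator_names <- paste0("M", seq_len(M))
  stopifnot(length(mediator_names) == M)
  structure(list(J_exposure = as.integer(J_exposure),
                 J_mediator = as.integer(J_mediator),
                 gamma_sd = gamma_sd, kappa_sd = kappa_sd,
                 alpha = alpha, beta_m = beta_m, beta_d = beta_d,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 se_x = se_x, se_m = se_m, se_y = se_y,
                 n_x = n_x, n_m = n_m, n_y = n_y,
                 mediator_names = mediator_names,
                 M = M, seed = as.integer(seed)),
            class = "mediation_truth")
}

#' Closed-form targets implied by a generative truth
#'
#' @param truth A [mediation_truth].
#' @return List with `total_effect` (= beta_d + sum(alpha * beta_m)),
#'   per-mediator `indirect` (= alpha * beta_m), `combined_indirect`, and
#'   `proportion` per mediator (NA with a flag when the total effect is
#'   zero).
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "mediation_truth"))
  indirect <- truth$alpha * truth$beta_m
  total <- truth$beta_d + sum(indirect)
  undefined <- total == 0
  list(total_effect = total,
       indirect = stats::setNames(indirect, truth$mediator_names),
       combined_indirect = sum(indirect),
       proportion = if (undefined) stats::setNames(rep(NA_real_, truth$M),
                                                   truth$mediator_names)
                    else stats::setNames(indirect / total, truth$mediator_names),
       combined_proportion = if (undefined) NA_real_ else sum(indirect) / total,
       proportion_undefined = undefined)
}

#' Simulate two-sample GWAS summary statistics under a mediation model
#'
#' Draws per-SNP true effects and observed summary statistics per
#' [mediation_truth], assigns non-palindromic A/G alleles (so
#' harmonization is exact) and an identity LD matrix. The same seed yields
#' bit-identical tables; the caller's RNG state is preserved.
#'
#' @param truth A [mediation_truth].
#' @return List with `exposure` (a [summary_table]), `mediators` (named
#'   list of summary tables), `outcome`, `ld` (an [ld_matrix]) and
#'   `truth`.
#' @export
simulate_mediation_sumstats <- function(truth) {
  stopifnot(inherits(truth, "mediation_truth"))
  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(truth$seed)

  Je <- truth$J_exposure; Jm <- truth$J_mediator; M <- truth$M
  J <- Je + M * Jm
  snp <- sprintf("rs%05d", seq_len(J))
  is_exp <- seq_len(J) <= Je
  med_block <- function(m) Je + (m - 1L) * Jm + seq_len(Jm)

  # exposure instruments are reported on the exposure-increasing allele
  # (the convention of published instrument tables), so gamma >= 0 and
  # directional pleiotropy has a well-defined sign
  gamma <- numeric(J)
  gamma[is_exp] <- abs(stats::rnorm(Je, 0, truth$gamma_sd))
  kappa <- matrix(0, J, M)
  for (m in seq_len(M))
    kappa[med_block(m), m] <- stats::rnorm(Jm, 0, truth$kappa_sd)

  # horizontal pleiotropy on a fixed fraction of exposure instruments
  theta <- numeric(J)
  n_invalid <- round(truth$invalid_fraction * Je)
  if (n_invalid > 0) {
    invalid <- sample.int(Je, n_invalid)
    theta[invalid] <- stats::rnorm(n_invalid, truth$pleiotropy_mean,
                                   truth$pleiotropy_sd)
  }

  true_med <- sweep(matrix(gamma, J, M), 2, truth$alpha, `*`) + kappa
  true_out <- gamma * truth$beta_d + true_med %*% truth$beta_m + theta

  eaf <- stats::runif(J, 0.05, 0.95)
  mk_table <- function(true_beta, se, n, name, type) {
    obs <- true_beta + stats::rnorm(J, 0, se)
    summary_table(data.frame(
      snp = snp, effect_allele = "A", other_allele = "G", eaf = eaf,
      beta = obs, se = se,
      pval = pmax(2 * stats::pnorm(abs(obs / se), lower.tail = FALSE),
                  .Machine$double.xmin),
      n = n, stringsAsFactors = FALSE), trait_name = name, trait_type = type)
  }

  exposure <- mk_table(gamma, truth$se_x, truth$n_x, "exposure", "binary")
  mediators <- stats::setNames(lapply(seq_len(M), function(m)
    mk_table(true_med[, m], truth$se_m, truth$n_m,
             truth$mediator_names[m], "continuous")), truth$mediator_names)
  outcome <- mk_table(as.numeric(true_out), truth$se_y, truth$n_y,
                      "outcome", "binary")
  ld <- ld_matrix(diag(J), snp_ids = snp)
  list(exposure = exposure, mediators = mediators, outcome = outcome,
       ld = ld, truth = truth)
}
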