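# in-code fixtures shared across test files

# a summary table from parallel vectors, with sensible fill-ins
make_table <- function(snp, beta, se, pval = NULL,
                       ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                       trait_name = "trait", trait_type = "continuous") {
  J <- length(snp)
  if (is.null(pval))
    pval <- pmax(2 * pnorm(abs(beta / se), lower.tail = FALSE),
                 .Machine$double.xmin)
  summary_table(data.frame(
    snp = snp, effect_allele = rep_len(ea, J), other_allele = rep_len(oa, J),
    eaf = rep_len(eaf, J), beta = beta, se = se, pval = pval,
    n = rep_len(n, J), stringsAsFactors = FALSE),
    trait_name = trait_name, trait_type = trait_type)
}

# a harmonized set assembled directly from effect vectors (K exposures)
make_h <- function(bx, by, sy, sx = NULL, snp = NULL,
                   exposure_names = NULL) {
  bx <- as.matrix(bx)
  J <- nrow(bx); K <- ncol(bx)
  if (is.null(sx)) sx <- matrix(1e-6, J, K) else sx <- as.matrix(sx)
  if (is.null(snp)) snp <- sprintf("rs%03d", seq_len(J))
  if (is.null(exposure_names)) exposure_names <- paste0("X", seq_len(K))
  structure(list(
    snp_ids = snp, exposure_names = exposure_names,
    exposure_types = rep("continuous", K),
    outcome_name = "Y", outcome_type = "binary",
    bx = bx, sx = sx, eafx = matrix(0.3, J, K),
    by = by, sy = sy, eafy = rep(0.3, J),
    dropped = data.frame(snp = character(0), reason = character(0))
  ), class = "harmonized_set")
}
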