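#' Construct a summary-statistics table
#'
#' A `summary_table` holds per-SNP association statistics for one trait:
#' variant identifier, effect and other allele, effect-allele frequency,
#' effect estimate (log-odds per effect-allele copy for binary traits, SD
#' units for continuous traits), its standard error, p-value and sample
#' size. Rows violating the record invariants (identical alleles,
#' non-positive SE, p-value outside (0, 1], non-ACGT alleles) are rejected
#' and logged; duplicate variant identifiers are resolved by keeping the
#' row with the smallest p-value.
#'
#' @param data data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (`eaf` and `n` may be
#'   `NA`).
#' @param trait_name Non-empty trait label.
#' @param trait_type `"binary"` or `"continuous"`; determines the scale on
#'   which `beta` is interpreted.
#' @return An object of class `summary_table`: the validated data.frame
#'   with attributes `trait_name`, `trait_type` and `rejected` (a
#'   data.frame of dropped rows with reasons).
#' @export
summary_table <- function(data, trait_name, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  if (!is.character(trait_name) || length(trait_name) != 1L || !nzchar(trait_name))
    stop("`trait_name` must be a non-empty string", call. = FALSE)
  required <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[required]
  data$snp <- as.character(data$snp)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])

  reason <- rep(NA_character_, nrow(data))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  nt <- c("A", "C", "G", "T")
  bad(!nzchar(data$snp) | is.na(data$snp), "missing snp id")
  bad(!(data$effect_allele %in% nt) | !(data$other_allele %in% nt),
      "allele not a single nucleotide")
  bad(data$effect_allele == data$other_allele, "identical alleles")
  bad(is.na(data$beta), "missing beta")
  bad(is.na(data$se) | data$se <= 0, "nonpositive se")
  bad(is.na(data$pval) | data$pval <= 0 | data$pval > 1, "pval outside (0,1]")
  # eaf/n may be missing, but if present must be in range
  eaf_bad <- !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1)
  reason[is.na(reason) & eaf_bad] <- "eaf outside [0,1]"
  n_bad <- !is.na(data$n) & data$n < 1
  reason[is.na(reason) & n_bad] <- "sample size < 1"

  rejected <- data.frame(snp = data$snp[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  data <- data[is.na(reason), , drop = FALSE]

  # duplicate snp ids: keep the smallest-p row, log the rest
  if (anyDuplicated(data$snp)) {
    ord <- order(data$pval, seq_len(nrow(data)))
    keep_first <- !duplicated(data$snp[ord])
    dup_rows <- ord[!keep_first]
    rejected <- rbind(rejected, data.frame(
      snp = data$snp[dup_rows],
      reason = "duplicate snp id (larger p-value)",
      stringsAsFactors = FALSE))
    keep <- sort(ord[keep_first])
    data <- data[keep, , drop = FALSE]
  }
  rownames(data) <- NULL

  structure(data,
            trait_name = trait_name,
            trait_type = trait_type,
            rejected = rejected,
            class = c("summary_table", "data.frame"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("Summary statistics for '%s' (%s trait): %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  (%d input rows rejected)\n", nrow(rej)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

# default column dialect: GWAS-SSF-like tab-separated export
.default_col_map <- c(snp = "SNP", effect_allele = "effect_allele",
                      other_allele = "other_allele", eaf = "eaf",
                      beta = "beta", se = "se", pval = "pval", n = "n")

#' Read GWAS summary statistics from a tab-separated file
#'
#' Default header is `SNP effect_allele other_allele eaf beta se pval n`
#' (tab-separated, `.` or empty for missing); other dialects are handled
#' through `col_map`. Invalid rows are dropped with a per-row reason,
#' available via `attr(, "rejected")`.
#'
#' @param path Path to the file.
#' @param trait_name Trait label.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param col_map Named character vector mapping the canonical names
#'   (`snp`, `effect_allele`, ...) to the file's header names.
#' @return A [summary_table].
#' @export
read_sumstats <- function(path, trait_name, trait_type = c("binary", "continuous"),
                          col_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- .default_col_map
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c(".", "", "NA"),
                           check.names = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols))
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- raw[unname(map)]
  names(data) <- names(map)
  tab <- summary_table(data, trait_name = trait_name, trait_type = trait_type)
  if (nrow(tab) == 0L)
    stop("no valid summary-statistic rows in ", path, call. = FALSE)
  tab
}

#' Write a summary-statistics table to a tab-separated file
#'
#' Writes the default column dialect; missing `eaf`/`n` serialize as `.`.
#' The written file round-trips through [read_sumstats()] without loss.
#'
#' @param table A [summary_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "summary_table"))
  if (nrow(table) == 0L)
    stop("refusing to write an empty summary table", call. = FALSE)
  out <- as.data.frame(table)
  names(out) <- unname(.default_col_map)
  for (col in names(out))
    out[[col]] <- ifelse(is.na(out[[col]]), ".", format(out[[col]], digits = 17,
                                                        scientific = FALSE,
                                                        trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every shared SNP to the first exposure's effect allele. Identical
#' alleles are kept as-is; swapped alleles negate the effect and reflect the
#' frequency; strand-complement alleles are mapped through A-T / C-G and
#' then treated the same way. Palindromic SNPs (A/T or C/G) cannot be
#' resolved from alleles alone and are handled by `palindrome_policy`:
#' `"frequency"` (default) drops the SNP if any table's effect-allele
#' frequency is missing or within (0.42, 0.58) and otherwise aligns by
#' frequency; `"drop"` always drops palindromic SNPs. Unresolvable allele
#' pairs are dropped with a reason.
#'
#' @param exposures A [summary_table] or list of them (the first defines
#'   the reference alleles).
#' @param outcome A [summary_table] for the outcome trait.
#' @param palindrome_policy `"frequency"` or `"drop"`.
#' @param ambiguity_band Frequency window around 0.5 inside which a
#'   palindromic SNP is considered ambiguous under the `"frequency"`
#'   policy.
#' @return An object of class `harmonized_set`: list with `snp_ids`,
#'   `exposure_names`, `bx`/`sx`/`eafx` (J x K matrices), `by`/`sy`/`eafy`
#'   vectors, `outcome_name`, trait types and `dropped` (data.frame of
#'   snp/reason).
#' @export
harmonize <- function(exposures, outcome,
                      palindrome_policy = c("frequency", "drop"),
                      ambiguity_band = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (inherits(exposures, "summary_table")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1L, inherits(outcome, "summary_table"))
  for (e in exposures) stopifnot(inherits(e, "summary_table"))

  tables <- c(exposures, list(outcome))
  shared <- Reduce(intersect, lapply(tables, function(t) t$snp))
  if (length(shared) == 0L)
    stop("no shared SNPs between exposure(s) and outcome", call. = FALSE)
  ref <- exposures[[1L]]
  ref <- ref[match(shared, ref$snp), , drop = FALSE]

  K <- length(exposures)
  J0 <- length(shared)
  bx <- sx <- eafx <- matrix(NA_real_, J0, K)
  dropped_reason <- rep(NA_character_, J0)

  # align one table's rows (matched to `shared`) to the reference alleles;
  # returns list(beta, se, eaf) with NA reason vector updated by side effect
  align_one <- function(tab) {
    tab <- tab[match(shared, tab$snp), , drop = FALSE]
    beta <- tab$beta; se <- tab$se; eaf <- tab$eaf
    ea <- tab$effect_allele; oa <- tab$other_allele
    pal_ref <- .is_palindromic(ref$effect_allele, ref$other_allele)
    for (j in seq_len(J0)) {
      if (!is.na(dropped_reason[j])) next
      rea <- ref$effect_allele[j]; roa <- ref$other_allele[j]
      if (pal_ref[j]) {
        if (palindrome_policy == "drop") {
          dropped_reason[j] <<- "palindromic"
          next
        }
        ambiguous <- function(f) is.na(f) ||
          (f > 0.5 - ambiguity_band && f < 0.5 + ambiguity_band)
        if (!(ea[j] %in% c(rea, roa))) {
          dropped_reason[j] <<- "incompatible alleles"
          next
        }
        if (ambiguous(eaf[j]) || ambiguous(ref$eaf[j])) {
          dropped_reason[j] <<- "palindromic, ambiguous frequency"
          next
        }
        # strand is unresolvable: orient by frequency agreement
        same_allele <- ea[j] == rea
        f <- if (same_allele) eaf[j] else 1 - eaf[j]
        if (!same_allele) { beta[j] <- -beta[j]; eaf[j] <- 1 - eaf[j] }
        if (sign(f - 0.5) != sign(ref$eaf[j] - 0.5)) {
          beta[j] <- -beta[j]; eaf[j] <- 1 - eaf[j]
        }
        next
      }
      if (ea[j] == rea && oa[j] == roa) next
      if (ea[j] == roa && oa[j] == rea) {
        beta[j] <- -beta[j]; eaf[j] <- 1 - eaf[j]; next
      }
      cea <- .complement[ea[j]]; coa <- .complement[oa[j]]
      if (cea == rea && coa == roa) next
      if (cea == roa && coa == rea) {
        beta[j] <- -beta[j]; eaf[j] <- 1 - eaf[j]; next
      }
      dropped_reason[j] <<- "incompatible alleles"
    }
    list(beta = beta, se = se, eaf = eaf)
  }

  for (k in seq_len(K)) {
    al <- align_one(exposures[[k]])
    bx[, k] <- al$beta; sx[, k] <- al$se; eafx[, k] <- al$eaf
  }
  alo <- align_one(outcome)

  keep <- is.na(dropped_reason)
  if (!any(keep))
    stop("no SNPs survive harmonization", call. = FALSE)
  dropped <- data.frame(snp = shared[!keep],
                        reason = dropped_reason[!keep],
                        stringsAsFactors = FALSE)
  not_shared <- setdiff(unique(unlist(lapply(tables, function(t) t$snp))), shared)
  if (length(not_shared))
    dropped <- rbind(dropped, data.frame(snp = not_shared,
                                         reason = "not present in all tables",
                                         stringsAsFactors = FALSE))

  structure(list(
    snp_ids = shared[keep],
    exposure_names = vapply(exposures, attr, "", which = "trait_name"),
    exposure_types = vapply(exposures, attr, "", which = "trait_type"),
    outcome_name = attr(outcome, "trait_name"),
    outcome_type = attr(outcome, "trait_type"),
    bx = bx[keep, , drop = FALSE],
    sx = sx[keep, , drop = FALSE],
    eafx = eafx[keep, , drop = FALSE],
    by = alo$beta[keep],
    sy = alo$se[keep],
    eafy = alo$eaf[keep],
    dropped = dropped
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d SNPs, exposure(s) [%s] -> outcome '%s'\n",
              length(x$snp_ids), paste(x$exposure_names, collapse = ", "),
              x$outcome_name))
  if (nrow(x$dropped))
    cat(sprintf("  %d SNPs dropped during harmonization\n", nrow(x$dropped)))
  invisible(x)
}

# internal: validate a K=1 harmonized set and return plain vectors
.univariable <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (ncol(h$bx) != 1L)
    stop("this estimator requires a single exposure (K = 1)", call. = FALSE)
  list(bx = h$bx[, 1L], sx = h$sx[, 1L], by = h$by, sy = h$sy,
       snp = h$snp_ids)
}
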