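#' Select genome-wide significant variants
#'
#' Keeps records with `pval` strictly below `p_threshold` (the conventional
#' genome-wide threshold is 5e-8), preserving input order.
#'
#' @param table A [summary_table].
#' @param p_threshold Significance threshold in (0, 1).
#' @return A [summary_table] with the passing subset.
#' @export
select_genomewide <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "summary_table"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold >= 1)
    stop("`p_threshold` must be in (0, 1)", call. = FALSE)
  keep <- table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_name", "trait_type", "rejected")] <-
    attributes(table)[c("trait_name", "trait_type", "rejected")]
  class(out) <- class(table)
  out
}

#' Construct an LD matrix
#'
#' @param r2 Square symmetric matrix of pairwise r-squared values in
#'   \[0, 1\] with unit diagonal.
#' @param snp_ids Variant identifiers for rows/columns (defaults to
#'   dimnames of `r2`).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("`snp_ids` required when r2 has no dimnames",
                             call. = FALSE)
  stopifnot(nrow(r2) == ncol(r2), length(snp_ids) == nrow(r2))
  if (max(abs(r2 - t(r2))) > 1e-12) stop("LD matrix is not symmetric",
                                         call. = FALSE)
  if (any(diag(r2) != 1)) stop("LD matrix diagonal must be exactly 1",
                               call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("LD r2 values must lie in [0, 1]",
                                 call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read / write an LD matrix as TSV
#'
#' File layout: first row and first column carry the SNP identifiers, the
#' body holds the r-squared values.
#'
#' @param path File path.
#' @return [read_ld_matrix()] returns an `ld_matrix`; [write_ld_matrix()]
#'   returns `path` invisibly.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  ld_matrix(as.matrix(raw), snp_ids = rownames(raw))
}

#' @rdname read_ld_matrix
#' @param ld An `ld_matrix`.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- cbind(SNP = rownames(ld), as.data.frame(unclass(ld)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p remaining SNP as the index variant and
#' removes every remaining SNP with r-squared at or above `r2_threshold`
#' with it, so that the retained set is pairwise below the threshold.
#' Equal p-values are broken by lexicographic SNP id for determinism.
#'
#' @param table A [summary_table].
#' @param ld An [ld_matrix] covering the table's SNPs.
#' @param r2_threshold Removal threshold; SNPs with r2 >= threshold to an
#'   index variant are pruned (so the kept set satisfies r2 < threshold).
#' @param assume_independent If `TRUE`, SNPs absent from the LD matrix are
#'   treated as unlinked (r2 = 0 with everything) and logged; otherwise
#'   their absence is an error.
#' @return An `instrument_report`: list with `kept` (snp ids), `removed`
#'   (data.frame snp/reason) and `table` (the clumped [summary_table]).
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.001,
                     assume_independent = FALSE) {
  stopifnot(inherits(table, "summary_table"), inherits(ld, "ld_matrix"))
  ids <- table$snp
  absent <- setdiff(ids, rownames(ld))
  if (length(absent) && !assume_independent)
    stop("SNP(s) absent from LD matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "),
         " (set assume_independent = TRUE to treat as unlinked)",
         call. = FALSE)
  removed <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (length(absent))
    message(length(absent), " SNP(s) absent from LD matrix assumed independent")

  r2 <- function(a, b) {
    if (a %in% rownames(ld) && b %in% rownames(ld)) unclass(ld)[a, b] else 0
  }
  remaining <- ids[order(table$pval[match(ids, table$snp)], ids)]
  kept <- character(0)
  while (length(remaining)) {
    idx <- remaining[1L]
    kept <- c(kept, idx)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    linked <- vapply(remaining, function(s) r2(idx, s) >= r2_threshold, logical(1))
    if (any(linked)) {
      removed <- rbind(removed, data.frame(
        snp = remaining[linked],
        reason = sprintf("r2 >= %g with index %s", r2_threshold, idx),
        stringsAsFactors = FALSE))
      remaining <- remaining[!linked]
    }
  }
  out_tab <- table[table$snp %in% kept, , drop = FALSE]
  rownames(out_tab) <- NULL
  attributes(out_tab)[c("trait_name", "trait_type", "rejected")] <-
    attributes(table)[c("trait_name", "trait_type", "rejected")]
  class(out_tab) <- class(table)
  structure(list(kept = out_tab$snp, removed = removed, table = out_tab),
            class = "instrument_report")
}

#' Per-SNP instrument-strength F-statistics
#'
#' Uses the single-SNP summary-level approximation F = (beta / se)^2. An
#' F above 10 is the conventional bar for a non-weak instrument.
#'
#' @param table A [summary_table].
#' @param min_f Weak-instrument threshold (default 10).
#' @param enforce If `TRUE`, SNPs with F <= `min_f` are removed from the
#'   returned table; otherwise they are only flagged.
#' @return An `instrument_report` with `f_stats` (named per-SNP F values),
#'   `min_f` (smallest F among kept), `kept`, `removed` and `table`.
#' @export
f_statistics <- function(table, min_f = 10, enforce = FALSE) {
  stopifnot(inherits(table, "summary_table"))
  f <- (table$beta / table$se)^2
  names(f) <- table$snp
  weak <- f <= min_f
  removed <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  out_tab <- table
  if (enforce && any(weak)) {
    removed <- data.frame(snp = table$snp[weak], reason = "weak instrument",
                          stringsAsFactors = FALSE)
    out_tab <- table[!weak, , drop = FALSE]
    rownames(out_tab) <- NULL
    attributes(out_tab)[c("trait_name", "trait_type", "rejected")] <-
      attributes(table)[c("trait_name", "trait_type", "rejected")]
    class(out_tab) <- class(table)
  }
  kept <- out_tab$snp
  structure(list(kept = kept, removed = removed,
                 f_stats = f, weak = names(f)[weak],
                 min_f = if (length(kept)) min(f[kept]) else NA_real_,
                 table = out_tab),
            class = "instrument_report")
}

#' @export
print.instrument_report <- function(x, ...) {
  cat(sprintf("Instrument report: %d kept, %d removed",
              length(x$kept), nrow(x$removed)))
  if (!is.null(x$min_f)) cat(sprintf(", min F = %.2f", x$min_f))
  cat("\n")
  invisible(x)
}
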