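#' Bonferroni-corrected significance threshold for a mediator family
#'
#' Mediators drawn from the same data source form a testing family; the
#' family-wise threshold is 0.05 divided by the family size (0.025 for a
#' 2-trait family, 0.017 for a 3-trait family, and so on).
#'
#' @param family_size Number of traits in the family (>= 1).
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(family_size) {
  if (!is.numeric(family_size) || length(family_size) != 1L ||
      family_size < 1 || family_size != round(family_size))
    stop("`family_size` must be a positive integer", call. = FALSE)
  0.05 / family_size
}

# round half up at `digits`, the convention used in report tables
.round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# restrict a summary table to a set of snp ids
.subset_table <- function(table, ids) {
  out <- table[table$snp %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_name", "trait_type", "rejected")] <-
    attributes(table)[c("trait_name", "trait_type", "rejected")]
  class(out) <- class(table)
  out
}

# Table-style serialization of a univariable sensitivity battery
.battery_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    base <- data.frame(Analysis = switch(f$method,
                                         ivw_random = ,
                                         ivw_fixed = "Inverse variance weighted",
                                         egger = "MR Egger",
                                         simple_median = "Simple median",
                                         weighted_median = "Weighted median",
                                         wald = "Wald ratio"),
                       Nsnp = f$nsnp,
                       Effect = .round_half_up(f$beta, 2),
                       Se = .round_half_up(f$se, 2),
                       P.value = signif(f$pval, 3),
                       OR = .round_half_up(f$or_, 2),
                       stringsAsFactors = FALSE)
    if (!is.null(f$egger_intercept))
      base <- rbind(base, data.frame(
        Analysis = "MR Egger intercept", Nsnp = NA_integer_,
        Effect = .round_half_up(f$egger_intercept, 2),
        Se = .round_half_up(f$egger_intercept_se, 2),
        P.value = signif(f$egger_intercept_p, 3), OR = NA_real_,
        stringsAsFactors = FALSE))
    base
  })
  do.call(rbind, rows)
}

#' Run the full two-step mediation workflow
#'
#' Orchestrates, for one exposure, a set of candidate mediators and one or
#' more outcomes:
#' 1. instrument selection for the exposure (genome-wide significance,
#'    optional LD clumping, F-statistics);
#' 2. total effects: univariable IVW of the exposure on each outcome with
#'    the full sensitivity battery (MR-Egger, simple and weighted median,
#'    MR-PRESSO, single-SNP, leave-one-out);
#' 3. step 1: IVW of the exposure on each mediator; mediators whose step-1
#'    p-value is not below `suggestive_p` are excluded, and Bonferroni
#'    significance is annotated per mediator family;
#' 4. step 2: multivariable MR of (mediator, exposure) on each outcome
#'    over the union of both traits' instruments; mediators failing
#'    p < `suggestive_p` are excluded, and fits with too few instruments
#'    (J <= K) are recorded as failures;
#' 5. mediation: per-mediator product-method results and the
#'    difference-method combined mediation over all eligible mediators,
#'    per outcome.
#'
#' All rounding happens only at serialization. With fixed seeds the run is
#' fully deterministic.
#'
#' @param exposure A [summary_table] for the exposure.
#' @param mediators Named list of [summary_table]s for candidate
#'   mediators.
#' @param outcomes Named list of [summary_table]s for outcomes.
#' @param ld Optional [ld_matrix] for clumping.
#' @param families Optional named integer/character vector assigning each
#'   mediator a family id for Bonferroni annotation; mediators sharing an
#'   id form one family. Default: each mediator its own family.
#' @param p_instrument Genome-wide significance threshold (default 5e-8).
#' @param clump_r2 LD clumping threshold (default 0.001).
#' @param suggestive_p Eligibility gate applied at step 1 and step 2
#'   (default 0.05).
#' @param presso_nsim,presso_seed MR-PRESSO simulation settings.
#' @param median_seed Seed for the median bootstrap SEs.
#' @param output_dir Optional directory; when given, report tables are
#'   written there as TSV.
#' @return An object of class `two_step_report`: list with
#'   `instruments` (exposure instrument report), `total_effects` (per
#'   outcome: list of fitted `mr_result`s, a `presso_result` and the
#'   serialized sensitivity table), `step1` (data.frame), `step2` (per
#'   outcome data.frame), `mediation` (per outcome data.frame with a
#'   combined row), `log` (instrument bookkeeping).
#' @export
run_two_step <- function(exposure, mediators, outcomes, ld = NULL,
                         families = NULL,
                         p_instrument = 5e-8, clump_r2 = 0.001,
                         suggestive_p = 0.05,
                         presso_nsim = 1000L, presso_seed = 1L,
                         median_seed = 1L, output_dir = NULL) {
  stopifnot(inherits(exposure, "summary_table"),
            is.list(mediators), length(mediators) >= 1L,
            is.list(outcomes), length(outcomes) >= 1L)
  if (is.null(names(mediators)) || any(!nzchar(names(mediators))))
    stop("`mediators` must be a named list", call. = FALSE)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("`outcomes` must be a named list", call. = FALSE)
  if (is.null(families))
    families <- stats::setNames(names(mediators), names(mediators))
  fam_size <- table(unlist(families[names(mediators)]))
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- exposure instrument selection -------------------------------------
  sel <- select_genomewide(exposure, p_instrument)
  note("exposure '%s': %d of %d SNPs at p < %g",
       attr(exposure, "trait_name"), nrow(sel), nrow(exposure), p_instrument)
  if (nrow(sel) == 0L)
    stop("no genome-wide significant instruments for the exposure",
         call. = FALSE)
  if (!is.null(ld)) {
    cl <- ld_clump(sel, ld, r2_threshold = clump_r2, assume_independent = TRUE)
    sel <- cl$table
    note("clumping at r2 < %g: %d kept, %d removed",
         clump_r2, length(cl$kept), nrow(cl$removed))
  }
  fstat <- f_statistics(sel)
  if (length(fstat$weak))
    note("weak instruments flagged (F <= 10): %s",
         paste(fstat$weak, collapse = ", "))

  select_instruments <- function(tab) {
    s <- select_genomewide(tab, p_instrument)
    if (!is.null(ld) && nrow(s) > 0L)
      s <- ld_clump(s, ld, r2_threshold = clump_r2,
                    assume_independent = TRUE)$table
    s
  }

  # --- total effects with sensitivity battery ----------------------------
  total_effects <- list()
  for (oname in names(outcomes)) {
    h <- harmonize(sel, outcomes[[oname]])
    note("total effect %s -> %s: %d SNPs harmonized, %d dropped",
         attr(exposure, "trait_name"), oname, length(h$snp_ids),
         nrow(h$dropped))
    fits <- list(simple_median = mr_simple_median(h, seed = median_seed),
                 weighted_median = mr_weighted_median(h, seed = median_seed),
                 egger = mr_egger(h),
                 ivw = mr_ivw(h))
    pres <- mr_presso(h, nsim = presso_nsim, seed = presso_seed)
    total_effects[[oname]] <- list(
      fits = fits, presso = pres,
      single_snp = single_snp_analysis(h),
      leave_one_out = leave_one_out(h),
      table = .battery_table(fits))
  }

  # --- step 1: exposure -> mediators -------------------------------------
  step1_rows <- lapply(names(mediators), function(mname) {
    h <- harmonize(sel, mediators[[mname]])
    fit <- mr_ivw(h)
    fam <- unlist(families)[mname]
    thr <- bonferroni_threshold(as.integer(fam_size[[fam]]))
    data.frame(mediator = mname, nsnp = fit$nsnp, a = fit$beta,
               se_a = fit$se, p_a = fit$pval,
               family = fam, bonferroni_p = thr,
               bonferroni_significant = fit$pval < thr,
               eligible = fit$pval < suggestive_p,
               stringsAsFactors = FALSE)
  })
  step1 <- do.call(rbind, step1_rows)
  for (i in seq_len(nrow(step1)))
    if (!step1$eligible[i])
      note("mediator '%s' excluded at step 1 (p = %.3g >= %g)",
           step1$mediator[i], step1$p_a[i], suggestive_p)

  # --- step 2: (mediator, exposure) -> outcomes by MVMR ------------------
  step2 <- list()
  for (oname in names(outcomes)) {
    rows <- lapply(names(mediators), function(mname) {
      row <- data.frame(mediator = mname, outcome = oname,
                        nsnp = NA_integer_, b = NA_real_, se_b = NA_real_,
                        p_b = NA_real_, failed = FALSE,
                        failure_reason = NA_character_,
                        eligible = FALSE, stringsAsFactors = FALSE)
      if (!step1$eligible[step1$mediator == mname]) {
        row$failure_reason <- "excluded at step 1"
        return(row)
      }
      med_sel <- select_instruments(mediators[[mname]])
      union_ids <- union(sel$snp, med_sel$snp)
      fit <- tryCatch({
        h2 <- harmonize(list(.subset_table(mediators[[mname]], union_ids),
                             .subset_table(exposure, union_ids)),
                        .subset_table(outcomes[[oname]], union_ids))
        mvmr_ivw(h2)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        row$failed <- TRUE
        row$failure_reason <- conditionMessage(fit)
        note("MVMR %s + exposure -> %s failed: %s", mname, oname,
             conditionMessage(fit))
        return(row)
      }
      cf <- mvmr_coef(fit, attr(mediators[[mname]], "trait_name"))
      row$nsnp <- fit$nsnp; row$b <- cf$beta; row$se_b <- cf$se
      row$p_b <- cf$pval
      row$eligible <- cf$pval < suggestive_p
      if (!row$eligible)
        note("mediator '%s' excluded at step 2 for outcome '%s' (p = %.3g)",
             mname, oname, cf$pval)
      row
    })
    step2[[oname]] <- do.call(rbind, rows)
  }

  # --- mediation: product method per mediator, difference method combined -
  mediation <- list()
  for (oname in names(outcomes)) {
    tot <- total_effects[[oname]]$fits$ivw
    s2 <- step2[[oname]]
    med_rows <- lapply(names(mediators), function(mname) {
      r1 <- step1[step1$mediator == mname, ]
      r2 <- s2[s2$mediator == mname, ]
      mr <- mediation_result(mname,
                             a = r1$a, se_a = r1$se_a, p_a = r1$p_a,
                             b = r2$b, se_b = r2$se_b, p_b = r2$p_b,
                             total = tot$beta, se_total = tot$se,
                             gate_p = suggestive_p)
      data.frame(mediator = mname, outcome = oname,
                 a = mr$a, se_a = mr$se_a, b = mr$b, se_b = mr$se_b,
                 indirect = mr$indirect, se_indirect = mr$se_indirect,
                 total = mr$total, se_total = mr$se_total,
                 proportion = mr$proportion, se_prop = mr$se_prop,
                 ci_low = mr$ci_low, ci_high = mr$ci_high,
                 percent = mr$percent, flag = mr$flag,
                 stringsAsFactors = FALSE)
    })
    med_df <- do.call(rbind, med_rows)

    eligible <- med_df$mediator[med_df$flag %in% c("ok", "inconsistent")]
    combined_row <- data.frame(
      mediator = "combined", outcome = oname, a = NA_real_, se_a = NA_real_,
      b = NA_real_, se_b = NA_real_, indirect = NA_real_,
      se_indirect = NA_real_, total = tot$beta, se_total = tot$se,
      proportion = NA_real_, se_prop = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, percent = NA_real_, flag = "no eligible mediators",
      stringsAsFactors = FALSE)
    if (length(eligible)) {
      union_ids <- Reduce(union, c(list(sel$snp),
                                   lapply(mediators[eligible],
                                          function(m) select_instruments(m)$snp)))
      fit_all <- tryCatch({
        h_all <- harmonize(c(list(.subset_table(exposure, union_ids)),
                             lapply(mediators[eligible], .subset_table,
                                    ids = union_ids)),
                           .subset_table(outcomes[[oname]], union_ids))
        mvmr_ivw(h_all)
      }, error = function(e) e)
      if (!inherits(fit_all, "error")) {
        cf <- mvmr_coef(fit_all, attr(exposure, "trait_name"))
        cm <- combined_mediation(tot$beta, tot$se, cf$beta, cf$se)
        combined_row$indirect <- cm$combined_indirect
        combined_row$se_indirect <- cm$se_indirect
        combined_row$proportion <- cm$proportion
        combined_row$se_prop <- cm$se_prop
        combined_row$ci_low <- cm$ci_low; combined_row$ci_high <- cm$ci_high
        combined_row$percent <- cm$percent
        combined_row$flag <- "ok"
      } else {
        combined_row$flag <- paste("failed:", conditionMessage(fit_all))
        note("combined MVMR for outcome '%s' failed: %s", oname,
             conditionMessage(fit_all))
      }
    }
    mediation[[oname]] <- rbind(med_df, combined_row)
  }

  report <- structure(list(instruments = fstat,
                           total_effects = total_effects,
                           step1 = step1, step2 = step2,
                           mediation = mediation, log = log_lines),
                      class = "two_step_report")
  if (!is.null(output_dir)) write_two_step_report(report, output_dir)
  report
}

#' Serialize a two-step report to TSV tables
#'
#' Writes, per outcome, the sensitivity battery (`sensitivity_<outcome>.tsv`,
#' effects and ORs rounded to 2 decimals), the step-2 table
#' (`step2_<outcome>.tsv`) and the mediation table
#' (`mediation_<outcome>.tsv`, percentages rounded half-up to whole
#' percent), plus `step1.tsv` and `log.txt`.
#'
#' @param report A `two_step_report`.
#' @param output_dir Directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_two_step_report <- function(report, output_dir) {
  stopifnot(inherits(report, "two_step_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file)
    utils::write.table(df, file.path(output_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
  s1 <- report$step1
  s1$a <- .round_half_up(s1$a, 2); s1$se_a <- .round_half_up(s1$se_a, 2)
  wt(s1, "step1.tsv")
  for (oname in names(report$total_effects)) {
    wt(report$total_effects[[oname]]$table,
       sprintf("sensitivity_%s.tsv", oname))
    s2 <- report$step2[[oname]]
    s2$b <- .round_half_up(s2$b, 2); s2$se_b <- .round_half_up(s2$se_b, 2)
    wt(s2, sprintf("step2_%s.tsv", oname))
    md <- report$mediation[[oname]]
    out <- data.frame(mediator = md$mediator,
                      percent = .round_half_up(md$percent, 0),
                      ci_low_pct = .round_half_up(100 * md$ci_low, 0),
                      ci_high_pct = .round_half_up(100 * md$ci_high, 0),
                      flag = md$flag, stringsAsFactors = FALSE)
    wt(out, sprintf("mediation_%s.tsv", oname))
  }
  writeLines(report$log, file.path(output_dir, "log.txt"))
  invisible(output_dir)
}

#' @export
print.two_step_report <- function(x, ...) {
  cat("Two-step MR mediation report\n")
  cat(sprintf("  %d exposure instruments (min F = %.1f)\n",
              length(x$instruments$kept), x$instruments$min_f))
  for (oname in names(x$mediation)) {
    cat(sprintf("  outcome '%s':\n", oname))
    md <- x$mediation[[oname]]
    for (i in seq_len(nrow(md))) {
      if (md$flag[i] %in% c("ok", "inconsistent"))
        cat(sprintf("    %-10s %5.1f%% [%5.1f%%, %5.1f%%]\n", md$mediator[i],
                    md$percent[i], 100 * md$ci_low[i], 100 * md$ci_high[i]))
      else
        cat(sprintf("    %-10s (%s)\n", md$mediator[i], md$flag[i]))
    }
  }
  invisible(x)
}

#' Recompute mediation proportions from published point estimates
#'
#' A worked example on reference estimates from a published two-sample MR
#' mediation study of type 2 diabetes and cardiovascular disease, shipped
#' as a plain-text fixture. For each mediator-outcome pair the fixture
#' carries the step-1 effect of diabetes liability on the mediator (SD per
#' log-odds, with 95% CI), the multivariable-MR odds ratio of the outcome
#' per SD of mediator adjusted for diabetes, and the total-effect odds
#' ratio of diabetes on the outcome. The function converts odds ratios to
#' log-odds, rebuilds the product-method indirect effect and the
#' proportion mediated with delta-method SEs (input SEs recovered from the
#' printed CIs as width / (2 x 1.96)), and reports the computed percentage
#' next to the published one.
#'
#' @param path Fixture path; defaults to the packaged table.
#' @return data.frame with one row per mediator-outcome pair: `mediator`,
#'   `outcome`, `indirect`, `se_indirect`, `percent`, `ci_low_pct`,
#'   `ci_high_pct`, `printed_pct`.
#' @export
worked_example_report <- function(path = system.file(
  "extdata", "reported_t2dm_cvd_estimates.tsv", package = "mrmediate")) {
  fx <- utils::read.delim(path, stringsAsFactors = FALSE)
  z <- stats::qnorm(0.975)
  rows <- lapply(seq_len(nrow(fx)), function(i) {
    r <- fx[i, ]
    a <- r$a; se_a <- (r$a_hi - r$a_lo) / (2 * z)
    b <- log(r$step2_or); se_b <- (log(r$step2_hi) - log(r$step2_lo)) / (2 * z)
    total <- log(r$total_or)
    se_total <- (log(r$total_hi) - log(r$total_lo)) / (2 * z)
    ie <- indirect_effect(a, se_a, b, se_b)
    pm <- suppressWarnings(
      proportion_mediated(ie$indirect, ie$se, total, se_total))
    data.frame(mediator = r$mediator, outcome = r$outcome,
               indirect = ie$indirect, se_indirect = ie$se,
               percent = pm$percent,
               ci_low_pct = 100 * pm$ci_low, ci_high_pct = 100 * pm$ci_high,
               printed_pct = r$printed_pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
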