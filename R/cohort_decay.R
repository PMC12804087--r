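# Cohort-level bookkeeping around the drift null: driver-specific tumour
# numbers, remaining proportions under rescue protocols, chi-squared decay
# tests against neutral expectations, fold changes, clonality classification,
# and the small closed-form summaries (percent reduction, clone width,
# cellularity).

#' Summarise one cohort/protocol
#'
#' @param label Cohort label (priming genotype).
#' @param protocol `"TE"` (priming: field induced before mutagenesis),
#'   `"ET10"` or `"ET30"` (rescue: field induced 10 or 30 days after
#'   mutagenesis).
#' @param mean_count Mean tumour count per mouse (small intestine or region).
#' @param sd_count Count standard deviation (optional).
#' @param proportions Named per-driver-class proportions from sequencing
#'   (each in \[0,1\], summing to <= 1).
#' @return A `cohort_summary` list.
#' @export
cohort_summary <- function(label, protocol = c("TE", "ET10", "ET30"),
                           mean_count, sd_count = NA_real_, proportions) {
  protocol <- match.arg(protocol)
  stopifnot(mean_count >= 0, !is.null(names(proportions)),
            all(proportions >= 0), all(proportions <= 1),
            sum(proportions) <= 1 + 1e-8)
  structure(list(label = label, protocol = protocol, mean_count = mean_count,
                 sd_count = sd_count, proportions = proportions),
            class = "cohort_summary")
}

#' Driver-specific tumour numbers
#'
#' Multiplies each driver class's sequencing-derived proportion by the mean
#' tumour count of the cohort.
#'
#' @param summary A `cohort_summary`.
#' @return Named per-class tumour numbers.
#' @export
driver_counts <- function(summary) {
  summary$proportions * summary$mean_count
}

#' Remaining proportion of a driver class under rescue
#'
#' Driver-specific tumour number in the rescue cohort divided by the same
#' quantity in the priming (TE) baseline. Scale-invariant in the two means.
#'
#' @param te Priming-baseline `cohort_summary`.
#' @param et Rescue `cohort_summary`.
#' @param driver Driver class name.
#' @return Proportion remaining (NA with a warning if the baseline is zero).
#' @export
remaining_proportion <- function(te, et, driver) {
  base <- driver_counts(te)[[driver]]
  if (is.na(base) || base == 0) {
    warning(sprintf("zero priming baseline for driver '%s'", driver))
    return(NA_real_)
  }
  driver_counts(et)[[driver]] / base
}

#' Chi-squared test of observed decay against the neutral null
#'
#' Compares the observed number of tumours remaining at a rescue timepoint
#' with the count expected under neutral drift (neutral surviving fraction
#' times the priming baseline), using two categories (remaining, lost) so the
#' expected counts sum to the baseline; 1 d.f., two-sided.
#'
#' @param observed Observed tumour count remaining.
#' @param baseline Tumour count in the priming (TE) protocol.
#' @param neutral_fraction Neutral surviving fraction at the rescue day (from
#'   [neutral_fraction_at()]).
#' @return List `chi2`, `p`, `observed`, `expected`.
#' @export
decay_test <- function(observed, baseline, neutral_fraction) {
  stopifnot(baseline > 0, observed >= 0)
  E <- neutral_fraction * baseline
  if (E <= 0) stop("expected remaining count is zero", call. = FALSE)
  if (E >= baseline) {
    if (neutral_fraction > 1) stop("neutral fraction above 1", call. = FALSE)
    # degenerate: neutral null predicts no loss at all
    chi2 <- if (observed == baseline) 0 else Inf
  } else {
    chi2 <- (observed - E)^2 / E +
      ((baseline - observed) - (baseline - E))^2 / (baseline - E)
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = observed, expected = E)
}

#' Fold change in driver-specific tumour numbers versus a control cohort
#'
#' @param cohort,control `cohort_summary` objects.
#' @param driver Driver class name.
#' @return Fold change (cohort / control).
#' @export
fold_change_vs_control <- function(cohort, control, driver) {
  base <- driver_counts(control)[[driver]]
  if (is.na(base) || base <= 0) {
    stop(sprintf("control cohort has no '%s'-driven tumours", driver),
         call. = FALSE)
  }
  driver_counts(cohort)[[driver]] / base
}

#' Percent reduction in tumour multiplicity under rescue
#'
#' `100 * (1 - rescued/primed)`, rounded to the nearest integer percent, or to
#' the nearest ten when `nearest = "ten"`.
#'
#' @param rescued_mean,primed_mean Mean tumour counts.
#' @param nearest `"one"` (default) or `"ten"`.
#' @return Percentage.
#' @export
percent_reduction <- function(rescued_mean, primed_mean,
                              nearest = c("one", "ten")) {
  nearest <- match.arg(nearest)
  stopifnot(primed_mean > 0, rescued_mean >= 0)
  pct <- 100 * (1 - rescued_mean / primed_mean)
  if (nearest == "ten") round(pct / 10) * 10 else round(pct)
}

#' Classify tumour clonality from its driver mutations
#'
#' A tumour is monoclonal when driven by one clone: one or two APC-truncating
#' mutations (and no beta-catenin exon-3 mutation), or exactly one beta-catenin
#' exon-3 mutation (and no APC truncation). Anything more is polyclonal; a
#' tumour with no drivers is undetermined. Vectorised over tumours.
#'
#' @param n_apc_truncating Count of APC-truncating mutations per tumour.
#' @param n_ctnnb1_exon3 Count of beta-catenin exon-3 driver mutations.
#' @return `"monoclonal"`, `"polyclonal"` or `"undetermined"`.
#' @export
classify_clonality <- function(n_apc_truncating, n_ctnnb1_exon3) {
  stopifnot(length(n_apc_truncating) == length(n_ctnnb1_exon3))
  a <- n_apc_truncating; b <- n_ctnnb1_exon3
  ifelse(a == 0 & b == 0, "undetermined",
  ifelse((a >= 1 & a <= 2 & b == 0) | (b == 1 & a == 0),
         "monoclonal", "polyclonal"))
}

#' Mean clone width in crypt-circumference eighths
#'
#' The lineage-tracing summary: each clone occupies 1-8 eighths of the crypt
#' circumference; the mean width is the size-weighted count divided by the
#' total number of clones.
#'
#' @param counts Named counts per clone size (names "1".."8").
#' @return Mean width in eighths.
#' @export
clone_width <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("no clones counted", call. = FALSE)
  }
  sizes <- as.numeric(names(counts))
  stopifnot(all(sizes %in% 1:8))
  sum(counts * sizes) / sum(counts)
}

#' Tumour cellularity from variant allele frequencies
#'
#' The copy-number pipeline's closed-form estimate: twice the average VAF,
#' capped at 1.
#'
#' @param vafs VAFs in \[0,1\].
#' @return Cellularity estimate in \[0,1\].
#' @export
cellularity <- function(vafs) {
  if (length(vafs) == 0L) stop("no VAFs supplied", call. = FALSE)
  stopifnot(all(vafs >= 0), all(vafs <= 1))
  min(1, 2 * mean(vafs))
}
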