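# Human colorectal arm: registry-style sample filtering, KRAS-stratified
# 20-amino-acid-repeat retention, VAF-based APC/KRAS mutation chronology, and
# the expected stop-codon profile from a colon trinucleotide signature.

#' Filter a registry-style sample table
#'
#' Removes samples carrying more than two driver mutations in the ten-gene
#' exclusion set (ATM, ARID1A, AMER1, BRAF, FBXW7, PTEN, PIK3CA, SMAD4, SOX9,
#' TCF7L2 - counted upstream into `n_other_drivers`) and samples with more
#' than two APC mutations. Idempotent and order-independent.
#'
#' @param samples Data frame with one row per sample (one sample per donor)
#'   and columns `n_other_drivers` and `n_apc`.
#' @return List with `samples` (retained rows) and `exclusions` (named counts
#'   per rule; a sample failing the driver rule is not also counted against
#'   the APC rule).
#' @export
registry_filter <- function(samples) {
  stopifnot(all(c("n_other_drivers", "n_apc") %in% names(samples)))
  drv <- samples$n_other_drivers > 2
  apc <- !drv & samples$n_apc > 2
  out <- samples[!(drv | apc), , drop = FALSE]
  rownames(out) <- NULL
  list(samples = out,
       exclusions = c(driver_excess = sum(drv), apc_excess = sum(apc)))
}

#' KRAS-stratified 20-amino-acid-repeat retention distribution
#'
#' Scores every sample with [sample_retention()] (most C-terminal mutation for
#' double-hit samples), tabulates the percentage of samples at each score 0-7
#' per KRAS stratum, and compares the strata at each score with two-sided
#' Fisher exact tests.
#'
#' @param samples Data frame with columns `apc1_residue`, `apc2_residue`
#'   (`NA` for single-hit samples) and logical `kras_mut`.
#' @param repeats A `repeat_annotation`.
#' @return List with `percent` (data frame score x stratum percentages,
#'   summing to 100 per stratum), `counts`, and `tests` (per-score Fisher
#'   p-values; `NA` where a stratum is empty, flagged).
#' @export
retention_by_kras <- function(samples, repeats = default_apc_repeats()) {
  stopifnot(all(c("apc1_residue", "kras_mut") %in% names(samples)))
  if (!"apc2_residue" %in% names(samples)) samples$apc2_residue <- NA_integer_
  score <- mapply(function(a, b) sample_retention(c(a, b), repeats),
                  samples$apc1_residue, samples$apc2_residue)
  stratum <- ifelse(samples$kras_mut, "KRAS-mutant", "KRAS-WT")
  keep <- !is.na(score)
  score <- score[keep]; stratum <- stratum[keep]
  strata <- c("KRAS-WT", "KRAS-mutant")
  counts <- table(factor(score, levels = 0:7),
                  factor(stratum, levels = strata))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("empty stratum: %s",
                    paste(strata[totals == 0], collapse = ", ")))
  }
  percent <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  tests <- vapply(0:7, function(s) {
    a <- counts[as.character(s), "KRAS-mutant"]; A <- totals["KRAS-mutant"]
    b <- counts[as.character(s), "KRAS-WT"]; B <- totals["KRAS-WT"]
    if (A == 0 || B == 0) return(NA_real_)
    stats::fisher.test(matrix(c(a, A - a, b, B - b), nrow = 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  list(percent = as.data.frame.matrix(percent),
       counts = as.data.frame.matrix(counts),
       tests = data.frame(score = 0:7, p = tests))
}

#' Halve the top-ranked APC VAF when it exceeds 0.5 (presumptive LOH)
#'
#' Mutations are ranked by VAF descending (ties broken toward the more
#' N-terminal mutation); if the rank-1 VAF is strictly above 0.5, it is
#' halved under the assumption that loss of heterozygosity doubled it. Other
#' mutations are unchanged.
#'
#' @param mutations Data frame with columns `vaf` and `residue`.
#' @return The data frame with an added `rank` column and adjusted `vaf`.
#' @export
halve_loh_vaf <- function(mutations) {
  stopifnot(all(c("vaf", "residue") %in% names(mutations)))
  o <- order(-mutations$vaf, mutations$residue)
  rank <- integer(nrow(mutations)); rank[o] <- seq_len(nrow(mutations))
  mutations$rank <- rank
  top <- which(rank == 1L)
  if (length(top) == 1L && !is.na(mutations$vaf[top]) &&
      mutations$vaf[top] > 0.5) {
    mutations$vaf[top] <- mutations$vaf[top] / 2
  }
  mutations
}

# Wilson score interval; the package's own closed form (tests cross-check it
# against an independent construction)
wilson_interval <- function(x, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  phat <- x / n
  den <- 1 + z^2 / n
  ctr <- (phat + z^2 / (2 * n)) / den
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

clopper_pearson_interval <- function(x, n, alpha = 0.05) {
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Order APC and KRAS mutations from their VAFs
#'
#' Builds (1 - alpha) binomial confidence intervals for both VAFs from alt
#' reads and depth. The verdict is APC-first when the APC interval lies
#' entirely above the KRAS interval, KRAS-first for the reverse, and
#' unresolved otherwise (or when a depth is missing). The APC VAF is expected
#' to be LOH-adjusted (see [halve_loh_vaf()]) before calling.
#'
#' @param apc_alt,apc_depth Alt reads and depth of the top-ranked APC mutation.
#' @param kras_alt,kras_depth Alt reads and depth of the KRAS mutation.
#' @param alpha Significance level (default 0.05: 95% confidence).
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A `chronology_call` list: `verdict` (`"APC-first"`, `"KRAS-first"`,
#'   `"unresolved"`), `confidence`, `vaf_ratio` (KRAS/APC), `apc_ci`,
#'   `kras_ci`, and `reason` when unresolved for a data reason.
#' @export
chronology_call <- function(apc_alt, apc_depth, kras_alt, kras_depth,
                            alpha = 0.05,
                            method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(is.na(c(apc_alt, apc_depth, kras_alt, kras_depth))) ||
      apc_depth <= 0 || kras_depth <= 0) {
    return(structure(list(verdict = "unresolved", confidence = 1 - alpha,
                          vaf_ratio = NA_real_, apc_ci = NULL, kras_ci = NULL,
                          reason = "missing read depth"),
                     class = "chronology_call"))
  }
  stopifnot(apc_alt >= 0, apc_alt <= apc_depth,
            kras_alt >= 0, kras_alt <= kras_depth)
  ci <- switch(method, wilson = wilson_interval,
               `clopper-pearson` = clopper_pearson_interval)
  apc_ci <- ci(apc_alt, apc_depth, alpha)
  kras_ci <- ci(kras_alt, kras_depth, alpha)
  verdict <- if (apc_ci["lower"] > kras_ci["upper"]) "APC-first"
             else if (kras_ci["lower"] > apc_ci["upper"]) "KRAS-first"
             else "unresolved"
  apc_vaf <- apc_alt / apc_depth
  structure(list(verdict = verdict, confidence = 1 - alpha,
                 vaf_ratio = if (apc_vaf > 0) (kras_alt / kras_depth) / apc_vaf
                             else NA_real_,
                 apc_ci = apc_ci, kras_ci = kras_ci, reason = NULL),
            class = "chronology_call")
}

#' Expected stop-codon profile along a protein
#'
#' For each residue up to `limit`, sums the signature frequencies of all
#' stop-generating SNVs in that codon, then normalises the profile to its
#' maximum (highest expected site = 1). Residues whose codon admits no
#' stop-gain SNV get 0.
#'
#' @param cds A `cds_fasta`.
#' @param sig A `trinuc_spectrum` (e.g. a normal-colon signature).
#' @param limit Most C-terminal residue to report (default: whole protein).
#' @return Data frame `residue`, `expected` (summed frequency),
#'   `expected_norm` (max = 1).
#' @export
expected_stop_profile <- function(cds, sig, limit = cds$protein_length) {
  stopifnot(limit >= 1, limit <= cds$protein_length)
  enum <- enumerate_snvs(cds)
  ns <- enum[enum$class == "nonsense" & !is.na(enum$channel) &
               enum$residue <= limit, , drop = FALSE]
  f <- signature_frequency(sig, ns$channel)
  expected <- vapply(seq_len(limit),
                     function(r) sum(f[ns$residue == r]), numeric(1))
  mx <- max(expected)
  if (mx <= 0) stop("no stop-generating signature mass below the limit",
                    call. = FALSE)
  data.frame(residue = seq_len(limit), expected = expected,
             expected_norm = expected / mx)
}
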