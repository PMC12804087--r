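# Observed/expected selection readout: O/E ratios per mutation class, bin or
# bin combination, with class-vs-rest chi-squared tests (1 d.f., no continuity
# correction), log2 fold changes and significance tiers. No multiple-testing
# correction is applied; each class is reported at alpha = 0.05 with */**/***
# tiers.

.sig_tier <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Observed/expected table for a set of mutation classes
#'
#' For each class the expected count is `probability * N` (N = total observed)
#' and the chi-squared statistic is the class-vs-rest goodness of fit with
#' 1 d.f.: `(O-E)^2/E + ((N-O)-(N-E))^2/(N-E)`. A class with zero expected
#' probability but non-zero observations has an undefined O/E and is flagged
#' (`zero_expected`); a class observed zero times is flagged `zero_observed`
#' with O/E 0.
#'
#' @param observed Named counts per class.
#' @param expected Named probabilities per class (summing to 1 over the union
#'   of classes; classes absent from `expected` get probability 0).
#' @return An `oe_table` data frame: `class`, `observed`, `expected_prob`,
#'   `expected_count`, `oe`, `log2_fc`, `chi2`, `p`, `signif`, `flag`.
#' @export
oe_table <- function(observed, expected) {
  stopifnot(!is.null(names(observed)), !is.null(names(expected)))
  classes <- union(names(observed), names(expected))
  O <- stats::setNames(numeric(length(classes)), classes)
  O[names(observed)] <- as.numeric(observed)
  p <- stats::setNames(numeric(length(classes)), classes)
  p[names(expected)] <- as.numeric(expected)
  if (any(p < 0)) stop("expected probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) {
    stop("expected probabilities must sum to 1", call. = FALSE)
  }
  N <- sum(O)
  if (N <= 0) stop("total observed count must be positive", call. = FALSE)
  E <- p * N
  oe <- ifelse(E > 0, O / E, NA_real_)
  chi2 <- ifelse(E > 0 & E < N,
                 (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E),
                 NA_real_)
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  flag <- ifelse(E == 0 & O > 0, "zero_expected",
          ifelse(O == 0, "zero_observed", ""))
  out <- data.frame(class = classes, observed = unname(O),
                    expected_prob = unname(p), expected_count = unname(E),
                    oe = unname(oe), log2_fc = log2_fc(unname(oe)),
                    chi2 = unname(chi2), p = unname(pval),
                    signif = .sig_tier(unname(pval)), flag = unname(flag),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("oe_table", "data.frame")
  out
}

#' Keep recurrent classes only
#'
#' Retains classes observed strictly more than `min_n` times (the "n > 9"
#' recurrence convention).
#'
#' @param observed Named counts.
#' @param min_n Strict lower bound (default 9).
#' @return Filtered named counts (possibly empty).
#' @export
recurrence_filter <- function(observed, min_n = 9) {
  stopifnot(min_n >= 0)
  observed[observed > min_n]
}

#' Two-sample proportion comparison
#'
#' Either a two-sided Fisher exact test or the two-sample test of equality of
#' proportions with continuity correction (1 d.f., two-sided).
#'
#' @param x1,n1 Successes and trials in sample 1.
#' @param x2,n2 Successes and trials in sample 2.
#' @param kind `"fisher"` or `"two-proportion"`.
#' @return List with `estimate` (the two sample proportions), `p.value`,
#'   `method`.
#' @export
proportion_test <- function(x1, n1, x2, n2,
                            kind = c("fisher", "two-proportion")) {
  kind <- match.arg(kind)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  est <- c(x1 / n1, x2 / n2)
  if (kind == "fisher") {
    ft <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2,
                                    byrow = TRUE), alternative = "two.sided")
    list(estimate = est, p.value = ft$p.value, method = "fisher")
  } else {
    pt <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE))
    list(estimate = est, p.value = pt$p.value, method = "two-proportion")
  }
}

#' Signed log2 fold change of an O/E ratio
#'
#' @param oe O/E ratios (numeric, or an `oe_table` whose `oe` column is used).
#' @return `log2(oe)`; an O/E of exactly 0 maps to `-Inf` (rendered as
#'   "depleted" in reports).
#' @export
log2_fc <- function(oe) {
  if (inherits(oe, "oe_table")) oe <- oe$oe
  ifelse(is.na(oe), NA_real_, ifelse(oe == 0, -Inf, log2(oe)))
}

#' Write an O/E table as TSV
#' @param x An `oe_table`.
#' @param path Output path.
#' @export
write_oe_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
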