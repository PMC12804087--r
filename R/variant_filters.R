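# Post-caller SNV filtering for the hybridization-capture and targeted-amplicon
# dialects. Every rule is a pure predicate over one row; the filter is their
# conjunction, so the outcome is independent of evaluation order and filtering
# is idempotent. A row lacking an optional support field skips only the rules
# that need it (logged); a column missing outright is a configuration error.

.need_cols <- function(x, cols, rule) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    stop(sprintf("cannot evaluate rule '%s': missing column(s) %s",
                 rule, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

# Apply a named list of per-row logical vectors (TRUE = pass, NA = rule not
# evaluable for that row -> skipped) as a conjunction.
.apply_rules <- function(x, rules) {
  n <- nrow(x)
  keep <- rep(TRUE, n)
  removed <- integer(length(rules)); names(removed) <- names(rules)
  skipped <- integer(length(rules)); names(skipped) <- names(rules)
  for (r in names(rules)) {
    p <- rules[[r]]
    skipped[r] <- sum(is.na(p))
    fail <- p %in% FALSE
    removed[r] <- sum(fail)
    keep <- keep & !fail
  }
  n_skip <- sum(skipped)
  if (n_skip > 0) {
    message(sprintf("skipped rule evaluations on rows lacking optional fields: %s",
                    paste(sprintf("%s (%d)", names(skipped)[skipped > 0],
                                  skipped[skipped > 0]), collapse = ", ")))
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dialect") <- attr(x, "dialect")
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- class(x)
  list(table = out,
       removals = data.frame(rule = names(removed), removed = unname(removed),
                             stringsAsFactors = FALSE),
       skipped = skipped,
       n_input = n, n_retained = nrow(out))
}

#' Filter hybridization-capture SNV calls
#'
#' Retains exactly the rows passing all of: (1) caller-internal filters;
#' (2) no known-SNP/indel overlap with the same allele; (3) no germline-mode
#' normal call with the same allele; (4) at least two alt reads of which at
#' least half have base alignment quality >= 30; (5) fewer than four normals
#' with >= 4 gapped reads within 10 bp; (6) mappability exactly 1; (7) called
#' in somatic mode in fewer than two normals; (8) for variants recurrent across
#' mice (same chrom/pos/alt in tumours of >= 2 distinct mice, a lymphoid-
#' contamination signature), excluded if the maximum tumour VAF is <= 0.05 or a
#' matched-normal VAF is >= 0.01 (either clause suffices).
#'
#' Expected columns beyond the SNV fields: `caller_pass`, `mgp_overlap`,
#' `germline_overlap` (logical), `alt_reads`, `alt_reads_baq30`,
#' `normals_gapped`, `mappability`, `normals_somatic`, `max_tumour_vaf`,
#' `normal_vaf`, `mouse`.
#'
#' @param table A capture-dialect `mutation_table`.
#' @return List with `table` (retained rows), `removals` (per-rule removal
#'   counts; a row may count against several rules), `skipped`, `n_input`,
#'   `n_retained`.
#' @export
filter_capture <- function(table) {
  x <- table
  .need_cols(x, "caller_pass", "caller internal filters")
  .need_cols(x, "mgp_overlap", "SNP/indel overlap")
  .need_cols(x, "germline_overlap", "germline normal overlap")
  .need_cols(x, c("alt_reads", "alt_reads_baq30"), "alt read support / BAQ30")
  .need_cols(x, "normals_gapped", "gapped reads in normals")
  .need_cols(x, "mappability", "mappability")
  .need_cols(x, "normals_somatic", "somatic calls in normals")
  .need_cols(x, c("mouse", "max_tumour_vaf", "normal_vaf"), "recurrent low-VAF variants")

  key <- paste(x$chrom, x$pos, x$alt, sep = ":")
  n_mice <- vapply(split(x$mouse, key),
                   function(m) length(unique(m[!is.na(m)])), integer(1))
  recurrent <- unname(n_mice[key]) >= 2L

  na_or <- function(a, b) ifelse(is.na(a), b, ifelse(is.na(b), a, a | b))
  low_max_vaf <- x$max_tumour_vaf <= 0.05
  high_normal_vaf <- x$normal_vaf >= 0.01
  lymphoid <- na_or(low_max_vaf, high_normal_vaf)

  rules <- list(
    caller_filters      = .as_flag(x$caller_pass),
    snp_overlap         = !.as_flag(x$mgp_overlap),
    germline_overlap    = !.as_flag(x$germline_overlap),
    alt_support_baq     = x$alt_reads >= 2L & x$alt_reads_baq30 >= x$alt_reads / 2,
    gapped_normals      = x$normals_gapped < 4L,
    mappability         = x$mappability == 1,
    somatic_normals     = x$normals_somatic < 2L,
    recurrent_low_vaf   = ifelse(recurrent, !lymphoid, TRUE)
  )
  .apply_rules(x, rules)
}

#' Filter targeted-amplicon SNV calls
#'
#' Retains rows that pass the caller noise filters, have allele fraction
#' >= 0.01, are called in at least two overlapping amplicons, and are supported
#' by at least five mutant reads. Only SNVs are admitted (indels never reach
#' this stage: the reader rejects multi-base alleles).
#'
#' Expected columns: `caller_pass`, `vaf` (allele fraction), `n_amplicons`,
#' `mutant_reads`.
#'
#' @param table An amplicon-dialect `mutation_table`.
#' @return As [filter_capture()].
#' @export
filter_amplicon <- function(table) {
  x <- table
  .need_cols(x, "caller_pass", "caller noise filters")
  .need_cols(x, "vaf", "minimum allele fraction")
  .need_cols(x, "n_amplicons", "overlapping amplicon support")
  .need_cols(x, "mutant_reads", "mutant read support")
  rules <- list(
    snv_only        = nchar(x$ref) == 1L & nchar(x$alt) == 1L,
    caller_filters  = .as_flag(x$caller_pass),
    allele_fraction = x$vaf >= 0.01,
    amplicon_support = x$n_amplicons >= 2L,
    mutant_reads    = x$mutant_reads >= 5L
  )
  .apply_rules(x, rules)
}

#' Write a per-rule removal report
#' @param result A filter result from [filter_capture()] or [filter_amplicon()].
#' @param path Output TSV.
#' @export
write_removal_report <- function(result, path) {
  utils::write.table(result$removals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
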