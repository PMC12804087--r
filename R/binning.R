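# APC truncation binning (mouse) and 20-amino-acid-repeat retention scoring
# (human). Bin boundaries and repeat intervals are configurable data; the
# shipped defaults are documented approximations and can be overridden from
# TSV files.

#' Construct a domain bin scheme
#'
#' Bins are ordered, non-overlapping, contiguous residue intervals (1-based
#' inclusive) labelled A, B, C, ...
#'
#' @param label Bin labels.
#' @param start,end Residue bounds per bin.
#' @return A `bin_scheme` data frame.
#' @export
bin_scheme <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  o <- order(start)
  label <- as.character(label)[o]; start <- as.integer(start)[o]
  end <- as.integer(end)[o]
  if (any(end < start)) stop("bin end before start", call. = FALSE)
  if (anyDuplicated(label)) stop("duplicate bin labels", call. = FALSE)
  if (length(start) > 1L && any(start[-1L] != end[-length(end)] + 1L)) {
    stop("bins must be contiguous and non-overlapping", call. = FALSE)
  }
  out <- data.frame(label = label, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' Default mouse APC domain bins A-H
#'
#' B spans the Armadillo repeats (residues 337-765) and E the 20-amino-acid
#' beta-catenin-binding repeats; the remaining boundaries are documented
#' approximations and should be overridden via [read_bin_scheme()] when exact
#' coordinates are available.
#'
#' @return A `bin_scheme` covering residues 1-2842.
#' @export
default_apc_bins <- function() {
  bin_scheme(label = LETTERS[1:8],
             start = c(1, 337, 766, 1001, 1261, 1601, 2001, 2401),
             end   = c(336, 765, 1000, 1260, 1600, 2000, 2400, 2842))
}

#' Read a bin scheme from TSV (columns label, start, end)
#' @param path TSV path.
#' @return A `bin_scheme`.
#' @export
read_bin_scheme <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  bin_scheme(x$label, x$start, x$end)
}

#' Assign residues to domain bins
#'
#' @param residue Residue positions (>= 1).
#' @param scheme A `bin_scheme`.
#' @return Bin labels; residues beyond the covered range map to `"unbinned"`.
#' @export
assign_bin <- function(residue, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"), all(residue >= 1, na.rm = TRUE))
  idx <- findInterval(residue, scheme$start)
  out <- rep("unbinned", length(residue))
  hit <- idx >= 1L & !is.na(idx)
  hit[hit] <- residue[hit] <= scheme$end[idx[hit]]
  out[hit] <- scheme$label[idx[hit]]
  out[is.na(residue)] <- NA_character_
  out
}

#' All unordered bin-pair combination labels
#' @param labels Bin labels (default A-E).
#' @return Character vector of sorted-pair labels ("AA", "AB", ..., "EE");
#'   `choose(k,2) + k` combos for k bins (15 for five bins).
#' @export
combo_labels <- function(labels = LETTERS[1:5]) {
  pairs <- expand.grid(a = labels, b = labels, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  sort(paste0(pairs$a, pairs$b))
}

#' Bin combination of a tumour's truncating mutations
#'
#' Two mutations give the unordered pair of their bins; a single mutation with
#' evidence of loss of heterozygosity is treated as two hits in the same bin
#' (homotypic pair). A single mutation without an LOH flag cannot be assigned
#' a combination.
#'
#' @param bins One or two bin labels.
#' @param loh Logical: presumptive LOH for a single-mutation tumour.
#' @return A combo label such as `"BD"`, or `"incomplete"`.
#' @export
combo_of <- function(bins, loh = FALSE) {
  bins <- as.character(bins)
  if (length(bins) == 1L) {
    if (!isTRUE(loh)) return("incomplete")
    bins <- c(bins, bins)
  }
  if (length(bins) != 2L) {
    stop("a tumour contributes one or two truncating mutations", call. = FALSE)
  }
  paste0(sort(bins), collapse = "")
}

#' Expected probabilities of bin combinations
#'
#' Under independent placement of the two hits, a heterotypic combination XY
#' has probability `2 p(X) p(Y)` and a homotypic XX has `p(X)^2`; the values
#' sum to 1. Setting `pair_factor = FALSE` drops the multinomial factor 2 and
#' returns the bare products (which do not sum to 1); this variant exists for
#' comparison with conventions that multiply the component probabilities
#' without accounting for order.
#'
#' @param p Named per-bin probabilities (should sum to 1).
#' @param pair_factor Include the factor 2 for heterotypic pairs (default).
#' @return Named numeric vector over [combo_labels()] of `names(p)`.
#' @export
combo_expected <- function(p, pair_factor = TRUE) {
  stopifnot(!is.null(names(p)), all(p >= 0))
  labs <- combo_labels(names(p))
  vapply(labs, function(l) {
    a <- substr(l, 1, 1); b <- substr(l, 2, 2)
    if (a == b) unname(p[a]^2)
    else unname(p[a] * p[b]) * (if (pair_factor) 2 else 1)
  }, numeric(1))
}

#' Construct a 20-amino-acid repeat annotation
#'
#' @param index Repeat indices 1-7.
#' @param start,end Residue bounds, ordered and non-overlapping.
#' @return A `repeat_annotation` data frame.
#' @export
repeat_annotation <- function(index, start, end) {
  o <- order(start)
  index <- as.integer(index)[o]; start <- as.integer(start)[o]
  end <- as.integer(end)[o]
  if (any(end < start)) stop("repeat end before start", call. = FALSE)
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)])) {
    stop("repeat intervals must not overlap", call. = FALSE)
  }
  out <- data.frame(index = index, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("repeat_annotation", "data.frame")
  out
}

#' Default human APC 20-amino-acid repeat intervals
#'
#' Approximate standard-annotation coordinates of the seven repeats; intended
#' to be overridden via [read_repeat_annotation()] where exact coordinates
#' matter. Repeats 1 and 2 end N-terminal of residue 1450, so an Arg1450
#' truncation retains two full repeats.
#'
#' @return A `repeat_annotation` with seven intervals.
#' @export
default_apc_repeats <- function() {
  repeat_annotation(index = 1:7,
                    start = c(1262, 1376, 1486, 1558, 1863, 2007, 2034),
                    end   = c(1281, 1395, 1505, 1577, 1882, 2026, 2053))
}

#' Read a repeat annotation from TSV (columns index, start, end)
#' @param path TSV path.
#' @return A `repeat_annotation`.
#' @export
read_repeat_annotation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  repeat_annotation(x$index, x$start, x$end)
}

#' 20-amino-acid repeat retention score of a truncation
#'
#' Counts the repeat intervals wholly upstream of (ending before) the
#' truncation residue: the number of full-length repeats the truncated protein
#' preserves, 0-7. Monotone non-decreasing in the truncation position.
#'
#' @param residue Truncation residue positions (vectorised).
#' @param repeats A `repeat_annotation`.
#' @return Integer scores.
#' @export
retention_score <- function(residue, repeats = default_apc_repeats()) {
  stopifnot(inherits(repeats, "repeat_annotation"))
  vapply(residue, function(r) {
    if (is.na(r)) return(NA_integer_)
    sum(repeats$end < r)
  }, integer(1))
}

#' Retention score of a sample's APC truncations
#'
#' Uses the single mutation, or the most C-terminal of two (double-hit cases),
#' so the score reflects the longest mutant protein present.
#'
#' @param residues One or two truncation residues.
#' @param repeats A `repeat_annotation`.
#' @return Integer score 0-7, or `NA` for an empty input.
#' @export
sample_retention <- function(residues, repeats = default_apc_repeats()) {
  residues <- residues[!is.na(residues)]
  if (length(residues) == 0L) return(NA_integer_)
  if (length(residues) > 2L) {
    stop("a sample contributes one or two truncating mutations", call. = FALSE)
  }
  retention_score(max(residues), repeats)
}

#' Write a bin scheme or repeat annotation as TSV
#' @param x A `bin_scheme` or `repeat_annotation`.
#' @param path Output path.
#' @export
write_intervals_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
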