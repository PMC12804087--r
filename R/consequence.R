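# Exhaustive single-nucleotide mutation enumeration over a coding sequence,
# with protein-consequence annotation. This is the bridge from a trinucleotide
# signature to expected driver-mutation probabilities: every possible SNV in
# the CDS is listed (3 per position), classified, and tagged with its folded
# 96-channel id so signature frequencies can be summed over any outcome set.

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Enumerate all SNVs over a coding sequence
#'
#' Produces exactly `3 * nchar(cds)` records. Consequence classes follow the
#' standard nuclear code: `missense`, `nonsense` (stop gained), `synonymous`,
#' and `other` for stop-loss and start-loss outcomes, which are excluded from
#' nonsense mass downstream. Flanking bases for channel assignment come from
#' the CDS itself; the first and last position either take flanks from a
#' supplied padding pair or are left without a channel (`NA`, the default), so
#' no context is fabricated at the sequence ends.
#'
#' @param cds A `cds_fasta`.
#' @param end_policy `"exclude"` (default; terminal positions get `NA`
#'   channels) or `"pad"` (use `pad`).
#' @param pad Character vector `c(before, after)` of single bases flanking the
#'   CDS, used only when `end_policy = "pad"`.
#' @return Data frame with columns `cds_pos`, `ref`, `alt`, `channel`,
#'   `residue`, `ref_aa`, `alt_aa`, `class`. The stop codon's own positions
#'   carry `residue = protein_length + 1` and class `other`/`synonymous`.
#' @export
enumerate_snvs <- function(cds, end_policy = c("exclude", "pad"), pad = NULL) {
  stopifnot(inherits(cds, "cds_fasta"))
  end_policy <- match.arg(end_policy)
  seq <- cds$seq
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  gc <- .genetic_code()

  pos <- rep(seq_len(n), each = 3L)
  ref <- chars[pos]
  alt <- unlist(lapply(chars, function(b) setdiff(.BASES, b)), use.names = FALSE)

  codon_idx <- (pos - 1L) %/% 3L + 1L
  within <- (pos - 1L) %% 3L + 1L
  codon_start <- (codon_idx - 1L) * 3L + 1L
  ref_codon <- substring(seq, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])

  cls <- ifelse(ref_aa == alt_aa, "synonymous",
         ifelse(ref_aa == "*", "other",            # stop-loss
         ifelse(alt_aa == "*", "nonsense",
         ifelse(codon_idx == 1L, "other",          # start-loss
                "missense"))))

  f5 <- c(NA_character_, chars)[pos]        # base before pos (NA at pos 1)
  f3 <- c(chars, NA_character_)[pos + 1L]   # base after pos (NA at pos n)
  if (end_policy == "pad") {
    stopifnot(length(pad) == 2L, all(toupper(pad) %in% .BASES))
    f5[pos == 1L] <- toupper(pad[1L])
    f3[pos == n] <- toupper(pad[2L])
  }
  ok <- !is.na(f5) & !is.na(f3)
  channel <- rep(NA_character_, length(pos))
  channel[ok] <- fold_context(ref[ok], alt[ok], f5[ok], f3[ok])

  data.frame(cds_pos = pos, ref = ref, alt = alt, channel = channel,
             residue = codon_idx, ref_aa = ref_aa, alt_aa = alt_aa,
             class = cls, stringsAsFactors = FALSE)
}

#' Protein-change label ("T41I" style) for enumerated SNVs
#' @param enum Rows of [enumerate_snvs()] output.
#' @return Character labels; stop gains are written with `*`.
#' @export
aa_change_label <- function(enum) {
  paste0(enum$ref_aa, enum$residue, enum$alt_aa)
}

#' Expected probabilities of amino-acid changes in a codon set
#'
#' Each distinct amino-acid change reachable by one SNV within `codons` gets a
#' probability proportional to the summed signature frequency of its
#' generating channels, renormalised over the outcome set (the no-selection
#' expectation for driver missense mutations).
#'
#' @param cds A `cds_fasta`.
#' @param sig A `trinuc_spectrum`.
#' @param codons Residue positions defining the outcome set (e.g. the seven
#'   beta-catenin phospho-degron codons).
#' @param classes Consequence classes admitted to the outcome set (default
#'   missense only).
#' @return Data frame `outcome`, `frequency`, `probability` (sums to 1).
#' @export
expected_missense_probs <- function(cds, sig, codons,
                                    classes = "missense") {
  stopifnot(all(codons >= 1), all(codons <= cds$protein_length))
  enum <- enumerate_snvs(cds)
  enum <- enum[enum$residue %in% codons & enum$class %in% classes &
                 !is.na(enum$channel), , drop = FALSE]
  if (nrow(enum) == 0L) {
    stop("no reachable outcomes in the requested codon set", call. = FALSE)
  }
  rescale_to_outcome_set(sig, data.frame(outcome = aa_change_label(enum),
                                         channel = enum$channel,
                                         stringsAsFactors = FALSE))
}

#' Expected probabilities of truncating mutations per domain bin
#'
#' For each bin, sums the signature frequencies of every stop-generating SNV
#' whose residue lies in the bin, then renormalises over the analysed bins.
#' Splice and stop-loss outcomes contribute nothing: expectation is computed
#' from stop-gain contexts only.
#'
#' @param cds A `cds_fasta`.
#' @param sig A `trinuc_spectrum`.
#' @param bins A `bin_scheme` (see [bin_scheme()]).
#' @param analyzed Bin labels to include (default: all bins in the scheme).
#' @return Data frame `bin`, `frequency` (unnormalised stop mass),
#'   `probability` (sums to 1 over the analysed bins).
#' @export
expected_stop_probs_by_bin <- function(cds, sig, bins, analyzed = NULL) {
  stopifnot(inherits(bins, "bin_scheme"))
  if (max(bins$end) > cds$protein_length) {
    stop(sprintf("bin scheme extends to residue %d beyond protein length %d",
                 max(bins$end), cds$protein_length), call. = FALSE)
  }
  if (is.null(analyzed)) analyzed <- bins$label
  enum <- enumerate_snvs(cds)
  ns <- enum[enum$class == "nonsense" & !is.na(enum$channel), , drop = FALSE]
  bin <- assign_bin(ns$residue, bins)
  f <- signature_frequency(sig, ns$channel)
  mass <- vapply(analyzed, function(b) sum(f[bin == b]), numeric(1))
  tot <- sum(mass)
  if (tot <= 0) stop("no stop-generating signature mass in the analysed bins",
                     call. = FALSE)
  data.frame(bin = analyzed, frequency = unname(mass),
             probability = unname(mass) / tot,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an enumeration table as TSV
#' @param enum Output of [enumerate_snvs()].
#' @param path Output path.
#' @export
write_enumeration_tsv <- function(enum, path) {
  utils::write.table(enum, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
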