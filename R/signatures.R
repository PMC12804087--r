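# 96-channel trinucleotide mutational signature machinery.
#
# All channels follow the COSMIC SBS96 convention: substitutions are expressed
# with a pyrimidine (C or T) reference base, so a purine-centred SNV is
# reverse-complemented together with its flanking bases before classification.
# Channel ids look like "A[C>T]G".

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 COSMIC-convention substitution channels
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G)
#' and, within a class, by 5' then 3' flanking base, matching the COSMIC
#' catalogue ordering.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  unlist(lapply(.SUBS, function(s) {
    as.vector(t(outer(.BASES, .BASES, function(f5, f3) {
      paste0(f5, "[", s, "]", f3)
    })))
  }), use.names = FALSE)
}

#' The 32 pyrimidine-centric trinucleotides
#'
#' @return Character vector of length 32 (centre base C or T).
#' @export
pyrimidine_trinucleotides <- function() {
  unlist(lapply(c("C", "T"), function(ctr) {
    as.vector(t(outer(.BASES, .BASES, function(f5, f3) paste0(f5, ctr, f3))))
  }), use.names = FALSE)
}

.check_bases <- function(x, what) {
  bad <- !(x %in% .BASES)
  if (any(bad)) {
    stop(sprintf("non-ACGT %s base: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
}

#' Fold an SNV with its flanks to its pyrimidine-centric channel
#'
#' Purine-centred substitutions are reverse-complemented (flanks swap and
#' complement) so the returned channel always carries a C or T reference.
#' Vectorised over all four arguments.
#'
#' @param ref,alt Reference and alternate bases (single characters, ref != alt).
#' @param flank5,flank3 Bases immediately 5' and 3' of the variant.
#' @return Character vector of channel ids, e.g. `"A[C>T]C"`.
#' @export
fold_context <- function(ref, alt, flank5, flank3) {
  ref <- toupper(ref); alt <- toupper(alt)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  .check_bases(ref, "reference"); .check_bases(alt, "alternate")
  .check_bases(flank5, "5' flank"); .check_bases(flank3, "3' flank")
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, unname(.COMP[ref]), ref)
  a <- ifelse(pur, unname(.COMP[alt]), alt)
  f5 <- ifelse(pur, unname(.COMP[flank3]), flank5)
  f3 <- ifelse(pur, unname(.COMP[flank5]), flank3)
  paste0(f5, "[", r, ">", a, "]", f3)
}

#' Trinucleotide underlying a channel id
#' @param channel Channel ids as returned by [fold_context()].
#' @return Pyrimidine-centric trinucleotides, e.g. `"ACG"` for `"A[C>T]G"`.
#' @export
channel_trinucleotide <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}

#' Target base of a channel id
#' @param channel Channel ids.
#' @return Alternate base of each channel.
#' @export
channel_alt <- function(channel) substr(channel, 5, 5)

# reverse complement of plain character sequences (no Biostrings round trip
# needed for the tiny strings handled here)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count pyrimidine-centric trinucleotide opportunities in a territory
#'
#' Slides a 3-base window over every sequence (interior positions only, each
#' counted once) and folds purine-centred windows to their reverse complement.
#' The resulting counts are the mutational opportunities used to normalise raw
#' channel counts into per-context rates.
#'
#' @param territory Character vector (or `DNAStringSet`) of sequences, each of
#'   length >= 3.
#' @return Named integer vector over the 32 pyrimidine-centric trinucleotides.
#' @export
count_opportunities <- function(territory) {
  territory <- toupper(as.character(territory))
  if (length(territory) == 0L || all(nchar(territory) < 3L)) {
    stop("territory must contain at least one sequence of length >= 3",
         call. = FALSE)
  }
  counts <- stats::setNames(integer(32L), pyrimidine_trinucleotides())
  for (s in territory) {
    n <- nchar(s)
    if (n < 3L) next
    tri <- substring(s, 1:(n - 2L), 3:n)
    tri <- tri[!grepl("[^ACGT]", tri)]
    ctr <- substr(tri, 2, 2)
    pur <- ctr %in% c("A", "G")
    if (any(pur)) {
      tri[pur] <- paste0(unname(.COMP[substr(tri[pur], 3, 3)]),
                         unname(.COMP[ctr[pur]]),
                         unname(.COMP[substr(tri[pur], 1, 1)]))
    }
    tab <- table(tri)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' Estimate an opportunity-normalised 96-channel signature
#'
#' Each passenger SNV is folded to its channel; per-channel counts are divided
#' by the opportunity count of the channel's trinucleotide in the sequenced
#' territory, and the resulting rates renormalised to sum to one. Channels
#' whose trinucleotide is absent from the territory are dropped from the
#' normalisation (their rate is undefined); a mutation observed in such a
#' channel is an inconsistency and raises an error.
#'
#' @param passengers A `mutation_table` (or data frame) with columns `ref`,
#'   `alt`, `flank5`, `flank3` and optionally `gene` and `class`.
#' @param opportunities Named counts as from [count_opportunities()].
#' @param exclusions Optional data frame with columns `gene` and `class`
#'   describing (gene, consequence-class) pairs to drop before counting;
#'   `class = "any"` (or `NA`) drops every mutation in the gene. Used to purge
#'   driver genes from the passenger set.
#' @return A `trinuc_spectrum`: data frame with columns `channel`, `count`,
#'   `opportunity`, `frequency` (96 rows; frequency `NA` for zero-opportunity
#'   channels). Attribute `n_excluded` reports rows removed by `exclusions`.
#' @export
estimate_signature <- function(passengers, opportunities, exclusions = NULL) {
  stopifnot(all(c("ref", "alt", "flank5", "flank3") %in% names(passengers)))
  n_excl <- 0L
  if (!is.null(exclusions) && nrow(passengers) > 0L) {
    stopifnot(all(c("gene", "class") %in% names(exclusions)))
    if (!"gene" %in% names(passengers)) {
      stop("exclusions supplied but passenger table has no 'gene' column",
           call. = FALSE)
    }
    drop <- rep(FALSE, nrow(passengers))
    for (i in seq_len(nrow(exclusions))) {
      g <- exclusions$gene[i]; cl <- exclusions$class[i]
      hit <- passengers$gene == g
      if (!is.na(cl) && cl != "any") {
        if (!"class" %in% names(passengers)) {
          stop("class-specific exclusion needs a 'class' column", call. = FALSE)
        }
        hit <- hit & passengers$class == cl
      }
      drop <- drop | (hit %in% TRUE)
    }
    n_excl <- sum(drop)
    passengers <- passengers[!drop, , drop = FALSE]
  }
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96L), channels)
  if (nrow(passengers) > 0L) {
    ch <- fold_context(passengers$ref, passengers$alt,
                       passengers$flank5, passengers$flank3)
    tab <- table(factor(ch, levels = channels))
    counts[] <- as.integer(tab)
  }
  opp <- stats::setNames(numeric(96L), channels)
  tri <- channel_trinucleotide(channels)
  known <- tri %in% names(opportunities)
  opp[known] <- as.numeric(opportunities[tri[known]])
  zero_opp <- opp == 0
  if (any(zero_opp & counts > 0)) {
    stop(sprintf(
      "mutations observed in channels with zero opportunity (%s): territory inconsistent",
      paste(channels[zero_opp & counts > 0], collapse = ", ")), call. = FALSE)
  }
  rate <- ifelse(zero_opp, NA_real_, counts / opp)
  tot <- sum(rate, na.rm = TRUE)
  freq <- if (tot > 0) rate / tot else rate
  out <- data.frame(channel = channels, count = as.integer(counts),
                    opportunity = opp, frequency = freq,
                    stringsAsFactors = FALSE)
  class(out) <- c("trinuc_spectrum", "data.frame")
  attr(out, "n_excluded") <- n_excl
  out
}

#' Build a spectrum object from per-channel frequencies
#'
#' Convenience constructor for analyses that start from published or synthetic
#' channel frequencies rather than raw counts.
#'
#' @param frequency Named numeric vector (names are channel ids); channels not
#'   named get frequency 0. Values are renormalised to sum to 1.
#' @return A `trinuc_spectrum`.
#' @export
spectrum_from_frequencies <- function(frequency) {
  channels <- sbs96_channels()
  f <- stats::setNames(numeric(96L), channels)
  bad <- setdiff(names(frequency), channels)
  if (length(bad)) {
    stop(sprintf("unknown channel id(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  f[names(frequency)] <- as.numeric(frequency)
  if (any(f < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (sum(f) <= 0) stop("frequencies sum to zero", call. = FALSE)
  out <- data.frame(channel = channels, count = NA_integer_,
                    opportunity = NA_real_, frequency = f / sum(f),
                    stringsAsFactors = FALSE)
  class(out) <- c("trinuc_spectrum", "data.frame")
  out
}

#' Uniform spectrum over all 96 channels
#' @return A `trinuc_spectrum` with every channel at frequency 1/96.
#' @export
flat_spectrum <- function() {
  spectrum_from_frequencies(stats::setNames(rep(1, 96), sbs96_channels()))
}

#' Look up channel frequencies in a spectrum
#' @param sig A `trinuc_spectrum`.
#' @param channel Channel ids.
#' @return Numeric frequencies (`NA` dropped to 0).
#' @export
signature_frequency <- function(sig, channel) {
  f <- sig$frequency[match(channel, sig$channel)]
  ifelse(is.na(f), 0, f)
}

#' Rescale signature frequencies over an outcome set
#'
#' Restricts the signature to the channels that can generate the outcomes under
#' analysis and renormalises: each outcome's expected probability is the summed
#' frequency of its generating channels divided by the total over the outcome
#' set. This is the step that turns a panel-wide signature into expected
#' probabilities for a specific set of driver mutations.
#'
#' @param sig A `trinuc_spectrum`.
#' @param outcomes Data frame with columns `outcome` and `channel` (an outcome
#'   may have several generating channels), or a named character vector of
#'   channels (names = outcome labels).
#' @return Data frame with columns `outcome`, `frequency` (unnormalised summed
#'   channel frequency) and `probability` (sums to 1).
#' @export
rescale_to_outcome_set <- function(sig, outcomes) {
  if (is.character(outcomes)) {
    outcomes <- data.frame(outcome = names(outcomes), channel = unname(outcomes),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("outcome", "channel") %in% names(outcomes)),
            nrow(outcomes) > 0L)
  f <- signature_frequency(sig, outcomes$channel)
  agg <- tapply(f, outcomes$outcome, sum)
  tot <- sum(agg)
  if (tot <= 0) stop("all outcome frequencies are zero", call. = FALSE)
  data.frame(outcome = names(agg), frequency = as.numeric(agg),
             probability = as.numeric(agg) / tot,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a signature table
#'
#' TSV with columns channel, count, opportunity, frequency (COSMIC channel
#' naming). Reading accepts tables with only channel + frequency.
#'
#' @param sig A `trinuc_spectrum`.
#' @param path File path.
#' @return `read_signature_tsv` returns a `trinuc_spectrum`.
#' @export
write_signature_tsv <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "frequency") %in% names(x))) {
    stop("signature TSV needs 'channel' and 'frequency' columns", call. = FALSE)
  }
  spectrum_from_frequencies(stats::setNames(x$frequency, x$channel))
}
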