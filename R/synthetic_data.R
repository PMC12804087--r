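# Synthetic inputs with the statistical structure the analysis assumes, so
# every stage is testable without external downloads: mutation catalogs drawn
# from a known signature with injected selection multipliers, cohort tumour
# counts with driver mixtures decayed through the drift model, and polyp
# APC/KRAS read-count tables with a configured true mutation chronology.
#
# Generative model for catalogs: the per-site mutation rate of an SNV equals
# the signature frequency of its folded channel (that is what an opportunity-
# normalised signature means), so each enumerated SNV is drawn with
# probability proportional to frequency(channel) x selection multiplier of
# its protein outcome. Re-estimating the signature from such a catalog over
# the same territory recovers the input frequencies.

#' Random coding sequence
#'
#' ATG start, random sense codons, single terminal stop. Used as a synthetic
#' substrate for consequence enumeration and catalog generation.
#'
#' @param n_codons Number of sense codons including the start (>= 2).
#' @param seed RNG seed.
#' @param gene Gene id for the record.
#' @return A `cds_fasta` with `protein_length = n_codons`.
#' @export
random_cds <- function(n_codons, seed = 1L, gene = "synthetic") {
  stopifnot(n_codons >= 2)
  set.seed(seed)
  gc <- .genetic_code()
  sense <- names(gc)[gc != "*"]
  body <- sample(sense, n_codons - 1L, replace = TRUE)
  stop_codon <- sample(.STOPS, 1L)
  cds_fasta(paste0("ATG", paste(body, collapse = ""), stop_codon), gene = gene)
}

#' Synthetic normal-colon-like trinucleotide signature
#'
#' A clearly synthetic stand-in for published normal-colon signatures: a
#' clock-like component concentrating C>T mass at NpCpG contexts over a flat
#' background. Replace with measured frequencies via [read_signature_tsv()]
#' for any analysis of real data.
#'
#' @param cpg_weight Mass multiplier for C>T at CpG channels (default 40).
#' @return A `trinuc_spectrum`.
#' @export
synthetic_colon_signature <- function(cpg_weight = 40) {
  ch <- sbs96_channels()
  w <- rep(1, 96)
  cpg_ct <- grepl("\\[C>T\\]G$", ch)
  w[cpg_ct] <- cpg_weight
  spectrum_from_frequencies(stats::setNames(w, ch))
}

#' Generate a synthetic SNV catalog over a coding sequence
#'
#' Draws `n` SNVs from the enumerated mutations of `cds`, each with
#' probability proportional to the signature frequency of its folded channel
#' times the selection multiplier of its protein outcome. Support fields
#' (read depths, alt reads, amplicon counts, normal-panel annotations) are
#' populated so the variant filters are exercisable; by default every drawn
#' row passes them.
#'
#' @param cds A `cds_fasta`.
#' @param sig A `trinuc_spectrum` to draw from.
#' @param n Number of SNVs.
#' @param multipliers Named numeric selection multipliers (> 0), keyed by
#'   protein-outcome label as produced by [aa_change_label()] (e.g. `"I35S"`);
#'   outcomes not named have multiplier 1.
#' @param seed RNG seed (fixed seed gives an identical catalog).
#' @param depth_mean Mean sequencing depth.
#' @param muts_per_tumour Average mutations per synthetic tumour (controls how
#'   many tumour/mouse identifiers are minted).
#' @return A capture-dialect `mutation_table` with columns for both filter
#'   dialects plus `flank5`/`flank3`, `class`, `outcome` and `gene`.
#' @export
gen_mutation_catalog <- function(cds, sig, n, multipliers = NULL, seed = 1L,
                                 depth_mean = 300, muts_per_tumour = 40) {
  stopifnot(n >= 1, is.null(multipliers) || all(multipliers > 0))
  set.seed(seed)
  enum <- enumerate_snvs(cds)
  enum <- enum[!is.na(enum$channel), , drop = FALSE]
  enum$outcome <- aa_change_label(enum)
  w <- signature_frequency(sig, enum$channel)
  if (!is.null(multipliers)) {
    m <- multipliers[enum$outcome]
    m[is.na(m)] <- 1
    w <- w * m
  }
  if (sum(w) <= 0) stop("signature places no mass on this CDS", call. = FALSE)
  idx <- sample.int(nrow(enum), n, replace = TRUE, prob = w)
  rows <- enum[idx, , drop = FALSE]

  chars <- strsplit(cds$seq, "")[[1]]
  n_tumours <- max(1L, ceiling(n / muts_per_tumour))
  tumour <- sample.int(n_tumours, n, replace = TRUE)
  depth <- stats::rnbinom(n, mu = depth_mean, size = 10) + 30L
  true_vaf <- stats::rbeta(n, 8, 12)
  alt_reads <- stats::rbinom(n, depth, true_vaf)
  vaf <- alt_reads / depth

  out <- data.frame(
    sample = paste0("T", tumour),
    mouse = paste0("M", ((tumour - 1L) %% max(2L, ceiling(n_tumours / 6))) + 1L),
    chrom = cds$gene, pos = rows$cds_pos, ref = rows$ref, alt = rows$alt,
    gene = cds$gene, protein_change = rows$outcome, class = rows$class,
    channel = rows$channel,
    flank5 = chars[rows$cds_pos - 1L], flank3 = chars[rows$cds_pos + 1L],
    vaf = vaf, alt_reads = alt_reads, depth = depth,
    # capture support fields (all passing by construction)
    caller_pass = TRUE, mgp_overlap = FALSE, germline_overlap = FALSE,
    alt_reads_baq30 = alt_reads, normals_gapped = 0L, mappability = 1,
    normals_somatic = 0L, max_tumour_vaf = NA_real_, normal_vaf = 0,
    # amplicon support fields
    n_amplicons = 2L + stats::rpois(n, 1), mutant_reads = pmax(alt_reads, 5L),
    stringsAsFactors = FALSE)
  out$alt_reads <- pmax(out$alt_reads, 2L)
  out$alt_reads_baq30 <- out$alt_reads
  out$mutant_reads <- pmax(out$mutant_reads, 5L)
  out$vaf <- pmax(out$vaf, 0.02)
  # the recurrence rule compares the maximum VAF across tumours sharing a variant
  key <- paste(out$chrom, out$pos, out$alt, sep = ":")
  out$max_tumour_vaf <- stats::ave(out$vaf, key, FUN = max)
  as_mutation_table(out, dialect = "capture", provenance = "synthetic catalog")
}

#' Default synthetic cohort grid
#'
#' The cohort conditions the generator emulates: priming (TE) means and
#' dispersions on the scale of the mouse experiments (hundreds of tumours for
#' strong priming fields, a handful for unprimed controls), rescue (ET)
#' protocols sharing the TE baseline with decay applied through the drift
#' model, and driver mixtures dominated by beta-catenin for Kras priming and
#' by APC otherwise.
#'
#' @return Data frame with columns `label`, `protocol`, `n_mice`, `mean`,
#'   `dispersion`, `p_ctnnb1` (the Apc share is the complement).
#' @export
default_cohort_grid <- function() {
  data.frame(
    label      = c("control", "Kras", "Kras", "Kras", "Apc_het", "Apc_het"),
    protocol   = c("TE", "TE", "ET10", "ET30", "TE", "ET30"),
    n_mice     = c(10L, 8L, 8L, 8L, 8L, 8L),
    mean       = c(3.1, 388, 388, 388, 967, 967),
    dispersion = c(3, 9.6, 9.6, 9.6, 13.2, 13.2),
    p_ctnnb1   = c(0.4, 0.85, 0.85, 0.85, 0.1, 0.1),
    stringsAsFactors = FALSE)
}

#' Generate synthetic cohorts with drift-mediated decay
#'
#' Per-mouse tumour counts are negative-binomial (overdispersed, as observed
#' count data are); each tumour draws a driver class from the cohort mixture.
#' For rescue protocols (ET10/ET30) the `mean` column is the TE-equivalent
#' baseline and each tumour survives to the rescue day with the probability
#' given by the drift model at that class's replacement bias `pr`.
#'
#' @param grid Cohort grid as [default_cohort_grid()].
#' @param pr_by_class Named replacement biases used to decay each driver class
#'   under rescue (default: `c(Ctnnb1 = 0.3, Apc = 0.3)`, negative bias).
#' @param drift Base `drift_params` (its `pr` is overridden per class).
#' @param seed RNG seed.
#' @return List with `tumours` (one row per surviving tumour: `cohort`,
#'   `protocol`, `mouse`, `class`) and `summaries` (named list of
#'   `cohort_summary`, keyed `label_protocol`, computed from the generated
#'   tumours).
#' @export
gen_cohorts <- function(grid = default_cohort_grid(),
                        pr_by_class = c(Ctnnb1 = 0.3, Apc = 0.3),
                        drift = drift_params(), seed = 1L) {
  set.seed(seed)
  tumours <- list()
  summaries <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    counts <- stats::rnbinom(g$n_mice, mu = g$mean, size = g$dispersion)
    cls <- sample(c("Ctnnb1", "Apc"), sum(counts), replace = TRUE,
                  prob = c(g$p_ctnnb1, 1 - g$p_ctnnb1))
    mouse <- rep(seq_len(g$n_mice), counts)
    keep <- rep(TRUE, length(cls))
    if (g$protocol != "TE") {
      day <- as.numeric(sub("ET", "", g$protocol))
      for (cl in unique(cls)) {
        pr <- if (cl %in% names(pr_by_class)) pr_by_class[[cl]] else 0.5
        pcl <- drift_params(ns = drift$ns, lambda = drift$lambda, pr = pr,
                            tau = drift$tau, t_max = max(drift$t_max, day),
                            t_step = drift$t_step, kernel = drift$kernel)
        surv <- neutral_fraction_at(pcl, day)
        sel <- cls == cl
        keep[sel] <- stats::runif(sum(sel)) < surv
      }
    }
    df <- data.frame(cohort = g$label, protocol = g$protocol,
                     mouse = paste0(g$label, "_", g$protocol, "_M", mouse),
                     class = cls, stringsAsFactors = FALSE)[keep, , drop = FALSE]
    tumours[[i]] <- df
    per_mouse <- tabulate(match(df$mouse,
                                paste0(g$label, "_", g$protocol, "_M",
                                       seq_len(g$n_mice))),
                          nbins = g$n_mice)
    props <- prop.table(table(factor(df$class, levels = c("Apc", "Ctnnb1"))))
    summaries[[paste(g$label, g$protocol, sep = "_")]] <-
      cohort_summary(g$label, g$protocol,
                     mean_count = mean(per_mouse),
                     sd_count = stats::sd(per_mouse),
                     proportions = stats::setNames(as.numeric(props),
                                                   names(props)))
  }
  list(tumours = do.call(rbind, tumours), summaries = summaries)
}

# residue giving a requested 20-AA-repeat retention score under `repeats`
.residue_for_score <- function(score, repeats) {
  ends <- repeats$end
  if (score == 0) return(max(1L, repeats$start[1] - 50L))
  if (score >= nrow(repeats)) return(ends[nrow(repeats)] + 50L)
  ends[score] + 5L
}

#' Generate a synthetic polyp registry table
#'
#' Each polyp carries one or two APC truncations and (optionally) a KRAS
#' driver. The true mutation chronology is configured: the earlier mutation's
#' cancer-cell fraction is drawn first and the later one is at most as large,
#' VAFs are half the cancer-cell fraction (diploid heterozygous), and read
#' counts are binomial at the configured depth. Retention scores are drawn
#' per KRAS stratum (KRAS-mutant polyps centred one repeat higher), emulating
#' the retention shift the human analyses measure.
#'
#' @param n Number of polyps.
#' @param p_kras Fraction of polyps with a KRAS driver.
#' @param p_apc_first Among KRAS-mutant polyps, probability the APC mutation
#'   is the earlier event.
#' @param p_two_hit Probability a polyp has two APC mutations.
#' @param depth_mean Mean sequencing depth.
#' @param repeats A `repeat_annotation`.
#' @param seed RNG seed.
#' @return Data frame, one row per polyp: identifiers, APC residues/VAFs/read
#'   counts, KRAS status and read counts, `n_apc`, `n_other_drivers`, `side`,
#'   and the latent `true_chronology`.
#' @export
gen_polyps <- function(n = 810, p_kras = 0.5, p_apc_first = 0.95,
                       p_two_hit = 0.6, depth_mean = 500,
                       repeats = default_apc_repeats(), seed = 1L) {
  set.seed(seed)
  kras_mut <- stats::runif(n) < p_kras
  apc_first <- ifelse(kras_mut, stats::runif(n) < p_apc_first, NA)
  two_hit <- stats::runif(n) < p_two_hit

  score_probs_wt <- c(0.15, 0.45, 0.2, 0.1, 0.05, 0.03, 0.01, 0.01)
  score_probs_mut <- c(0.05, 0.2, 0.45, 0.15, 0.07, 0.04, 0.02, 0.02)
  score <- integer(n)
  score[!kras_mut] <- sample(0:7, sum(!kras_mut), TRUE, score_probs_wt)
  score[kras_mut] <- sample(0:7, sum(kras_mut), TRUE, score_probs_mut)
  apc1_residue <- vapply(score, .residue_for_score, integer(1), repeats = repeats)
  apc2_residue <- ifelse(two_hit,
                         pmax(50L, apc1_residue -
                                sample(100:600, n, replace = TRUE)),
                         NA_integer_)

  ccf_early <- stats::runif(n, 0.3, 1)
  ccf_late <- stats::runif(n, 0, 1) * ccf_early
  apc_ccf <- ifelse(is.na(apc_first) | apc_first, ccf_early, ccf_late)
  kras_ccf <- ifelse(is.na(apc_first), NA,
                     ifelse(apc_first, ccf_late, ccf_early))

  apc_depth <- stats::rnbinom(n, mu = depth_mean, size = 20) + 50L
  kras_depth <- stats::rnbinom(n, mu = depth_mean, size = 20) + 50L
  apc_alt <- stats::rbinom(n, apc_depth, apc_ccf / 2)
  kras_alt <- ifelse(kras_mut, stats::rbinom(n, kras_depth,
                                             ifelse(is.na(kras_ccf), 0,
                                                    kras_ccf) / 2), NA)
  data.frame(
    sample = paste0("P", seq_len(n)),
    kras_mut = kras_mut,
    kras_alt = kras_alt,
    kras_depth = ifelse(kras_mut, kras_depth, NA),
    apc1_residue = apc1_residue, apc2_residue = apc2_residue,
    apc1_alt = apc_alt, apc1_depth = apc_depth,
    apc1_vaf = apc_alt / apc_depth,
    n_apc = ifelse(two_hit, 2L, 1L),
    n_other_drivers = stats::rpois(n, 0.8),
    side = sample(c("right", "left", "rectum"), n, TRUE, c(0.4, 0.45, 0.15)),
    true_chronology = ifelse(!kras_mut, "no-KRAS",
                             ifelse(apc_first, "APC-first", "KRAS-first")),
    stringsAsFactors = FALSE)
}
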