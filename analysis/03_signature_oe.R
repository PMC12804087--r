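#!/usr/bin/env Rscript
# Stage 3: signature estimation and the O/E selection readout.
#
# Re-estimates the 96-channel opportunity-normalised signature from the
# filtered catalog, computes expected missense probabilities over the coding
# sequence, and fits O/E ratios. The injected fourfold outcome should surface
# with O/E near 4; everything else should sit near 1.

suppressMessages(library(cryptsel))

cds <- read_cds_fasta("results/synthetic_driver.fa")
catalog <- read_mutation_table("results/catalog_filtered.tsv", "capture")
target <- readLines("results/injected_outcome.txt")

opp <- count_opportunities(cds$seq)
sig <- estimate_signature(catalog, opp)
write_signature_tsv(sig, "results/signature.tsv")
message(sprintf("signature estimated from %d SNVs over %d opportunity contexts",
                sum(sig$count), sum(opp > 0)))

exp_probs <- expected_missense_probs(cds, sig,
                                     codons = seq_len(cds$protein_length))
mis <- catalog[catalog$class == "missense", ]
observed <- setNames(rep(0, nrow(exp_probs)), exp_probs$outcome)
tab <- table(mis$protein_change)
hit <- names(tab)[names(tab) %in% names(observed)]
observed[hit] <- tab[hit]
oe <- oe_table(observed, setNames(exp_probs$probability, exp_probs$outcome))
write_oe_tsv(oe, "results/oe_missense.tsv")

got <- oe[oe$class == target, ]
message(sprintf("injected outcome %s: O/E = %.2f (chi2 = %.1f, p = %.2g)",
                target, got$oe, got$chi2, got$p))
recur <- recurrence_filter(observed, 9)
message(sprintf("recurrent (n > 9) outcomes: %d of %d", length(recur),
                length(observed)))

# binned truncation expectation over an A-E-style prefix partition
len <- cds$protein_length
cuts <- round(seq(0, len, length.out = 6))
bins <- bin_scheme(LETTERS[1:5], head(cuts, 5) + 1, cuts[-1])
stop_probs <- expected_stop_probs_by_bin(cds, sig, bins)
write.table(stop_probs, "results/expected_stop_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
combo <- combo_expected(setNames(stop_probs$probability, stop_probs$bin))
write.table(data.frame(combo = names(combo), probability = unname(combo)),
            "results/expected_bin_combos.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d bin combinations; expected probabilities sum to %.6f",
                length(combo), sum(combo)))
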