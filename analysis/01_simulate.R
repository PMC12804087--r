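#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces a driver-mutation catalog over a synthetic coding sequence (with a
# fourfold selection multiplier injected on one missense outcome), cohort
# tumour tables for priming and rescue protocols, and a polyp registry table
# with a configured APC-first mutation chronology. All downstream stages read
# these tables from results/.

suppressMessages(library(cryptsel))
seed <- 20260919L
dir.create("results", showWarnings = FALSE)

cds <- random_cds(400, seed = seed, gene = "synthetic_driver")
write_cds_fasta(cds, "results/synthetic_driver.fa")

sig <- flat_spectrum()
exp_probs <- expected_missense_probs(cds, sig, codons = seq_len(cds$protein_length))
target <- exp_probs$outcome[which.min(abs(exp_probs$probability - 0.003))]
message("injecting selection multiplier 4 on missense outcome ", target)
catalog <- gen_mutation_catalog(cds, sig, n = 8000,
                                multipliers = setNames(4, target),
                                seed = seed + 1L)
write_mutation_table(catalog, "results/catalog.tsv")
writeLines(target, "results/injected_outcome.txt")

cohorts <- gen_cohorts(default_cohort_grid(),
                       pr_by_class = c(Ctnnb1 = 0.3, Apc = 0.3),
                       seed = seed + 2L)
write.table(cohorts$tumours, "results/cohort_tumours.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

polyps <- gen_polyps(n = 810, p_kras = 0.5, p_apc_first = 0.95,
                     seed = seed + 3L)
write.table(polyps, "results/polyps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("catalog: %d SNVs over %d tumours; cohorts: %d tumours; polyps: %d",
                nrow(catalog), length(unique(catalog$sample)),
                nrow(cohorts$tumours), nrow(polyps)))
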