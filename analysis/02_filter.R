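#!/usr/bin/env Rscript
# Stage 2: post-caller SNV filtering.
#
# Applies the capture-dialect support rules to the synthetic catalog and both
# rule sets to the packaged toy tables (whose expected survivors are derived
# by hand), writing the filtered tables and per-rule removal reports.

suppressMessages(library(cryptsel))

catalog <- read_mutation_table("results/catalog.tsv", dialect = "capture")
res <- filter_capture(catalog)
message(sprintf("catalog: %d of %d rows pass the capture filters",
                res$n_retained, res$n_input))
write_mutation_table(res$table, "results/catalog_filtered.tsv")
write_removal_report(res, "results/catalog_removals.tsv")

cap <- read_mutation_table(system.file("extdata", "capture_toy.tsv",
                                       package = "cryptsel"), "capture")
cap_res <- filter_capture(cap)
message(sprintf("capture toy: %d/%d retained (expected 1)",
                cap_res$n_retained, cap_res$n_input))
write_removal_report(cap_res, "results/capture_toy_removals.tsv")

amp <- read_mutation_table(system.file("extdata", "amplicon_toy.tsv",
                                       package = "cryptsel"), "amplicon")
amp_res <- filter_amplicon(amp)
message(sprintf("amplicon toy: %d/%d retained (expected 3)",
                amp_res$n_retained, amp_res$n_input))
write_removal_report(amp_res, "results/amplicon_toy_removals.tsv")
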