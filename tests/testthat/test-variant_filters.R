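# A fully passing capture row; individual tests break one field at a time.
capture_row <- function(...) {
  base <- list(sample = "T1", chrom = "chr1", pos = 100L, ref = "C", alt = "T",
               mouse = "M1", caller_pass = TRUE, mgp_overlap = FALSE,
               germline_overlap = FALSE, alt_reads = 10L, alt_reads_baq30 = 8L,
               normals_gapped = 0L, mappability = 1, normals_somatic = 0L,
               max_tumour_vaf = 0.3, normal_vaf = 0, vaf = 0.3)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

test_that("capture filter applies each support rule", {
  tab <- as_mutation_table(rbind(
    capture_row(),
    capture_row(sample = "T2", pos = 200L, alt_reads = 1L, alt_reads_baq30 = 1L),
    capture_row(sample = "T3", pos = 300L, alt_reads = 10L, alt_reads_baq30 = 4L),
    capture_row(sample = "T4", pos = 400L, mappability = 0.8)
  ))
  res <- filter_capture(tab)
  expect_equal(res$table$sample, "T1")
  rem <- setNames(res$removals$removed, res$removals$rule)
  expect_equal(unname(rem["alt_support_baq"]), 2L)  # < 2 alt reads; < half BAQ30
  expect_equal(unname(rem["mappability"]), 1L)
})

test_that("recurrent low-VAF rule needs >= 2 mice and either clause suffices", {
  shared <- list(pos = 900L, ref = "C", alt = "T")
  tab <- as_mutation_table(rbind(
    do.call(capture_row, c(shared, list(sample = "T1", mouse = "M1",
                                        max_tumour_vaf = 0.04, normal_vaf = 0))),
    do.call(capture_row, c(shared, list(sample = "T2", mouse = "M2",
                                        max_tumour_vaf = 0.04, normal_vaf = 0))),
    capture_row(sample = "T3", mouse = "M3", pos = 950L,
                max_tumour_vaf = 0.04, normal_vaf = 0),   # private: rule 8 inert
    capture_row(sample = "T4", mouse = "M4", pos = 960L,
                max_tumour_vaf = 0.3, normal_vaf = 0.05)  # private: rule 8 inert
  ))
  res <- filter_capture(tab)
  expect_setequal(res$table$sample, c("T3", "T4"))

  # normal-VAF clause alone removes a recurrent variant
  tab2 <- as_mutation_table(rbind(
    do.call(capture_row, c(shared, list(sample = "T1", mouse = "M1"))),
    do.call(capture_row, c(shared, list(sample = "T2", mouse = "M2",
                                        normal_vaf = 0.02)))
  ))
  res2 <- filter_capture(tab2)
  expect_equal(res2$table$sample, "T1")
})

test_that("packaged capture toy table retains exactly the hand-derived row", {
  path <- system.file("extdata", "capture_toy.tsv", package = "cryptsel")
  tab <- read_mutation_table(path, dialect = "capture")
  res <- filter_capture(tab)
  expect_equal(res$table$sample, "T1")
  rem <- setNames(res$removals$removed, res$removals$rule)
  expect_equal(unname(rem[c("alt_support_baq", "gapped_normals", "mappability",
                            "somatic_normals", "recurrent_low_vaf")]),
               c(1L, 1L, 1L, 1L, 1L))
  # idempotence: filtering the filtered table removes nothing
  res2 <- filter_capture(res$table)
  expect_equal(nrow(res2$table), nrow(res$table))
  expect_true(all(res2$removals$removed == 0L))
})

test_that("filter outcome is invariant to row order", {
  path <- system.file("extdata", "capture_toy.tsv", package = "cryptsel")
  tab <- read_mutation_table(path, dialect = "capture")
  set.seed(4)
  perm <- sample(nrow(tab))
  shuffled <- as_mutation_table(as.data.frame(tab)[perm, ])
  expect_setequal(filter_capture(shuffled)$table$sample,
                  filter_capture(tab)$table$sample)
})

test_that("missing support column is a configuration error naming the rule", {
  tab <- as_mutation_table(capture_row())
  tab$mappability <- NULL
  expect_error(filter_capture(tab), "mappability")
  tab2 <- as_mutation_table(capture_row())
  tab2$normal_vaf <- NULL
  expect_error(filter_capture(tab2), "recurrent")
})

test_that("rows lacking optional per-row fields skip only those rules", {
  # a recurrent variant whose VAF annotations are missing: the lymphoid rule
  # cannot be evaluated, so it is skipped (logged) and the rows are kept
  rows <- rbind(
    capture_row(sample = "T1", mouse = "M1", normal_vaf = NA,
                max_tumour_vaf = NA),
    capture_row(sample = "T2", mouse = "M2", normal_vaf = NA,
                max_tumour_vaf = NA))
  expect_message(res <- filter_capture(as_mutation_table(rows)), "skipped")
  expect_equal(nrow(res$table), 2L)
})

test_that("amplicon filter applies AF, amplicon and read-support thresholds", {
  path <- system.file("extdata", "amplicon_toy.tsv", package = "cryptsel")
  tab <- read_mutation_table(path, dialect = "amplicon")
  res <- filter_amplicon(tab)
  expect_setequal(res$table$sample, c("A2", "A3", "A4"))  # AF >= 0.01 inclusive
  # idempotent
  expect_true(all(filter_amplicon(res$table)$removals$removed == 0L))

  one_amp <- data.frame(sample = "X", chrom = "c", pos = 1L, ref = "C",
                        alt = "T", caller_pass = TRUE, vaf = 0.2,
                        n_amplicons = 1L, mutant_reads = 20L)
  expect_equal(nrow(filter_amplicon(as_mutation_table(one_amp,
                                                      "amplicon"))$table), 0L)
  ok <- one_amp; ok$n_amplicons <- 2L; ok$mutant_reads <- 5L; ok$vaf <- 0.02
  expect_equal(nrow(filter_amplicon(as_mutation_table(ok, "amplicon"))$table), 1L)
})

test_that("retained plus removed rows account for the whole input", {
  path <- system.file("extdata", "capture_toy.tsv", package = "cryptsel")
  tab <- read_mutation_table(path, dialect = "capture")
  res <- filter_capture(tab)
  expect_gte(sum(res$removals$removed), res$n_input - res$n_retained)
  expect_equal(res$n_input, nrow(tab))
})
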