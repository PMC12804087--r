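test_that("registry filtering removes driver-heavy and APC-heavy samples", {
  samples <- data.frame(
    sample = c("S1", "S2", "S3"),
    n_other_drivers = c(3L, 0L, 1L),   # S1: ATM + BRAF + PTEN
    n_apc = c(2L, 3L, 2L),             # S2: three APC hits; S3: 2 APC + SMAD4
    stringsAsFactors = FALSE)
  res <- registry_filter(samples)
  expect_equal(res$samples$sample, "S3")
  expect_equal(res$exclusions, c(driver_excess = 1L, apc_excess = 1L))
  # idempotent and order-independent
  again <- registry_filter(res$samples)
  expect_equal(again$samples, res$samples)
  expect_equal(sum(again$exclusions), 0L)
  perm <- registry_filter(samples[c(3, 1, 2), ])
  expect_setequal(perm$samples$sample, res$samples$sample)
})

test_that("retention stratification gives per-stratum percentages and tests", {
  reps <- default_apc_repeats()
  samples <- data.frame(
    apc1_residue = c(rep(1400L, 4), rep(1300L, 5)),  # scores 2 and 1
    apc2_residue = NA_integer_,
    kras_mut = c(rep(TRUE, 4), rep(FALSE, 5)))
  res <- retention_by_kras(samples, reps)
  expect_equal(res$percent["2", "KRAS-mutant"], 100)
  expect_equal(res$percent["1", "KRAS-WT"], 100)
  expect_equal(colSums(res$percent), c(`KRAS-WT` = 100, `KRAS-mutant` = 100))
  # identical strata: all Fisher p-values 1
  same <- data.frame(apc1_residue = rep(1400L, 8), apc2_residue = NA_integer_,
                     kras_mut = rep(c(TRUE, FALSE), 4))
  expect_true(all(retention_by_kras(same, reps)$tests$p == 1))
  # empty stratum is flagged
  solo <- data.frame(apc1_residue = 1400L, apc2_residue = NA_integer_,
                     kras_mut = TRUE)
  expect_warning(retention_by_kras(solo, reps), "empty stratum")
})

test_that("a known retention shift between strata is detected", {
  polyps <- gen_polyps(n = 600, seed = 31)
  res <- retention_by_kras(polyps, default_apc_repeats())
  # generator centres KRAS-mutant polyps one repeat higher
  expect_lt(res$tests$p[res$tests$score == 2], 0.01)
  expect_gt(res$percent["2", "KRAS-mutant"], res$percent["2", "KRAS-WT"])
})

test_that("LOH halving applies to the top-ranked VAF only, strictly above 0.5", {
  m <- data.frame(vaf = c(0.8, 0.3), residue = c(1200L, 700L))
  adj <- halve_loh_vaf(m)
  expect_equal(adj$vaf, c(0.4, 0.3))
  expect_equal(adj$rank, c(1L, 2L))
  # boundary: exactly 0.5 is untouched
  expect_equal(halve_loh_vaf(data.frame(vaf = 0.5, residue = 1L))$vaf, 0.5)
  # rank 2 above 0.5 is untouched
  m2 <- data.frame(vaf = c(0.9, 0.7), residue = c(100L, 200L))
  expect_equal(halve_loh_vaf(m2)$vaf, c(0.45, 0.7))
  # tie: the more N-terminal mutation ranks first
  tie <- halve_loh_vaf(data.frame(vaf = c(0.6, 0.6), residue = c(900L, 300L)))
  expect_equal(tie$rank, c(2L, 1L))
  expect_equal(tie$vaf, c(0.6, 0.3))
})

test_that("chronology calls compare Wilson intervals and are antisymmetric", {
  call <- chronology_call(40, 100, 5, 100)
  expect_equal(call$verdict, "APC-first")
  # interval bounds match an independent Wilson construction
  oracle <- wilson_oracle(40, 100)
  expect_equal(unname(call$apc_ci), unname(oracle), tolerance = 1e-9)
  expect_equal(chronology_call(5, 100, 40, 100)$verdict, "KRAS-first")
  expect_equal(chronology_call(20, 100, 20, 100)$verdict, "unresolved")
  missing <- chronology_call(10, NA, 5, 100)
  expect_equal(missing$verdict, "unresolved")
  expect_equal(missing$reason, "missing read depth")
  cp <- chronology_call(40, 100, 5, 100, method = "clopper-pearson")
  expect_equal(cp$verdict, "APC-first")
})

test_that("chronology calls are conservative under equal true VAFs", {
  set.seed(41)
  n <- 400L
  resolved <- vapply(seq_len(n), function(i) {
    a <- stats::rbinom(1, 200, 0.3)
    k <- stats::rbinom(1, 200, 0.3)
    chronology_call(a, 200, k, 200)$verdict != "unresolved"
  }, logical(1))
  expect_lt(mean(resolved), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("deep coverage recovers a configured APC-first chronology", {
  polyps <- gen_polyps(n = 400, p_apc_first = 1, depth_mean = 2000, seed = 43)
  kras <- polyps[polyps$kras_mut, ]
  verdicts <- vapply(seq_len(nrow(kras)), function(i) {
    chronology_call(kras$apc1_alt[i], kras$apc1_depth[i],
                    kras$kras_alt[i], kras$kras_depth[i])$verdict
  }, character(1))
  resolved <- verdicts[verdicts != "unresolved"]
  expect_gt(length(resolved), 0)
  expect_gt(mean(resolved == "APC-first"), 0.9)
})

test_that("expected stop profile follows stop-opportunity under a flat signature", {
  cds <- random_cds(60, seed = 47)
  prof <- expected_stop_profile(cds, flat_spectrum())
  e <- enumerate_snvs(cds)
  ns <- e[e$class == "nonsense" & !is.na(e$channel), ]
  counts <- vapply(seq_len(cds$protein_length),
                   function(r) sum(ns$residue == r), numeric(1))
  # flat signature: profile proportional to the stop-generating SNV count
  expect_equal(prof$expected / max(prof$expected), counts / max(counts))
  expect_true(all(prof$expected[counts == 0] == 0))
  expect_equal(max(prof$expected_norm), 1)
})

test_that("CpG-weighted signature concentrates stop mass on CGA codons", {
  # CGA (Arg) -> TGA by C>T at a CpG; CAA -> TAA is the unweighted comparator
  cds <- cds_fasta("ATGCGAACTCAAACTTAA", gene = "cpg")
  prof <- expected_stop_profile(cds, synthetic_colon_signature())
  expect_equal(which.max(prof$expected), 2L)   # the CGA residue
  expect_equal(prof$expected_norm[2], 1)
  expect_gt(prof$expected[2] / prof$expected[4], 5)
})
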