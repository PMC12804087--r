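test_that("context folding is pyrimidine-centric and idempotent", {
  expect_equal(fold_context("C", "T", "A", "C"), "A[C>T]C")   # stays as is
  expect_equal(fold_context("G", "A", "T", "A"), "T[C>T]A")   # revcomp fold
  expect_equal(fold_context("A", "G", "C", "T"), "A[T>C]G")
  # purine- and pyrimidine-strand descriptions of the same event agree
  set.seed(11)
  for (i in 1:25) {
    ref <- sample(c("C", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    f5 <- sample(c("A", "C", "G", "T"), 1); f3 <- sample(c("A", "C", "G", "T"), 1)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    expect_equal(fold_context(comp[[ref]], comp[[alt]], comp[[f3]], comp[[f5]]),
                 fold_context(ref, alt, f5, f3))
  }
  expect_error(fold_context("C", "C", "A", "A"), "differ")
  expect_error(fold_context("N", "A", "A", "A"), "non-ACGT")
})

test_that("channel set is the 96 COSMIC classes", {
  ch <- sbs96_channels()
  expect_length(ch, 96L)
  expect_equal(anyDuplicated(ch), 0L)
  expect_equal(ch[1], "A[C>A]A")
  expect_true(all(substr(ch, 3, 3) %in% c("C", "T")))
})

test_that("opportunity counting slides interior windows and folds centres", {
  expect_equal(count_opportunities("ACTGA")[c("ACT", "CTG", "TCA")],
               c(ACT = 1L, CTG = 1L, TCA = 1L))
  expect_equal(sum(count_opportunities("ACTGA")), 3L)
  expect_equal(unname(count_opportunities("AAA")["TTT"]), 1L)
  # additivity over sequences
  one <- count_opportunities("ACGTACGTAC")
  expect_equal(count_opportunities(c("ACGTACGTAC", "ACGTACGTAC")), one * 2L)
  expect_error(count_opportunities(character(0)), "territory")
})

test_that("folded opportunities are strand-symmetric", {
  set.seed(21)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    expect_equal(count_opportunities(s), count_opportunities(rc(s)))
  }
})

test_that("signature estimation divides counts by opportunities and renormalises", {
  # channels on distinct trinucleotides so opportunities differ: ACA vs CCA
  passengers <- data.frame(
    ref = "C", alt = "A",
    flank5 = rep(c("A", "C"), each = 10), flank3 = "A",
    stringsAsFactors = FALSE)
  opp <- c(ACA = 100, CCA = 50)
  sig <- estimate_signature(passengers, opp)
  expect_equal(signature_frequency(sig, "A[C>A]A"), 1 / 3)
  expect_equal(signature_frequency(sig, "C[C>A]A"), 2 / 3)
  expect_equal(sum(sig$frequency, na.rm = TRUE), 1)

  solo <- estimate_signature(passengers[1:10, ], c(ACA = 100))
  expect_equal(signature_frequency(solo, "A[C>A]A"), 1)

  # zero opportunity for a mutated channel is a territory inconsistency
  expect_error(estimate_signature(passengers, c(ACA = 100)), "zero opportunity")
})

test_that("signature estimation is invariant to row order and batching", {
  set.seed(5)
  cds <- random_cds(120, seed = 5)
  cat <- gen_mutation_catalog(cds, flat_spectrum(), 400, seed = 6)
  opp <- count_opportunities(cds$seq)
  full <- estimate_signature(cat, opp)
  perm <- cat[sample(nrow(cat)), ]
  expect_equal(estimate_signature(perm, opp)$frequency, full$frequency)
  # batch counts then pool: counts are additive
  a <- estimate_signature(cat[1:200, ], opp)
  b <- estimate_signature(cat[201:400, ], opp)
  expect_equal(a$count + b$count, full$count)
})

test_that("exclusion rules purge driver genes before counting", {
  passengers <- data.frame(
    gene = c("Apc", "Apc", "Ctnnb1", "Ros1"),
    class = c("nonsense", "synonymous", "missense", "missense"),
    ref = "C", alt = "T", flank5 = "A", flank3 = "C",
    stringsAsFactors = FALSE)
  excl <- data.frame(gene = c("Apc", "Ctnnb1", "Ros1"),
                     class = c("nonsense", "any", "any"),
                     stringsAsFactors = FALSE)
  sig <- estimate_signature(passengers, c(ACC = 10), exclusions = excl)
  expect_equal(attr(sig, "n_excluded"), 3L)
  expect_equal(sig$count[sig$channel == "A[C>T]C"], 1L)
})

test_that("catalog drawn from a known signature recovers it (simulation oracle)", {
  cds <- random_cds(300, seed = 7)
  set.seed(8)
  w <- stats::rgamma(96, shape = 1)
  truth <- spectrum_from_frequencies(setNames(w, sbs96_channels()))
  n <- 10000L
  cat <- gen_mutation_catalog(cds, truth, n, seed = 9)
  opp <- count_opportunities(cds$seq)
  # per-channel draw probability under the generative model
  tri <- channel_trinucleotide(sbs96_channels())
  sites <- ifelse(tri %in% names(opp), opp[tri], 0)
  p <- truth$frequency * sites
  p <- p / sum(p)
  est <- estimate_signature(cat, opp)
  # counts are multinomial; the per-channel 3-SE error rate is applied
  # family-wise across the 96 simultaneous comparisons (otherwise a correct
  # implementation is expected to trip one channel by chance alone)
  z_crit <- stats::qnorm(1 - (2 * stats::pnorm(-3)) / 2 / 96)
  dev <- abs(est$count - n * p)
  tol <- z_crit * sqrt(n * p * (1 - p))
  expect_true(all(dev <= tol + 1e-9))
  # aggregate goodness of fit: no systematic distortion
  keep <- p > 0
  # some low-opportunity channels have small expected counts: simulate the
  # reference distribution instead of relying on the asymptotic chi-squared
  gof <- suppressWarnings(
    stats::chisq.test(est$count[keep], p = p[keep] / sum(p[keep]),
                      simulate.p.value = TRUE, B = 500))
  expect_gt(gof$p.value, 1e-4)
  # and the opportunity-normalised frequencies track the truth
  keep <- !is.na(est$frequency) & p > 0
  expect_gt(stats::cor(est$frequency[keep], truth$frequency[keep]), 0.97)
})

test_that("outcome-set rescaling renormalises and is projectively consistent", {
  sig <- spectrum_from_frequencies(c("A[C>T]C" = 0.02, "T[C>T]C" = 0.02,
                                     "A[C>T]G" = 0.01))
  out <- rescale_to_outcome_set(sig, c(x = "A[C>T]C", y = "T[C>T]C",
                                       z = "A[C>T]G"))
  expect_equal(setNames(out$probability, out$outcome),
               c(x = 0.4, y = 0.4, z = 0.2))
  expect_equal(rescale_to_outcome_set(sig, c(x = "A[C>T]C"))$probability, 1)
  # restricting twice equals restricting once
  sub <- rescale_to_outcome_set(sig, c(x = "A[C>T]C", y = "T[C>T]C"))
  expect_equal(setNames(sub$probability, sub$outcome), c(x = 0.5, y = 0.5))
  expect_error(rescale_to_outcome_set(sig, c(q = "A[T>A]A")), "zero")
})

test_that("signature tables round-trip through TSV", {
  sig <- synthetic_colon_signature()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, path)
  back <- read_signature_tsv(path)
  expect_equal(back$frequency, sig$frequency, tolerance = 1e-12)
})
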