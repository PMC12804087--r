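toy_cds <- function() cds_fasta("ATGCAATGGTAA", gene = "toy")

test_that("enumeration yields exactly 3 records per CDS position", {
  cds <- toy_cds()
  e <- enumerate_snvs(cds)
  expect_equal(nrow(e), 3L * nchar(cds$seq))
  expect_true(all(table(e$cds_pos) == 3L))
  expect_true(all(e$residue == (e$cds_pos - 1L) %/% 3L + 1L))
})

test_that("stop-gain outcomes per codon match the genetic code", {
  e <- enumerate_snvs(toy_cds())
  # codon 2 CAA: only C>T gives TAA
  expect_equal(sum(e$class == "nonsense" & e$residue == 2L), 1L)
  # codon 3 TGG: TAG and TGA
  expect_equal(sum(e$class == "nonsense" & e$residue == 3L), 2L)
  # stop-loss at the terminal codon is "other", never nonsense
  expect_true(all(e$class[e$ref_aa == "*" & e$alt_aa != "*"] == "other"))
  # start-loss is "other"
  expect_true(all(e$class[e$residue == 1L & e$alt_aa != e$ref_aa] == "other"))
})

test_that("degron-style codon gives the expected change and channel", {
  # ACC codon with 5' A and 3' C context: middle C>T is T->I via A[C>T]C
  cds <- cds_fasta("ATGGCAACCTAA", gene = "deg")
  e <- enumerate_snvs(cds)
  hit <- e[e$cds_pos == 8L & e$alt == "T", ]
  expect_equal(hit$ref_aa, "T")
  expect_equal(hit$alt_aa, "I")
  expect_equal(hit$channel, "A[C>T]C")
  expect_equal(aa_change_label(hit), "T3I")
})

test_that("end positions get no fabricated context unless padding is supplied", {
  e <- enumerate_snvs(toy_cds())
  n <- nchar(toy_cds()$seq)
  expect_true(all(is.na(e$channel[e$cds_pos %in% c(1L, n)])))
  expect_true(all(!is.na(e$channel[!e$cds_pos %in% c(1L, n)])))
  ep <- enumerate_snvs(toy_cds(), end_policy = "pad", pad = c("G", "G"))
  expect_true(all(!is.na(ep$channel)))
})

test_that("enumeration agrees with the re-translation oracle", {
  for (seed in c(31, 32, 33)) {
    cds <- random_cds(sample(10:60, 1), seed = seed)
    e <- enumerate_snvs(cds)
    o <- brute_force_consequences(cds)
    key <- function(d) order(d$cds_pos, d$alt)
    e <- e[key(e), ]; o <- o[key(o), ]
    expect_equal(e$class, o$class)
    expect_equal(e$residue, o$residue)
    expect_equal(e$ref_aa, o$ref_aa)
    expect_equal(e$alt_aa, o$alt_aa)
  }
})

test_that("expected missense probabilities match brute-force enumeration", {
  # uniform signature: probability proportional to the number of generating
  # SNVs with assignable context
  cds <- cds_fasta("ATGATCGCATAA", gene = "two")   # Ile and Ala codons
  sig <- flat_spectrum()
  probs <- expected_missense_probs(cds, sig, codons = c(2L, 3L))
  e <- enumerate_snvs(cds)
  e <- e[e$residue %in% c(2L, 3L) & e$class == "missense" & !is.na(e$channel), ]
  hand <- table(aa_change_label(e))
  hand <- hand / sum(hand)
  expect_equal(setNames(probs$probability, probs$outcome),
               setNames(as.numeric(hand), names(hand)))
  expect_equal(sum(probs$probability), 1)
  # I35S-style change: ATC -> AGC appears among the outcomes
  expect_true("I2S" %in% probs$outcome)
})

test_that("signature mass on one channel forces its outcome probability to 1", {
  cds <- cds_fasta("ATGGCAACCTAA", gene = "deg")
  sig <- spectrum_from_frequencies(c("A[C>T]C" = 1))
  probs <- expected_missense_probs(cds, sig, codons = 3L)
  expect_equal(probs$probability[probs$outcome == "T3I"], 1)
})

test_that("per-bin stop mass is renormalised, additive, and bounded by the protein", {
  cds <- toy_cds()
  sig <- flat_spectrum()
  bins <- bin_scheme(c("b1", "b2"), c(2L, 3L), c(2L, 3L))
  p <- expected_stop_probs_by_bin(cds, sig, bins)
  expect_equal(p$probability, c(1 / 3, 2 / 3))   # 1 vs 2 stop-generating SNVs
  # merging the bins sums the unnormalised mass
  merged <- expected_stop_probs_by_bin(cds, sig, bin_scheme("b", 2L, 3L))
  expect_equal(merged$frequency, sum(p$frequency))
  # a bin beyond the protein is an error
  expect_error(expected_stop_probs_by_bin(cds, sig, bin_scheme("b", 2L, 50L)),
               "beyond protein length")
  # zero signature mass on a bin's stop channels gives probability 0
  sig0 <- spectrum_from_frequencies(c("G[C>T]A" = 1))  # generates codon-2 TAA only
  p0 <- expected_stop_probs_by_bin(cds, sig0, bins)
  expect_equal(p0$probability, c(1, 0))
})

test_that("unnormalised stop mass is invariant to how a prefix is partitioned", {
  cds <- random_cds(40, seed = 44)
  sig <- flat_spectrum()
  one <- expected_stop_probs_by_bin(cds, sig, bin_scheme("all", 1L, 30L))
  two <- expected_stop_probs_by_bin(cds, sig,
                                    bin_scheme(c("x", "y"), c(1L, 16L), c(15L, 30L)))
  expect_equal(sum(two$frequency), one$frequency)
})
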