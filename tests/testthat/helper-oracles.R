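# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: consequences are obtained by mutating the full
# CDS and re-translating with Biostrings, interval bounds come from
# stats::prop.test, and chi-squared tail probabilities from the normal CDF.

# Re-translate every possible SNV of a CDS and classify the change by
# comparing whole proteins (the enumeration module never sees this path).
brute_force_consequences <- function(cds) {
  seq <- cds$seq
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- rep(seq_len(n), each = 3L)
  alt <- unlist(lapply(chars, function(b) setdiff(c("A", "C", "G", "T"), b)))
  mut <- vapply(seq_along(pos), function(i) {
    s <- seq
    substr(s, pos[i], pos[i]) <- alt[i]
    s
  }, character(1))
  prots <- as.character(Biostrings::translate(Biostrings::DNAStringSet(mut),
                                              no.init.codon = TRUE))
  refp <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(seq),
                          no.init.codon = TRUE)), "")[[1]]
  res <- lapply(prots, function(p) {
    pc <- strsplit(p, "")[[1]]
    d <- which(pc != refp)
    if (length(d) == 0L) return(list(residue = NA_integer_,
                                     ref_aa = NA_character_,
                                     alt_aa = NA_character_,
                                     class = "synonymous"))
    d <- d[1L]
    cls <- if (refp[d] == "*") "other"
           else if (pc[d] == "*") "nonsense"
           else if (d == 1L) "other"
           else "missense"
    list(residue = d, ref_aa = refp[d], alt_aa = pc[d], class = cls)
  })
  out <- data.frame(cds_pos = pos, ref = chars[pos], alt = alt,
                    residue = vapply(res, `[[`, integer(1), "residue"),
                    ref_aa = vapply(res, `[[`, character(1), "ref_aa"),
                    alt_aa = vapply(res, `[[`, character(1), "alt_aa"),
                    class = vapply(res, `[[`, character(1), "class"),
                    stringsAsFactors = FALSE)
  # synonymous changes have no protein diff; recover the residue from the position
  syn <- out$class == "synonymous"
  out$residue[syn] <- (out$cds_pos[syn] - 1L) %/% 3L + 1L
  out$ref_aa[syn] <- refp[out$residue[syn]]
  out$alt_aa[syn] <- out$ref_aa[syn]
  out
}

# Wilson score interval without the package's closed form
wilson_oracle <- function(x, n, alpha = 0.05) {
  ci <- suppressWarnings(stats::prop.test(x, n, conf.level = 1 - alpha,
                                          correct = FALSE)$conf.int)
  c(lower = ci[1], upper = ci[2])
}

# two-sided tail of a 1-d.f. chi-squared statistic via the normal CDF
chisq1_p_oracle <- function(chi2) 2 * stats::pnorm(-sqrt(chi2))

# plain-string reverse complement for property tests
rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
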