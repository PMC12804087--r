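---
title: "Measuring selection on intestinal driver mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection on intestinal driver mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsel)
```

`cryptsel` quantifies selection acting on cancer-driver mutations in
mutagenized intestinal epithelium. The central question it addresses is
whether a driver mutation's abundance among tumours reflects positive
selection or merely a high underlying mutation rate — and, symmetrically,
whether its disappearance under a delayed "rescue" protocol reflects negative
selection or ordinary neutral stem-cell drift. This vignette describes the
models, the tunable parameters, the synthetic-data generator, and the design
decisions taken where the methodology left genuine choices open.

## Mutational signatures with opportunity normalisation

Every somatic SNV is classified into one of 96 channels by its substitution
(written with a pyrimidine reference base; purine-centred events are
reverse-complemented together with their flanks) and its two flanking bases,
the standard SBS96 convention. Raw channel counts confound the mutagen's
chemistry with the sequence composition of the territory that was sequenced,
so counts are divided by per-trinucleotide *opportunities* — the number of
occurrences of each channel's trinucleotide in the territory
(`count_opportunities()`) — and renormalised to sum to one. The resulting
frequencies are per-context rates: what the mutagen does, independent of how
often it gets the chance.

Passenger selection matters here: `estimate_signature()` accepts exclusion
rules (gene, consequence-class pairs) so that positively selected driver
mutations (APC truncations, beta-catenin exon-3 missense changes and similar)
do not contaminate the estimate of the mutagenic process. Channels whose
trinucleotide is absent from the territory are dropped from the
normalisation rather than imputed — an opportunity of zero makes the rate
undefined, and a mutation observed in such a channel is treated as an error
(the territory and the catalog disagree).

Flanking context comes exclusively from supplied sequence. At the ends of a
coding sequence the default is to *exclude* the terminal positions from
channel assignment rather than fabricate context; padding bases can be
supplied where the genomic neighbourhood is known.

## From signature to expectation: consequence enumeration

`enumerate_snvs()` lists all `3 * length(cds)` possible SNVs of a coding
sequence with their protein consequences under the standard nuclear code.
Expected probabilities for any outcome set follow by summing signature
frequencies over each outcome's generating channels and renormalising over
the set (`rescale_to_outcome_set()`):

* missense outcomes at selected codons, e.g. the seven beta-catenin
  phospho-degron codons (`expected_missense_probs()`);
* truncating (stop-gain) mutations per APC domain bin
  (`expected_stop_probs_by_bin()`); splice and stop-loss events are accepted
  in observed tables but contribute nothing to expected stop mass, which is
  computed from stop-generating contexts only;
* the per-residue expected stop profile of a protein
  (`expected_stop_profile()`), normalised to its maximum.

The default outcome set for degron analyses is the missense outcomes at the
degron codons themselves. Whether to admit synonymous or other changes before
rescaling is surfaced as the outcome-set argument rather than hard-coded,
because either convention is defensible and the choice changes the
normalising constant.

The enumeration is verified against an independent oracle that mutates the
full sequence and re-translates it, on dozens of random coding sequences per
test run.

## The O/E selection readout

For observed class counts and expected probabilities, `oe_table()` reports
the observed/expected ratio per class with a class-vs-rest chi-squared
statistic on one degree of freedom:

$$\chi^2 = \frac{(O-E)^2}{E} + \frac{((N-O)-(N-E))^2}{N-E}, \qquad E = pN.$$

This is deliberately a per-class test, not an omnibus test, and carries no
continuity correction; the two-sample proportion comparison
(`proportion_test()`) is the place where the continuity-corrected test (or a
Fisher exact test) applies. No multiple-testing correction is made;
significance is displayed at the conventional three-star tiers. Classes with
zero expectation or zero observations are flagged rather than dropped.
Fold changes are reported as signed log2 of O/E, with exact depletion
rendered as `-Inf`.

Bin *combinations* model the two-hit structure of APC inactivation: with
per-bin probabilities $p_X$, an unordered heterotypic pair XY has expected
probability $2 p_X p_Y$ and a homotypic pair $p_X^2$, so the 15 combinations
over five bins sum to one. The multinomial factor 2 is the probabilistically
correct expectation for unordered pairs and is the default; a switch
(`pair_factor = FALSE`) reproduces the bare product for comparison with
conventions that omit it.

## Neutral drift as the decay null

A labelled clone of $k$ stem cells in a crypt niche of $N_s$ is modelled as a
birth–death chain on $\{0, \dots, N_s\}$ with absorbing boundaries: between
them the clone expands at rate $\lambda\, p_r\, w(k)$ and contracts at rate
$\lambda (1-p_r)\, w(k)$. Parameters and defaults:

| parameter | meaning | default |
|---|---|---|
| $N_s$ | stem cells per crypt | 5 |
| $\lambda$ | replacement rate (events/day) | 0.1 |
| $p_r$ | probability a replacement expands the clone | 0.5 (neutral) |
| $\tau$ | start of the reporting grid (days) | 1, grid to day 30 by 0.5 |
| $w(k)$ | contact kernel | $w(k)=1$ |

The default kernel $w(k)=1$ reflects the boundary-driven one-dimensional
niche picture: a contiguous clone on a ring has two boundaries regardless of
its size, so the replacement propensity does not grow with $k$. The
per-cell-rate variant $w(k)=k$ is available (`kernel = "percell"`); both
conventions appear in the neutral-drift literature and share the key neutral
invariants (fixation probability $k/N_s$, long-time surviving fraction
$1/N_s$ from a single cell).

`drift_oracle()` solves the chain exactly by exponentiating the
$(N_s{+}1)$-state generator — no time-discretisation error — and
`drift_simulate()` is an independent Gillespie event simulator used to verify
it (and vice versa). The surviving fraction is 1 at $t=0$ by construction;
$\tau$ controls only where the reported grid starts.
`neutral_fraction_at()` evaluates the exact solution at any requested day
rather than interpolating a grid, since the matrix exponential is available
in closed form at any $t$.

Cohort decay is then bookkeeping (`cohort_decay` functions): driver-specific
tumour numbers are sequencing-derived class proportions times mean tumour
counts; remaining proportions divide rescue by priming baselines; and
`decay_test()` compares observed remaining counts against the neutral
expectation with a two-category (remaining/lost) chi-squared test so that
expected counts sum to the baseline. Percent reductions are rounded to the
nearest integer by default, with a nearest-ten rendering available because
headline summaries are often quoted at that precision.

## Human APC arm

Registry-style samples are filtered to at most two APC mutations and at most
two additional drivers from a ten-gene set (`registry_filter()`). Each
sample's APC 20-amino-acid-repeat *retention score* (0–7) counts the repeats
wholly upstream of its most C-terminal truncation; distributions are
stratified by KRAS status and compared per score with Fisher exact tests
(`retention_by_kras()`).

For mutation chronology, the top-ranked APC VAF is halved when it exceeds
0.5 (presumptive loss of heterozygosity, `halve_loh_vaf()`; ties in VAF rank
the more N-terminal mutation first, a determinism choice), and
`chronology_call()` compares binomial confidence intervals of the APC and
KRAS VAFs: APC-first only if the APC interval lies entirely above the KRAS
interval at the requested confidence. Wilson score intervals are the default
(well-behaved at modest depth); Clopper–Pearson is available. Under equal
true VAFs the resolved-call rate is at most the nominal error level, which
the test suite checks by simulation.

The repeat intervals and mouse domain-bin boundaries ship as editable TSV
data. The bin boundaries beyond the Armadillo span (B, residues 337–765) and
the repeat-region bin are documented approximations, and the human repeat
coordinates are approximate standard-annotation values; both are expected to
be overridden when exact coordinates matter. The packaged normal-colon
signature is a synthetic CpG>TpG-weighted stand-in (clearly labelled as
such) and should be replaced by measured frequencies for real-data work.

## What the synthetic generator does and does not emulate

`gen_mutation_catalog()` draws SNVs over a coding sequence with probability
proportional to the signature frequency of the folded channel times a
per-outcome selection multiplier — the generative model under which an
opportunity-normalised signature is exactly recoverable, and under which an
injected multiplier $s$ on a rare outcome surfaces downstream as
$O/E \approx s$. Support fields are drawn so both filter dialects are
exercisable. `gen_cohorts()` draws overdispersed (negative-binomial)
per-mouse tumour counts on the scale of the mouse experiments (hundreds of
tumours for strong priming fields, a handful for controls), assigns driver
classes from a mixture, and thins rescue cohorts through the drift model at
a configurable per-class bias. `gen_polyps()` encodes a configured true
APC/KRAS chronology by drawing the earlier mutation's cancer-cell fraction
first and bounding the later one by it, with binomial read counts.

The generator reproduces the *statistical structure* the analysis assumes,
not real data: no linkage between mutations in a tumour, no copy-number
variation beyond the LOH VAF convention, no sequencing artefacts beyond what
the filter fields encode, independent clones rather than spatially
interacting crypts, and synthetic rather than real coding sequences. Passing
tests therefore demonstrate correctness of the machinery and calibration of
its tests under the assumed model — not that real tumours satisfy the model.

## Numerical choices and problem sizes

Tolerances in the test suite are derived from the sampling distributions
involved: binomial/multinomial three-standard-error bounds for simulation
against exact solutions (applied family-wise where many channels are tested
simultaneously), and analytic identities checked to numerical precision.
Simulation sizes were chosen to keep the default test run fast while leaving
comfortable statistical margins: 10,000 clones per drift-bias setting, 8,000
mutations for multiplier recovery, and 1,000 replicates for test-size
calibration. The matrix exponential is computed densely; the generator has at
most nine states in any analysis shipped here, so numerical conditioning is
not a concern.

Boundary semantics follow the printed conventions they implement: filter
thresholds are inclusive exactly as stated (allele fraction ≥ 0.01, maximum
VAF ≤ 0.05), recurrence filters are strict (`n > 9` keeps 10), and the LOH
halving applies strictly above VAF 0.5.

## Known limitations

* Splice-site driver mutations cannot be enumerated from a CDS alone; they
  are carried through observed tables but never contribute expected mass.
* The capture filter's recurrence rule needs mouse-of-origin annotations;
  rows lacking optional fields skip only the rules that need them, which is
  logged but means sparse annotations weaken filtering silently beyond that
  log.
* The drift model is zero-dimensional: no crypt fission, no spatial
  structure, no interaction between clones.
* Chronology calls from bulk VAFs are conservative by design; most calls on
  realistic depths are unresolved, and resolved calls depend on the
  LOH-adjustment convention.
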