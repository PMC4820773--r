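---
title: "Designing and validating MIP marker panels with mipkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating MIP marker panels with mipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipkit)
```

## The problem

Molecular Inversion Probes (MIPs) capture short, predefined genomic targets
at very high specificity: a single-stranded 70-nt oligo carries two terminal
arms complementary to the sequence flanking a target of roughly 112 bp; after
hybridization, polymerase gap-fill and ligation circularize the probe around
a copy of the target, which is then amplified and sequenced. Panels of
hundreds of such probes fill the methodological gap between multiplex PCR
(high specificity, low multiplexing) and hybridization capture (megabase
targets, heavy protocols).

In organisms without a sequenced genome the probes must be designed from a
transcriptome assembly, while genotyping happens on genomic DNA. This creates
the central design constraint `mipkit` addresses: **a probe whose footprint
crosses an exon-exon junction in the transcript will straddle an intron in
the genome and capture nothing**. Exon boundaries therefore have to be
inferred in each transcript before any probe is placed, here by local
alignment to ortholog gene models from an annotated relative (amphibian
newt transcripts against *Xenopus*-like models is the motivating setting,
with roughly 300 My of divergence).

The second half of the toolkit treats the panel after sequencing: per-probe
capture performance, pool rebalancing, and — because transcriptome-designed
markers in large, duplication-rich genomes are frequently collapsed
paralogs — formal validation of each marker as a single-copy Mendelian
locus.

## Exon boundary identification

`align_transcript_to_gene()` aligns a transcript locally against every exon
of one gene model (match +1, mismatch −2, gap open 5, gap extend 2) and
keeps hits of ≥60% identity over ≥30 aligned bp. Hits are then chained by
dynamic programming into the colinear, non-overlapping subset maximizing
total alignment score, which resolves spurious secondary hits. Boundaries
fall at the shared endpoint of abutting blocks, or at the midpoint of the
inter-block gap (ties toward the lower coordinate — deterministic and
unbiased); junction gaps wider than 30 bp are flagged low-confidence.

`assign_best_gene()` guards against paralogous gene models: the best gene is
accepted only when the runner-up scores below 80% of it, otherwise the
transcript is `AMBIGUOUS` and excluded from design. Genes are pre-screened
by shared 12-mers before alignment; unrelated sequences of a few kb share
essentially no 12-mers, so the screen only removes gene models that could
not have aligned above threshold anyway, and the result is invariant to
gene order.

The identity/length thresholds and the 80% ambiguity margin are
configuration keys. They are deliberately conservative: a leaked paralog
costs far more downstream (a wasted synthesized probe, a flagged marker)
than a discarded borderline transcript.

## Probe design

A probe targets a window `[s, e)` of the transcript plus strand. The
extension arm (16–20 nt) is the reverse complement of `[e, e + len_ext)`,
the ligation arm (20–24 nt) the reverse complement of `[s − len_lig, s)`,
and the oligo is `ligation arm + 30-nt linker + extension arm` (5′→3′).
Arm lengths are constrained to sum to 40 nt — the only arithmetic consistent
with arms of 16–20 and 20–24 nt, a 30-nt linker and a 70-nt oligo — so
exactly five `(ext, lig)` length pairs exist per window.

`enumerate_targets()` lists every window whose footprint fits inside a
single exon block for the *minimal* arm lengths (20 nt left, 16 nt right);
`design_arms()` then re-checks each of the five sum-40 pairs against the
block and picks the admissible pair minimizing
`|Tm_ext − t_opt| + |Tm_lig − t_opt|` (default `t_opt` 60 °C, matching the
hybridization step of the capture protocol), with ties resolved toward
balanced arms, then the shorter extension arm. The reported probe score is
the negated Tm cost.

Melting temperatures come from unified nearest-neighbor thermodynamics
(the 10 unique dinucleotide stack parameters plus terminal initiation
terms), an entropic salt correction `0.368 (N−1) ln[Na+]` at 50 mM
monovalent salt, and `Tm = 1000 ΔH / (ΔS + R ln(C_T/4)) − 273.15` at 0.25 µM
oligo. The model and its constants are configuration-visible; the unit tests
pin the implementation to an independently transcribed ΔH/ΔS table within
0.1 °C. Because a probe arm is the reverse complement of its plus-strand
site and duplex Tm is strand-symmetric, the package computes window Tm
values from cumulative stack sums along the transcript in O(1) per window.

Two design choices are deliberate extensions beyond the minimal recipe:

* **Boundary margin.** Called boundaries carry a few bp of uncertainty at
  realistic model divergence. `design_candidates()` therefore keeps probe
  footprints 5 bp clear of *internal* boundaries by default (transcript
  ends are exact and get no margin). Without the margin, probes designed
  flush against a boundary that was called a few bp too generously would
  straddle the intron and fail capture.
* **SNP-free arms.** Known polymorphic sites inside an arm footprint
  disqualify a candidate by default (`arms_snp_free`), limiting allele
  dropout from arm-template mismatches.

`rank_and_select()` keeps candidates whose target contains a diagnostic
SNP — a site homozygous within each of two species panels with different
alleles between them, maximally informative for hybrid linkage mapping —
and draws one probe per gene uniformly at random under a mandatory seed.
Candidates are sorted before sampling, so the panel is a pure function of
the candidate set and the seed.

`in_silico_capture_check()` closes the loop: each arm must have exactly one
perfect-match site on the reference (either strand), the ligation site must
sit upstream of the extension site, and the simulated gap-fill between them
must reproduce the designed target exactly. Multi-site arms produce a
warning with the loci; geometry violations are errors.

## The capture simulator

The simulator generates data with the statistical structure the analyses
assume — it is the package's test bed, not a sequencing model. Its defaults
are the study conditions of the motivating experiment: 248 probes,
24 individuals, ~6.4×10⁵ read pairs per sample, 22.7% off-target reads
under an equimolar pool (62.7% after rebalancing), 5.6% total probe
dropout, and per-probe log10 capture efficiencies with SD 0.5.

* `simulate_reference()`: genes of 1–10 exons (binomial around 5) with
  log-normal exon lengths (median 250 bp; introns median 300 bp), half on
  the minus strand, one contig per gene. Transcripts are exact exon
  concatenations; the *gene models* receive 5% substitutions by default,
  emulating an ortholog annotation from a diverged relative. True
  boundaries (cumulative exon lengths) are retained as ground truth.
* `simulate_capture()`: per sample, the on-target total is
  `Binomial(reads, 1 − off_target_fraction)`; on-target reads are
  apportioned multinomially with weights `efficiency × concentration`,
  jittered by a per-sample log-normal effect (σ = 0.15); dropout probes get
  weight zero everywhere.
* `simulate_family()`: an F1 intercross — both parents heterozygous at
  every diagnostic site, offspring 1:2:1. Collapsed paralogs are the
  superposition of two independent loci whose allele union is reported:
  this single mechanism produces both heterozygote excess (7/8 observed
  heterozygotes instead of 1/2 when both loci segregate) and segregation
  distortion, the two signals the validation flags detect. Null alleles
  drop one allele of a heterozygous call with probability `f_null`, so it
  reports homozygous.
* `simulate_population()`: genotype probabilities
  `(p² + Fpq, 2pq(1−F), q² + Fpq)` under inbreeding coefficient `F`, with
  the same contamination mechanisms.

What the simulator does *not* model: read-level errors, PCR duplicates,
mapping artifacts, linked sites within a marker (family sites segregate
independently), allele-frequency spectra of real populations, or the
mechanism by which rebalancing degrades specificity (the off-target
fraction is an input, not an emergent property). Passing tests therefore
demonstrate the correctness and statistical behavior of the *methods* under
their stated assumptions, not the field performance of any particular panel.

## Performance metrics and rebalancing

The Fraction of Mapped Reads (FMR) is a probe's share of all on-target
reads within a sample — columns of the FMR matrix sum to one, making every
downstream statistic invariant to per-sample sequencing depth.
`summarize_uniformity()` reports the per-marker median FMR, the best
"decade" fraction (the maximal share of markers whose medians fit a sliding
10-fold window, each observed median tried as anchor — a reproducible rule
for the "within one order of magnitude" style of claim), and the per-marker
p90/p10 fold across samples using type-7 percentiles (pinned so the
statistic is bit-stable). Markers with zero median FMR are dropouts,
excluded and counted separately.

`select_rebalancing()` implements the concentration adjustment: probes with
median FMR below 0.001 get a 100× boost, the single best probe is reduced
to 0.1×, everything else stays at 1. The paired before/after comparison
uses the Wilcoxon signed-rank test (`V` = sum of positive-difference ranks);
its two-sided p-value is exact for up to 25 pairs, computed from the full
sign-flip distribution via a generating-function convolution over the
(doubled, hence integral) mid-ranks — numerically identical to enumerating
all 2ⁿ sign patterns, which the tests verify at n = 12. Zero differences
are dropped by default (classic policy) with Pratt's as an option. Variance
comparisons use the Brown–Forsythe statistic (ANOVA on |x − median|), and
rank correlations use mid-ranks with the t approximation on n − 2 degrees
of freedom.

## Marker validation

Genotype calls with depth below 16 or genotype quality below 30 phred are
masked as missing (`apply_genotype_filters()`; calls lacking the
annotations pass by default, with a strict mode to fail them).

**Family test.** For each marker with complete family genotypes, every site
polymorphic between the parents is tested: observed offspring genotype
counts against the Mendelian expectation from the parental cross, with an
exact multinomial test. The p-value uses the probability-ordering rule —
the total probability of all outcome vectors no more probable than the
observed one (a 10⁻¹² relative tolerance tames float ties) — by full
enumeration, feasible for the k ≤ 4, n ≤ 200 regime of family data. A
marker is flagged as a potential paralog when its smallest site p-value
falls below 0.015. The threshold corresponds to an exact test size of
0.0137 for a het × het cross with 21 offspring (the discrete null puts no
mass exactly at 0.015); the type-I tests compare simulated flag rates to
this enumerated size, not to the threshold. The companion observation that
an expected genotype class is entirely absent is reported alongside the
flag; a strict mode requires both, but the default treats the absence as
descriptive, since the exact p-value already captures the evidence.

**Population test.** Per population, each polymorphic site gets the exact
conditional Hardy–Weinberg test: given the allele counts, the probability
of `h` heterozygotes is `n!/(n_AA! n_Aa! n_aa!) · 2^h · n_A! n_a!/(2n)!`
over the admissible parity class. Heterozygote-excess p-values across all
sites and populations form one Benjamini–Hochberg family and deficit
p-values another, each at FDR 0.05 — excess flags collapsed paralogs,
deficit flags null alleles, and the two may co-occur on a marker. The
correction families are a design choice (the two alternatives answer
different questions and mixing them would couple their thresholds); sites
with more than two alleles are reduced to the two most frequent, with a
warning.

**Concordance.** Replicate pairs are compared at sites called in both; the
non-reference discrepancy rate excludes pairs where both calls are
homozygous-reference, so it is not diluted by the uninformative majority
class. **Classification** applies the precedence: no reads → uncallable →
monomorphic/untested → family paralog → population flags → validated.

## Diversity and cost

`segregating_sites()` counts sites with ≥2 alleles among called genotypes.
`nucleotide_diversity()` uses the per-site unbiased estimator
`π = (1/L) Σ n_s/(n_s−1) (1 − Σ p_a²)`, with the per-site called chromosome
count `n_s` correcting for missing data, and the denominator `L` equal to
all surveyed sites (monomorphic included) so π lands on the usual per-site
scale; the tests verify its algebraic identity with the mean pairwise
difference on fully-called data. The cost model is two constants — probe
synthesis $9.1 per probe (independent of samples) and reagents $7.4 per
sample (independent of probes) — giving
`per-sample = 9.1 · n_probes / n_samples + 7.4` and per-genotype cost as
its quotient by the panel size. Display rounding is half-up (so $0.0165
prints as $0.017); full precision is kept internally.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance runs are deliberately
desk-scale and were fixed as such: geometry and boundary recovery on 100–200
simulated genes, efficiency recovery at 50 probes × 24 samples × 10⁵ reads,
type-I behavior on 200 simulated families/populations, and power on 60
replicates per contamination type. The efficiency-recovery check disables
dropout, because a dropout probe's FMR carries no information about its
efficiency by construction. Every stochastic routine takes a mandatory
integer seed and restores the caller's RNG state; there is no clock
fallback. Exact tests are cross-checked against independent oracles in the
test suite: outcome enumeration via `dmultinom` for the multinomial test,
combinatorial allele-pairing enumeration for the Hardy–Weinberg
distribution, explicit 2ⁿ sign enumeration for the signed-rank test, and
`car`/`stats` implementations for Levene and Wilcoxon.

## Known limitations

* Alignment is substitution-oriented; transcripts with real indels relative
  to the models (or misassemblies) will shift boundary estimates, and the
  5 bp margin only absorbs small errors.
* The family test treats sites within a marker as independent, which is
  anti-conservative at the marker level when sites are tightly linked; with
  the paper-scale ~7 polymorphic sites per marker the marker-level type-I
  rate exceeds the single-site size accordingly. Validation decisions
  should weigh the per-site p-values the report retains.
* Multiallelic sites are handled by biallelic reduction in the population
  test only.
* The cost model excludes sequencing, and the simulator's off-target
  fractions are inputs rather than a mechanism.

## A worked run

```{r demo, eval = FALSE}
report <- run_demo("demo_run", seed = 1, n_genes = 20)
str(report$design)
report$validation$status_counts
```

The demo simulates a reference, designs one probe per gene, verifies every
probe by in-silico capture, simulates both capture experiments and the full
validation study (hybrid family, three populations, 16 replicate pairs,
planted paralog and null-allele markers), and writes `report.json`,
`truth.json` and all intermediate artifacts into the output directory.
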