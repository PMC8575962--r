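# ibdtrace

Characterizing a rare autosomal-dominant risk allele in a large genotype
database, end to end: unphased identity-by-descent (IBD) segment
detection, IBD-network carrier imputation, population-ancestry and
genealogical birth-record enrichment, and coalescent allele dating —
exercised entirely on synthetic pedigree data with known truth.

## Who this is for

Statistical/population geneticists who want a tested, desk-scale
re-implementation of the database side of a rare-variant family study:
given a handful of *known carriers* of a dominant allele, find their
genetic matches in a cohort, impute further carriers from at-locus IBD
sharing, describe the ancestry and migration history of the matched
population, and date the allele — with every stage validated against a
gene-dropping simulator that knows the answers.

## The methods in brief

* **IBD detection** (seed-and-extend, GERMLINE regime): exact haplotype
  agreement over a `word_size`-marker window seeds a match that is
  extended at genotype level until an opposite-homozygote marker, so
  reported segments are unphased. *Genetic matches* share ≥1 segment
  > 6 cM with ≥1 known carrier; *at-locus matches* additionally share
  > 1 cM summed overlap with the focal locus window. A brute-force scanner
  (maximal opposite-homozygote-free runs) serves as an independent oracle.
* **Carrier imputation**: a sample sharing at-locus IBD with *all* known
  carriers is a putative carrier; with some but not all, it is unlikely to
  carry the allele (sharing presumed on the non-risk homolog). Meioses
  separation M is estimated from the shared genome fraction f by inverting
  f = k·2^(−M) (k common ancestors ∈ {1, 2}).
* **Enrichment**: one-sided Mann–Whitney U per ancestry region
  (pass: p < 0.05 and in-group median > 0); upper-tail hypergeometric per
  community label with Bonferroni correction (pass: adjusted p < 0.001,
  fold > 1.5); time-binned birth-record odds ratios per map cell from
  unique-family-tree 2×2 tables with Haldane–Anscombe correction
  (pass: OR ≥ 4, ≥ 10 trees; small-set mode: integer-degree cells,
  ≥ 2 trees).
* **Allele dating**: flank lengths L of the shared haplotype around the
  allele are Exponential(2t) in Morgans (recombination clock), pair-private
  derived alleles Poisson(2tμ·span) (mutation clock); the joint
  log-likelihood plus a pairwise-coalescent prior Exp(1/(2Ne)) gives a
  grid posterior whose mode and equal-tailed interval are reported
  (defaults r = 1e-8, μ = 1.25e-8, Ne = 10,000, 25 years/generation).

See `vignettes/ibdtrace-methods.Rmd` for assumptions, parameter
rationales, numerical choices and limitations.

## Worked example

```r
library(ibdtrace)
rep <- run_study(study_config(seed = 42))
```

prints (abridged from `rep$counts`, `rep$evaluation`, `rep$enrichment`,
`rep$geo`, `rep$age`):

```
pedigree size:         351
true carriers:         19
database size:         2346
genetic matches:       158
at-locus matches:      29
degree histogram:      1:14  2:1  5:14
putative carriers:     14
PPV / sensitivity:     1 / 1
ethnicity enriched:    scandinavia, england_nw_europe
community enriched:    mountain_west_pioneers
top geo cells:         1700-1800 (56.0, 10.0) OR=38; 1800-1850 (42.0, -74.0) OR=52;
                       1850-1910 (41.0, -112.5) OR=73
allele age:            2.1 generations (1.1-8.7), ~53 years, percentile 0.0
                       among 76 controls
```

Reading this: an 8-generation pedigree (351 members, 19 of them true
carriers of the planted allele) sits inside a 2346-sample database. 158
samples genetically match at least one of the 5 known carriers; 29 also
share > 1 cM IBD across the locus window. Most at-locus matches share with
only one known carrier (degree 1 — sharing on the non-risk homolog); the
14 samples sharing with all 5 are called putative carriers, and against
truth every call is correct (PPV 1) and every reachable true carrier was
found (sensitivity 1). The planted ancestry regions, community label and
three migration waypoints are all recovered, and the allele dates as very
recent (it arose on a pedigree founder a handful of generations back) —
younger than essentially all simulated control variants, as expected for a
recent family mutation.

`run_study(cfg, out_dir = "...")` additionally writes the stage files
(phased VCF, genetic map, match file, call tables, enrichment CSVs,
GeoJSON map cells, GraphML network, `report.json`). A command-line front
end is installed at `inst/cli/ibdtrace`
(`simulate` / `detect` / `run-all`).

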