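---
title: "Screening germline CNV calls with SNV allele frequencies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening germline CNV calls with SNV allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscreen)
```

## The model

`cnvscreen` decides, for each germline CNV call in a diploid genome, whether
the allele frequencies (AF) of the SNVs overlapping it are consistent with
the called copy-number state. Two rules, one per call type:

**Deletions — the heterozygosity rule.** A true heterozygous deletion leaves
a single haplotype, so the region shows loss of heterozygosity: every SNV
inside it should be effectively homozygous (AF near 100%, or near 0 and
therefore not called at all). Observed heterozygous SNVs contradict the
call. Because SNV calling itself has errors, one stray het should not
overturn a deletion; the call is flagged as a false positive only when

$$\frac{n_{het}}{n_{het} + n_{hom}} \ge \tau_{del}$$

with $\tau_{del} = 30\%$ by default. The comparison is inclusive ("at
least"), so 3 het among 10 classifiable SNVs flags the call at the default
threshold. SNVs whose genotype class is `unknown` are excluded from the
denominator: a site that cannot be classed as het or hom is evidence for
neither hypothesis, and dropping it from both numerator and denominator
keeps the fraction interpretable. The exclusion is auditable — verdicts
report `n_snvs` (all overlapping, QC-passing SNVs) next to `n_het` and the
fraction. With zero classifiable SNVs there is no evidence either way and
the call is kept with rule `no_evidence`.

**Duplications — the fuzzy scoring rule.** In a true single-copy duplication
(three copies total) a heterozygous SNV lies on the duplicated haplotype
with expected AF $2/3$, or on the other haplotype with expected AF $1/3$.
If the duplication is a false positive the region is diploid and the
expectation is $1/2$. Each overlapping *heterozygous* SNV is therefore
scored by how close its AF is to the nearest expectation: $+1$ at 50%
(evidence of a false positive), $-1$ at $100/3$% and $200/3$% (evidence of
a true duplication), $0$ at and beyond the informative bounds (28% and 72%
by default), where the AF no longer discriminates between the hypotheses.
The call is flagged when

$$\sum_i s(\mathrm{AF}_i) > \tau_{dup}$$

strictly, with $\tau_{dup} = 0.5$ by default. Homozygous SNVs (AF near
100% under either hypothesis) and unclassifiable SNVs contribute nothing in
either direction; with no het SNV the verdict is `no_evidence`.

### The scoring interpolant

The scoring curve is defined by seven anchors — the informative bounds at
score 0, the two duplication means at $-1$, the het mean at $+1$, and the
two midpoints between the het mean and each duplication mean at 0 (the AF
at which the evidence flips sign) — joined by raised-cosine segments:
between anchors $(a, s_a)$ and $(b, s_b)$,

$$s(f) = s_a + (s_b - s_a)\,\frac{1 - \cos\!\big(\pi\,(f-a)/(b-a)\big)}{2}.$$

This interpolant is continuous everywhere, hits every anchor exactly, has
zero slope at each anchor (so small AF noise around an expectation barely
moves the score), and is exactly symmetric about 50% under the default
anchors. The default duplication means are exact thirds ($100/3$, $200/3$)
rather than the rounded 33/66 — the copy-number arithmetic those roundings
come from — which is what makes the symmetry exact. The functional form is
isolated in `score_dup_snv()`, so replacing it with a different curve is a
one-function change; `plot_scoring_model()` samples that same function, so
the plotted model can never drift from the decisions.

```{r model-plot, eval = FALSE}
plot_scoring_model(scoring_params(), "scoring_model.png")
```

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `expected_ht_mean` | 50 | % AF | diploid het expectation; score $+1$ |
| `expected_dup_mean_low/high` | 100/3, 200/3 | % AF | true-duplication expectations; score $-1$ |
| `informative_low/high` | 28, 72 | % AF | support of the scoring curve; 0 outside |
| `del_het_threshold_pct` | 30 | % | het fraction at/above which a deletion is flagged |
| `dup_score_threshold` | 0.5 | score | summed score strictly above flags a duplication |
| `het_window` / `hom_window` | [20, 80) / [80, 100] | % AF | genotype fallback when no GT field |
| `depth_floor` | 10 | reads | minimum total depth for an SNV to be used |

All are arguments of `scoring_params()`, validated together (the anchor
ordering `informative_low < dup_low < het < dup_high < informative_high`
is enforced). The deletion threshold and the informative bounds are the
kind of tuning a lab may want to revisit for very deep or very shallow
data; the AF expectations are copy-number arithmetic and should not
normally be touched.

## Input handling choices

*Allele frequencies are percentages* (0–100) everywhere, matching how
variant callers and genome browsers print them; all thresholds are in the
same units.

*Coordinates are 1-based closed* internally, the VCF convention, so overlap
is plain closed-interval membership (`start <= pos <= end`, both ends
inclusive) with no conversion at query time; BED-style 0-based half-open
CNV tables are converted once on load. Overlap is computed with
`GenomicRanges::findOverlaps()`.

*VCF dialects.* Callers encode depths differently: VarScan2 reports a
percent string (`FREQ`) with `RD`/`AD` depths; Strelka an `AD` ref,alt pair
with `DP`; freeBayes `AO`/`RO` observations; the GATK callers an `AD` pair
whose sum is the total. Detection reads the `##source` /
`##GATKCommandLine` provenance lines first and falls back to
characteristic FORMAT declarations (`FREQ`; `AO`+`RO`; `GQX` to separate
Strelka from GATK, which share `AD`). Any other caller is loadable through
a `dialect_spec()` override choosing one of three arithmetic modes
(percent string, alt+total, alt+ref). Records a dialect cannot interpret
are counted and reported, never silently zeroed.

*Record screens.* Only biallelic single-nucleotide records are used — the
AF arithmetic above assumes clean two-allele sites — plus an optional
`FILTER` = `PASS`/`.` screen (default on) and the depth floor. Every load
returns a report in which accepted + rejected equals the number of data
lines.

*Genotype class.* The VCF `GT` field is authoritative when present: two
distinct alleles are het, two identical alternate alleles hom.
Hom-reference and half-calls fall back, like missing GT, to AF windows
(het [20, 80), hom [80, 100]) that are deliberately wide to tolerate
read-count noise. Both windows are configurable because the choice is a
judgment call, not a derived quantity.

## The synthetic-data generator

`simulate_sample()` produces a paired CNV table, VCF and truth table with
planted calls from four classes: `true_del`, `false_del`, `true_dup`,
`false_dup`. It emulates only the statistical structure the rules rest on:

* het SNV sites on a regular grid (default 1 site/kb — typical of the
  genome-wide heterozygosity seen in outbred human samples, and regular so
  per-region site counts are reproducible rather than Poisson-scattered);
* per-site depth Poisson with mean 100 (a deep WGS/panel regime in which
  AF evidence is informative); alternate reads Binomial(depth, p);
* p = 1/2 at diploid het sites — the background and everything inside
  *false* calls, which by definition do not change copy number;
* p ∈ {1/3, 2/3}, equal probability per site, inside true duplications;
* true deletions implement loss of heterozygosity structurally: each het
  site survives on the remaining haplotype with probability 1/2 (becoming
  p = 1, reported `1/1`) or vanishes with the deleted haplotype;
* sites whose alternate draw is 0 are not emitted — a caller would not
  report a non-variant site.

Placement puts one CNV per equal-width genome slot (shuffled class order,
random offset), guaranteeing non-overlap by construction; configurations
whose slots cannot hold the longest CNV are refused. Background sites
outside CNVs exercise the overlap logic against distractors. The generator
can emit any supported dialect, which doubles as the round-trip conformance
suite for the VCF loader. A fixed seed gives byte-identical files.

Defaults: one 10-Mb chromosome, 5 CNVs per class of 10–20 kb (so ≥10 het
sites per CNV at the default density), GATK-style VCF.

What the generator does **not** model: mapping and GC bias, contamination,
mosaicism, multi-copy (CN ≥ 4) states, indels and multi-allelic sites, or
the error modes of any particular CNV caller. Passing the recovery suite
therefore shows the decision rules work when AF evidence behaves ideally;
it does not predict performance on real callsets, where AF noise is not
binomial and CNV breakpoints are uncertain.

## Numerical and degenerate-input choices

* Scoring is exact at anchors (the interpolant evaluates to the anchor
  score when `f` equals an anchor, with no floating drift) and defined as
  0 on the closed complement of the informative range; AFs outside
  [0, 100] are a domain error, not clamped.
* Deletion rule boundary is inclusive (≥), duplication strictly exclusive
  (>): "at least" versus "greater than". A duplication summing exactly to
  the threshold is kept.
* Zero overlapping (or zero classifiable/het) SNVs always yield `keep` with
  rule `no_evidence` — absence of evidence never flags a call, and no
  minimum SNV count beyond that is imposed by default.
* Empty callsets, empty VCFs and all-rejected loads return empty,
  fully-typed objects with a warning, not errors, so batch runs survive
  sparse samples.
* `filter_cnvs()` is deterministic and order-preserving; verdict tables
  round-trip through `write_results()`/`read_results()` with decisions
  intact.

## Evaluation at desk scale

The test suite checks the engine against an independently written
straight-line implementation of both rules (exact verdict agreement on a
50-call simulated sample) and runs a seeded recovery study at the
generator's default study conditions — depth 100, ≥10 het sites per CNV,
50 CNVs per class on one 10-Mb chromosome, a problem size that keeps the
whole suite under a minute — requiring ≥95% of planted false calls
flagged, ≤5% of planted true calls flagged, and a strict F1 increase after
filtering. Scoring-function range, symmetry (to 1e−9), continuity at all
anchors and dialect round-trips (counts exact, frequencies within 0.1
percentage points to absorb the percent-string rounding) are asserted as
properties.

## Known limitations

* Diploid germline genomes only: no mosaic fractions, no somatic AF
  conventions, no sex-chromosome special-casing.
* Deletions supported by zero called SNVs are unfalsifiable here — a region
  can be empty of SNV calls either because it is truly deleted or by
  chance; such calls are kept as `no_evidence`.
* The duplication model assumes a single extra copy; higher amplifications
  shift expectations toward 1/4, 3/4 and beyond the default informative
  range.
* The screen flags the CNV, never the SNVs: when a het SNV sits in a real
  deletion it is the SNV call that is wrong, and this package does not
  adjudicate that direction.
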