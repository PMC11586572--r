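---
title: "Trio-based variant prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based variant prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

## The problem

When two related animals are born with the same rare congenital syndrome and
their parents are healthy, two inheritance hypotheses compete. Under an
**autosomal recessive** model, both affected offspring are homozygous for a
rare allele and every parent is an obligate heterozygous carrier. Under a
**paternal germline (gonadal) mosaicism** model — relevant when the affected
animals are paternal half-sibs sharing one sire — a de novo mutation present
in the sire's germ cells is transmitted to both offspring as a heterozygous,
fully penetrant dominant allele, while the dams are homozygous reference.

`trioscan` turns whole-genome genotypes of such a half-sib trio (two cases,
two dams, one sire), together with control cohorts, into a short ranked list
of candidate variants, and cross-checks the recessive hypothesis with two
orthogonal genomic signals: shared runs of homozygosity (identity by
descent) around the candidates, and a read-depth screen that excludes large
structural explanations. A population-screening module then quantifies how
the candidate alleles segregate in the wider breeding population.

## The filtering cascade

Each inheritance scenario defines a genotype pattern over the pedigree
roles. Writing genotypes as alt-allele dosages (0 = hom-ref, 1 = het,
2 = hom-alt):

| scenario | cases | dams | sire | control policy |
|---|---|---|---|---|
| `RECESSIVE_HOMOZYGOUS` | 2 | 1 | 1 | exclude if any control is hom-alt |
| `PATERNAL_GERMLINE_DENOVO` | 1 | 0 | 1 | exclude if any control carries the allele |

The cascade applies, in order: (1) the genotype-pattern filter; (2) a
functional-impact filter keeping "protein-changing" classes (snpEff
`MODERATE` + `HIGH` by default); (3) exclusion against a sequenced local
control cohort; (4) exclusion against a large global variant catalog. Under
the recessive model controls may be carriers — only homozygous-alt controls
veto a candidate, since a recessive allele can circulate at low frequency in
a healthy population. Under the de novo model any control occurrence vetoes,
because a fresh germline mutation should be absent from unrelated genomes.
Steps (2)–(4) are independent predicates, so their order changes only the
per-step audit counts, never the final candidate set; the fixed order
mirrors how such analyses are conventionally reported, and the report
records in/out counts at every step.

Two deliberate choices: missing genotypes in the trio **fail** the pattern
(the trio calls are treated as confirmed data, not as an occurrence
catalog), while missing control calls never veto an exclusion decision; and
"private" is operationalized purely as absence from the control catalogs —
no allele-frequency threshold is applied. Visual inspection of alignments
(IGV-style review) is outside computational scope; candidates carry a
`manual_review` status field instead.

## Runs of homozygosity and shared IBD regions

If the recessive hypothesis is right and the causal allele descends from a
common ancestor, both cases must be homozygous across an extended haplotype
around it. The detector is a *consecutive-runs* scanner: it reports every
maximal marker window with homozygous endpoints in which heterozygous calls
stay ≤ `max_het_in_run` (default 1), missing calls ≤ `max_missing_in_run`
(default 5), and no adjacent-marker gap exceeds `max_gap_kb` (default
1000 kb); windows shorter than `min_length_kb` (default 1000 kb, i.e. 1 Mb)
or `min_snps` (default 50) are then discarded. Intervals are 1-based
inclusive bp end to end, so lengths are `end − start + 1` with no 0-based
off-by-one. The consecutive formulation was chosen over sliding-window
heuristics because it is deterministic, parameter-light, and admits an
exhaustive enumeration oracle that the test suite runs against it.

Overlapping runs of the two cases are certified as *shared* only by allelic
matching: over jointly non-missing markers in the overlap, the fraction of
identical genotypes must reach `match_threshold` (default 0.95), and at
least `min_match_snps` (default 20) markers must be jointly observed —
matching 95% of a handful of markers would certify nothing. Each parent is
annotated `HETEROZYGOUS_COMPATIBLE` for a region when at least one marker
in it has both cases hom-alt and that parent heterozygous, i.e. the region
can harbor a recessive allele for which the parent is an obligate carrier.
A stricter reading — requiring the parent never to be hom-alt anywhere in
the region — was rejected: in any population with segregating variation a
carrier parent is *expected* to be homozygous for common alleles at some
sites inside a long shared haplotype, so that criterion would disqualify
essentially every true region. Overlapping certified regions with identical
parent annotation are merged (the unmerged pairwise regions remain
available as an attribute, since segment counts differ between the two
views).

## Depth screen

Aneuploidies and megabase-scale imbalances leave a copy-number footprint in
binned coverage. Profiles are consumed pre-binned (TSV of fixed-width
windows; default width 10 kb) and normalized by each sample's autosomal
median bin depth, making the diploid baseline exactly 1.0 and the screen
independent of sequencing depth; sex chromosomes are excluded from the
baseline. Chromosome-level medians screen for whole-chromosome events and
region-level means screen candidate intervals. Flag thresholds default to
0.75 (`LOSS`) and 1.25 (`GAIN`) — midway between the diploid expectation
(1.0) and the one-copy (0.5) / three-copy (1.5) expectations — and are
configurable; a queried region with no bins is reported `NO_DATA` rather
than silently passing.

## Segregation analysis

Genotype counting is exact per cohort with missing calls reported
separately and excluded from denominators — cohorts genotyped at two loci
need not share denominators (assay failures differ per locus). The
variant-allele frequency of a count triple $(n_{rr}, n_{rv}, n_{vv})$ is
$\hat q = (n_{rv} + 2 n_{vv}) / 2N$, reported with a Wilson score 95\%
interval on the $2N$ allele trials. The Wilson interval was preferred over
the Wald interval because carrier screens live in the small-$\hat q$,
moderate-$N$ regime where Wald intervals collapse or cross zero; the
interval is an addition of this package, clearly labelled in output. An
integer-rounded percentage accompanies the estimate because that is how
carrier frequencies are conventionally reported.

The digenic module tabulates the 3×3 joint genotype classes of two
candidate loci and issues verdicts: *digenic-consistent* when every
affected individual is hom-alt at both loci and no unaffected individual
is; *monogenic-A(-or-B)-inconsistent* when some unaffected individual is
hom-alt at one locus alone — the configuration that argues against that
locus acting as a fully penetrant monogenic recessive and keeps the
two-locus hypothesis alive. A table of all-reference genotypes is vacuously
consistent and flagged *uninformative*.

## The synthetic cohort generator

No raw sequencing data accompany the study design this package targets, so
validation rests on a seeded generator that reproduces the *statistical
structure* the analysis assumes. Its defaults are the study conditions:
a half-sib pedigree (two affected offspring, two dams, one sire), a
sequenced local control cohort of 942, a global catalog cohort of 5279,
and ~10,000 biallelic background markers (5 autosomes × 20 Mb ×
100 markers/Mb) with allele frequencies drawn from a Beta(0.3, 3) spectrum
— a rare-skewed site-frequency spectrum with mean ≈ 0.09, chosen as
representative of a within-breed biallelic SNP panel. Background impact
classes are assigned with probabilities (HIGH 0.005, MODERATE 0.035,
LOW 0.16, MODIFIER 0.80), giving a protein-changing fraction of ~4%,
consistent with the shape of published filtering tables. The default
injections mirror the target study: a digenic pair of recessive variants on
two chromosomes (one MODERATE missense-like, one HIGH splice-like, screened
male allele frequencies 5% and 2%) plus one paternal germline MODERATE
variant; the screened-bull table additionally plants one unaffected male
hom-alt at the first digenic locus only — the discordant-carrier
configuration that drives the digenic verdict.

For each recessive injection a common-ancestor haplotype spanning
`ancestral_haplotype_kb` (default 2000 kb) is copied into one haplotype of
the sire and of each dam, forcing the cases homozygous-by-descent across
the window and all three parents to be carriers. Transmission within these
windows is haplotype-block meiosis with Poisson crossovers
(`recomb_rate_per_mb`, default 0.01 = one crossover per 100 Mb per
meiosis), conditioned to transmit the planted allele, so recombination can
— rarely — erode the shared run below the 1 Mb detection floor; that
erosion is exactly what the recovery-rate acceptance property measures.
*Background* markers, by contrast, segregate independently per site: each
offspring draws one of each parent's two alleles at random, exactly
Mendelian and HWE-marginal but unlinked across sites. This split is a
deliberate design decision: linkage is simulated where it carries signal
(the IBD windows), while keeping background cascade-survival events
independent across sites and offspring, so the expected number of
background survivors has the closed form

$$\lambda_{rec} = \sum_i \left(2q_i(1-q_i)\right)^3 \tfrac{1}{16}\;
  \mathbb{1}[\text{impact}_i \in \{M,H\}]\;(1-q_i^2)^{N_L + N_G}$$

(and the analogous expression for the de novo pattern), against which
observed counts are tested with a two-sided Poisson band equivalent to 3σ.
A generator with genome-wide linkage would make these counts heavily
correlated within chromosomes and the binomial-error comparison invalid.
The cost of the split is that the background carries no realistic LD and no
incidental autozygosity: passing tests demonstrate correctness of the
filtering and mapping logic under the stated model, not robustness to the
LD structure, genotyping error profile or call-rate patterns of real WGS
data. Control genotypes are Hardy–Weinberg draws per site; the global
cohort is emitted as a count catalog rather than per-sample columns,
mirroring how large consortium resources are used as occurrence catalogs.

Depth profiles are `mean × copy-ratio × lognormal` with unit-mean noise
(default mean 18.2×, CV 0.1); planted events multiply the copy ratio (1.5
for a trisomy, 0.5 for a heterozygous deletion). Everything is a pure
function of the seed; identical configurations produce byte-identical
files.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere internally; BED export
  converts to 0-based half-open on write.
* Genotypes collapse to dosages {0, 1, 2, missing}; phase is discarded.
  Half-missing VCF calls (`./1`) are treated as missing — conservative, and
  the only reading that never invents an allele.
* Multi-allelic sites split into one biallelic record per alt; a genotype
  containing an allele foreign to a given biallelic view is missing in that
  view.
* A variant absent from a control catalog survives exclusion (absence of
  evidence is privacy, by construction of the catalogs).
* `detect_roh` errors on unsorted positions rather than sorting silently;
  an all-zero depth profile errors rather than normalizing to NaN; an empty
  cohort still yields a zero-count genotype row; an empty record list flows
  through the whole cascade producing zero counts at every step.
* An optional PASS-only VCF switch exists but is off by default, since
  upstream QUAL/FILTER handling varies between callers.

## Problem sizes used in validation

The test suite and the acceptance script validate at the default generator
scale (~10,000 markers, 942 + 5279 controls): cascade recovery and
background-survival calibration over 20 seeds, planted-IBD recovery and the
ROH oracle over 100 replicates each, depth-event detection and
Wilson-interval coverage over 100 seeds each. These sizes give the
stochastic properties enough resolution (binomial standard errors of a few
percent) while keeping a full validation run in the minutes range.

## Known limitations

* No genotype likelihoods or phasing: inheritance logic is genotype-based,
  so a miscalled trio genotype at the causal site is fatal to recovery —
  as it is in the real analyses this mirrors.
* The ROH scanner has no genetic map; gap and length parameters are
  physical distances.
* The digenic verdict is a co-segregation consistency check, not a
  statistical test of interaction; with few affected individuals it cannot
  have power, only falsification value.
* The depth screen detects megabase-scale imbalances; it is not a
  split-read/paired-end SV caller and estimates no breakpoints.
* X/Y are excluded from ROH scanning and depth baselines but otherwise
  treated as diploid in filtering; hemizygous logic is out of scope (the
  intended use cases are autosomal).
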