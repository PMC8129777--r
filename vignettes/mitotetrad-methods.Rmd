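---
title: "Methods: quantifying mitochondrial inheritance in fission-yeast tetrads"
author: "mitotetrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitochondrial inheritance in fission-yeast tetrads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotetrad)
```

## The biological question and the measurement model

During *S. pombe* meiosis, parental mitochondria are anchored at opposite
cell poles, so each of the four spores of a tetrad should inherit
mitochondria — and hence a mitochondrial genome — from exactly one parent,
two spores per parent (2:2 segregation). Shotgun sequencing of colonies
grown from dissected spores turns this into a quantitative read-counting
problem. At a biallelic mitochondrial SNP where the two parents carry
different alleles, the per-colony reference and alternate observation
counts (`RO`, `AO` in a freebayes-style multi-sample VCF) estimate the
fraction of the colony's mitochondrial DNA pool descending from each
parent. Because the mitochondrial genome is present in many copies per
cell and colonies pool thousands of cells, these fractions are continuous:
a pure colony sits at 0 or 1, a mixed (heteroplasmic) colony in between,
and a colony carrying a recombinant mitochondrial genome switches parental
assignment between neighbouring markers.

Three observations motivate every statistic in the package: (i) colony
pools can contain both parental alleles at a site (heteroplasmy), (ii)
parental assignment can switch along the genome (recombination), and
(iii) tetrads can violate 2:2. The package computes each of these from
the same primitive — the parent-1 observation fraction per (colony,
marker).

## Data model

`MitoTetradExperiment` extends `RangedSummarizedExperiment`: rows are
variant sites (`GRanges` spanning the reference allele, with `ref`,
`alt`, `qual`, `varClass` row data), columns are sequenced colonies, and
assays hold the per-sample called allele (`GT`: 0 reference, *k*-th
alternate, `NA` missing), `RO`, and `AO` (a list-matrix, one count per
alternate allele, so multi-allelic records survive I/O intact and are
removed by the *filter*, which owns that rule). Colony metadata (role,
cross, tetrad, spore index, exclusion state) lives in `colData`; the
cross design table in `metadata()`. Positions are 1-based throughout, as
in the VCF, so printed breakpoint coordinates match the input.

## Filters

`filterSites()` reproduces a standard post-calling hygiene stack as pure
post-hoc operations on the VCF, in this order:

* **call masking**: calls with `RO + sum(AO) < 3` or alternate calls with
  `AO < 3` are set to missing. These re-express caller-side
  minimum-coverage/minimum-alternate-support settings for a pipeline that
  starts from an already-called VCF.
* **site retention**: biallelic SNPs only; `QUAL >= 30` (phred); no indel
  record within 3 bp (inclusive distance from the SNP position to the
  nearest base spanned by the indel's reference allele — the `--SnpGap`
  convention); missing-call fraction of at most 0.5, computed *after*
  masking, with exactly half missing retained ("more than half uncalled"
  is a strict inequality).

Each dropped site records one primary reason, the first failing rule in
the fixed order `not-SNP`, `multiallelic`, `qual`, `snp-gap`,
`missingness`, so rejection tables are deterministic and comparable
between runs. The filter is idempotent, and tightening any single
threshold can only shrink the retained set; both properties are enforced
by tests.

## Markers and orientation

A retained site becomes a **marker** for a cross when both parental
controls are confidently called for different alleles. Confidence is a
major-allele observation fraction of at least `purity = 0.95`: parents
are expected to be effectively homoplasmic, so an impure control suggests
contamination and skips the site (with a warning) rather than fixing a
possibly wrong orientation. 0.95 is a design choice, not an estimate —
at typical 200–1000× mitochondrial coverage a true homoplasmic control
essentially never dips below it, while cross-contamination at the few
percent level is caught. Sites where the parents agree are simply
non-segregating for that cross; a site can be a marker in one cross and
not another, which is why markers are (cross, site) pairs.

## Per-colony statistics

* **Parent-1 fraction** at a marker:
  `f = RO/(RO+AO)` when parent 1 carries the reference allele, otherwise
  `AO/(RO+AO)`. Reads supporting neither parental allele never enter
  `RO`/`AO` and are thereby excluded from the denominator. `f` is missing
  when the call is missing or depth is zero.
* **Minor observation fraction** (heteroplasmy): `AO/(AO+RO)` for
  reference calls, `RO/(AO+RO)` for alternate calls — identically
  `min(f, 1-f)` at a biallelic marker. The summary statistic is the
  percentage of evaluable spore calls strictly above 5%.
* **Recombination**: a colony's major parent is the one with the larger
  mean `f` across informative markers (a tie resolves to parent 1, with a
  message — determinism matters more than the arbitrary choice). The
  colony is recombinant when the *other* parent's fraction strictly
  exceeds 10% at one or more markers. This sample-level reading of "minor
  allele frequency" is deliberate: the per-site reading
  `min(f, 1-f) > 0.1` would never flag a clean crossover colony
  (fractions 1, 1, 0, 0 have per-site minor fraction 0 everywhere), which
  is exactly the pattern that demonstrates recombination. The per-site
  rule remains available (`rule = "site"`) for sensitivity analysis.
* **Crossover intervals**: markers are hard-assigned to a parent at
  cutoff 0.5 (exactly 0.5 is unassigned and skipped); each sign change
  between consecutive assigned markers yields an interval spanned by the
  flanking marker positions. With 8 markers the spatial resolution is
  coarse — intervals, not points, are the honest output.

## Tetrad and cross summaries

Spore means are unweighted over informative markers (depth weighting
would let one deep marker dominate a profile that is conceptually a
per-site vote). Predominance uses the 0.5 cutoff with exact ties left
`unassigned` rather than arbitrarily assigned. A tetrad deviates from
2:2 when at least three assigned spores share a predominant parent — a
rule that deliberately includes 3-spore tetrads, since dissection
practice mostly yields 3–4 viable spores. Per cross, transmission bias is
the fraction of assigned colonies predominantly inheriting parent 1,
with an exact two-sided binomial test against 1/2 (two-sidedness by
summing all outcomes no more likely than the observed one). The test is
an *extension* of the descriptive bias percentages: when colonies come
from complete tetrads under strict tethering, parental origins are
negatively correlated within tetrads and the binomial test is
conservative; its nominal calibration holds for independent colonies,
which is how the null-calibration test exercises it. Both denominators —
all assigned colonies and colonies from complete 4-spore tetrads — are
reported, since either could be of interest.

Self-mated tetrads (a real artefact of mating-type plate crosses) are
detected from nuclear markers, derived with the same machinery on
non-mitochondrial contigs: in a genuine cross every spore's nuclear
genome mixes both parents, so a tetrad whose spores match a single
parent at *every* informative nuclear call (at least 10 such calls
required) is flagged and excluded with reason `"self-mating"`. With
fewer than 10 informative calls the tetrad is left unflagged with a
warning — absence of evidence, not evidence of selfing.

## The simulator

`simulateDataset()` generates the whole experiment from one seed, in a
fixed draw order (markers, nuclear panel, site qualities, per-tetrad
truth, then per-sample reads), so identical seeds give byte-identical
emitted files. The model:

* **Markers**: 8 positions uniform without replacement on a 20 kb
  mitochondrial genome; each marker's alternate allele is assigned to a
  subset of parental strains such that every marker segregates in at
  least one cross and every cross has at least two markers. Three crosses
  share one wild strain, mirroring a design where one natural isolate is
  crossed against several partners.
* **Inheritance**: tethered 2:2 baseline (spores 1–2 from parent 1,
  3–4 from parent 2). Per spore, with probability `p_mix = 0.15` the
  colony pool is mixed, with minor-parent fraction `m ~ Beta(1.5, 4.5)`
  (mostly small minor fractions, occasionally near or above 0.5 — draws
  above 0.5 flip the colony's predominant parent and are the model's
  route to 2:2 violations). With probability `p_crossover = 1` the minor
  contribution is a recombinant haplotype with `K ~ Poisson(1)`, `K ≥ 1`,
  breakpoints uniform — mixing and recombination co-occur, reflecting the
  observation that mixed colonies show haplotype switching rather than a
  flat intermediate frequency. The mixing parameters are illustrative:
  colony-level sequencing cannot distinguish stable heteroplasmy,
  sorting-out in progress, or colony subpopulations, so the generator
  models the colony pool directly with a single aggregate minor fraction
  and makes no claim about mitotic dynamics.
* **Reads**: depth `~ NB(mean 500, size 6)` — central 95% range roughly
  180–980× (`qnbinom(c(.025, .975), size = 6, mu = 500)` gives 182 and
  975), emulating the
  wide mitochondrial coverage of colony shotgun data; a fixed-depth
  switch exists for exact tests. Alternate reads
  `~ Binomial(d, q(1-e) + (1-q)e)` with per-read error `e = 0.001`.
* **Viability and selfing**: spores die with probability 0.35; tetrads
  are redrawn until ≥ 3 spores are viable (dissection selects such
  tetrads), giving ≈ 3.3 sequenced colonies per tetrad. Whole tetrads are
  self-mated with probability 0.09; the nuclear panel (12 sites, ~5×
  coverage, strict 2:2 segregation per site in genuine crosses) carries
  the detection signal.

What passing recovery tests on this generator shows — and what it does
not: the pipeline provably recovers markers, mixing, crossovers,
segregation patterns and self-mating from data generated under its own
model, including realistic depth dispersion and read error. It does not
validate against alignment artefacts, mapping bias, nuclear
mitochondrial insertions (NUMTs), or strain-specific coverage
differences, none of which the generator emulates.

## Numerical conventions and degenerate inputs

Strict inequalities at the 5% heteroplasmy and 10% recombination
thresholds ("above", "greater than"). Fractions are missing (never 0)
when depth is zero or a call is masked. Colonies with no informative
marker are `unassigned` and excluded from bias denominators; crosses
with zero assigned colonies are an error. Fewer than two hard-assigned
markers means crossover calling returns an empty interval list with a
warning. All tables are written with fixed formatting so reruns are
byte-identical.

## Problem sizes used in the test suite

Tests run the generator at 2–11 tetrads per cross, property suites at
1,000+ randomized cases, crossover-recovery at 1,000 replicates of
8-marker single-crossover colonies (depth 500, error 0.002), and the
binomial-null calibration at 2,000 crosses of 30 colonies. These sizes
give stable stochastic assertions (binomial standard errors well inside
the asserted bands) while keeping the full suite around a minute.

## Known limitations

* With 8 markers, crossover intervals are wide and multiple crossovers
  between adjacent markers are invisible (an undercount by design).
* The recombination call cannot distinguish a mixed colony with a
  recombinant minor haplotype from a colony of mixed pure populations;
  both are "recombinant" under the 10% rule.
* The binomial bias test treats colonies as independent; under strict
  tethering with complete tetrads it is conservative (see above).
* Self-mating detection needs nuclear coverage; at very low depth the
  10-call minimum can leave tetrads unassessed.
* The purity threshold assumes homoplasmic parents; a genuinely
  heteroplasmic parental strain would suppress its markers rather than
  mis-orient them.
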