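---
title: "Detecting locus-wise assortative mating: models, choices and limits"
author: "MateAssort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting locus-wise assortative mating: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MateAssort)
```

## The question and the model

Given a cohort of diploid individuals genotyped at biallelic SNPs and a
set of observed mate pairs within a mating group, we ask per locus
whether mates are more similar (positive assortment) or less similar
(negative assortment) than random pairing would produce. Negative
assortment is the pattern expected under mate choice for heterozygosity,
long discussed for immune-gene regions in fish and other vertebrates;
comparing two groups — say hatchery-origin versus natural-origin
spawners — asks whether captivity shifts the cues involved.

Genotypes are encoded as **minor-allele dosage** $d \in \{0,1,2\}$, the
count of the locus's rarer allele. A pair with dosages $(d_f, d_m)$
shares

$$s(d_f, d_m) = 2 - |d_f - d_m|$$

allele classes: 2 for identical genotype classes, 1 when exactly one
allele class is common, 0 for opposite homozygotes. The test statistic
at a locus is the mean of $s$ over the group's pairs in which **both**
mates are genotyped there; the informative pair count varies by locus
and is reported (`n_pairs_used`).

The score is symmetric and invariant to relabelling which allele is
"minor" ($d \mapsto 2-d$ on both sides leaves $|d_f-d_m|$ unchanged),
so the minor-allele convention affects bookkeeping, never inference.
The minor allele is fixed once per dataset, from allele frequencies over
all genotyped individuals after individual-level filtering; an exact 0.5
frequency tie deterministically designates the alternate allele minor,
which also makes re-encoding idempotent.

## The permutation null

Under the null hypothesis mates pair at random with respect to the locus.
We hold every genotype fixed and randomise only the pairing: in each of
`nPermutations` replicates the multiset of males appearing in the pair
set (a male occurring in $k$ pairs enters $k$ times) is randomly
re-matched to the females, and the replicate's mean score is computed
under the same both-genotyped rule as the observed mean. The observed
mean's percentile in the replicate-mean distribution classifies the
locus: strictly below `lowerCutoff` (default 0.025) → `negative`,
strictly above `upperCutoff` (default 0.975) → `positive`, else `none`.
No multiple-testing correction is applied — the output is the raw-tail
convention of this scan type, and roughly 5% of null loci are flagged by
construction; consumers who need error control should treat the flags as
a ranking.

Three null schemes are implemented (`AssortConfig(nullScheme=)`):

* **`permute-males`** (default) — bijective random re-matching of the
  observed male multiset, the classical permutation test. Only the
  dosage-class cross-tabulation of a matching matters, and for a uniform
  random bijection that 4×4 table (dosage 0/1/2/missing on both sides)
  is multivariate hypergeometric with margins fixed at the observed
  class counts, so replicates are drawn directly with `r2dtable()`
  (Patefield's algorithm) instead of looping over assignments.
* **`resample-males`** — every female is independently assigned a male
  drawn *with replacement* from the male multiset, the literal reading
  of "assign each female a random male from the dataset". This null
  additionally varies the male composition of each replicate — variance
  the observed statistic, whose male multiset is fixed by definition,
  does not have. At study-like sizes (150 pairs) this makes the test
  conservative: in our synthetic calibration runs the per-tail rate
  drops to roughly 1–1.7% instead of 2.5%, while `permute-males` stays
  at the nominal rate. That measured miscalibration is why bijective
  re-matching is the default; `resample-males` is retained because the
  with-replacement description is common in this literature and because
  males genuinely mate multiply.
* **`single-pairs`** — the null is the distribution of single random
  pair scores rather than replicate means; only useful for sensitivity
  analysis, since a mean over ~150 pairs almost never escapes the
  {0,1,2}-atom distribution's inner range.

Percentiles use the **mid-rank** convention,
$(\#\{\text{null} < \text{obs}\} + \tfrac12\,\#\{\text{null} =
\text{obs}\}) / n$: symmetric under ties, and a fully degenerate null
(e.g. a locus where every individual is heterozygous) lands exactly at
0.5 rather than at an arbitrary tail. Ties are detected with an absolute
tolerance of $10^{-9}$, far below the $\sim 1/n_{\text{pairs}}$ spacing
of attainable means. Replicates with fewer informative assignments than
`minPairsPerLocus` (default 2) are redrawn, with the redraw count capped;
loci whose *observed* informative count is below the floor are emitted
with classification `none` and a `low_n` flag rather than dropped, so
two groups' scans stay aligned on one locus universe.

Per-locus RNG streams are derived deterministically from the global seed
and the locus index, so results are independent of locus processing
order; identical inputs and seed give bit-identical output.

## Filter chain

`runFilterChain()` reproduces the standard post-calling cleanup for
reduced-representation data, in this order: (1) HDplot-style paralog
blacklisting, (2) individual-level missingness, (3) mean site depth,
(4) site-level missingness. Defaults (all strict comparisons): drop
individuals with more than 20% missing genotypes; drop sites whose mean
total depth is below 5 or above 30, or with more than 80% missing data.
The HDplot statistics are $H$, the fraction of genotyped individuals
called heterozygous, and $D = (a-b)/\sqrt{a+b}$ with $a, b$ the ref and
alt reads pooled over heterozygotes — approximately a z-score for the
50/50 read split a true diploid heterozygote should show; defaults flag
$H > 0.6$ or $D$ outside $[-5, 7]$, the asymmetric window reflecting
per-tail tuning of the z-bounds, and a locus with no heterozygotes gets
$D = 0$ and is judged on $H$ alone. Because this chain runs on called
genotypes only, it approximates the two-pass practice of blacklisting
paralogs and re-calling; each site is counted at the first stage that
removes it, and the report enforces
`out = in − paralog − depth − missing`.

Two genuinely open conventions were fixed as follows. *Mean depth over
individuals*: individuals with a missing genotype are excluded from a
site's mean by default (`depthMissing = "exclude"`), since an uncalled
genotype usually means no usable reads and counting zeros would conflate
missingness with depth; `"zero"` is available for pipelines that define
it the other way. *Filter-then-encode*: the minor allele is re-derived
after individuals are removed, so dosage reflects the analysed cohort;
the stages can also be called individually in any order.

## Group comparison

`compareGroups()` outer-joins two result tables on locus id (absent =
`none`) and reports per-group negative/positive counts, loci sharing the
same flag (`sharedNegative`, `sharedPositive`, summing to
`sameDirection`), loci flagged in both groups with opposite signs
(`oppositeDirection`), and per-chromosome counts for a bar-style
summary. The shared percentage is

$$100 \times \frac{\text{shared}}{n_A + n_B},$$

i.e. the *sum* of the two groups' flagged counts in the denominator,
not their union. The union would be the more conventional overlap
measure; the sum-denominator is used deliberately because it is the
convention under which shared counts and percentages of this analysis
type are mutually consistent, and it is verified against worked integer
examples in the test suite. Percentages are displayed rounded half-up
to two decimals (`roundHalfUp()`), avoiding R's round-half-to-even.
No significance test of the overlap is computed — the comparison reports
raw counts.

## Annotation

`annotateSnps()` reports a (SNP, gene) row whenever the SNP position
lies within a gene body — `start ≤ pos ≤ end`, 1-based inclusive on the
same sequence, GFF3 native coordinates — with no upstream or downstream
window and no strand effect. Only GFF3 records of type `gene` are used
(not mRNA/exon children). SNPs in no gene are kept with `NA` gene
fields; overlapping genes yield multiple rows. Containment queries go
through `GenomicRanges::findOverlaps()` and are property-tested against
a naive all-pairs scan.

## Synthetic data generator

`simulateCohort()` draws, per locus, a minor-allele frequency $q$
uniform on [`mafMin`, `mafMax`] (defaults 0.05–0.5; the floor keeps
sharing informative and is configurable), genotypes under Hardy-Weinberg
proportions, negative-binomial per-cell read depth (default mean 15,
size 5 — a realistic overdispersed GBS coverage comfortably inside the
5–30 depth window), Binomial(depth, ½) heterozygote read splits, and
per-cell missingness (default 3%, typical of filtered GBS matrices;
masked cells get zero reads, as uncalled genotypes do). A configurable
fraction of loci is simulated paralog-like — heterozygote probability
forced to 0.75 and read splits skewed to 0.85 — the signature HDplot is
designed to catch.

`simulatePairs()` injects assortment: the probability of observing pair
$(f, m)$ is proportional to $\prod_{\ell} w_\ell^{\,s_\ell(f,m)}$ over
the configured loci, with $w_\ell = e^{-\beta}$ for negative direction
and $e^{+\beta}$ for positive ($\beta \ge 0$; missing genotypes
contribute factor 1), which nests uniform random mating at $\beta = 0$.
Rather than accept–reject sampling of proposals — whose acceptance rate
collapses once many strong loci multiply together — the female×male
table is enumerated and `nPairs` unique pairs are drawn by exact
weighted sampling without replacement, which realises the same target
law for arbitrarily strong biases. Default scenario sizes mirror the
motivating study design: ≈150 observed pairs per mating group from a
cohort of 150 females and 150 males, at 1,000 loci in tests (the real
data scale, ~15,000 SNPs and two groups of 142/152 pairs, is linear in
loci and runs the same way).

What the generator does *not* emulate: linkage disequilibrium between
loci (loci are independent), pedigree structure or relatedness among
individuals, population structure, allele-frequency differences between
sexes, genotyping error beyond missingness, or selection on offspring
survival between mating and sampling. Passing tests therefore show that
the statistic, null and classification behave correctly under the
stated sampling model — not that real GBS data meet that model.

## Numerical and testing choices

Simulated checks use 5,000 permutations per locus (scaled down from the
50,000 default, chosen as ample for 2.5% tails: the Monte-Carlo SE of a
tail percentile at 5,000 replicates is ~0.2%) over 1,000 loci and 150
pairs. Under the null the negative and positive classification rates sit
within three binomial standard errors of 2.5% each; with 20 loci per
direction injected at $\beta = 2$, over 90% of injected loci are
recovered with the correct sign while unmarked loci stay at the nominal
false-flag rate. Exact oracles back the stochastic ones: the sharing
score is enumerated against an allele-multiset intersection oracle over
all nine genotype combinations, and Monte-Carlo percentiles are checked
against exhaustive enumeration of all male assignments on small pairing
tables (27 with-replacement outcomes, 6 bijective matchings, for a 3×3
toy).

Degenerate inputs are defined, not special-cased: empty result lists
compare to all-`none`; a locus with no informative pairs is flagged
`low_n`; an all-heterozygous locus yields percentile 0.5; filters on an
already-empty matrix are no-ops; and the filter chain warns (rather than
errors) when nothing survives.

## Known limitations

* The test is marginal per locus; flags are raw 2.5%/97.5% tails, and
  with ~15,000 loci several hundred null flags are expected — the
  cross-group comparison inherits that noise.
* Group comparisons assume both scans ran on the same locus universe;
  loci missing from one side are treated as unclassified there, which
  deflates shared counts if the universes differ materially.
* Mate pairs inferred from surviving offspring conflate mate choice with
  differential offspring survival; nothing in the statistic can separate
  the two.
* The HDplot filter needs per-genotype allele depths; VCFs without `AD`
  must skip the depth and paralog stages explicitly.
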