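---
title: "Dissecting a QTL with branching congenic strains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a QTL with branching congenic strains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congenicQTL)
```

## The problem

A quantitative trait locus (QTL) mapped in an intercross typically spans
tens of megabases. Congenic strains refine it: each strain carries a
defined donor-strain chromosomal fragment introgressed onto an inbred host
background, so comparing carrier (heterozygous donor, here 129/B6) mice
against their homozygous host littermates (B6/B6) tests exactly the
fragment. A panel of strains with staggered fragment boundaries can, in
principle, localize the locus to the region shared by all
phenotype-positive strains. That "common segment" logic assumes a single
QTL; when several linked QTLs with opposing allelic effects hide inside
one mapped peak, it fails in a characteristic way — positive strains share
no region, and a strain spanning two cancelling loci looks like a
negative. This package implements both the common segment classification
(to demonstrate that failure) and the sequential comparison method that
resolves it, for the motivating phenotype of gonadal adipose depot weight
on mouse chromosome 9.

## Pipeline model, stage by stage

**Genotype imputation.** Missing codes are filled only when the nearest
non-missing flanking markers agree and lie within 26 Mb of each other, the
smallest distance at which a double recombination has been observed in
densely genotyped populations of this cross. Flank distance is measured
flank-to-flank because that is the interval a double recombination would
have to fit inside. Chromosome-terminal missing runs have a single flank,
which cannot exclude a distal recombination, so they are left missing
unless `fill_terminal = TRUE`. The operation is deterministic and
idempotent.

**Donor regions.** A mouse's donor region is the union of maximal runs of
heterozygous markers, with boundaries reported at the observed marker
positions (inner bounds). The true breakpoint lies between the last
heterozygous and first host marker; we do not invent midpoints, which
keeps all reported coordinates at marker resolution. Residual missing
codes at a breakpoint simply leave the boundary at the nearest observed
heterozygous marker (`na_policy = "omit"`), which is the same convention.

**Phenotype preparation.** Flagged mice (sick, tumors) are removed first.
Depot weights are diagnosed by moment skewness plus a Kolmogorov-Smirnov
screen against a fitted normal; the natural-log transform is applied when
raw skewness exceeds 0.5 or the KS screen rejects at 0.05. The KS test
uses estimated parameters, a Lilliefors-style shortcut that is
anti-conservative for strict testing but is used here only as a
transform-or-not decision rule, which is all the downstream stages need.
The log base is immaterial to every test statistic. Covariates are
screened by Pearson correlation (retain at |r| > 0.3 and p < 0.05): body
weight is strongly correlated with depot weight and is retained; age,
tightly controlled by the necropsy schedule, is not.

**Marker scan.** All mice form one mapping population. Per marker, an OLS
model with sequential (Type-1) sums of squares is fitted with body weight
entering first, then strain, then genotype, so the genotype F test is
adjusted for both. The entry order is the conservative reading of
"genotype and strain as fixed factors and body weight as a covariate"; it
is configurable, and only the genotype-last convention matters for the
reported scores. Strains not segregating at a marker are pooled into one
background level, since their mice inform the covariate and residual
variance but carry no genotype contrast. Thresholds are
`-log10(alpha/N)`: with N = 148 markers, 3.47 at alpha = 0.05
(significant) and 2.37 at alpha = 0.63 (suggestive). Support intervals
extend from each significant local peak over consecutive markers within 2
units of `-log10 p` of that peak.

**Common segment classification.** One joint model (body weight, then
strain-by-genotype cells) supplies adjusted means and a pooled residual
mean square; each strain's donor-host contrast is a Fisher's LSD test,
`t = difference / sqrt(MSE (1/n1 + 1/n2))` on the joint residual df, at
unadjusted p < 0.05 as is conventional for LSD post hocs (the lack of
multiplicity correction is deliberate and documented in the output). The
narrow analysis uses full-length donor mice from strains with at least 12
mice per genotype; the broad analysis keeps nearly all mice, excluding
strains with a genotype group under 2, the smallest group a contrast can
use. The shared-region test then asks, per marker, whether all positive
strains are heterozygous and all negative strains host.

**Sequential method.** Strains (plus a synthetic host node with an empty
region) form a complete graph weighted by the base-pair length of the
symmetric difference of donor regions — a metric chosen because it makes
nested fragments neighbors and disjoint fragments distant, reproducing
the lineage branching of the panel. The minimum spanning tree (Kruskal,
deterministic tie-break on weight then lexicographic node pair) fixes the
comparison order: breadth-first from the host, children by ascending edge
weight. Each edge is an LSD contrast in a joint model over all groups,
yielding a ternary verdict (greater, less, equal at p >= 0.05).

**Multi-QTL inference.** Donor-region endpoints partition the chromosome
into atomic bins. The inference searches assignments of {absent, +, -} to
bins in increasing number of active bins. An assignment is consistent
when every significant comparison has an active bin of the matching
effective sign inside its difference region (a bin carried by the second
group counts with flipped sign), and every "equal" comparison's
difference region holds either no active bins or active bins of both
effective signs. The both-signs clause is essential: a donor region
spanning two opposing loci of similar magnitude is phenotypically silent,
and pure "no QTL there" semantics would declare the true model
inconsistent. Such comparisons are flagged as masked. Among consistent
assignments with the fewest active bins, those of minimal total length
are all reported (no arbitrary winner); adjacent same-sign bins merge
into one QTL interval. Statistical non-significance is taken at face
value as "equal"; the power caveat lives here, not in the model. A wide,
poorly localized interval can be refined around an external anchor marker
(`refine_qtl4`), where the flanking-region argument is the total width
centered on the anchor — the convention that reproduces the published
refined coordinates.

**Candidate filtering.** Expression experiments are filtered at
|log2 fold change| > 0.58 (1.5-fold) or Benjamini-Hochberg FDR < 0.05 —
an OR, since fold-change-only and FDR-only genes are both treated as
passing in the motivating analysis; an AND mode is a switch. The
reproducible set is the intersection across experiments, restricted to
the donor region. Variant-effect and human-orthologue evidence enter as
precomputed boolean flags; the evidence table reports all 2^3
intersection cells.

## The synthetic panel: what it emulates and what it does not

`sim_config()` defaults describe the study conditions end to end: 148
markers spanning 3-124.6 Mb of one chromosome; 12 strains in three
lineages whose nested fragments place breakpoints around four planted
QTLs (43.5, 52.5, 54.26, 113.915 Mb; signs +, +, -, +); body weight
Normal(31, 3) g; log-scale depot weights around 0.5 g with residual SD
0.4 and body-weight slope 0.08 per gram, giving the right-skewed raw
distribution (log-normal), a depot-body weight correlation near 0.5, and
coefficients of variation matching adult congenic mice. Donor mice carry
the strain fragment, truncated from the distal end with probability 0.15
at a uniform point (single paternal recombination); genotypes are masked
at rate 0.02. Planted effects are standardized: an effect of `e` shifts
log depot weight by `e` times the within-genotype SD (which includes the
body-weight contribution), so a fully linked marker shows Cohen's D
approximately `e`. Effect magnitudes default to 1.0 pooled-SD units —
congenic isolation shows large per-locus effects, and the motivating
panel reached LSD significance with groups as small as 12 — with QTL2 and
QTL3 equal and opposite so that a fragment spanning both is silent.

The generator draws fragments directly rather than simulating meioses
across backcross generations, models no residual background
heterozygosity, no strain-specific background effects (a random-intercept
toggle exists but defaults off), no age structure beyond noise, and no
genotyping error other than missingness. Passing tests on these panels
therefore validate the inferential machinery under the stated model, not
robustness to the full messiness of a real vivarium.

## Numerical and degenerate-input choices

Interval coordinates are 1-based inclusive base pairs throughout; set
operations are delegated to IRanges and are canonical (adjacent intervals
merge). Type-1 decompositions come from `stats::anova` on an `lm` fit;
aliased coefficients from rank-deficient designs are pivoted out and
flagged. Factor terms with one observed level are dropped with a warning.
Markers monomorphic in the analyzed mice score `NA` in the scan. A zero
pooled SD makes Cohen's D undefined (flagged). Strains with identical
donor regions would create a zero-weight MST edge and are merged into one
node with a warning. The exhaustive model search is capped (default 6
active bins) and reports the conflicting comparisons when nothing
consistent exists.

## Problem sizes used in the test suite

The bundled checks run the full pipeline on panels of 12 strains times 60
mice (about 720 mice, 148 markers), 50 replicate panels for the recovery
rate, pooled populations of 2,000 mice for effect-size calibration, and
brute-force oracles (bp-membership interval algebra, normal equations,
exhaustive spanning trees up to 7 nodes, exhaustive sign assignments up
to 9 bins) at toy scale. A single panel analysis takes about 1.5 s.

## Known limitations

Exact recovery of all four planted QTLs across replicate panels runs at
about 84%, not higher, and this is a property of the method, not of the
implementation: every qualifying replicate must avoid a false-positive
LSD verdict on each of the four structurally QTL-free tree edges that the
interval localization needs (binomial ceiling 0.95^4 ~ 0.81 at the
method's fixed alpha = 0.05, partially offset by the near-perfect power
of the informative comparisons). The common-segment half of the same
experiment — positive strains share no single region — holds in every
replicate. Similarly, the Cohen's D estimator at n = 2,000 has sampling
SD ~0.045, so single-panel estimates scatter accordingly around the
planted 0.5. Inference quality is bounded by breakpoint informativeness:
removing the strains whose boundaries isolate QTL3 collapses the minimal
model to two loci, mirroring the caution that sparse breakpoints can hide
linked QTLs.
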