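---
title: "From daily EAE scores to QTL and candidate genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From daily EAE scores to QTL and candidate genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaemap)
```

`eaemap` chains three analyses that are usually done with ad hoc spreadsheet
work and loosely coupled scripts: (1) deriving quantitative trait variables
(QTVs) from daily clinical scores of experimental autoimmune
encephalomyelitis (EAE), the induced mouse model of multiple sclerosis;
(2) mapping those traits to loci by regression on eight-founder haplotype
probabilities of a multiparent panel such as the Collaborative Cross (CC);
and (3) prioritizing positional candidate genes inside mapped intervals with
an ensemble of linear support vector machines over tissue-specific
functional gene networks. A synthetic-data layer generates every input with
known ground truth, so each stage's statistical behavior can be verified
without any animal or genotype downloads.

## Clinical-score preprocessing

Mice are scored daily on two 0–5 scales: the classic ascending-paralysis
scale and an axial-rotary (AR) scale for the atypical ataxic presentation.
The observation window defaults to days 5–50 post-induction (the usual
MOG~35–55~ protocol scores from day 5 for 50 days) and is configurable for
other protocols.

Two recording conventions are enforced before any trait is computed:

* **Humane endpoint.** A mouse scoring 5 on either scale for 72 hours is
  euthanized and its score on that scale is recorded as 5 for the remainder
  of the window. Because scoring is daily, "72 hours" is operationalized as
  3 consecutive recorded days at 5. If both scales sustain a 5, both are
  carried forward; the convention for a simultaneous double endpoint is not
  standardized anywhere we know of, so carrying both is the least
  destructive reading.
* **Mortality.** A mouse that dies after more than 2 consecutive days of
  disease has the presenting scale carried forward as 5; a mouse that dies
  with no signs, or with at most 2 days of disease, is excluded outright.
  The "presenting" scale is taken as the one with the higher score on the
  last day alive, ties going to classic, since the convention names one
  scale without saying which.

`apply_endpoint_rules()` is idempotent, never invents disease, and reports
exclusions rather than silently dropping mice. Missing interior days are
imputed by carrying the previous day's scores forward, with a warning and a
log: silently inserting zeros would fabricate remissions, which the course
classifier below would then misread. Missing leading days are taken as 0.

## Quantitative trait variables

The combined daily **disease score** is the classic score when only classic
is positive, the AR score when only AR is positive, and the mean of the two
on simultaneous days. The **cumulative disease score (CDS)** sums the
combined series; classic-CDS and AR-CDS sum the raw scales. Note that the
averaging rule makes CDS deliberately non-additive: a day scored classic 3 /
AR 1 contributes 2, less than the 3 contributed when AR is 0. This is a
property of the definition, not a bug, and one regression test pins the
counterexample.

**Incidence** requires at least 2 consecutive positive days of the combined
score; onset is the first day of the first qualifying run. **Subtype** is
mutually exclusive: classic-only and AR-only presentations are assigned
directly; mixed presentations compare classic-only days against AR-only
days, excluding simultaneous days, with exact ties assigned to classic and
flagged. **Disease course** is classified on the combined series:

* *monophasic* — an initial bout followed by zeros for the remainder;
* *relapsing-remitting (RR)* — initial bout, remission of ≥ 3 consecutive
  zero days, then a relapse of ≥ 2 consecutive positive days;
* *chronic* — the catch-all: persistent disease, including any series whose
  zero-dips are shorter than the 3-day remission requirement.

A bout that runs to the end of the window is chronic (there is no remitted
day), and a mouse carried to 5 by the endpoint rules can never remit, so
endpoint mice are always chronic. The classifier is validated against an
independent regular-expression rule-checker on tens of thousands of random
series.

`summarize_strain()` aggregates per-mouse rows to per-strain percentages and
means; excluded mice never enter a denominator.

## Genome scans on founder haplotype dosages

Each strain's genome is a mosaic of eight founder haplotypes, represented at
every marker by an 8-vector of ancestry dosages summing to 1 (founder order
A/J, B6, 129S1, NOD, NZO, CAST, PWK, WSB). The scan regresses the phenotype
on these dosages marker by marker:

$$\mathrm{LOD}_m = \frac{n}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1(m)}$$

where RSS₀ is the intercept-only residual sum of squares and RSS₁ adds the
eight dosages (one column dropped against the intercept for
identifiability; fully collinear columns at a marker are dropped by pivoted
QR rather than failing). An RSS floor of $10^{-12}\,\mathrm{RSS}_0$ caps the
LOD on numerically perfect fits. LOD is invariant to affine transforms of
the phenotype.

Preprocessing follows the standard order for mouse-level traits such as
CDS: residualize on experimental batch (cohort) first, then apply the
rank-based inverse normal (rank-Z) transform
$\Phi^{-1}\!\big((r-0.5)/n\big)$ with average ranks for ties. Strain-level
traits (incidence percentages) are rank-Z transformed only.

**Kinship.** `compute_kinship()` builds $K = \tfrac1M \sum_m D_m D_m^\top$
from the dosage matrices, rescaled to unit average diagonal, optionally
leave-one-chromosome-out (LOCO). When supplied to `scan_qtl()`, the model
is rotated by the eigendecomposition of $K$ with the heritability estimated
once under the null by maximum likelihood; the LOD contrast is then computed
in the rotated, reweighted space. Kinship is off by default: with a few
dozen strains the variance-component estimate is noisy, and both paths are
exposed so users can compare.

**Permutation thresholds.** Genome-wide significance is calibrated by
permuting phenotype values across *strains* — mouse rows move with their
strain, preserving within-strain correlation — and recording the genome-wide
maximum LOD of each permutation (default 1,000 permutations; 15% and 20%
thresholds by default, the relaxed levels appropriate for panels of ~30–40
strains and complex traits). When every strain has the same number of
replicates the implementation reuses each marker's orthogonal projection for
all permutations at once, which is why 200-permutation scans over 300
markers take well under a second; unequal group sizes fall back to an
explicit per-permutation scan.

**Peaks.** `founder_effects()` reports the eight allele effects at a marker
as deviations from their mean (sum-to-zero), so signs read directly as
"this founder's allele raises/lowers the trait". `credible_interval()`
normalizes $10^{\mathrm{LOD}}$ over a chromosome and returns the smallest
closed marker interval containing the peak with ≥ 95% of the mass;
`genotype_by_phenotype()` assigns each strain its maximum-dosage founder at
the peak (ties report all tied founders) for the classic
genotype-by-phenotype panel.

## Candidate-gene prioritization

Positional candidates inside a mapped interval are ranked by how much they
"look like" known disease genes in a tissue-specific functional network
(immune/hemolymphoid and CNS networks are the intended pair). A gene's
feature vector is its connection weights to every positive training gene;
genes with no connection to any positive carry no information and are
trimmed (reported, and later surfaced as *unrankable* rather than silently
dropped — a candidate can be biologically interesting yet invisible to the
network).

The ensemble trains 100 linear SVMs (cost C = 1, no feature scaling —
weights share one scale within a network; the kernel choice is deliberately
the simplest maximum-margin option). Each round draws, afresh and without
replacement, as many negatives as there are positives from the non-trait
gene pool. Candidates are scored per round by the false positive rate at a
cutoff equal to their own decision value,

$$\mathrm{FPR}_x = \frac{\mathrm{FP}}{\mathrm{FP}+\mathrm{TN}},$$

with ties counted on the positive side, averaged across the 100 rounds, and
reported as $-\log_{10}$ of the average with a floor of
$1/(100\,m + 1)$ ($m$ = negatives per round) so that a gene beating every
negative in every round keeps a finite score. Significance is mean
FPR ≤ 0.05. We aggregate as $-\log_{10}(\overline{\mathrm{FPR}})$, not the
mean of per-round $-\log_{10}$ values: under the alternative ordering a
single zero-FPR round would dominate the average through the floor, whereas
averaging FPRs first lets occasional zeros dilute as they should.

One design point deserves emphasis. The FPR reference set for each round is
a **fresh, out-of-sample draw of negatives**, not the round's training
negatives. A maximum-margin fit pushes its own training negatives' decision
values down, so scoring unseen candidates against them is anti-conservative:
in null simulations (no planted signal) the training-negative variant calls
roughly three times the nominal 5% of candidates significant, while the
out-of-sample reference is calibrated. Because the FPR is a rank statistic,
the final score is invariant under any strictly monotone transform of the
decision values, and calibrated class probabilities would change nothing.

`overlap_gene_lists()` (set intersection through a supplied mouse–human
orthology table) and `nssnp_segregating()` (nonsynonymous variants whose
alleles differ between the two founders with the strongest opposing effects,
inside the closed interval) implement the two follow-up filters typically
applied to prioritized candidates.

## What the simulators emulate — and what they do not

* `gen_scores()` draws trajectories from six archetypes (resistant,
  chronic, monophasic, RR, progressive-to-endpoint, AR-chronic) as
  piecewise-linear templates rounded to integer scores — the simplest family
  that realizes every course class exactly. Default penetrances
  (0/0.8–1.0), onsets (days 10–12 ± 1.5–2), and ~5 mice/sex/strain mirror a
  realistic panel screen. Score jitter (`noise_sd`) perturbs only
  symptomatic days by ±1: daily clinical scoring mis-grades a sick mouse by
  a point, but does not hallucinate symptoms in a healthy one, and
  fabricated one-day blips would change course classes rather than add
  noise.
* `gen_genomes()` draws founder mosaics from a per-chromosome Markov chain
  (switch probability 0.08/marker by default) — it does not reproduce real
  CC recombination maps, funnel pedigrees, or segregation distortion.
* `plant_qtl()` adds an additive effect of the summed high-founder dosage,
  an optional polygenic term from random founder effects at background
  markers, and Gaussian noise; incidence traits map through a logistic
  link.
* `gen_network()` plants a heavier-weighted module in an otherwise sparse
  exponential-weight background; real functional networks have hubs,
  degree heterogeneity, and correlated annotation biases that this does not
  model.

Passing tests on these simulators therefore demonstrate *statistical
correctness of the machinery* — calibration, recovery, bookkeeping — not
that any particular biological claim would replicate on real animals,
genotypes, or networks.

## Verification scales and numerical choices

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to be informative yet quick on a laptop: course recovery on 300 mice
per condition plus 10,000 randomized series against an independent
rule-checker; threshold calibration on 50 pure-noise datasets of 40 strains
× 300 markers with 200 permutations each (expected ~20% exceedance of the
20% threshold); planted-QTL recovery on 25 datasets of 40 strains × 5 mice
with the locus explaining ~40% of phenotypic variance; prioritization on a
2,000-gene network with a 150-gene planted module and 100 SVMs. Key
numerical conventions: positions are Mb with closed intervals; day indexing
is 1-based post-induction; rank-Z uses the $(r-0.5)/n$ offset; quantiles of
permutation maxima use R's default type-7 interpolation; all generators and
both random stages (permutations, SVM negative draws) take explicit seeds
and are bit-reproducible given one.

## Limitations

* The scan is single-locus; no multi-QTL model selection, no epistasis, and
  the X chromosome is treated as an ordinary listed chromosome.
* Kinship permutations reuse the null variance-component estimate rather
  than refitting per permutation.
* The subtype tie-break (equal classic-only and AR-only day counts →
  classic, flagged) and the double-endpoint carry-forward are conventions;
  both are logged so affected mice can be audited.
* Orthology and the tissue networks are inputs; nothing here builds or
  updates them.
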