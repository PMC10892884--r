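---
title: "Dominant-marker population genetics and virulence bioassays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker population genetics and virulence bioassays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issrpop)
```

## The setting

`issrpop` analyses two kinds of data produced by surveys of entomopathogenic
fungi such as *Metarhizium rileyi* collected from infected insect hosts:

1. **Dominant binary marker fingerprints.** ISSR (inter-simple sequence
   repeat) PCR yields presence/absence bands scored 1/0 per isolate and
   locus. Because the markers are dominant and the fungus is effectively a
   haploid clone, band frequency at a locus can be read directly as allele
   frequency. The survey this package models scored 31 isolates from 13
   geographic groups (8 with at least two isolates) at 54 loci amplified by
   7 primers.
2. **Insect virulence bioassays.** Cohorts of larvae (30 per replicate,
   3 replicates per fungal strain) are dipped in a spore suspension and
   observed daily for 10 days; cumulative deaths and mycosed ("rigid")
   cadavers are recorded.

The raw band matrix and the individual survival records behind such surveys
are typically not deposited; only summary tables are printed. The package
therefore does three things: implements every summary statistic so it can be
recomputed from any raw matrix; ships the printed summary tables as
worked-example anchors (`reference_table()`); and provides simulators with
known ground truth so each estimator's behaviour can be verified by
parameter recovery.

## Marker statistics

**Allele frequencies.** For a locus with band-present count $k$ among
$n$ scored isolates, the default haploid mode uses $\hat p = k/n$. For
diploid outcrossers the band-absent phenotype is the null homozygote, so the
`dominant-diploid` mode uses $\hat q = \sqrt{(n-k)/n}$, $\hat p = 1-\hat q$
(valid under Hardy–Weinberg). Missing cells leave the denominator
(pairwise-available policy); they are never treated as absent bands. The two
modes agree only at fixation, which the test suite asserts.

**Per-locus diversity.** With $q = 1-p$:
$N_a = \#\{\text{states observed}\}$, $N_e = 1/(p^2+q^2)$,
$H_e = 1-(p^2+q^2)$ (Nei's gene diversity), and the Shannon index
$I_s = -(p\ln p + q\ln q)$ with $0\ln 0 \equiv 0$. The algebraic identity
$H_e = 1 - 1/N_e$ holds exactly and is asserted to $10^{-12}$. A locus is
called polymorphic iff both states are observed — no 95%/99% frequency
criterion — because the printed primer survey counts (51 of 54 bands
polymorphic, 94.44%) are observed-state counts. Summaries are unweighted
means over loci; the percentage of polymorphic loci completes the
within-population panel.

**Diversity partition.** Per locus, with unweighted mean frequency
$\bar p$ over the $K$ analyzable populations:
$H_T = 2\bar p(1-\bar p)$ and $H_S = \frac1K\sum_k 2p_k(1-p_k)$, so
$H_S \le H_T$ (Jensen). The overall coefficient of differentiation is the
ratio of across-locus means, $G_{ST} = (\bar H_T - \bar H_S)/\bar H_T$ —
consistent with how summary tables print a Mean row — rather than the mean
of per-locus ratios. Monomorphic loci ($H_T = 0$) are excluded. The printed
34.82%/65.18% among/within "genetic variation" split is exactly
$100\,G_{ST}$ and $100(1-G_{ST})$, and that is how the package computes it
(the within percentage is computed as $100 - 100\,G_{ST}$ so the two always
sum to exactly 100).

**Gene flow.** $Nm = c\,(1-G_{ST})/G_{ST}$. The ploidy coefficient is a
genuine fork: the diploid form uses $c = 1/4$, the haploid form $c = 1/2$.
The study this models printed the diploid formula but a haploid-form value
($0.5 \times (1-0.3482)/0.3482 = 0.9360$), which is also what Popgene uses
for haploid data; since the organism is haploid the package defaults to
$c = 0.5$ and exposes both.

**Identity, distance, clustering.** Nei's identity
$I = J_{xy}/\sqrt{J_xJ_y}$ with $J_{xy}$ the across-locus mean of
$p_xp_y + q_xq_y$, and $D = -\ln I$. All 28 printed population pairs of the
worked example satisfy $|-\ln I - D| \le 5\times10^{-4}$, which is the
consistency check the package asserts. Individual-level similarity uses
Dice $2a/(2a+b+c)$ by default (the common NTSYS choice for dominant
fingerprints; the original analysis does not name its coefficient), with
Jaccard and simple matching available; distance is $1-$similarity.

UPGMA is implemented in the package rather than delegated to
`stats::hclust` because reproducible trees need a deterministic tie-break:
when several pairs attain the minimal distance, the pair whose (sorted)
cluster labels — a cluster is labelled by its lexicographically smallest
leaf — come first is merged. Merged-cluster distances are size-weighted
means, i.e. plain averages over all between-cluster leaf pairs; a
brute-force oracle that recomputes those averages from the original matrix
at every step must agree exactly, and does, on batches of random matrices.
Node heights are half the merge distance, so trees are ultrametric (asserted
to $10^{-9}$). Newick serialization goes through `ape`; note
`ape::as.phylo.hclust` halves hclust-convention heights, which
`to_newick()` compensates for.

## Bioassay statistics

**Summaries.** Final mortality per replicate is $100\cdot$deaths/exposed;
the mycosis rate counts mycosed cadavers out of exposed larvae. The
"±" values are standard errors over replicates ($s/\sqrt{r}$).

**Probit LT50.** Mortality is pooled across the replicates of a strain
(one regression per strain), transformed to the classical empirical probit
$Y = \Phi^{-1}(m) + 5$, and regressed by OLS on $X = \log_{10}t$. $r$ is the
Pearson correlation of $(X, Y)$ — matching the plain "correlation
coefficient" such tables print — rather than Finney's iteratively weighted
maximum likelihood, which could be added but would not reproduce a printed
$r$. Days at 0% or 100% mortality carry no probit information and are
dropped; the Bartlett adjustment $(d+0.375)/(n+0.75)$ is available as an
option for short assays where dropping extremes is wasteful.
$LT_{50} = 10^{(5-a)/b}$ is reported only when the slope is positive
(slopes below $10^{-8}$ are treated as zero — OLS on exactly constant
probits returns a slope of order $10^{-17}$) and observed mortality reached
50%, mirroring the "-" convention of bioassay tables for weakly virulent
strains. No Abbott control-mortality correction is applied: the assays
modelled here run no untreated control group.

**Kaplan–Meier.** Cumulative counts are expanded to individual event times
(a larva first counted dead on day $t$ died on day $t$), survivors are
censored at the last observation day, and the product-limit estimator is
computed via the `survival` package. The median lethal time is the smallest
event time with $S(t) \le 0.5$ (a $10^{-9}$ tolerance absorbs floating-point
round-off in the survival products). Without censoring the estimator reduces
to the empirical survival curve, which the tests assert exactly. Which of
the two procedures (probit vs Kaplan–Meier) produced the published LT50
values is ambiguous — the printed regression equations do not reproduce the
printed LT50s through $10^{(5-a)/b}$ — so the package reports both per
strain and asserts neither against the printed values.

## The simulators

**Markers: the F-model.** Per locus an ancestral frequency $\bar p$ is drawn
uniform on $[0.1, 0.9]$ (clamped to $[0.05, 0.95]$ to keep the beta shapes
non-degenerate), then population frequencies
$p_k \sim \mathrm{Beta}(\bar p\frac{1-F}{F},\,(1-\bar p)\frac{1-F}{F})$,
then isolate bands $\sim\mathrm{Bernoulli}(p_k)$. The dispersion parameter
$F$ *is* the expected differentiation, which makes parameter recovery the
natural end-to-end check: at $K = 8$ groups of $n = 50$ isolates and 54
loci, the mean estimated $G_{ST}$ over 200 replicates must fall within
$\pm 0.05$ of the generating $F = 0.35$ (it sits slightly below $F$, near
0.32–0.33: the realized among-group variance of $K = 8$ beta draws enters
through their sample mean, deflating $H_T$ by roughly a factor $1 - F/K$).
The study-shaped preset (default $F = 0.35$, the differentiation level the
modelled survey reports) uses group sizes 3, 8, 2, 2, 3, 2, 3, 3 plus five
singletons and the real per-primer band counts, so reports have the
original's shape. With 2–8 isolates per group the estimated $G_{ST}$ is
strongly inflated relative to $F$ (sampling noise in $\bar p$ masquerades as
among-group variance) — a caveat that applies equally to the real survey's
printed value. The simulator attaches the true $p_k$ matrix as an attribute
so law-of-large-numbers tests need not replay the RNG.

**Bioassay: log-normal death times.** Death probability by day $t$ is
$\Phi(b(\log_{10}t - \log_{10}LT_{50}))$ — exactly the model the probit
regression assumes — implemented as $T = 10^{\,\log_{10}LT_{50} + Z/b}$ with
$Z$ standard normal. A larva dying in $(t-1, t]$ is recorded on day $t$,
matching daily observation; survivors past the last day are censored. Note
the discretization makes integer-valued $LT_{50}$ a boundary case (half the
deaths land on the next day), so degenerate-limit tests place the true
$LT_{50}$ off the day grid. Mycosis is Bernoulli per dead larva.

What the simulators do **not** emulate: linkage between loci, scoring error
and band homoplasy (co-migrating non-homologous bands), missing data
mechanisms, overdispersion between bioassay replicates beyond binomial
sampling, and death from causes other than infection. Passing
parameter-recovery tests therefore shows the estimators are correct under
the stated model, not that the model captures every feature of real gels
and assays.

## Problem sizes and numerical choices

The test suite runs the full pipeline at the study's own shape
(31 × 54 markers; 31 × 3 × 30 bioassay), the UPGMA oracle on batches of
random 6 × 6 matrices, frequency convergence at $n = 10^4$, and the two
recovery studies at 200 marker replicates and a 900-larva cohort; the whole
suite completes in well under a minute. Other conventions: GST is clipped to
$[0, 1]$ against round-off; a zero identity yields an infinite Nei distance,
which `upgma()` refuses with a clear error rather than clustering; Newick
branch lengths default to 6 significant digits; all generators are
bit-for-bit reproducible from a mandatory integer seed.

## Known limitations

- Small-sample bias: neither $H_T/H_S$ nor Nei's identity is
  bias-corrected; with 2–3 isolates per group, estimates are noisy and
  $G_{ST}$ runs high. Bayesian dominant-marker estimators and rarefaction
  are out of scope.
- The variance partition is $G_{ST}$ restated as percentages, not an AMOVA
  with permutation tests.
- Probit fitting is OLS on empirical probits, not weighted ML; confidence
  intervals for LT50 (e.g. Fieller's) are not computed.
- The individual-level tree depends on an arbitrary similarity coefficient
  choice; with unpublished raw data the original figure's topology cannot
  be, and is not, a verification target.
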