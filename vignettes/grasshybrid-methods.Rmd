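---
title: "Methods: dominant-marker hybrid identification and trait-based selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker hybrid identification and trait-based selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasshybrid)
```

## The problem

Hybrid breeding in self-incompatible, cross-pollinated grasses (Russian
wildrye, *Psathyrostachys juncea*, is the motivating species) starts from a
controlled cross between two selected plants. Because pollination is done
under isolation bags on a partially self-fertile female, a fraction of the
harvested "hybrid" seed is actually maternal selfing — false hybrids that
would dilute every downstream measurement. The workflow this package
implements is the standard low-budget answer:

1. score dominant SSR bands (present/absent per lane) for both parents and
   every putative offspring;
2. find **characteristic bands** — bands present in exactly one parent;
3. call an offspring a **true hybrid** if it carries at least one *paternal*
   characteristic band, a **maternal (self) type** if all paternal
   characteristic loci are scored and absent, and compute population
   **purity** = (tested − maternal type) / tested × 100%;
4. cross-check the false-hybrid proportion against the female parent's
   bagging-isolation self-fertility range;
5. evaluate the quantitative traits of the confirmed hybrids (normality,
   variation, correlation, heterosis) and rank plants by a PCA-based
   synthesis score to pick the non-recurrent parent for backcrossing.

## Marker model and its assumptions

Bands are modelled as dominant biallelic loci: a diploid plant with band
allele dosage $d \in \{0,1,2\}$ shows the band iff $d>0$, so heterozygotes
are indistinguishable from homozygous carriers. Consequences used
throughout:

* A **paternal characteristic band** (father banded, mother not) appears in
  a true-cross offspring with probability 1 if the father is homozygous
  ($d=2$), and 1/2 per band if heterozygous. With $k$ independent
  heterozygous paternal bands and selfing rate $s$, the expected
  maternal-type call fraction is $s + (1-s)\,2^{-k}$ — a quantity the test
  suite recovers from simulation. With at least one homozygous paternal
  band, classification error is zero and estimated purity equals
  $100(1-\hat s)$ exactly.
* A maternal self carries only maternal alleles, so it can never show a
  paternal characteristic band (no mutation is modelled).

**Classification edge cases.** An offspring with too few present calls to
reach `min_paternal_bands` is a maternal type only when *every* paternal
characteristic locus is scored; if any is missing the lane cannot exclude
hybridity and the plant is **unresolved**. Unresolved plants are excluded
from the purity denominator ("tested plants" are plants with interpretable
lanes).

**Purity convention.** One published formula line prints a purity as
(tested − true hybrids)/tested while reporting the value of
true hybrids/tested. This package always computes
purity = (tested − maternal type)/tested, which reproduces both of the
published percentages (96.75% for 4/123 false hybrids, 95.80% for 6/143).

## Diversity and similarity statistics

Allele frequencies at a dominant locus are not observable directly; two
estimators are first-class because the original analyses (Popgene-style)
do not say which was used and the raw matrices are not public:

* `phenotypic` (default): $p$ = band frequency — treats the band itself as
  the allele;
* `hwe_dominant`: assumes Hardy–Weinberg proportions, $q=\sqrt{f_{absent}}$.

Per locus: $na = 1 + [0<p<1]$, $ne = 1/(p^2+q^2)$, Nei diversity
$h = 1-p^2-q^2$, Shannon $I = -p\ln p - q\ln q$. Per primer these are
arithmetic means over the primer's loci, with $T$ = locus count and PPB the
percent of polymorphic loci; the panel "Mean" row averages per-primer means
rather than pooling loci, matching the printed tables. Two identities hold
by construction and are asserted on every simulated panel:
$na_{mean} = 1 + \mathrm{PPB}/100$ and $h = 1 - 1/ne$ per locus.

Similarity is computed from the pairwise band contingency counts $a,b,c,d$
over loci scored in both individuals. Simple matching $(a+d)/(a+b+c+d)$ is
the default (the common NTSYS qualitative choice); Dice and Jaccard are
provided because the original coefficient is unnamed. No attempt is made to
reproduce published similarity ranges — the underlying matrices are
supplementary-only.

## Quantitative trait statistics

* **Normality**: one-sample Kolmogorov–Smirnov distance against
  $N(\bar x, s)$ with plug-in parameters. The default p-value is the
  classical asymptotic one (`estimated_params`) because that is what the
  consumer packages behind the published figures report; it is
  anticonservative with estimated parameters, so a Monte-Carlo
  `lilliefors` variant is offered as the correct alternative. Verdict
  "normal" at $p \ge 0.05$.
* **Moments**: $g_1 = m_3/m_2^{3/2}$, excess $g_2 = m_4/m_2^2 - 3$ (normal
  ⇒ both ≈ 0). SD is the sample SD ($n-1$) everywhere; the source does not
  state its convention and this one is declared once and used throughout.
* **Correlation**: Pearson over pairwise-complete rows with the two-sided
  t-test, tiers \*,\*\*,\*\*\* at 0.1/0.05/0.01. No multiplicity correction
  by default (none was applied originally); Benjamini–Hochberg is a flag.
* **Heterosis**: MPH $=(\bar F_1-MP)/MP$ and heterobeltiosis
  $HB=(\bar F_1-HP)/HP$ with $MP$ the mid-parent and $HP$ the higher-parent
  mean, reported as percentages at 2 dp together with the means of the
  positive and of the negative values across traits. $HB \le MPH$ whenever
  parent means are positive.

**Which published heterosis cells recompute.** Recomputing from printed
(rounded) parental and F1 means reproduces, at 2 dp: reproductive tiller
number (MPH 116.31, HB 54.39), nutritional tiller number (HB 80.45), tiller
height (6.64, −1.34), spikelet number per spike (1.98, −9.90). Other cells
(e.g. thousand kernel weight 36.80 vs 36.49 recomputed; seed number per
plant 143.17 vs 171.76 recomputed) do not recompute from the printed means
— they were evidently derived from unrounded data — and are excluded from
any numeric assertion here.

## PCA synthesis score

PCA is performed on the correlation matrix of the (standardized) traits —
the published eigenvalues sum to ≈ 12, which fixes this choice. Components
are retained until the cumulative contribution rate
$\lambda_i/p$ reaches 0.85 by default (the reference analysis retained 6
components at 86.41%). Per-plant component scores are
$Y_i = z^\top v_i$ with unit-norm eigenvectors $v_i$, and the comprehensive
score is the contribution-weighted mean

$$Z = \frac{\sum_{i=1}^k w_i Y_i}{\sum_{i=1}^k w_i}, \qquad
  w_i = \frac{\lambda_i}{p},$$

with selection of plants with $Z > 0.80$ (strict). Numerical conventions:

* **Sign orientation**: each eigenvector is flipped so its
  largest-magnitude loading is positive. Eigenvector signs are otherwise
  arbitrary and $Z$ is *not* sign-invariant, so per-plant $Z$ from a fresh
  fit matches a published table only up to component sign choices; the
  published-score checks therefore feed the printed $Y$ vectors and printed
  contribution rates directly into `synthesis_score()`.
* **Missing traits**: plants with any missing trait are excluded from the
  fit and reported with `NA` scores, mirroring the exclusion of plants with
  incomplete data for lack of reproductive organs.
* **Ties**: ranking breaks ties on plant id, stably.
* $Z$ is reported at 2 dp; ranking and selection use unrounded values.

## What the synthetic generator emulates — and what it does not

`simulate_parents()` / `simulate_offspring()` model diploid parents with
per-locus dosages, Mendelian gamete sampling with free recombination,
maternal selfing as the only contamination mode (matching the
self-fertility interpretation of false hybrids; stray third-party pollen is
not modelled), and completely-at-random missing calls (gel dropout is never
quantified in the source, so 2% was chosen once as a realistic PAGE
dropout level for the `paper-like-F1` scenario). Loci are unlinked — no map
exists for this species in the source — and band homoplasy (two different
fragments in one size bin) is not modelled. A green classification test on
these data therefore establishes the *logic* of the caller, not robustness
to linkage, scoring error or homoplasy.

The `paper-like-F1` scenario fixes the stated world: 123 offspring, three
primer pairs with 10/16/12 loci, 3/3/2 paternal and 2/2/3 maternal
characteristic bands, selfing rate 0.0325 (the published 4/123 = 3.25%
false-hybrid proportion), homozygous paternal characteristic bands.
Parental genotypic states at marker loci are never stated in the source, so
they are explicit parameters; the scenario's homozygous choice is what
makes purity a deterministic function of the realized selfing draw.

`simulate_traits()` targets, per trait, an offspring mean of
$(1+\mathrm{MPH})\times MP$ and an SD of $\mathrm{CV}\times$ that mean (CV
is matched at the offspring scale because the reference table reports CV
only for the F1 population). Noise is multivariate normal under a declared
correlation; the default 12-trait spec uses a two-block exchangeable
structure (0.3 within the nutritional and reproductive blocks, 0.1 across)
— a single realistic choice, not a fit to the published correlation figure.
The two traits that failed normality in the field data are pushed through a
monotone standardized-lognormal tilt
$(e^{\lambda z} - e^{\lambda^2/2})/\sqrt{e^{\lambda^2}(e^{\lambda^2}-1)}$
with $\lambda = 0.75$ (skewness ≈ 3.3) after correlation is imposed;
correlations involving skewed traits are attenuated and only guaranteed to
±0.1. Negative draws are possible for high-CV count traits and are left in
place rather than truncated, which would bias the targeted means.

## Known limitations

* Dominant calls only: no codominant genotyping, no Hardy–Weinberg tests.
* The `hwe_dominant` estimator is biased at small samples and is offered
  for comparability, not as a recommendation.
* The asymptotic KS p-value with estimated parameters is anticonservative;
  use `lilliefors` when the verdict matters.
* Published diversity values (h, ne, I) and similarity ranges are not
  reproduced: they depend on supplementary-only raw matrices.
* The CLI is a thin, deterministic wrapper; it does no plotting.
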