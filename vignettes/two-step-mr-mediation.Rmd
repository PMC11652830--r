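---
title: "Two-step Mendelian randomisation mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomisation mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem and the model

Two-sample Mendelian randomisation (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instruments, with the
variant–exposure and variant–outcome associations taken from two
non-overlapping GWAS. `mrmediate` implements the full workflow for a
three-trait mediation question: an exposure $X$, a candidate mediator $M$,
and an outcome $Y$, assumed to follow the linear structural model

$$M = aX, \qquad Y = c'X + bM,$$

so the total effect of $X$ on $Y$ is $c' + ab$, the indirect (mediated)
effect is $ab$, and the proportion mediated is $ab/(c'+ab)$, reported
*signed*: when the indirect and total effects oppose, the proportion is
negative, and we do not take absolute values.

The three instrumental-variable assumptions are operationalised as checks,
not articles of faith: relevance through the per-variant $F$ statistic
($F > 10$), exclusion through the MR-Egger intercept and MR-PRESSO, and
heterogeneity through Cochran's Q.

## Instrument selection

Three filters, applied in a fixed order: genome-wide significance
($p < 5\times 10^{-8}$, strict inequality), greedy LD clumping, then the
weak-instrument filter $F = (\beta/\mathrm{se})^2 > 10$. The order is part
of the contract — filtering on $F$ before clumping can change which index
variants survive.

Clumping sorts candidates by ascending p (ties broken lexicographically by
variant id, for determinism), takes the best remaining variant as an index,
and removes every remaining same-chromosome variant within the window whose
$r^2$ with the index reaches the threshold. Defaults are $r^2 < 0.001$ and
10,000 kb. A published restatement of this criterion elsewhere gives
"$R^2 > 0.01$"; we follow the data-sources description ($0.001$ as the
exclusion threshold) and expose it as an argument, so either convention is
one flag away. No LD reference panel is bundled: the LD matrix is an
explicit input (identity by default), which keeps the package free of
downloads; real-data users supply a panel-derived matrix.

The single-SNP approximation $F = (\beta/\mathrm{se})^2$ is used because it
needs neither per-variant sample sizes nor allele frequencies; it equals
the squared Wald $z$.

## Harmonisation

GWAS exports do not share effect alleles, so outcome (and additional
exposure) records are aligned to the first exposure's effect allele:
identical alleles pass through; swapped alleles negate the beta and map
$\mathrm{eaf} \mapsto 1-\mathrm{eaf}$; complementary-strand records are
mapped through A/T and C/G first. Palindromic variants (A/T or C/G) cannot
be resolved from alleles alone: when the effect-allele frequency is within
0.08 of 0.5 in any dataset, or missing, the variant is dropped as
ambiguous; otherwise orientation is inferred from frequency concordance.
The window default (drop when $\mathrm{eaf} \in [0.42, 0.58]$) is the
field-standard conservative choice; the source analysis never states how
palindromes were handled, so this is a package design decision, documented
rather than hidden. Every exclusion is recorded with a reason
(`missing`, `palindromic_ambiguous`, `allele_mismatch`), and row count plus
dropped count always equals the instrument count.

After harmonisation, rows are re-oriented so exposure betas are
non-negative *only* for MR-Egger (the intercept is uninterpretable
otherwise); all other estimators are orientation-invariant and use rows
as-is.

## Estimators and their numerical choices

**IVW.** Weighted least squares of `by` on `bx` through the origin,
weights $1/\mathrm{se}_Y^2$. The default is multiplicative random effects —
the fixed-effect SE times $\sqrt{\max(1, Q/(n-1))}$ — because heterogeneity
is the norm in behavioural and psychiatric traits; `mode = "fixed"` is
available. The truncation at 1 means the random-effects SE never undercuts
the fixed one. P-values are normal-based.

**MR-Egger.** The same regression with an intercept; coefficient
covariance is the unscaled WLS covariance inflated by
$\max(1, Q/(n-2))$, and inference uses $t_{n-2}$. At least three
instruments are required.

**Weighted median.** Ratios $by_i/bx_i$ with weights $bx_i^2/\mathrm{se}_{Y,i}^2$;
the estimate interpolates the sorted ratios at cumulative standardized
weight $(\sum_{j\le i} w_j - w_i/2)/\sum_j w_j = 0.5$. The SE comes from a
parametric bootstrap (default 5000 draws) resampling both `bx` and `by`
from normal distributions; the seed is mandatory, so results are exactly
reproducible.

**Wald ratio.** The single-instrument base case, $by/bx$ with first-order
SE $|\mathrm{se}_Y/bx|$; the second-order form (adding
$by^2\mathrm{se}_X^2/bx^4$) is available and agrees within 1% for strong
instruments.

**MVMR.** Weighted multiple regression of `by` on $k$ exposure columns
without intercept; coefficient $j$ is exposure $j$'s direct effect. SEs
use $\max(1, Q/(n-k))$ inflation and $t_{n-k}$ inference. Exposure
columns with condition number above $10^8$ raise a collinearity error
rather than returning unstable coefficients. Instruments are the union of
each exposure's selected instruments, restricted to variants present in
all datasets — standard MVMR-IVW practice; conditional F statistics are
out of scope, and plain per-exposure F is reported instead.

**Cochran's Q.** $\sum (by_i - \hat\beta bx_i)^2/\mathrm{se}_{Y,i}^2$ with
$n-1$ df at the IVW estimate ($n-2$ for the Egger residual).

**MR-PRESSO.** The observed residual sum of squares uses leave-one-out IVW
estimates; the null distribution is parametric (default 1000 simulations —
desk-scale runtime with a stable p at the 0.05 level; the count is a
configuration knob since the source analysis does not state one). The
Monte-Carlo p uses the add-one estimator $(1 + \#\{\mathrm{sim} \ge
\mathrm{obs}\})/(1 + n_\mathrm{sim})$, which can never be zero. Outliers
are flagged when their Bonferroni-corrected per-variant simulation p falls
below $\alpha/n$, and removed **once** (no iteration) before IVW
re-estimation, matching the one-shot outlier-removal re-analysis design.
Note that a sufficiently large outlier biases the leave-one-out estimates
of the *other* instruments, so neighbouring variants can be co-flagged;
the planted outlier is always among the flagged set, which is the property
the tests assert. The per-variant outlier test needs
$n_\mathrm{sim} \ge n/\alpha$ to be able to reject at all; with the
defaults (1000, 0.05) this holds for up to 50 instruments.

## Two-step mediation

Step a is the univariable X→M estimate; step b is the *mediator's MVMR
coefficient* from the joint regression of Y on (X, M) — not the
univariable M→Y estimate, which is confounded by the X path (both are
reported). The indirect effect is $ab$ with first-order delta SE
$\sqrt{b^2\mathrm{se}_a^2 + a^2\mathrm{se}_b^2}$; the covariance term is
set to zero because the two estimates come from non-overlapping two-sample
fits, a documented assumption rather than an approximation error bound.
The pipeline computes the decomposition only when the mediator's MVMR
coefficient is significant at `mediation$alpha` (default 0.05), mirroring
the practice of decomposing only MVMR-significant paths; the gate is a
flag, not a hard-coded rule.

## The synthetic-data generator

`simulate_mediation_gwas()` generates summary statistics directly — no
individual-level genotypes — because two-sample MR consumes only summary
data, and this keeps the generator desk-scale. Per-instrument true effects
on their own trait are $\gamma_i \sim N(0, \mathrm{effect\_scale}^2)$ and
propagate linearly ($a\gamma$ to the mediator, $(c'+ab)\gamma$ to the
outcome). Observed betas add noise with the standard per-allele-regression
SE $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$, which yields realistic
F statistics for the weak-instrument filter to act on. Defaults — 100
instruments per trait, GWAS sample sizes of $10^5$, MAF in (0.05, 0.5),
effect scale 0.1 — emulate a well-powered UK-Biobank-scale behavioural
GWAS: instrument counts in the tens-to-hundreds and median F in the
hundreds. Structural defaults $a = 0.4$, $b = 0.5$, $c' = 0.1$ give total
0.3 and proportion mediated $2/3$, a strong but not degenerate mediation
signal.

Directional pleiotropy is defined on the allele that increases the
instrument's own trait — the orientation under which an Egger intercept is
interpretable; without this convention a nonzero pleiotropy mean cancels
in expectation when rows are re-oriented. Planted outliers multiply the
instrument's true outcome effect by `outlier_multiplier` (default 10).
Instrument sets for exposure and mediator are disjoint by default so the
MVMR union logic is genuinely exercised; an overlap fraction is
configurable.

What the generator does **not** model: LD between instruments (identity
LD), binary-trait liability scales (all effects are continuous-scale; the
real ADHD GWAS is case-control), sample overlap between the two samples,
winner's-curse-free replication, and population stratification. A green
parameter-recovery test therefore establishes that the estimators are
correct under the stated linear model — not that any real-data result is
unbiased.

## What the tests establish

- Exact oracle agreement: IVW and MVMR equal brute-force weighted
  least squares (`lm`) to $10^{-10}$; Egger recovers exact affine fixtures
  to machine precision.
- Published-arithmetic agreement: the product-of-coefficients and signed
  proportion reproduce the reference decompositions (0.426, −22.46%,
  0.433, −19.62%, 64.8%) from their printed inputs; one printed proportion
  differs by 0.01 percentage points from the recomputation because the
  printed inputs are 3-d.p. roundings.
- Calibration: Cochran's Q rejects at 5% ± 2% under homogeneity; the Egger
  intercept p is uniform under no pleiotropy; null-effect IVW type-I error
  is 5% ± 2%.
- Robustness: a planted 10× outlier is PRESSO-flagged in ≥ 90% of 100
  seeded repetitions; the weighted median stays within 0.05 of truth with
  40% invalid weight.
- Parameter recovery: the full two-step pipeline recovers $a$, $b$, the
  total effect and the proportion mediated within two SEs on the fixed
  reference simulation, and the delta-method CI covers the true indirect
  effect 95% ± 3% over 500 replicates. The coverage loop estimates on the
  known instrument sets without genome-wide selection, because it tests the
  interval; selection-induced winner's curse is a (small) property of the
  design that the single-run pipeline test retains.

## Known limitations

- Real accession-based results (odds ratios on external GWAS) are not
  reproduced here; they require the external data and are supported only
  by pointing the configuration at exported TSVs.
- The distortion test of MR-PRESSO is implemented but deliberately not part
  of the validated surface.
- No proxy-SNP lookup, no VCF parsing, no multi-allelic variants or
  indels, no liftover.
- One mediator per decomposition; multiple simultaneous mediators and
  bootstrap mediation CIs are out of scope.
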