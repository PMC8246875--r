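---
title: "Semi-automated Rasch item selection: model, criterion, and design choices"
author: "raschsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated Rasch item selection: model, criterion, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschsel)
```

## The problem

Clinimetric instruments — questionnaires measuring a latent trait such as
sleep-related distress or coping ability — usually start life as a long item
pool. Classical Rasch analysis shortens the pool by iteratively removing
items that misfit (outfit/infit far from 1), load on a second dimension, or
violate local independence. Those judgements are made by an expert, one item
at a time. `raschsel` replaces the per-item judgement with a single global
criterion so that item selection becomes an optimization problem, while
keeping the standard diagnostics available for the sanity checks no
automated procedure removes the need for.

## The response model

Responses are ordinal: subject $n$ answers item $i$ in category
$x_{ni} \in \{0, \dots, m_i\}$. The package uses the generalized partial
credit model (GPCM). With ability $\theta_n$, thresholds
$\beta_{i1}, \dots, \beta_{im_i}$ and discrimination $\alpha_i > 0$,

$$P(X_{ni} = x) \;=\;
\frac{\exp\!\big(\alpha_i \sum_{j \le x} (\theta_n - \beta_{ij})\big)}
     {1 + \sum_{k=1}^{m_i} \exp\!\big(\alpha_i \sum_{j \le k} (\theta_n - \beta_{ij})\big)},$$

with the empty sum for $x = 0$. Special cases: $\alpha_i \equiv 1$ gives the
partial credit model; $m_i = 1$ gives the two-parameter logistic and, with
$\alpha_i = 1$, the dichotomous Rasch model. The discrimination parameter is
the reason for choosing the GPCM here: it encodes how *predictable* an
item's responses are, which is exactly what the outfit/infit statistics of a
Rasch analysis probe (the two are strongly inversely related in fitted
models; `item_fit()` exposes both).

## Penalized joint estimation

All fits are joint maximum likelihood (persons and items together) with
ridge penalties:

$$F_S = \sum_{i \in S}\sum_n \log P(X_{ni} = x_{ni})
  \;-\; \lambda_\theta \sum_n \theta_n^2
  \;-\; \lambda_\alpha \sum_{i \in S} (\ln \alpha_i)^2 .$$

The penalties do two jobs: they resolve the translation/scale
non-identifiability of joint estimation without hard constraints, and they
keep estimates finite for perfect or zero scores. Penalizing
$\ln \alpha_i$ (rather than $\alpha_i$) shrinks discriminations toward 1,
i.e. toward the partial credit model, and makes positivity automatic since
the optimizer works in $(\theta, \beta, \ln\alpha)$.

One caveat worth knowing: $\beta$ itself carries no penalty, so for an item
answered entirely in one extreme category the likelihood supremum lies at
infinite thresholds. In practice the fit stops at large finite values
because the gradient vanishes there; abilities remain pinned by their own
ridge. This is documented behaviour, not an error.

Defaults are $\lambda_\theta = .05$, $\lambda_{in} = 50$ for the included
itemset and $\lambda_{out} = .05$ for the excluded itemset. The asymmetry
is essential (see below); the precise values are not, as long as
$\lambda_{in} \gg 1 \gg \lambda_{out}$.

## The IPOQ-LL criterion

For a candidate instrument $S_{in}$ (complement $S_{out}$), `ipoq_ll()`
computes:

1. a joint fit on $S_{in}$ under $\lambda_\theta, \lambda_{in}$, giving
   $\hat\theta, \hat\beta_{S_{in}}, \hat\alpha_{S_{in}}$;
2. IQ-LL: the *unpenalized* log likelihood of those parameters on $S_{in}$;
3. a fit of the excluded items' thresholds and discriminations under
   $\lambda_{out}$, with abilities held at $\hat\theta$;
4. OQ-LL: their unpenalized log likelihood;
5. IPOQ-LL = IQ-LL + OQ-LL.

Every item contributes exactly once, to one side, so the criterion is
comparable across splits of the same survey. The logic: a good instrument
must estimate abilities that explain its own items *and* still predict the
left-out items reasonably well. Because excluded items may shrink their
discrimination cheaply ($\lambda_{out}$ small), unpredictable items lose
little likelihood when excluded but drag the fit down when included — which
is how goodness-of-fit screening emerges from the criterion. Items from a
second dimension are likewise better accommodated outside the instrument.
With equal penalties ($\lambda_{in} = \lambda_{out}$) moving an item into
the instrument can never decrease the criterion; the asymmetric defaults
create the interior maximum that serves as the stopping rule.

## Search

`ipoq_search()` implements stepwise selection from the full survey
downward. Each cycle removes the single item whose removal gives the
highest IPOQ-LL, then attempts forward recovery: the best single addition
is accepted if it strictly improves the best score already recorded at the
resulting size by more than `improve_tol` (default $10^{-6}$), and an
accepted addition earns one further attempt. The exact interplay of
backward and forward passes is a design choice of this package: the
two-attempt rule reproduces the "remove two items, re-introduce an
earlier one" recoveries expected from this class of procedure while the
strict-improvement threshold and a visited-set guard make cycles
impossible. Candidate fits are warm-started from the parent split but
polished to full tolerance, so the trajectory does not depend on
evaluation order; the whole search is deterministic and single-threaded by
construction (determinism would have to be preserved by any future
parallel candidate evaluation).

The suggested instrument is the size at the global IPOQ-LL maximum, but
`best_itemset(trajectory, k)` reads off the best set of any visited size,
e.g. to match the length of an existing instrument. `ipoq_exhaustive()`
scores all $2^P - 1$ subsets (capped at $P \le 20$) and is used as the
oracle for the stepwise search in the tests: on four-item surveys the
greedy trajectory matched the exhaustive optimum in at least 80% of seeded
instances, and can by construction never exceed it by more than optimizer
noise (~0.01 on the IPOQ-LL scale for the default tolerances).

## Optimization details

* L-BFGS-B on the full free block with analytic gradients (implemented in
  C++); category sums use max-subtraction so extreme
  $\alpha(\theta - \beta)$ cannot overflow.
* Convergence: gradient inf-norm below $10^{-5}$ or relative objective
  change below $10^{-9}$, iteration cap 500 per fit; hitting the cap
  flags the fit (`converged = FALSE`) and warns, never silently. Doubling
  precision moves IPOQ-LL by well under 0.01 on the simulated designs.
* Initialization: abilities from standardized raw sum scores on the
  itemset, thresholds 0, $\ln\alpha = 0$; warm starts override.
* With abilities fixed, excluded items are conditionally independent, so
  the excluded-set fit runs one small optimization per item rather than
  one joint block — same optimum, better conditioning (the near-flat
  $\ln\alpha$ direction of a noise item slows a joint quasi-Newton run
  considerably).
* Abilities pass unchanged from the included fit to the excluded fit (no
  re-centering between the two stages).
* Ties among candidate splits are broken toward the lowest item index;
  exact ties occur for duplicated items.
* Single-start fits are the deterministic default; `multistart` with
  seeded jittered starts exists for small-instance property checks, where
  those checks also raise the iteration cap.

## Diagnostics conventions

The criterion does not print fit statistics, so the package provides the
standard ones, with these (documented, not universal) conventions:

* outfit$_i$ = mean over observed cells of $z_{ni}^2$,
  infit$_i = \sum (x - E)^2 / \sum W$, with $E, W$ the model mean and
  variance at the *fitted* discriminations (not forced to 1). Items with
  zero observed response variance are reported as `NA` with a warning.
* Residual correlations are Pearson correlations of standardized
  residuals; summaries report the mean of absolute off-diagonal values
  (plus the signed mean, since either aggregation is found in practice)
  and the maximum, to which the conventional $|r| > .3$ flag applies.
* Ability standard errors use the unpenalized test information
  $I_n = \sum_i \alpha_i^2 W_{ni}$ at the penalized estimate: the ridge
  shrinks the point estimate but is not counted as information about the
  subject.
* PSR $= (\mathrm{var}(\hat\theta) - \overline{se^2}) /
  \mathrm{var}(\hat\theta)$, clipped to $[0, 1]$.
* `overlap_probability()` is the exact hypergeometric tail; use it to
  judge whether agreement between two instruments of given sizes could be
  chance.
* `random_baseline()` draws uniform instruments of a fixed size and
  computes these statistics per draw, the reference distribution against
  which a selected instrument should be judged.

## Simulated designs

Three seeded generators reproduce the survey designs used to validate the
procedure; all default to 301 subjects and 6-item blocks.

* `sim_inhomogeneous()`: one dimension, three blocks with discriminations
  {.04–.065}, {.2–.45}, {2.6–2.85}; abilities on an even grid over
  $[-3, 3]$.
* `sim_multidimensional()`: three blocks on three uncorrelated dimensions
  (the first block's ability grid, independently permuted for the other
  two), equal discriminations.
* `sim_correlated()`: two polytomous blocks whose ability vectors have
  *empirical* correlation exactly $\rho$ (built from a standardized
  normal and its orthogonalized residual), each mapped affinely onto
  $[-4, 4]$.

Two settings were genuinely open and are this package's reconstructions,
chosen once: thresholds are evenly spaced and centered (0 for dichotomous
items; $(-1.5, -.5, .5, 1.5)$ for 5-category items), and the equal
discrimination of the multidimensional designs is 1 (the partial credit
model). "Dichotomous" and "polytomous" mean 2 and 5 categories
respectively. The qualitative outcomes these designs exist to show — the
IPOQ-LL peak at one 6-item block, block-by-block removal, mixing of
correlated dimensions from $\rho \approx .4$ — are robust to these
choices, and the peak size can fluctuate by an item across seeds, which is
why the acceptance checks use the modal size over five replicate surveys.

What the simulators deliberately do not emulate: missing responses,
differential item functioning, disordered-threshold pathologies, and
real-world category sparsity. Passing the simulated checks therefore says
nothing about those features; on real data the category-coverage
validation and `recode_categories()` handle sparsity before fitting, and
the rest remains the analyst's job.

## Degenerate inputs and edge rules

* An empty included itemset is an error (abilities would be
  unidentified); the full itemset is legal and has OQ-LL = 0 exactly.
* Items with an unobserved intermediate category are rejected at load
  time with a pointer to `recode_categories()`; merging is never done
  silently. Simulated data may declare intended category counts instead.
* Missing cells simply drop out of every likelihood, moment and residual
  sum (complete-case per cell); no missingness model is implied.
* Subjects with no observed response on the included itemset are
  reported; their ability is whatever the ridge makes it (0).

## Problem sizes in the tests

The test suite runs the three designs at their native 301 × 18 (or
301 × 12) size — five replicate surveys per design for the peak-location
checks — and uses 30–60-subject, 3–5-item instances for the
property-style checks (gradient correctness, additivity, the
equal-penalty monotonicity, stepwise-vs-exhaustive). The Monte-Carlo
cross-check of the overlap probability uses $10^6$ draws.

## Known limitations

* Joint (not marginal/conditional) estimation: ability estimates carry
  the usual JMLE small-test bias; with six informative items the
  ability–truth correlation plateaus around .95 on the simulated grid.
* One latent dimension per fit; no DIF terms; no missing-data model.
* The stepwise scheme is greedy with limited recovery: it can stay below
  the exhaustive optimum (reported gap in the tests, not hidden).
* `ipoq_exhaustive()` is exponential in $P$ and guarded at 20 items.
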