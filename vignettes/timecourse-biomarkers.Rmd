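---
title: "Selecting consistently predictive genes from time-course expression data"
author: "tcenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting consistently predictive genes from time-course expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcenet)
```

## The model and its assumptions

`tcenet` targets binary treatment-response prediction from longitudinal
expression profiles: the same subjects are measured at $T \ge 2$ time
points, each visit giving an $n \times p$ matrix $X_t$, with one label
per subject ($y_i = 1$ good responder, $0$ poor responder). The working
model at any single time point is logistic,

$$\Pr(y = 1 \mid X_t) = \frac{1}{1 + e^{-(X_t\beta + \beta_0)}},$$

fitted with a weighted elastic-net penalty,

$$\min_{\beta_0,\beta}\; \frac{1}{n}\,\mathrm{NLL}(y, X_t\beta+\beta_0)
  + \lambda \sum_{j=1}^{p} w_j\Big[\tfrac{1-\alpha}{2}\beta_j^2
  + \alpha\,\lvert\beta_j\rvert\Big],$$

with the intercept unpenalized. The per-gene penalty factor $w_j$
multiplies *both* penalty terms, which makes the solution exactly
invariant under $(w, \lambda) \to (c\,w, \lambda/c)$ — a property the
test suite asserts to $10^{-8}$. The mixing parameter $\alpha = 0.5$ by
default; the elastic net (rather than the lasso) is used precisely
because co-regulated genes are strongly correlated and the ridge
component lets correlated informative genes enter together.

The loss is the binomial negative log-likelihood. The penalized
formulation is sometimes written with a least-squares loss in this
setting, but the response is binary and the prediction model is
logistic throughout, so the binomial likelihood is the coherent choice;
the $(1/n)$ scaling keeps the meaning of the $\lambda$ grid independent
of the subsample size.

Rather than tuning $\lambda$ by cross-validation — which tends to
reward genes that are only selected in narrow $\lambda$ windows —
the package uses **stability selection**: draw $B$ stratified
subsamples, fit the penalized model on each subsample at every
$\lambda$ of a fixed grid, record per-gene selection frequencies, and
define a gene's *selection probability* as its maximum frequency over
the grid. Genes with selection probability $\ge \theta_{ss}$ are
selected. The same $B$ subsamples are reused across the whole grid
(one warm-started path fit per subsample); this reduces Monte-Carlo
noise in the max over $\lambda$ and is substantially cheaper. Re-drawing
per $\lambda$ is an equally defensible reading of the procedure; the
choice only affects Monte-Carlo noise, and the enumeration test on a
six-sample design confirms the implemented sampling law converges to
the exhaustive one.

## The three stages

1. **Gene pool** (`buildGenePool`): unweighted stability selection at
   each time point; the pool is the union of genes selected at least
   once. Screening at each time point separately means a gene only
   needs to be informative *somewhere* to get a chance.
2. **Sequential ranking** (`sequentialWeightedSelection`,
   `rankBySPFinal`): time points are processed chronologically on the
   pool-restricted data. At $t_1$ all weights are 1; afterwards
   $$w_{t,j} = \begin{cases}1 & g_j \in GL_{t-1}\\
   \gamma & g_j \notin GL_{t-1}\end{cases}\qquad \gamma > 1,$$
   where $GL_{t-1}$ is the thresholded selection at the previous time
   point. If some $GL_{t-1}$ is empty, all weights fall back to 1 (the
   neutral choice; the weighting rule is only defined relative to a
   previous list). The consistency score is the product
   $SP_{final,j} = \prod_t SP_{t,j}$, ranked descending with stable
   ties (pool order), so results are bit-reproducible. The product is
   deliberately unforgiving: one uninformative time point sends a gene
   to the bottom, which is exactly the behaviour that distinguishes
   consistently from transiently differential genes.
3. **Model search** (`searchBestModel`): for every ranking prefix
   $k = 1, \dots, k_{max}$ and every construction time point, a
   logistic model is fitted and scored by
   $$ACC_{mean} = \frac{1}{T}\Big(ACC_o + \sum_{d \ne t_{build}} ACC_T^{(d)}\Big),$$
   the mean of the leave-one-out accuracy at the construction time
   point and the all-sample plug-in accuracy at every other time
   point. Ties prefer the smaller prefix (parsimony), then the earlier
   time point (an earlier usable prediction is clinically preferable).
   $ACC_{min}$, the worst of the $T$ entries, is reported alongside.

The prediction-stage models are plain logistic fits with a small ridge
term ($10^{-4}$), solved by damped Newton iteration. The groups are
small (single digits to a few tens of genes), but with two dozen
samples perfect separation is routine; the ridge floor keeps the
optimum finite and the fit deterministic, and such fits are flagged
(`separable`) via their vanishing training log-loss. The selection
stages never use this solver; they use the coordinate-descent
elastic-net solver (C++, fixed coordinate order, warm-started
$\lambda$ paths) whose KKT conditions are verified directly in the
tests.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | elastic-net mixing; 1 = lasso, 0 = ridge |
| `lambda_grid` | 0.01–1.00 step 0.01 | penalty grid for stability selection |
| `n_iterations` | 500 | subsample draws per grid |
| `n_good_sub`, `n_poor_sub` | 12, 8 | per-class subsample sizes |
| `theta_ss` | 0.5 | selection-probability threshold (inclusive) |
| `gamma` | 2 | penalty multiplier for genes not in $GL_{t-1}$; must exceed 1 |
| `k_max` | min(pool, 30) | largest ranking prefix searched |
| `ridge` | 1e-4 | stabilizer of prediction-stage fits |
| `n_replicates` | 50 | bootstrap replicates in evaluation |

The defaults of the subsampling scheme (12 + 8 from 15 + 9 samples),
the grid, $B$, $\theta_{ss}$, $\alpha$ and $\gamma$ are the original
study conditions. For the package's own examples, tests and the
acceptance script, stability selection runs at desk scale: the grid is
thinned to ten values ($0.1, 0.2, \dots, 1.0$) and $B = 100$. The
smallest penalties of the full grid are omitted at the $p = 100$,
$n = 24$ scale of the synthetic data because there nearly every gene
enters each fit, so those columns carry no ranking information while
dominating the run time; the retained range spans the entire
informative region (from "most genes in" to "no genes in", which the
`lambdaMax` bound makes checkable).

## What the synthetic generator emulates

`simulateTimeCourse` draws class-conditional normals per time point:

* *consistent* genes: mean $\pm\,effect/2$ between classes at every
  time point (default effect 2.5 SD);
* *inconsistent* genes: the same shift but at exactly one (cycling)
  time point — the transiently predictive pattern that misleads
  single-time-point analyses; their shift is separately tunable
  (`effect_inconsistent`) to make that failure mode pronounced;
* *block* genes: no class signal, pairwise correlation $\rho$ through a
  latent factor, $x = \sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon$,
  which hits the target correlation exactly in expectation;
* *null* genes: independent noise.

Matrices are returned per-gene standardized (population SD), matching
the solvers' input convention; the raw scale is available with
`standardize = FALSE`. The generator does **not** emulate probe-level
artifacts, missingness, batch effects, heavy-tailed noise or
subject-level longitudinal correlation (each visit's noise is drawn
independently). Passing tests on these data therefore demonstrate that
the algorithmic chain is correct and recovers planted structure under
its own model assumptions — not that the method is robust to every
property of real microarray data.

Note one consequence of standardization: a planted raw shift of
$\Delta$ SDs appears as $\Delta/\sqrt{1 + \Delta^2 \pi_g \pi_p}$ on the
standardized scale (the class signal itself inflates the per-gene
variance), e.g. 2.5 becomes roughly 1.6. Generator checks of the
planted effect therefore run on the raw scale.

## Numerical choices and degenerate inputs

* Coordinate descent uses the global curvature bound $1/4$ of the
  logistic loss (working response $z_i = \eta_i + 4(y_i - p_i)$) with
  cyclic updates in fixed gene order; convergence is declared when a
  majorization refresh moves no coefficient by more than `tol`
  ($10^{-7}$ by default), at which point the exact KKT conditions hold
  to comparable accuracy. Coefficients with $|\beta_j| \le 10^{-8}$
  count as zero.
* Classification threshold is fixed at 0.5; probabilities exactly at
  the threshold classify as good responders.
* A leave-one-out fold whose training set loses a class predicts the
  training majority.
* Non-converged stability-selection fits count as "no selection" and
  are reported once per run as a warning.
* Quantile normalization equalizes distributions **across samples
  within a time point** (genes are the ranked units; ties receive the
  mean of the tied ranks' reference values) — the standard microarray
  convention; the underlying computation is `limma`'s.
* Z-scores divide by the population SD, making the transform
  idempotent; the sample-SD convention is available as a switch.
  Zero-variance genes are an error, named so the caller can drop them.
* The log2 fold-change baseline is deliberately configurable and off
  by default (plain `log2`), because a fold-change reference is a
  dataset-specific design decision; when a reference time point is
  used its own matrix becomes identically zero and is dropped.
* Master seed discipline: every random stage (per-time-point
  subsampling, bootstrap, AUC resampling) derives its own seed
  deterministically from one master seed, so stages can be re-run
  independently and whole runs are byte-identical under a fixed seed.

## Evaluation suite

Bootstrap evaluation resamples subjects with replacement (redrawing on
single-class draws), refits at the construction time point, and scores
at every other time point against all original samples — the published
protocol for this design; out-of-bag scoring is available as an option
(`scoring = "oob"`). Method comparisons use Welch's two-sample t-test
on replicate-level accuracies (the safer default when only "Student's
t-test" is specified). AUC uses the rank formulation with midrank tie
handling — verified exactly against an all-pairs count — with a
stratified bootstrap percentile interval by default and DeLong's
variance as an option. Rank-sum p-values come from `wilcox.test`
(exact when tie-free and small), adjusted by Benjamini–Hochberg within
each time point across the reported genes, the family that matches a
per-gene-per-time-point report. Direction flags compare class medians
at every time point.

## Known limitations

* The data-splitting caveat of the original design is inherited:
  gene selection and the leave-one-out estimate share the same
  samples, so $ACC_o$ is optimistic relative to a fully nested
  evaluation; the bootstrap cross-time evaluation mitigates but does
  not remove this.
* The prefix-search space is linear in the ranking; gene groups that
  are jointly but not marginally informative can be missed.
* $\gamma$ trades consistency bias against the ability to recover a
  gene that misses one selection list; extreme values make the ranking
  either equal to independent per-time-point selection ($\gamma \to 1$,
  excluded by validation) or winner-take-all.
* Subjects are assumed measured at all time points; missing visits
  must be handled upstream (genes missing at some time points are
  dropped on read with a warning).
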