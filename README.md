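# tcenet

Time-course biomarker selection with weighted elastic-net stability
selection.

## The problem

In longitudinal treatment studies — the motivating case is predicting
good vs poor response to a therapy from blood gene-expression profiles
measured at several visits — a useful predictive gene must separate the
two responder groups **consistently at every time point**. Standard
single-time-point analyses routinely pick genes that are strongly
differential at the observed visit but uninformative before or after
it, so the resulting classifiers degrade as soon as they are applied to
data from another visit. Expression data add two further obstacles:
far more genes than samples (p ≫ n) and heavy multicollinearity
between co-regulated genes.

`tcenet` implements a three-stage procedure that addresses all three
issues:

1. **Gene-pool screening.** At each time point *t*, a logistic model
   Pr(y = 1 | X_t) = 1 / (1 + e^{−(X_t β + β₀)}) is fitted with the
   weighted elastic-net penalty

   (1/n) NLL(y, X_t β + β₀) + λ Σ_j w_j [ (1−α) β_j²/2 + α |β_j| ],

   inside a stability-selection loop: B stratified subsamples are drawn,
   the model is refitted on each over a λ grid, and a gene's *selection
   probability* SP is its maximum selection frequency over the grid.
   The pool is the union over time points of genes with SP ≥ θ_ss.
2. **Sequential consistency ranking.** Stability selection is re-run on
   the pool time point by time point. Genes selected at the previous
   time point keep penalty weight w = 1; all others are penalized by
   w = γ > 1, biasing selection towards genes that stay informative.
   Each pool gene is then scored by SP_final = Π_t SP_{t,j} and the
   pool is ranked by SP_final in descending order.
3. **Model search.** For every prefix of the ranking (adding one gene
   at a time) and every candidate construction time point, a ridge-
   stabilized logistic model is built and scored by ACC_mean — the mean
   of its leave-one-out accuracy at the construction time point and its
   plug-in accuracy at every other time point, with
   ACC [%] = 100 (TP + TN) / (TP + FP + FN + TN). The best ACC_mean
   wins; ties prefer fewer genes, then the earlier time point.

Evaluation utilities cover bootstrap accuracy at the time points not
used for construction (with Welch t comparisons between methods),
ROC/AUC with bootstrap or DeLong confidence intervals, and per-gene
Wilcoxon rank-sum reports with Benjamini–Hochberg adjustment and
median-direction consistency flags. A synthetic-data generator plants
consistent genes, transiently differential genes and correlated gene
blocks with known ground truth, so the whole pipeline is testable
without any external download.

## Worked example

```r
library(tcenet)

sim <- simulateTimeCourse(simControl(), seed = 42)   # 100 genes, 3 visits,
tcs <- sim$dataset                                   # 15 good / 9 poor
ss  <- ssControl(n_iterations = 100, lambda_grid = seq(0.1, 1, 0.1),
                 seed = 42)
res <- runProposed(tcs, ss)
res
#> Time-course pipeline run (pool of 24 genes )
#> BestModel: 3 genes built at t1
#>   mean accuracy: 98.6 %, min: 95.8 %
#>   genes: g001, g002, g003
#>   bootstrap cross-time mean accuracy: 98.0 %

head(rankedGenes(res$ranking), 5)
#> [1] "g001" "g002" "g003" "g080" "g004"
sim$truth$consistent
#> [1] "g001" "g002" "g003"
```

The three genes planted with a consistent between-class shift
(`g001`–`g003`) top the SP_final ranking and form the selected model;
its mean accuracy across the leave-one-out estimate at the construction
visit and the two cross-visit predictions is 98.6 %, and bootstrap
resampling of the training samples keeps the cross-visit accuracy at
98 %. The transiently differential genes (`g004`–`g006`) score near
zero because SP_final multiplies per-visit selection probabilities —
one uninformative visit is enough to drop a gene down the ranking.

A thin command-line front end over the same functions ships in
`inst/cli/tcenet.R` (subcommands `simulate`, `run-all`,
`run-conventional`).

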