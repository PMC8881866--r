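# cfsace — counterfactual feature selection and average causal effects

Interpretable two-stage prediction for tabular clinical data. Most
feature-attribution tools answer *"which features correlate with this
prediction?"*; for medical decisions the useful question is causal:
*which few features, for this particular patient, actually drive the
predicted outcome, and by how much would forcing one of them to a value
shift the predicted risk?*

**Stage 1 — instance-wise causal feature selection.** Three jointly
trained fully connected networks: a *selection network* (actor) emits
per-feature Bernoulli selection probabilities; a *counterfactual
prediction network* classifies from the masked input `(x ⊙ s, s)`; a
*factual prediction network* (critic) classifies from the full input. The
selector is trained with a score-function (REINFORCE) gradient on the
detached advantage

    l̂(x, s) = CE[counterfactual(x ⊙ s, s)] − CE[factual(x)]

plus a sparsity penalty `λ · mean_i p_i(x)` — subsets that predict as well
as the full feature vector, with as few features as possible, become
likely; everything else decays. At test time selection is deterministic
thresholding at 0.5.

**Stage 2 — average causal effects (ACE).** The trained counterfactual
predictor, mask held fixed, is read as a structural causal mechanism
`F: features → class probability`. For each selected feature the package
computes an intervention curve

    ACE_i(α) = E[F | do(x_i = α)] − baseline_i

via a second-order Taylor expansion of the interventional expectation
(`F(μ) + ½ Tr[H Σ_do]`, with the intervened coordinate's variance zeroed),
using integrated-gradient path smoothing so saturated network gradients do
not flatten the curves. The baseline is the grid average of the
interventional expectations, so every ACE curve integrates to zero over
its grid.

The package ships generators for three standard 11-dimensional Gaussian
selection benchmarks with known ground truth, selection metrics (per
instance TPR/FDR), ranking metrics (AUROC by Mann–Whitney ranks, AUPRC by
step summation), and a command-line driver
(`inst/cli/cfsace`: `simulate`, `train`, `evaluate`, `ace`, `report`).

## Worked example

```r
library(cfsace)

# Benchmark 2: odds of class 0 are exp(x2² + x3² + x4² + x5² − 4);
# features x0, x1, x6..x10 are pure noise.
res <- run_benchmark("dataset2", seed = 1)   # 20k/20k split; ~30 s on one core
round(res$metrics, 3)
#>    tpr_pct    fdr_pct      auroc      auprc   accuracy auroc_fact auprc_fact
#>    100.000      0.000      0.898      0.904      0.825      0.889      0.896
```

The selector recovers exactly {x2, x3, x4, x5} for every test instance
(TPR 100%, FDR 0%), and the counterfactual predictor — seeing only those
four features — outperforms the full-input factual network (AUROC 0.898
vs 0.889), because the nine noise features only invite overfitting.

```r
# Stage 2: ACE curves of the selected features on P(class 0)
st  <- estimate_stats(res$test$features)
rep <- ace_report(res$model, res$selection, st, ig_config(), n_grid = 21)
rep
#> ace_report: 4 feature curves
#>   feature 3: max |ACE| = 0.6409
#>   feature 4: max |ACE| = 0.575
#>   feature 5: max |ACE| = 0.6503
#>   feature 6: max |ACE| = 0.6114
cv <- rep[["3"]]   # feature x2
round(data.frame(alpha = cv$alphas, ace = cv$ace)[6:17, ], 2)
#>    alpha   ace
#> 6  -2.12  0.19
#> 7  -1.72 -0.25
#> 8  -1.33 -0.48
#> 9  -0.93 -0.54
#> 10 -0.54 -0.59
#> 11 -0.15 -0.59
#> 12  0.25 -0.59
#> 13  0.64 -0.56
#> 14  1.04 -0.53
#> 15  1.43 -0.50
#> 16  1.82 -0.28
#> 17  2.22  0.24
```

Each curve reports, per intervention value α, how far
`E[P(class 0) | do(x_i = α)]` sits above or below that feature's baseline.
For this benchmark the curves are U-shaped — decreasing for α < 0,
increasing for α > 0 — matching the generative law, where large |x2|
raises the odds of class 0; an irrelevant feature's curve is flat at 0.

From a shell, the same workflow:

```sh
Rscript inst/cli/cfsace simulate dataset=dataset2 n_samples=6000 seed=1 out=d2.csv
Rscript inst/cli/cfsace train input=d2.csv seeds=1,2,3 out_dir=run \
    hidden_selector=32,32 hidden_predictors=64,64 learning_rate=3e-4 \
    batch_size=500 n_steps=4000
Rscript inst/cli/cfsace ace model=run/model_seed1.json input=d2.csv out=curves.csv
Rscript inst/cli/cfsace report runs=run model=run/model_seed1.json input=d2.csv
```

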