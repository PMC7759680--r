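# cfgan

Individualized treatment effects from observational tabular data via
counterfactual generative adversarial networks, for biostatisticians and
methods researchers who need per-subject — not merely average — effect
estimates across binary, categorical and continuous (dosed) treatments,
together with sparse biomarker selection for optimal treatment choice.

## The model

Each subject carries covariates `X`, a one-hot treatment-assignment
indicator `M` (arm `eta` received), a treatment-quantity vector `T` with a
single nonzero entry (1 for binary/categorical arms, the dose for continuous
arms) and one observed factual outcome `Y_f = sum_k M_k Y(T_k)`.  Under
ignorability, common support and no interference, the package estimates the
unobserved counterfactuals and the per-subject pairwise effects
`xi_jk = Y(T_j) - Y(T_k)` (ATE/ATT/ATC are their means over all subjects,
the arm-`j` stratum and the arm-`k` stratum).

Two adversarial blocks do the work:

1. **Imputation block.** A generator
   `Ytilde = G(X, Y_f, T*M, (1-M)*z)` (uniform noise `z` masked to the
   counterfactual slots) against a discriminator `D(X, Ybar)` that scores,
   per arm, the probability of being the factual component of the completed
   outcome vector `Ybar` (factual slot overwritten with `Y_f`).  Training
   alternates ascent/descent on
   `V = E[M' log D + (1-M)' log(1-D)]`, plus a supervised
   factual-reconstruction term for the generator.
2. **ITE block.** A second conditional GAN `Yhat = G_I(X, T, Z)` against a
   scalar discriminator `D_I(X, T, Y*)` learns the conditional law of the
   full potential-outcome vector from the completed data; sampling it at
   query treatment vectors yields effect distributions, and for dosed
   treatments the dose–response counterfactual at any dose.

Both networks are 7-layer sigmoid feedforward nets (64-unit hidden layers,
concatenation layer for response/treatment/noise inputs) trained with Adam
(batch 16, generator rate 1e-3, exponential decay to 10% over the first 70%
of batches, 20% dropout), implemented in compiled code with a pure-R
reference implementation checked by numeric gradients.

Biomarker selection solves multi-response LASSOs of estimated effects on
covariates (plus a dose-coefficient block with its own penalty for dosed
treatments, and a best-arm variant for optimal treatment choice) by
coordinate descent, reporting single and accumulated R-square tables and
Garson importance of the trained generator.

## Worked example

```r
library(cfgan)

## simulate the binary-treatment design: 10,000 subjects, 30 covariates,
## quadratic outcome surfaces thresholded at 0.5, ground truth retained
sim <- simulate_binary(binary_sim_spec(seed = 1))
fr  <- sim$frame

## imputation block: default hyperparameters, budget scaled to 50k
## batches (~1 min on one core)
fit <- train_imputation(fr, gan_config(total_batches = 50000, seed = 2))
tail(fit$trace[, 1:4], 1)
#>     batch disc_accuracy replication_error separation_distance
#> 100 50000       0.57175      7.965102e-07           0.1050224

## complete the data and train the ITE block on it
po   <- generate_counterfactuals(fit$generator, fr, n_draws = 100, seed = 3)
ifit <- train_ite_block(make_complete(po, fr), fr,
                        gan_config(total_batches = 50000, seed = 4))

## potential-outcome point estimates: mean over 100 noise draws
est <- ite_point_estimate(sample_potential_outcomes(ifit$generator, fr$X,
                                                    fr$T, n_draws = 100,
                                                    seed = 5))
outcome_metrics(est, cbind(sim$truth$Y1, sim$truth$Y0))
#> $mse 0.0804   $std 0.272   $accuracy 0.92
roc_auc(est[, 1], sim$truth$Y1)
#> 0.9719165

## effect report on the 500-subject evaluation subset
comp <- (est >= 0.5) + 0
comp[cbind(1:fr$n, fr$eta)] <- fr$Y_f
effect_summary(comp, fr, 1, 2, subset = sim$truth$eval_idx)
#> <effect_report> arms 1 vs 2: ATE 0.0900, ATT 0.0536, ATC 0.1297
#> ITE counts  -1 /  0 / +1: 7 / 441 / 52
mean(sim$truth$ITE[sim$truth$eval_idx])   # ground truth for comparison
#> 0.096

## compare with per-arm (T-learner) baselines
run_baseline_harness(fr, sim$truth, methods = c("LR", "RF_C"))
#>   method mse_cf accuracy   ate        fpr
#> 1     LR 0.3241   0.6759 0.140 0.18701683
#> 2   RF_C 0.0464   0.9536 0.092 0.02103229
```

The trace prints the training diagnostics (discriminator accuracy,
replication error, separation distance); `outcome_metrics` shows the
potential-outcome error against the retained ground truth (for binary
outcomes MSE is the misclassification proportion, so accuracy is its
complement); the effect report gives ATE/ATT/ATC and the signed-ITE count
table, here close to the design's true subset ATE of 0.096.  Effect counts
are conservative by construction — the imputation generator is conditioned
on the factual outcome, which biases desk-scale effects toward zero on some
runs — the methods vignette (`vignettes/counterfactual-gans.Rmd`) discusses
this at length, along with every modelling convention and parameter.

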