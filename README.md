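# dgattn

Disease-informed attention supervision for 3D brain-image classification.

`dgattn` implements a two-stage training strategy for volumetric three-way
staging of cognitive status (NC — normal cognition, MCI — mild cognitive
impairment, AD — Alzheimer's disease dementia), aimed at models that
generalize across cohorts by attending to disease-relevant anatomy:

1. **Stage 1** trains a baseline 3D classifier (small convolutional encoder,
   class-wise sigmoid attention gates `M_k`, global-average-pooling
   classifier) with inverse-frequency weighted cross-entropy
   `L_WCE = -(1/N) Σ_i w_{y_i} log ŷ_{i,y_i}`, `w_k = 1/count_k`.
2. **Class priors**: Shapley-style voxel attributions (expected gradients,
   with an exact subset-enumeration Shapley oracle for testing) are averaged
   over the baseline's *correct* predictions of each class into per-class
   saliency maps `SHAP_k`.
3. **Stage 2** trains a fresh model on the combined loss
   `L = L_WCE + λ · L_sim` with
   `L_sim = (1/N) Σ_i Σ_k ‖ M_{i,k} − SHAP_k ‖₂`,
   pulling each attention channel toward its class prior.

Around that core the package provides: a synthetic-cohort generator
(block-atlas parcellation, planted severity-graded atrophy, 0–3 ordinal
stain grades) so the whole pipeline is testable without MRI data; macro F1
and multiclass MCC with a stratified 5-fold, 3:1:1 train/val/test harness;
region-level attention scoring with Spearman correlation against pathology
grades (unadjusted p-values); NIfTI/CSV/YAML/JSON I/O; and a CLI.

Everything is plain R (the model's forward and backward passes are
implemented in base R and verified against finite differences), so the
package runs on one CPU in seconds at desk scale.

## Worked example

```r
library(dgattn)

parc   <- make_parcellation(c(32, 32, 32), n_regions = 27, seed = 1)
spec   <- cohort_spec(n_per_class = c(60, 60, 60), shape = c(32, 32, 32),
                      n_regions = 27, disease_regions = c(3, 7, 12),
                      effect_size = 0.25, noise_sd = 0.02, seed = 11)
cohort <- generate_cohort(spec, parc)

fold <- stratified_kfold(cohort_labels(cohort), k = 5, seed = 2)$folds[[1]]
tr <- cohort$samples[fold$train]; va <- cohort$samples[fold$val]
te <- cohort$samples[fold$test]

fit1   <- train_stage1(tr, va,
            model_config(c(32, 32, 32), encoder_channels = 8,
                         downsample_factor = 4, seed = 101),
            train_config(lambda = 0, epochs = 30, steps_per_epoch = 27,
                         micro_batch = 4, lr = 0.01, seed = 11))
priors <- build_class_priors(fit1$model, tr,
            attribution_config(n_background = 6, n_draws = 8, seed = 301))
tc2    <- train_config(lambda = 5e-4, epochs = 30, steps_per_epoch = 27,
                       micro_batch = 4, lr = 0.01, prior_scale = "unit",
                       seed = 21)
fit2   <- train_stage2(tr, va, priors,
            model_config(c(32, 32, 32), encoder_channels = 8,
                         downsample_factor = 4, seed = 201), tc2)

unlist(evaluate_model(fit2, te)[c("accuracy", "macro_f1", "mcc")])
#>  accuracy  macro_f1       mcc
#> 0.8333333 0.8230769 0.7606388
c(stage1 = model_sim_loss(fit1, va, priors, tc2),
  stage2 = model_sim_loss(fit2, va, priors, tc2))
#>   stage1   stage2
#> 48.09403 11.59732
```

The stage-2 model classifies held-out subjects near the Bayes ceiling of the
synthetic task (≈ 0.82) while its attention maps sit far closer to the class
priors than the baseline's (validation similarity loss 11.6 vs 48.1); its AD-channel attention concentrates on the planted
disease regions, and region-level attention scores correlate strongly
(Spearman ρ ≈ 0.8) with the planted 0–3 severity grades on a held-out
23-subject "autopsy" cohort — the synthetic analogue of validating attention
against post-mortem histology.

## Command line

```sh
Rscript inst/cli/dgattn.R simulate           --config config.yaml
Rscript inst/cli/dgattn.R train-baseline     --config config.yaml
Rscript inst/cli/dgattn.R compute-priors     --config config.yaml
Rscript inst/cli/dgattn.R train-dg           --config config.yaml
Rscript inst/cli/dgattn.R evaluate           --config config.yaml
Rscript inst/cli/dgattn.R validate-pathology --config config.yaml
```

The YAML config (see `default_run_config()`) fixes one master seed; every
artifact embeds the config hash, and a rerun of the chain from one config is
bit-identical.

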