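# End-to-end pipeline: simulate -> stage-1 baseline -> class priors ->
# stage-2 prior-supervised model -> evaluation. Every stochastic component
# draws its seed deterministically from the single config seed, so a rerun
# from the same config reproduces the metric report bit for bit.

pipeline_objects <- function(cfg) {
  ms <- as.integer(unlist(cfg$cohort$shape))
  parc <- make_parcellation(ms, cfg$cohort$n_regions,
                            seed = derive_seed(cfg$seed, "parcellation"))
  spec <- cohort_spec(unlist(cfg$cohort$n_per_class), ms, cfg$cohort$n_regions,
                      unlist(cfg$cohort$disease_regions),
                      effect_size = cfg$cohort$effect_size,
                      noise_sd = cfg$cohort$noise_sd,
                      seed = derive_seed(cfg$seed, "cohort"))
  list(parc = parc, spec = spec)
}

split_samples <- function(cohort, cfg) {
  labels <- cohort_labels(cohort)
  plan <- stratified_kfold(labels, k = cfg$split$k,
                           seed = derive_seed(cfg$seed, "split"))
  fold <- plan$folds[[cfg$split$fold]]
  list(train = cohort$samples[fold$train], val = cohort$samples[fold$val],
       test = cohort$samples[fold$test], plan = plan, fold = fold)
}

pipeline_model_config <- function(cfg, stage) {
  model_config(input_shape = as.integer(unlist(cfg$cohort$shape)),
               n_classes = 3L,
               encoder_channels = as.integer(unlist(cfg$model$encoder_channels)),
               downsample_factor = cfg$model$downsample_factor,
               seed = derive_seed(cfg$seed, paste0("model", stage)))
}

pipeline_train_config <- function(cfg, stage, lambda) {
  tr <- cfg$train
  train_config(lambda = lambda,
               epochs = tr$epochs, steps_per_epoch = tr$steps_per_epoch,
               micro_batch = tr$micro_batch,
               accumulation_steps = tr$accumulation_steps %||% 1L,
               lr = tr$lr %||% 3e-3,
               sim_scope = tr$sim_scope %||% "all_classes",
               prior_scale = tr$prior_scale %||% "unit",
               normalize_by_voxels = isTRUE(tr$normalize_by_voxels),
               seed = derive_seed(cfg$seed, paste0("train", stage)))
}

#' Run the full two-stage pipeline from a configuration
#'
#' Simulates the cohort, trains the stage-1 baseline, computes class priors,
#' trains the stage-2 prior-supervised model, and evaluates both on the held
#' out test fold. Deterministic given the config (including its seed).
#'
#' @param cfg a `dg_run_config` (see [read_run_config()],
#'   [default_run_config()]).
#' @param write_artifacts write the metric report (and per-stage history)
#'   under `cfg$paths$workdir`.
#' @return list with `cohort`, `split`, `fit1`, `priors`, `fit2`,
#'   `metrics` (named list as written to JSON).
#' @export
run_pipeline <- function(cfg, write_artifacts = TRUE) {
  obj <- pipeline_objects(cfg)
  cohort <- generate_cohort(obj$spec, obj$parc)
  sp <- split_samples(cohort, cfg)
  tc1 <- pipeline_train_config(cfg, 1L, lambda = 0)
  fit1 <- train_stage1(sp$train, sp$val, pipeline_model_config(cfg, 1L), tc1)
  acfg <- attribution_config(n_background = cfg$attribution$n_background,
                             n_draws = cfg$attribution$n_draws,
                             seed = derive_seed(cfg$seed, "priors"))
  priors <- build_class_priors(fit1$model, sp$train, acfg)
  tc2 <- pipeline_train_config(cfg, 2L, lambda = cfg$train$lambda)
  fit2 <- train_stage2(sp$train, sp$val, priors, pipeline_model_config(cfg, 2L), tc2)
  ev1 <- evaluate_model(fit1, sp$test)
  ev2 <- evaluate_model(fit2, sp$test)
  sim1 <- model_sim_loss(fit1, sp$val, priors, tc2)
  sim2 <- model_sim_loss(fit2, sp$val, priors, tc2)
  share <- function(fit) {
    mean(vapply(sp$test, function(s) {
      att <- attention_maps(fit$model, s$volume)
      attention_mass_share(att[3, , , ], cohort$parcellation,
                           cohort$spec$disease_regions)
    }, numeric(1)))
  }
  metrics <- list(
    config_hash = cfg$config_hash %||% config_hash(unclass(cfg)),
    n_train = length(sp$train), n_val = length(sp$val), n_test = length(sp$test),
    stage1 = list(accuracy = ev1$accuracy, macro_f1 = ev1$macro_f1,
                  mcc = ev1$mcc, val_sim_loss = sim1,
                  disease_attention_share = share(fit1)),
    stage2 = list(accuracy = ev2$accuracy, macro_f1 = ev2$macro_f1,
                  mcc = ev2$mcc, val_sim_loss = sim2,
                  disease_attention_share = share(fit2)))
  if (write_artifacts) {
    wd <- cfg$paths$workdir
    dir.create(wd, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(wd, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, split = sp, fit1 = fit1, priors = priors, fit2 = fit2,
       metrics = metrics)
}

#' Per-fold evaluation report
#'
#' Runs inference of a fitted model over each test fold of a split plan and
#' reports accuracy, macro F1 and MCC with mean and standard deviation
#' across folds.
#'
#' @param model a `dg_model` or `dg_fit`.
#' @param samples full list of `dg_sample`s the plan indexes into.
#' @param plan a [stratified_kfold()] plan.
#' @return list with `per_fold` (data frame) and `summary` (mean, sd).
#' @export
crossval_report <- function(model, samples, plan) {
  rows <- lapply(seq_along(plan$folds), function(f) {
    ev <- evaluate_model(model, samples[plan$folds[[f]]$test])
    data.frame(fold = f, accuracy = ev$accuracy, macro_f1 = ev$macro_f1,
               mcc = ev$mcc)
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, summary = aggregate_folds(per_fold[, -1]))
}
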