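# Shared fixtures, all built in code. Heavy objects (the study cohort used
# by the end-to-end checks) are constructed lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Seeded evaluation of an expression, restoring the caller's RNG (internal
# helper reused across test files).
with_seed <- asNamespace("osteoage")$with_seed

# Tiny noiseless phantom parameters for fast deterministic unit tests.
quiet_params <- function(n = 2, ...) {
  phantom_params(n_subjects = n, noise_sd = 0, subject_sd = 0, ...)
}

# The desk-scale study cohort: n = 200, seed 7, default (paper-anchored)
# generator settings; preprocessed once into 1/8-scale working voxels.
study_scale <- 0.125

study_cohort <- function() {
  cached("study_cohort", function() {
    generate_cohort(phantom_params(n_subjects = 200, seed = 7))
  })
}

study_records <- function() {
  cached("study_records", function() {
    cohort_records(study_cohort(),
                   shapes = list(femur = scaled_shapes("femur", study_scale)$voxel,
                                 mandible = scaled_shapes("mandible", study_scale)$voxel))
  })
}

# Desk-scale training recipe: with roughly an order of magnitude fewer
# optimizer steps than a full-size run, the learning rate is raised by the
# same order (the package defaults keep the full-size recipe).
study_train_config <- function(seed = 7) {
  train_config(epochs = 20, lr = 3e-3, min_lr = 3e-4, seed = seed)
}

study_cv <- function(tag) {
  key <- paste0("cv_", tag)
  cached(key, function() {
    cfg <- switch(tag,
      femur = network_config(backbone = "resnet50_3d", fusion = "none",
                             modality = "femur", scale = study_scale, seed = 7),
      mandible = network_config(backbone = "resnet34_3d", fusion = "none",
                                modality = "mandible", scale = study_scale,
                                seed = 7),
      middle = network_config(fusion = "middle", scale = study_scale, seed = 7))
    plan <- kfold_split(study_cohort()$truth, k = 3, seed = 7)
    cross_validate(study_records(), cfg, study_train_config(), plan)
  })
}

# A small random eval-vector pair generator used by metric property tests.
random_pairs <- function(n, len = 50) {
  lapply(seq_len(n), function(i) {
    list(y = rnorm(len, 45, 12), yhat = rnorm(len, 45, 12))
  })
}
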