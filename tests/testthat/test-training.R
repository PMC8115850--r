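# Loss, augmentation, LR scheduling, the training loop, and progressive
# input-size transfer.

oa <- asNamespace("osteoage")

tiny_cfg <- function(seed = 3) {
  network_config(backbone = "resnet34_3d", fusion = "none",
                 modality = "femur", scale = 0.0625, seed = seed)
}

# 12 deterministic noiseless phantom records at the tiny working shape.
tiny_records <- function() {
  cached("tiny_records", function() {
    cohort <- generate_cohort(quiet_params(n = 12, seed = 5))
    cohort_records(cohort,
                   shapes = list(femur = scaled_shapes("femur", 0.0625)$voxel),
                   modalities = "femur")
  })
}

test_that("mse_loss matches hand arithmetic and a loop oracle", {
  expect_equal(mse_loss(c(30, 50), c(30, 50)), 0)
  expect_equal(mse_loss(c(30, 50), c(35, 45)), 25)
  expect_error(mse_loss(1:3, 1:2), "length mismatch")
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  set.seed(2)
  for (i in 1:20) {
    y <- rnorm(37, 45, 12); p <- rnorm(37, 45, 12)
    acc <- 0
    for (j in seq_along(y)) acc <- acc + (y[j] - p[j])^2   # loop oracle
    expect_equal(mse_loss(y, p), acc / length(y), tolerance = 1e-12)
  }
})

test_that("random crops stay within the valid offset range", {
  v <- array(as.numeric(seq_len(20 * 256 * 256)), c(20, 256, 256))
  set.seed(3)
  for (i in 1:10) {
    cr <- random_crop(v, c(20, 224, 224))
    expect_equal(dim(cr), c(20, 224, 224))
    # locate the crop corner in the source from its (unique) value
    corner <- cr[1, 1, 1]
    x0 <- (corner - 1) %/% (20 * 256) + 1
    y0 <- ((corner - 1) %% (20 * 256)) %/% 20 + 1
    z0 <- (corner - 1) %% 20 + 1
    expect_equal(z0, 1)                       # z offset always 0
    expect_true(y0 >= 1 && y0 <= 33)          # in-plane offsets in 0..32
    expect_true(x0 >= 1 && x0 <= 33)
    expect_identical(cr[, 1, 1], v[, y0, x0])
  }
  # identity crop and determinism
  expect_identical(random_crop(v, dim(v)), v)
  set.seed(9); a <- random_crop(v, c(10, 100, 100))
  set.seed(9); b <- random_crop(v, c(10, 100, 100))
  expect_identical(a, b)
  expect_error(random_crop(v, c(21, 224, 224)), "crop too large")
  # centre crop is deterministic without touching the RNG
  cc1 <- random_crop(v, c(10, 100, 100), center = TRUE)
  cc2 <- random_crop(v, c(10, 100, 100), center = TRUE)
  expect_identical(cc1, cc2)
})

test_that("the LR schedule decays on plateau and floors at the minimum", {
  cfg <- train_config()
  # 10 flat validation epochs at 3e-4 -> 2.4e-4
  expect_equal(lr_schedule_step(rep(100, 10), 3e-4, cfg), 2.4e-4)
  # improving loss -> unchanged
  expect_equal(lr_schedule_step(seq(100, 60, length.out = 10), 3e-4, cfg),
               3e-4)
  # floor at the minimum LR
  expect_equal(lr_schedule_step(rep(100, 10), 3e-5, cfg), 3e-5)
  expect_equal(lr_schedule_step(rep(100, 10), 3.5e-5, cfg), 3e-5)
  # short plateaus do not trigger
  expect_equal(lr_schedule_step(rep(100, 5), 3e-4, cfg), 3e-4)
})

test_that("one small-LR step on a fixed batch decreases the loss", {
  cfg <- tiny_cfg()
  m <- model_build(cfg)
  recs <- tiny_records()
  ds <- prepare_dataset(recs[1:4], cfg)
  m$nodes[[m$output_id]]$p$b <- mean(ds$ages)
  ins <- oa$dataset_batch(ds, 1:4, augment = FALSE)
  tcfg <- train_config(lr = 1e-4, weight_decay = 0)
  state <- oa$adam_init(m)
  fwd <- oa$net_forward(m, ins, training = TRUE)
  m$nodes <- fwd$nodes
  l0 <- mse_loss(ds$ages, as.numeric(fwd$out))
  dout <- matrix(2 * (as.numeric(fwd$out) - ds$ages) / 4, 1)
  pg <- oa$net_backward(m, fwd$vals, fwd$caches, dout)
  upd <- oa$adam_step(m, pg, state, 1, tcfg, tcfg$lr)
  fwd2 <- oa$net_forward(upd$model, ins, training = TRUE)
  l1 <- mse_loss(ds$ages, as.numeric(fwd2$out))
  expect_lt(l1, l0)
})

test_that("training is reproducible and its LR trace is monotone", {
  cfg <- tiny_cfg()
  recs <- tiny_records()
  ds <- prepare_dataset(recs[1:8], cfg)
  vd <- prepare_dataset(recs[9:12], cfg)
  tcfg <- train_config(epochs = 6, batch_size = 4, lr = 1e-3, seed = 11)
  r1 <- train(model_build(cfg), ds, vd, tcfg)
  r2 <- train(model_build(cfg), ds, vd, tcfg)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$lr) <= 0))
  expect_true(all(r1$history$lr >= tcfg$min_lr))
  expect_error(train(model_build(cfg),
                     prepare_dataset(list(), cfg), vd, tcfg),
               "empty training set")
})

test_that("a scale-reduced model overfits a handful of subjects", {
  cfg <- tiny_cfg()
  recs <- tiny_records()
  ds <- prepare_dataset(recs[1:8], cfg)
  tcfg <- train_config(epochs = 30, batch_size = 8, lr = 1e-2, min_lr = 1e-3,
                       augment = FALSE, seed = 1)
  res <- train(model_build(cfg), ds, ds, tcfg)
  h <- res$history
  expect_lt(tail(h$train_loss, 1), 0.10 * h$train_loss[1])
})

test_that("a single-rung ladder reproduces plain training", {
  cfg <- tiny_cfg(seed = 7)
  recs <- tiny_records()
  tcfg <- train_config(epochs = 3, batch_size = 4, seed = 2)
  plain <- train(model_build(cfg), prepare_dataset(recs[1:8], cfg),
                 prepare_dataset(recs[9:12], cfg), tcfg)
  ladder <- progressive_pretrain(list(cfg), recs[1:8], recs[9:12], tcfg)
  expect_identical(ladder$histories[[1]], plain$history)
})

test_that("progressive transfer carries weights and helps the next rung", {
  recs <- tiny_records()
  small <- network_config(backbone = "resnet34_3d", fusion = "none",
                          modality = "femur", scale = 0.0625,
                          shape_scale = 0.03, seed = 7)
  large <- network_config(backbone = "resnet34_3d", fusion = "none",
                          modality = "femur", scale = 0.0625,
                          shape_scale = 0.0625, seed = 7)
  tcfg <- train_config(epochs = 5, batch_size = 4, lr = 3e-3, seed = 2)
  ladder <- progressive_pretrain(list(small, large), recs[1:8], recs[9:12],
                                 tcfg)
  expect_length(ladder$histories, 2)
  # every parameter is transferable across input sizes (global pooling
  # makes all shapes input-independent)
  expect_equal(ladder$transferred,
               length(oa$net_params(model_build(large))))
  # the transferred rung starts no worse than a fresh model of the same seed
  fresh <- train(model_build(large), prepare_dataset(recs[1:8], large),
                 prepare_dataset(recs[9:12], large), tcfg)
  expect_lte(ladder$histories[[2]]$val_loss[1], fresh$history$val_loss[1])
  # incompatible ladders are refused
  other <- network_config(backbone = "resnet50_3d", fusion = "none",
                          modality = "femur", scale = 0.0625, seed = 7)
  expect_error(progressive_pretrain(list(small, other), recs[1:8],
                                    recs[9:12], tcfg),
               "transfer mismatch")
})
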