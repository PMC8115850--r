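# Network construction, fusion strategies, and architectural identities.

oa <- asNamespace("osteoage")

small_input <- function(shape, n = 1, channels = 1, seed = 1) {
  set.seed(seed)
  array(runif(prod(shape) * channels * n), c(shape, channels, n))
}

test_that("every backbone produces a finite scalar through the head", {
  for (bb in c("resnet34_3d", "resnet50_3d", "mobilenet_3d", "squeezenet_3d")) {
    cfg <- network_config(backbone = bb, fusion = "none", modality = "mandible",
                          scale = 0.0625, seed = 2)
    m <- model_build(cfg)
    x <- small_input(cfg$shapes$mandible$crop)
    p <- predict_single(m, x, sex = 1)
    expect_length(p, 1)
    expect_true(is.finite(p))
  }
})

test_that("parameter initialization is deterministic given the seed", {
  cfg <- network_config(backbone = "resnet34_3d", fusion = "none",
                        modality = "femur", scale = 0.0625, seed = 5)
  m1 <- model_build(cfg)
  m2 <- model_build(cfg)
  expect_identical(oa$net_params(m1), oa$net_params(m2))
  m3 <- model_build(network_config(backbone = "resnet34_3d", fusion = "none",
                                   modality = "femur", scale = 0.0625,
                                   seed = 6))
  expect_false(identical(oa$net_params(m1), oa$net_params(m3)))
})

test_that("a basic block with zero convolution weights is the identity path", {
  g <- oa$new_graph()
  x <- oa$g_input(g, "x")
  out <- oa$resnet_basic_block(g, x, 2L, 2L, 1L)
  m <- list(nodes = g$nodes, output_id = out)
  for (i in seq_along(m$nodes)) {
    if (m$nodes[[i]]$op == "conv") {
      m$nodes[[i]]$p$W[] <- 0
      m$nodes[[i]]$p$b[] <- 0
    }
  }
  xin <- array(runif(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))   # positive input
  y <- oa$net_forward(m, list(x = xin), training = FALSE)$out
  expect_equal(y, xin)   # residual branch contributes nothing
})

test_that("the sex embedding is 32 wide and validates its domain", {
  expect_equal(dim(gender_branch(0)), c(32L, 1L))
  expect_equal(dim(gender_branch(c(0, 1, 1))), c(32L, 3L))
  # all-zero weights collapse both codes to the zero vector
  expect_identical(gender_branch(0), gender_branch(1))
  expect_true(all(gender_branch(1) == 0))
  w <- list(W = matrix(rnorm(32), 32, 1), b = rnorm(32))
  expect_false(identical(gender_branch(0, w), gender_branch(1, w)))
  expect_error(gender_branch(2), "invalid sex code")
})

test_that("predict_single is deterministic and validates shapes", {
  cfg <- network_config(backbone = "resnet50_3d", fusion = "none",
                        modality = "femur", scale = 0.0625, seed = 3)
  m <- model_build(cfg)
  x <- small_input(cfg$shapes$femur$crop)
  expect_identical(predict_single(m, x, 0), predict_single(m, x, 0))
  expect_error(predict_single(m, array(0, c(3, 3, 3)), 0), "shape mismatch")
  expect_error(predict_single(m, x, 3), "invalid sex code")
})

test_that("the head is linear: scaling its weights scales centred output", {
  cfg <- network_config(backbone = "resnet34_3d", fusion = "none",
                        modality = "femur", scale = 0.0625, seed = 4)
  m <- model_build(cfg)
  x <- small_input(cfg$shapes$femur$crop, seed = 8)
  b <- m$nodes[[m$output_id]]$p$b
  p1 <- predict_single(m, x, 1)
  m2 <- m
  m2$nodes[[m2$output_id]]$p$W <- 2 * m2$nodes[[m2$output_id]]$p$W
  p2 <- predict_single(m2, x, 1)
  expect_equal(p2 - b, 2 * (p1 - b), tolerance = 1e-12)
})

test_that("a zeroed backbone predicts exactly the head bias", {
  cfg <- network_config(backbone = "resnet34_3d", fusion = "none",
                        modality = "mandible", scale = 0.0625, seed = 4)
  m <- model_build(cfg)
  for (i in seq_along(m$nodes)) {
    for (nm in names(m$nodes[[i]]$p)) m$nodes[[i]]$p[[nm]][] <- 0
  }
  m$nodes[[m$output_id]]$p$b <- 47.5
  x <- array(0, c(cfg$shapes$mandible$crop, 1, 1))
  expect_equal(predict_single(m, x, 0), 47.5)
})

test_that("late fusion is exactly the arithmetic mean", {
  expect_identical(fuse_late(40, 50), 45)
  x <- rnorm(20, 45, 10)
  expect_identical(fuse_late(x, x), x)
  set.seed(12)
  a <- rnorm(1000, 45, 12); b <- rnorm(1000, 45, 12)
  oracle <- rowMeans(cbind(a, b))              # independent mean oracle
  expect_identical(fuse_late(a, b), oracle)
  expect_error(fuse_late(c(1, 2), 3))
})

test_that("middle fusion concatenates widths and is permutation-equivariant", {
  set.seed(6)
  fm <- matrix(rnorm(8 * 3), 8); ff <- matrix(rnorm(16 * 3), 16)
  fg <- matrix(rnorm(32 * 3), 32)
  W <- matrix(rnorm(56), 1)
  p <- fuse_middle(fm, ff, fg, W, b = 5)
  expect_length(p, 3)
  # zero head -> bias regardless of inputs
  expect_equal(fuse_middle(fm, ff, fg, W * 0, b = 5), rep(5, 3))
  # swapping the modality blocks with correspondingly swapped weights
  Wsw <- cbind(W[, 9:24, drop = FALSE], W[, 1:8, drop = FALSE],
               W[, 25:56, drop = FALSE])
  expect_equal(fuse_middle(ff, fm, fg, Wsw, b = 5), p, tolerance = 1e-12)
  expect_error(fuse_middle(fm, ff, fg, W[, 1:10, drop = FALSE]),
               "width mismatch")
})

test_that("early fusion is symmetric under channel swap and linear stacking", {
  cfg <- network_config(backbone = "resnet34_3d", fusion = "early",
                        scale = 0.0625, seed = 9)
  m <- model_build(cfg)
  sh <- cfg$shapes$early$crop
  set.seed(2)
  vm <- array(runif(prod(sh)), sh)
  vf <- array(runif(prod(sh)), sh)
  p <- fuse_early(m, vm, vf, sex = 0)
  expect_true(is.finite(p))
  # swap input channels and the first conv's channel weights -> identical
  stem <- which(vapply(m$nodes, function(nd) nd$op == "conv", logical(1)))[1]
  msw <- m
  msw$nodes[[stem]]$p$W <- m$nodes[[stem]]$p$W[, , , c(2, 1), , drop = FALSE]
  expect_equal(fuse_early(msw, vf, vm, sex = 0), p, tolerance = 1e-10)
  # duplicate channels with channel-summed first-layer weights collapse
  mcol <- m
  W <- m$nodes[[stem]]$p$W
  W[, , , 1, ] <- W[, , , 1, ] + W[, , , 2, ]
  W[, , , 2, ] <- 0
  mcol$nodes[[stem]]$p$W <- W
  expect_equal(fuse_early(mcol, vm, vm, sex = 0),
               {
                 mdup <- m
                 fuse_early(mdup, vm, vm, sex = 0)
               }, tolerance = 1e-10)
  expect_error(fuse_early(m, NULL, vf, 0), "missing modality")
})

# Independent closed-form parameter counts from the stage arithmetic.
count_resnet <- function(base, blocks, type, in_ch = 1, gender = TRUE) {
  n <- 343 * in_ch * base + base + 2 * base       # stem conv + bn
  cin <- base
  for (s in 1:4) {
    w <- base * 2^(s - 1)
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1 && s > 1) 2 else 1
      if (type == "basic") {
        n <- n + 27 * cin * w + w + 2 * w + 27 * w * w + w + 2 * w
        if (cin != w || stride != 1) n <- n + cin * w + w + 2 * w
        cin <- w
      } else {
        cout <- 4 * w
        n <- n + cin * w + w + 2 * w + 27 * w * w + w + 2 * w +
          w * cout + cout + 2 * cout
        if (cin != cout || stride != 1) n <- n + cin * cout + cout + 2 * cout
        cin <- cout
      }
    }
  }
  feat <- cin
  if (gender) n <- n + 32 * 1 + 32
  n + (feat + if (gender) 32 else 0) * 1 + 1      # head
}

test_that("parameter counts match independent block arithmetic", {
  for (spec in list(list(bb = "resnet34_3d", type = "basic"),
                    list(bb = "resnet50_3d", type = "bottleneck"))) {
    cfg <- network_config(backbone = spec$bb, fusion = "none",
                          modality = "femur", scale = 0.0625, seed = 1)
    m <- model_build(cfg)
    expect_equal(oa$net_num_params(m),
                 count_resnet(cfg$base_width, c(3, 4, 6, 3), spec$type))
  }
})

test_that("backbone feature vectors have the configured width", {
  bb <- build_backbone("resnet50_3d", scale = 0.0625, seed = 2)
  expect_equal(bb$feature_width, 32L * bb$base_width)
  f <- backbone_features(bb, small_input(c(8, 12, 12)))
  expect_equal(dim(f), c(bb$feature_width, 1L))
  expect_true(all(is.finite(f)))
  bb34 <- build_backbone("resnet34_3d", scale = 0.0625, seed = 2)
  expect_equal(bb34$feature_width, 8L * bb34$base_width)
})

test_that("models round-trip through checkpoints", {
  cfg <- network_config(backbone = "squeezenet_3d", fusion = "none",
                        modality = "mandible", scale = 0.0625, seed = 3)
  m <- model_build(cfg)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(m, path)
  back <- load_model(path)
  x <- small_input(cfg$shapes$mandible$crop)
  expect_identical(predict_single(back, x, 1), predict_single(m, x, 1))
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
})
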