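# 3D CNN regressors and fusion strategies. A feature extractor F_theta maps a
# bone voxel X to a fixed-width embedding (Eq.-style feature_X = F(X)); a
# fully connected head maps the embedding, concatenated with a 32-wide
# binary-sex embedding, to the scalar age estimate.

# Network-facing shapes, axis order (z, y, x). "voxel" is the stored
# fixed-shape bone voxel (resized by `scale`); "crop" is what the network
# consumes after random (train) / centre (eval) cropping.
FULL_VOXEL_SHAPES <- list(femur = c(112L, 128L, 128L),
                          mandible = c(20L, 256L, 256L),
                          early = c(64L, 128L, 128L))
FULL_CROP_SHAPES <- list(femur = c(112L, 112L, 112L),
                         mandible = c(20L, 224L, 224L),
                         early = c(64L, 128L, 128L))

#' Working shapes for a modality at a given scale
#'
#' The `scale` configuration uniformly shrinks stage widths and input shapes
#' so the full training pipeline can run at desk scale; `scale = 1` is the
#' full-size geometry (femur voxel 112 x 128 x 128 cropped to
#' 112 x 112 x 112; mandible 20 x 256 x 256 cropped to 20 x 224 x 224; early
#' fusion on a shared 64 x 128 x 128 grid).
#'
#' @param modality `"femur"`, `"mandible"` or `"early"`.
#' @param scale multiplier in `(0, 1]`.
#' @return List with integer `voxel` and `crop` shapes.
#' @export
scaled_shapes <- function(modality, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  v <- pmax(1L, as.integer(round(FULL_VOXEL_SHAPES[[modality]] * scale)))
  cr <- pmin(v, pmax(1L, as.integer(round(FULL_CROP_SHAPES[[modality]] * scale))))
  list(voxel = v, crop = cr)
}

# Align-corners trilinear resize of a rank-3 array to `shape`.
resize_array <- function(arr, shape) {
  d <- dim(arr)
  shape <- as.integer(shape)
  if (all(d == shape)) return(arr)
  step <- ifelse(shape > 1L, (d - 1) / (shape - 1), 0)
  .resample_trilinear(arr, shape, step)
}

## ---- backbone builders -----------------------------------------------------

resnet_basic_block <- function(g, x, cin, cout, stride = 1L) {
  c1 <- g_conv(g, x, cin, cout, 3L, stride)
  r1 <- g_relu(g, g_bn(g, c1, cout))
  c2 <- g_conv(g, r1, cout, cout, 3L, 1L)
  b2 <- g_bn(g, c2, cout)
  sc <- if (cin == cout && stride == 1L) x else {
    g_bn(g, g_conv(g, x, cin, cout, 1L, stride, pad = 0L), cout)
  }
  g_relu(g, g_add(g, b2, sc))
}

resnet_bottleneck_block <- function(g, x, cin, width, stride = 1L) {
  cout <- 4L * width
  c1 <- g_conv(g, x, cin, width, 1L, 1L, pad = 0L)
  r1 <- g_relu(g, g_bn(g, c1, width))
  c2 <- g_conv(g, r1, width, width, 3L, stride)
  r2 <- g_relu(g, g_bn(g, c2, width))
  c3 <- g_conv(g, r2, width, cout, 1L, 1L, pad = 0L)
  b3 <- g_bn(g, c3, cout)
  sc <- if (cin == cout && stride == 1L) x else {
    g_bn(g, g_conv(g, x, cin, cout, 1L, stride, pad = 0L), cout)
  }
  g_relu(g, g_add(g, b3, sc))
}

build_resnet_graph <- function(g, x, in_channels, base, blocks, block_type) {
  stem <- g_conv(g, x, in_channels, base, 7L, 2L, pad = 3L)
  cur_id <- g_maxpool(g, g_relu(g, g_bn(g, stem, base)))
  cur_ch <- base
  for (stage in 1:4) {
    w <- base * 2L^(stage - 1L)
    for (b in seq_len(blocks[stage])) {
      stride <- if (b == 1L && stage > 1L) 2L else 1L
      if (block_type == "basic") {
        cur_id <- resnet_basic_block(g, cur_id, cur_ch, w, stride)
        cur_ch <- w
      } else {
        cur_id <- resnet_bottleneck_block(g, cur_id, cur_ch, w, stride)
        cur_ch <- 4L * w
      }
    }
  }
  list(feat = g_gap(g, cur_id), width = cur_ch)
}

build_mobilenet_graph <- function(g, x, in_channels, base) {
  stem <- g_conv(g, x, in_channels, base, 3L, 2L)
  cur_id <- g_relu(g, g_bn(g, stem, base))
  cur_ch <- base
  plan <- list(c(base, 1L), c(2L * base, 2L), c(2L * base, 1L),
               c(4L * base, 2L), c(4L * base, 1L),
               c(8L * base, 2L), c(8L * base, 1L))
  for (blk in plan) {
    dw <- g_dwconv(g, cur_id, cur_ch, 3L, blk[2L])
    rdw <- g_relu(g, g_bn(g, dw, cur_ch))
    pw <- g_conv(g, rdw, cur_ch, blk[1L], 1L, 1L, pad = 0L)
    cur_id <- g_relu(g, g_bn(g, pw, blk[1L]))
    cur_ch <- blk[1L]
  }
  list(feat = g_gap(g, cur_id), width = cur_ch)
}

squeeze_fire <- function(g, x, cin, squeeze, expand) {
  s <- g_relu(g, g_bn(g, g_conv(g, x, cin, squeeze, 1L, 1L, pad = 0L), squeeze))
  e1 <- g_conv(g, s, squeeze, expand, 1L, 1L, pad = 0L)
  e3 <- g_conv(g, s, squeeze, expand, 3L, 1L)
  out <- g_concat_c(g, c(e1, e3))
  g_relu(g, g_bn(g, out, 2L * expand))
}

build_squeezenet_graph <- function(g, x, in_channels, base) {
  half <- max(2L, base %/% 2L)
  stem <- g_conv(g, x, in_channels, 2L * base, 3L, 2L)
  cur_id <- g_maxpool(g, g_relu(g, g_bn(g, stem, 2L * base)))
  cur_id <- squeeze_fire(g, cur_id, 2L * base, half, base)       # -> 2*base
  cur_id <- squeeze_fire(g, cur_id, 2L * base, half, base)       # -> 2*base
  cur_id <- g_maxpool(g, cur_id)
  cur_id <- squeeze_fire(g, cur_id, 2L * base, base, 2L * base)  # -> 4*base
  list(feat = g_gap(g, cur_id), width = 4L * base)
}

BACKBONES <- c("resnet34_3d", "resnet50_3d", "mobilenet_3d", "squeezenet_3d")

add_backbone <- function(g, x, backbone, in_channels, base) {
  switch(backbone,
         resnet34_3d = build_resnet_graph(g, x, in_channels, base,
                                          c(3L, 4L, 6L, 3L), "basic"),
         resnet50_3d = build_resnet_graph(g, x, in_channels, base,
                                          c(3L, 4L, 6L, 3L), "bottleneck"),
         mobilenet_3d = build_mobilenet_graph(g, x, in_channels, base),
         squeezenet_3d = build_squeezenet_graph(g, x, in_channels, base),
         stop("unknown backbone: ", backbone))
}

## ---- configuration ---------------------------------------------------------

#' Network configuration
#'
#' Describes one age-regression model: backbone family, fusion strategy,
#' whether the sex embedding is used, and the width/shape scale. `fusion =
#' "none"` requires exactly one `modality`; `"middle"` and `"early"` build a
#' single joint model over both bones; `"late"` trains two gender-aware
#' single-modality models whose predictions are averaged.
#'
#' @param backbone one of `"resnet34_3d"`, `"resnet50_3d"`, `"mobilenet_3d"`,
#'   `"squeezenet_3d"` (single-modality / early fusion). For middle/late
#'   fusion, `mandible_backbone` and `femur_backbone` are used instead
#'   (defaults: ResNet-34 for the mandible, ResNet-50 for the femur).
#' @param fusion `"none"`, `"early"`, `"middle"`, or `"late"`.
#' @param modality for `fusion = "none"`: `"femur"` or `"mandible"`.
#' @param mandible_backbone,femur_backbone backbones for the two-modality
#'   fusion strategies.
#' @param use_gender include the 32-wide sex embedding (default `TRUE`).
#' @param scale width/shape multiplier in `(0, 1]`; 1 is the full-size
#'   architecture (base stage width 64).
#' @param shape_scale input-shape multiplier, defaulting to `scale`. Setting
#'   it below `scale` gives the reduced-input rungs of progressive
#'   input-size transfer learning: widths (and so every parameter shape)
#'   stay constant across rungs while the input grows.
#' @param seed parameter-initialization seed.
#' @return List of class `network_config`.
#' @export
network_config <- function(backbone = "resnet50_3d",
                           fusion = c("none", "early", "middle", "late"),
                           modality = c("femur", "mandible"),
                           mandible_backbone = "resnet34_3d",
                           femur_backbone = "resnet50_3d",
                           use_gender = TRUE, scale = 1,
                           shape_scale = scale, seed = 1L) {
  fusion <- match.arg(fusion)
  modality <- match.arg(modality)
  stopifnot(backbone %in% BACKBONES, mandible_backbone %in% BACKBONES,
            femur_backbone %in% BACKBONES, scale > 0, scale <= 1,
            shape_scale > 0, shape_scale <= 1)
  cfg <- list(backbone = backbone, fusion = fusion, modality = modality,
              mandible_backbone = mandible_backbone,
              femur_backbone = femur_backbone,
              use_gender = isTRUE(use_gender), scale = scale,
              shape_scale = shape_scale,
              base_width = max(4L, as.integer(round(64 * scale))),
              seed = as.integer(seed))
  cfg$shapes <- switch(fusion,
    none = stats::setNames(list(scaled_shapes(modality, shape_scale)), modality),
    early = list(early = scaled_shapes("early", shape_scale)),
    list(mandible = scaled_shapes("mandible", shape_scale),
         femur = scaled_shapes("femur", shape_scale)))
  class(cfg) <- "network_config"
  cfg
}

#' Build a bare feature-extractor backbone
#'
#' Constructs the parameterized 3D CNN for one input stream: stacked
#' residual basic blocks (ResNet-34 layout), bottleneck blocks (ResNet-50
#' layout), depthwise-separable blocks (MobileNet style) or fire modules
#' (SqueezeNet style), ending in global average pooling that yields the
#' feature vector. Parameter initialization is deterministic given `seed`.
#'
#' @param backbone backbone name, see [network_config()].
#' @param in_channels input channels (2 for early fusion).
#' @param scale width multiplier in `(0, 1]`.
#' @param seed initialization seed.
#' @return List of class `osteo_backbone` with `nodes`, `input_id`,
#'   `output_id` (feature node), `feature_width`.
#' @export
build_backbone <- function(backbone, in_channels = 1L, scale = 1, seed = 1L) {
  stopifnot(backbone %in% BACKBONES)
  base <- max(4L, as.integer(round(64 * scale)))
  with_seed(seed, {
    g <- new_graph()
    x <- g_input(g, "x")
    bb <- add_backbone(g, x, backbone, in_channels, base)
    structure(list(nodes = g$nodes, output_id = bb$feat, input_id = x,
                   feature_width = bb$width, backbone = backbone,
                   base_width = base),
              class = "osteo_backbone")
  })
}

#' Extract backbone features from a voxel batch
#'
#' @param bb an `osteo_backbone` from [build_backbone()].
#' @param x a rank-3 array (one volume), rank-4 `(D,H,W,C)`, or rank-5 batch.
#' @return A `(feature_width, n)` matrix.
#' @export
backbone_features <- function(bb, x) {
  net_forward(bb, list(x = as_batch(x)), training = FALSE)$out
}

# Coerce a rank-3/4/5 array to the (D,H,W,C,N) batch layout.
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 4L) dim(x) <- c(d, 1L)
  x
}

# Stack a list of equally shaped rank-3 (or rank-4) arrays into one batch.
stack_batch <- function(xs) {
  d <- dim(as_batch(xs[[1L]]))[1:4]
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) out[, , , , i] <- as_batch(xs[[i]])
  out
}

GENDER_WIDTH <- 32L

#' Sex embedding branch
#'
#' Embeds the binary sex code (0 = male, 1 = female) through a 32-unit fully
#' connected layer with ReLU. With all-zero weights both codes map to the
#' zero vector; after any nonzero training step the two embeddings differ.
#'
#' @param sex 0 or 1 (vectorized).
#' @param weights list with `W` (32 x 1) and `b` (length 32); defaults to
#'   zeros.
#' @return A `(32, n)` matrix of embeddings.
#' @export
gender_branch <- function(sex, weights = NULL) {
  if (!all(sex %in% c(0, 1))) stop("invalid sex code")
  if (is.null(weights)) {
    weights <- list(W = matrix(0, GENDER_WIDTH, 1L), b = numeric(GENDER_WIDTH))
  }
  z <- weights$W %*% matrix(as.numeric(sex), 1L) + weights$b
  z * (z > 0)
}

## ---- full models -----------------------------------------------------------

# Attach the gender fc + concat + scalar head to a feature node.
add_head <- function(g, feat_ids, widths, use_gender, sex_id = NULL) {
  ids <- feat_ids
  win <- sum(widths)
  if (use_gender) {
    gf <- g_relu(g, g_fc(g, sex_id, 1L, GENDER_WIDTH))
    ids <- c(ids, gf)
    win <- win + GENDER_WIDTH
  }
  cat_id <- if (length(ids) > 1L) g_concat(g, ids) else ids
  g_fc(g, cat_id, win, 1L, gain = 1)
}

#' Build an age-regression model from a configuration
#'
#' For `fusion = "none"` and `"early"` this is one backbone plus the sex
#' embedding and scalar head; for `"middle"`, two backbones whose features
#' are concatenated (with the sex embedding) before a joint head, so
#' gradients flow into both streams; for `"late"`, two independent
#' single-modality models whose predictions are averaged at inference.
#'
#' @param config a [network_config()].
#' @return An `osteo_model` (or `osteo_late` pair of models).
#' @export
model_build <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (config$fusion == "late") {
    sub <- function(mod, bb) {
      cfg <- network_config(backbone = bb, fusion = "none", modality = mod,
                            use_gender = config$use_gender,
                            scale = config$scale,
                            shape_scale = config$shape_scale,
                            seed = config$seed + match(mod, c("mandible", "femur")))
      model_build(cfg)
    }
    return(structure(list(mandible = sub("mandible", config$mandible_backbone),
                          femur = sub("femur", config$femur_backbone),
                          config = config),
                     class = "osteo_late"))
  }
  with_seed(config$seed, {
    g <- new_graph()
    if (config$fusion == "none") {
      x <- g_input(g, "x")
      sex <- if (config$use_gender) g_input(g, "sex")
      bb <- add_backbone(g, x, config$backbone, 1L, config$base_width)
      out <- add_head(g, bb$feat, bb$width, config$use_gender, sex)
      feat_ids <- bb$feat
    } else if (config$fusion == "early") {
      x <- g_input(g, "x")
      sex <- if (config$use_gender) g_input(g, "sex")
      bb <- add_backbone(g, x, config$backbone, 2L, config$base_width)
      out <- add_head(g, bb$feat, bb$width, config$use_gender, sex)
      feat_ids <- bb$feat
    } else {  # middle
      xm <- g_input(g, "mandible")
      xf <- g_input(g, "femur")
      sex <- if (config$use_gender) g_input(g, "sex")
      bm <- add_backbone(g, xm, config$mandible_backbone, 1L, config$base_width)
      bf <- add_backbone(g, xf, config$femur_backbone, 1L, config$base_width)
      out <- add_head(g, c(bm$feat, bf$feat), c(bm$width, bf$width),
                      config$use_gender, sex)
      feat_ids <- c(bm$feat, bf$feat)
    }
    structure(list(nodes = g$nodes, output_id = out, feature_ids = feat_ids,
                   config = config),
              class = "osteo_model")
  })
}

#' @export
print.osteo_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<osteo_model> %s fusion=%s scale=%g  %d nodes, %s parameters\n",
              if (cfg$fusion == "middle") {
                paste(cfg$mandible_backbone, "+", cfg$femur_backbone)
              } else cfg$backbone,
              cfg$fusion, cfg$scale, length(x$nodes),
              format(net_num_params(x), big.mark = ",")))
  invisible(x)
}

# Assemble the named input list a model expects from per-modality voxel
# batches and a sex vector.
model_inputs <- function(model, voxels, sex) {
  ins <- lapply(voxels, function(v) as_batch(v))
  if (model$config$use_gender) {
    ins$sex <- matrix(as.numeric(sex), 1L)
  }
  ins
}

#' Predict ages with a fitted model (inference mode)
#'
#' @param model an `osteo_model` or `osteo_late`.
#' @param voxels named list of voxel batches (rank-3 array or rank-5 batch
#'   per entry); names must match the model's inputs (`x` for
#'   single-modality/early, `mandible`/`femur` for middle and late fusion).
#' @param sex numeric vector of 0/1 codes (recycled to the batch).
#' @return Numeric vector of predicted ages (years).
#' @export
model_predict <- function(model, voxels, sex = 0) {
  if (inherits(model, "osteo_late")) {
    pm <- model_predict(model$mandible, list(x = voxels$mandible), sex)
    pf <- model_predict(model$femur, list(x = voxels$femur), sex)
    return(fuse_late(pm, pf))
  }
  n <- dim(as_batch(voxels[[1L]]))[5L]
  ins <- model_inputs(model, voxels, rep_len(sex, n))
  out <- net_forward(model, ins, training = FALSE)$out
  as.numeric(out)
}

#' Single-modality age prediction
#'
#' `age = fc(concat(F_theta(X), gender(sex)))`: runs one voxel (or batch)
#' through a gender-aware single-modality model.
#'
#' @param model an `osteo_model` built with `fusion = "none"` or `"early"`.
#' @param voxel rank-3 array (or rank-5 batch) matching the model input
#'   shape.
#' @param sex 0/1 vector.
#' @return Numeric vector of predicted ages.
#' @export
predict_single <- function(model, voxel, sex) {
  stopifnot(inherits(model, "osteo_model"))
  if (!all(sex %in% c(0, 1))) stop("invalid sex code")
  want <- model$config$shapes[[1L]]$crop
  have <- dim(as_batch(voxel))[1:3]
  if (!all(have == want)) stop("shape mismatch")
  model_predict(model, list(x = voxel), sex)
}

#' Late fusion: average of per-modality predictions
#'
#' The final estimate is the arithmetic mean of the mandible and femur
#' predictions; no learned parameters are involved.
#'
#' @param pred_mandible,pred_femur numeric vectors of predicted ages.
#' @return `(pred_mandible + pred_femur) / 2`.
#' @export
fuse_late <- function(pred_mandible, pred_femur) {
  stopifnot(length(pred_mandible) == length(pred_femur),
            all(is.finite(pred_mandible)), all(is.finite(pred_femur)))
  (pred_mandible + pred_femur) / 2
}

#' Middle fusion head on extracted features
#'
#' Concatenates the mandible features, femur features, and sex embedding and
#' applies the fully connected head. This is the closed-form head of the
#' joint middle-fusion model; [model_build()] with `fusion = "middle"`
#' builds the trainable end-to-end version.
#'
#' @param feat_mandible,feat_femur,feat_gender feature matrices
#'   (`width x n`); `feat_gender` may be `NULL`.
#' @param W,b head weights: `W` is `1 x total_width`, `b` scalar.
#' @return Numeric vector of predicted ages.
#' @export
fuse_middle <- function(feat_mandible, feat_femur, feat_gender, W, b = 0) {
  z <- rbind(as.matrix(feat_mandible), as.matrix(feat_femur))
  if (!is.null(feat_gender)) z <- rbind(z, as.matrix(feat_gender))
  if (ncol(W) != nrow(z)) stop("width mismatch")
  as.numeric(W %*% z + b)
}

#' Early fusion: stacked-channel prediction
#'
#' Resamples both bone voxels onto the model's shared grid, stacks them as
#' two input channels of a single backbone, and predicts with the
#' gender-aware head.
#'
#' @param model an `osteo_model` built with `fusion = "early"`.
#' @param voxel_mandible,voxel_femur rank-3 arrays (single subject).
#' @param sex 0/1.
#' @return Predicted age (scalar).
#' @export
fuse_early <- function(model, voxel_mandible, voxel_femur, sex) {
  stopifnot(inherits(model, "osteo_model"),
            model$config$fusion == "early")
  if (is.null(voxel_mandible) || is.null(voxel_femur)) stop("missing modality")
  shape <- model$config$shapes$early$crop
  x <- array(0, c(shape, 2L, 1L))
  x[, , , 1L, 1L] <- resize_array(voxel_mandible, shape)
  x[, , , 2L, 1L] <- resize_array(voxel_femur, shape)
  model_predict(model, list(x = x), sex)
}

#' Save / load a model checkpoint
#'
#' The parameter archive is a single serialized file; a JSON sidecar records
#' the configuration for tooling.
#'
#' @param model an `osteo_model` or `osteo_late`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- if (inherits(model, "osteo_late")) model$config else model$config
  jsonlite::write_json(
    cfg[c("backbone", "fusion", "modality", "use_gender", "scale", "seed")],
    sub("\\.rds$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
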