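# Training: MSE objective, Adam with weight decay, reduce-on-plateau learning
# rate schedule, random-crop augmentation, and progressive input-size
# transfer learning. Everything is seeded through R's RNG, so a run is
# reproducible bitwise on one machine.

#' Training configuration
#'
#' Defaults follow the reference recipe: up to 50 epochs, Adam with
#' minibatch size 16, weight decay 1e-4 and first-moment coefficient 0.9,
#' learning rate starting at 3e-4 with floor 3e-5, reduced by a factor of
#' 0.8 when the validation loss has plateaued for 10 epochs. Random-crop
#' augmentation crops mandible voxels to 20 x 224 x 224 and femur voxels to
#' 112 x 112 x 112 at full scale (scaled shapes come from the network
#' configuration).
#'
#' @param epochs maximum epochs (default 50).
#' @param batch_size minibatch size (default 16).
#' @param lr,min_lr initial and minimum learning rate.
#' @param plateau_factor multiplicative LR decay on plateau (default 0.8).
#' @param plateau_patience epochs without validation-loss improvement that
#'   trigger a decay (default 10).
#' @param improvement_tol relative decrease below the running best that
#'   counts as an improvement (default 1e-3).
#' @param weight_decay L2 coefficient on convolution/fc weights.
#' @param beta1,beta2,eps Adam moment coefficients ("momentum 0.9" is read
#'   as the first-moment coefficient; Adam has no classical momentum).
#' @param augment use random crops during training (centre crops are always
#'   used for evaluation).
#' @param val_fraction inner train/validation split used by the scheduler
#'   and best-epoch selection (default 0.1).
#' @param seed RNG seed for data order, crops and initialization.
#' @param verbose print per-epoch progress.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 16L, lr = 3e-4,
                         min_lr = 3e-5, plateau_factor = 0.8,
                         plateau_patience = 10L, improvement_tol = 1e-3,
                         weight_decay = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, augment = TRUE, val_fraction = 0.1,
                         seed = 1L, verbose = FALSE) {
  stopifnot(min_lr <= lr, plateau_factor > 0, plateau_factor < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, min_lr = min_lr, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 improvement_tol = improvement_tol,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 eps = eps, augment = isTRUE(augment),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Mean squared error between true and predicted ages
#'
#' `(1/n) * sum((y - yhat)^2)`, the training objective.
#'
#' @param y,yhat numeric vectors of equal nonzero length (years).
#' @return Scalar MSE (years squared).
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) == 0L) stop("empty input")
  mean((y - yhat)^2)
}

#' Random or centre crop of a voxel
#'
#' Extracts a contiguous sub-block of exactly `target` shape. During
#' training the offset is uniform over all valid positions (data
#' augmentation); at evaluation time the deterministic centre crop is used.
#' For a 20 x 256 x 256 mandible voxel cropped to 20 x 224 x 224 the z
#' offset is always 0 and the in-plane offsets range over 0..32.
#'
#' @param voxel rank-3 array, or rank-4 with trailing channel axis (the
#'   channel axis is never cropped).
#' @param target integer length-3 target spatial shape.
#' @param center if `TRUE`, take the deterministic centre crop.
#' @return Cropped array of spatial shape `target`.
#' @export
random_crop <- function(voxel, target, center = FALSE) {
  d <- dim(voxel)
  target <- as.integer(target)
  if (any(target > d[1:3])) stop("crop too large")
  off <- integer(3)
  for (a in 1:3) {
    m <- d[a] - target[a]
    off[a] <- if (center || m == 0L) m %/% 2L else sample.int(m + 1L, 1L) - 1L
  }
  iz <- (off[1] + 1L):(off[1] + target[1])
  iy <- (off[2] + 1L):(off[2] + target[2])
  ix <- (off[3] + 1L):(off[3] + target[3])
  if (length(d) == 4L) voxel[iz, iy, ix, , drop = FALSE]
  else voxel[iz, iy, ix, drop = FALSE]
}

#' Reduce-on-plateau learning rate step
#'
#' Pure function of the validation-loss history: an epoch counts as an
#' improvement when its loss undercuts the running best by more than
#' `improvement_tol` (relative). When the number of trailing epochs without
#' improvement reaches a multiple of `plateau_patience`, the learning rate
#' is multiplied by `plateau_factor`, never falling below `min_lr`.
#'
#' @param val_losses numeric vector of validation losses, one per epoch so
#'   far (most recent last).
#' @param current_lr current learning rate.
#' @param config a [train_config()].
#' @return The learning rate for the next epoch.
#' @export
lr_schedule_step <- function(val_losses, current_lr, config) {
  stopifnot(length(val_losses) >= 1L)
  n <- length(val_losses)
  best <- val_losses[1L]
  last_improve <- 0L
  for (i in seq_len(n)[-1L]) {
    if (val_losses[i] < best * (1 - config$improvement_tol)) {
      best <- val_losses[i]
      last_improve <- i
    }
  }
  wait <- n - last_improve
  if (wait >= config$plateau_patience &&
      (wait - config$plateau_patience) %% config$plateau_patience == 0L) {
    max(current_lr * config$plateau_factor, config$min_lr)
  } else {
    current_lr
  }
}

## ---- dataset preparation ---------------------------------------------------

#' Build training records from a phantom cohort
#'
#' Runs the full preprocessing chain (isotropic resampling + femur
#' windowing / mandible extraction) on every subject of an in-memory
#' [generate_cohort()] result and resizes the fixed-shape bone voxels to the
#' requested working shapes. The result is the lightweight per-subject
#' record list the training and cross-validation functions consume.
#'
#' @param cohort a `phantom_cohort` with volumes kept in memory.
#' @param shapes named list of target shapes per modality (e.g.
#'   `list(femur = c(14, 16, 16))`); `NULL` keeps the full fixed shapes.
#' @param modalities which bones to preprocess.
#' @return List of records: `id`, `age_years`, `sex`, and one array per
#'   modality.
#' @export
cohort_records <- function(cohort, shapes = NULL,
                           modalities = c("femur", "mandible")) {
  stopifnot(inherits(cohort, "phantom_cohort"), !is.null(cohort$subjects))
  lapply(seq_along(cohort$subjects), function(i) {
    rec <- list(id = cohort$truth$subject_id[i],
                age_years = cohort$truth$age_years[i],
                sex = cohort$truth$sex[i])
    for (mod in modalities) {
      bv <- preprocess_volume(cohort$subjects[[i]][[mod]], mod)
      v <- bv$values
      if (!is.null(shapes[[mod]])) v <- resize_array(v, shapes[[mod]])
      rec[[mod]] <- v
    }
    rec
  })
}

# Resolve a model's named inputs to (working voxel array, crop shape) pairs
# for one record.
record_inputs <- function(record, config) {
  sh <- config$shapes
  if (config$fusion %in% c("none")) {
    mod <- config$modality
    list(x = list(v = resize_array(record[[mod]], sh[[mod]]$voxel),
                  crop = sh[[mod]]$crop))
  } else if (config$fusion == "early") {
    shape <- sh$early$voxel
    x <- array(0, c(shape, 2L))
    x[, , , 1L] <- resize_array(record$mandible, shape)
    x[, , , 2L] <- resize_array(record$femur, shape)
    list(x = list(v = x, crop = sh$early$crop))
  } else {
    list(mandible = list(v = resize_array(record$mandible, sh$mandible$voxel),
                         crop = sh$mandible$crop),
         femur = list(v = resize_array(record$femur, sh$femur$voxel),
                      crop = sh$femur$crop))
  }
}

#' Prepare a model-ready dataset from subject records
#'
#' @param records list from [cohort_records()] (or compatible).
#' @param config a [network_config()].
#' @return List of class `osteo_dataset`: `subjects` (per-subject named
#'   input arrays + crop shapes), `ages`, `sexes`, `ids`.
#' @export
prepare_dataset <- function(records, config) {
  structure(list(
    subjects = lapply(records, record_inputs, config = config),
    ages = vapply(records, `[[`, numeric(1), "age_years"),
    sexes = vapply(records, `[[`, numeric(1), "sex"),
    ids = vapply(records, `[[`, character(1), "id")
  ), class = "osteo_dataset")
}

# Assemble a (possibly cropped) input batch for the given subject indices.
dataset_batch <- function(data, idx, augment) {
  keys <- names(data$subjects[[1L]])
  ins <- list()
  for (key in keys) {
    crops <- lapply(idx, function(i) {
      s <- data$subjects[[i]][[key]]
      random_crop(s$v, s$crop, center = !augment)
    })
    ins[[key]] <- stack_batch(crops)
  }
  ins$sex <- matrix(data$sexes[idx], 1L)
  ins
}

## ---- optimizer and training loop -------------------------------------------

adam_init <- function(model) {
  lapply(model$nodes, function(nd) {
    lapply(nd$p, function(w) list(m = w * 0, v = w * 0))
  })
}

adam_step <- function(model, pgrads, state, t, cfg, lr) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(model$nodes)) {
    pg <- pgrads[[i]]
    if (is.null(pg)) next
    for (nm in names(pg)) {
      g <- pg[[nm]]
      w <- model$nodes[[i]]$p[[nm]]
      if (nm == "W" && cfg$weight_decay > 0) g <- g + cfg$weight_decay * w
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      state[[i]][[nm]] <- st
      model$nodes[[i]]$p[[nm]] <-
        w - lr * (st$m / corr1) / (sqrt(st$v / corr2) + cfg$eps)
    }
  }
  list(model = model, state = state)
}

#' Train an age-regression model
#'
#' Minimizes the MSE between predicted and true ages with Adam, random-crop
#' augmentation, and the reduce-on-plateau schedule, checkpointing the epoch
#' with the best validation MAE (ties resolved to the earlier epoch). The
#' output head bias is initialized to the mean training age so the model
#' starts at the predict-the-mean baseline. Fully seeded: two runs with the
#' same seed produce identical loss curves.
#'
#' @param model an `osteo_model` from [model_build()].
#' @param train_data,val_data `osteo_dataset`s from [prepare_dataset()].
#' @param config a [train_config()].
#' @return List of class `train_result`: `model` (best checkpoint),
#'   `final_model`, `history` (per-epoch data frame with training loss,
#'   validation loss, validation MAE, learning rate), `best_epoch`.
#' @export
train <- function(model, train_data, val_data, config = train_config()) {
  stopifnot(inherits(model, "osteo_model"),
            inherits(train_data, "osteo_dataset"))
  n <- length(train_data$subjects)
  if (n == 0L) stop("empty training set")
  with_seed(config$seed, {
    # start from the predict-the-mean baseline
    head_id <- model$output_id
    if (all(model$nodes[[head_id]]$p$b == 0)) {
      model$nodes[[head_id]]$p$b <- mean(train_data$ages)
    }
    state <- adam_init(model)
    lr <- config$lr
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_mae = numeric(0),
                       lr = numeric(0))
    best <- list(mae = Inf, model = model, epoch = 0L)
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        ins <- dataset_batch(train_data, idx, augment = config$augment)
        fwd <- net_forward(model, ins, training = TRUE)
        model$nodes <- fwd$nodes            # adopt BN running stats
        pred <- as.numeric(fwd$out)
        y <- train_data$ages[idx]
        loss <- mse_loss(y, pred)
        if (!is.finite(loss)) stop("training diverged (non-finite loss)")
        losses[bi] <- loss
        dout <- matrix(2 * (pred - y) / length(y), 1L)
        pgrads <- net_backward(model, fwd$vals, fwd$caches, dout)
        t_step <- t_step + 1L
        upd <- adam_step(model, pgrads, state, t_step, config, lr)
        model <- upd$model
        state <- upd$state
      }
      vp <- predict_dataset(model, val_data)
      val_loss <- mse_loss(val_data$ages, vp)
      val_mae <- mean(abs(val_data$ages - vp))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(losses),
                                     val_loss = val_loss,
                                     val_mae = val_mae, lr = lr))
      if (val_mae < best$mae) {
        best <- list(mae = val_mae, model = model, epoch = epoch)
      }
      lr <- lr_schedule_step(hist$val_loss, lr, config)
      if (config$verbose) {
        message(sprintf("epoch %3d  train %8.2f  val %8.2f  val MAE %6.2f  lr %.2g",
                        epoch, mean(losses), val_loss, val_mae, lr))
      }
    }
    structure(list(model = best$model, final_model = model, history = hist,
                   best_epoch = best$epoch),
              class = "train_result")
  })
}

#' Predict ages for a prepared dataset
#'
#' Inference-mode forward pass with deterministic centre crops.
#'
#' @param model an `osteo_model` or `osteo_late`.
#' @param data an `osteo_dataset`.
#' @param batch_size evaluation batch size.
#' @return Numeric vector of predicted ages, one per subject.
#' @export
predict_dataset <- function(model, data, batch_size = 16L) {
  if (inherits(model, "osteo_late")) {
    stop("late-fusion models are evaluated per submodel; see cross_validate")
  }
  n <- length(data$subjects)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    ins <- dataset_batch(data, idx, augment = FALSE)
    out[idx] <- as.numeric(net_forward(model, ins, training = FALSE)$out)
  }
  out
}

#' Progressive input-size transfer learning
#'
#' Trains the model at the smallest input size first, then transfers every
#' parameter whose shape matches (all convolutions and, thanks to global
#' average pooling, usually the head as well) into the next-larger rung and
#' continues training; shape-incompatible parameters keep their fresh
#' initialization. A single-rung ladder is identical to a plain [train()].
#'
#' @param configs list of [network_config()]s ordered small to large; all
#'   rungs must share backbone and fusion strategy.
#' @param train_records,val_records record lists (see [cohort_records()]).
#' @param config a [train_config()].
#' @return List of class `progressive_result`: `model` (last rung's best
#'   checkpoint), `histories` (per-rung), `transferred` (parameter counts
#'   moved between rungs).
#' @export
progressive_pretrain <- function(configs, train_records, val_records,
                                 config = train_config()) {
  stopifnot(length(configs) >= 1L)
  key <- function(cfg) paste(cfg$backbone, cfg$fusion, cfg$modality)
  if (length(unique(vapply(configs, key, character(1)))) != 1L) {
    stop("transfer mismatch")
  }
  prev <- NULL
  histories <- list()
  transferred <- integer(0)
  for (r in seq_along(configs)) {
    model <- model_build(configs[[r]])
    if (!is.null(prev)) {
      moved <- 0L
      pp <- net_params(prev)
      mp <- net_params(model)
      common <- intersect(names(pp), names(mp))
      take <- common[vapply(common, function(k) {
        identical(dim(pp[[k]]), dim(mp[[k]])) &&
          length(pp[[k]]) == length(mp[[k]])
      }, logical(1))]
      if (length(take) == 0L) stop("transfer mismatch")
      model <- net_set_params(model, pp[take])
      # carry batch-norm running statistics along with the weights
      for (i in seq_along(model$nodes)) {
        if (model$nodes[[i]]$op == "bn" && i <= length(prev$nodes) &&
            prev$nodes[[i]]$op == "bn") {
          model$nodes[[i]]$buf <- prev$nodes[[i]]$buf
        }
      }
      moved <- length(take)
      transferred <- c(transferred, moved)
    }
    res <- train(model,
                 prepare_dataset(train_records, configs[[r]]),
                 prepare_dataset(val_records, configs[[r]]),
                 config)
    prev <- res$model
    histories[[r]] <- res$history
  }
  structure(list(model = prev, histories = histories,
                 transferred = transferred),
            class = "progressive_result")
}
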