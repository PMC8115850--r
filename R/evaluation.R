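# Evaluation: agreement metrics between true and predicted ages, the
# stratified k-fold protocol, and per-fold report tables.
#
# Moment convention: Pearson's rho and the concordance correlation
# coefficient are computed with population (1/n) moments, matching their
# expectation-form definitions; the choice only matters at small n and is
# fixed here for reproducibility.

check_eval_vector <- function(y, yhat, min_n = 2L) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < min_n) stop("need at least ", min_n, " pairs")
  if (anyNA(y) || anyNA(yhat) || !all(is.finite(y)) || !all(is.finite(yhat))) {
    stop("non-finite values")
  }
}

#' Mean absolute error
#'
#' `(1/n) * sum(|y_i - yhat_i|)`, in years.
#'
#' @param y true ages; @param yhat predicted ages.
#' @return Scalar MAE (years).
#' @export
mae <- function(y, yhat) {
  check_eval_vector(y, yhat, min_n = 1L)
  mean(abs(y - yhat))
}

#' Pearson correlation between true and predicted ages
#'
#' `cov(y, yhat) / (sigma_y * sigma_yhat)` with population moments. A
#' constant side has no defined correlation and raises an error rather than
#' silently returning 0.
#'
#' @param y,yhat numeric vectors, `n >= 2`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(y, yhat) {
  check_eval_vector(y, yhat)
  my <- mean(y); mp <- mean(yhat)
  vy <- mean((y - my)^2); vp <- mean((yhat - mp)^2)
  if (vy == 0 || vp == 0) stop("undefined correlation")
  mean((y - my) * (yhat - mp)) / sqrt(vy * vp)
}

#' Lin's concordance correlation coefficient
#'
#' `2 * cov / (sigma_y^2 + sigma_yhat^2 + (mu_y - mu_yhat)^2)` with
#' population moments: penalizes both decorrelation and location/scale
#' shift, so CCC = 1 only for perfect agreement on the identity line.
#' Degenerate inputs are defined explicitly: two identical constant vectors
#' give 1; two constant vectors with different means give 0.
#'
#' @param y,yhat numeric vectors, `n >= 2`.
#' @return Concordance in `[-1, 1]`.
#' @export
ccc <- function(y, yhat) {
  check_eval_vector(y, yhat)
  my <- mean(y); mp <- mean(yhat)
  vy <- mean((y - my)^2); vp <- mean((yhat - mp)^2)
  if (vy == 0 && vp == 0) return(if (my == mp) 1 else 0)
  2 * mean((y - my) * (yhat - mp)) / (vy + vp + (my - mp)^2)
}

#' Stratified k-fold plan
#'
#' Partitions subjects into k disjoint folds whose sizes differ by at most
#' one, preserving the age/sex distribution: within every age-decade x sex
#' stratum the per-fold counts also differ by at most one. The plan is a
#' deterministic function of the subject ids and the seed, not of the input
#' row order.
#'
#' @param subjects data frame with `subject_id`, `age_years`, `sex` (a
#'   cohort `truth` or manifest table works).
#' @param k number of folds (default 10).
#' @param age_bin_width stratification bin width in years (default 10).
#' @param seed RNG seed for the within-stratum shuffles.
#' @return List of class `fold_plan`: `folds` (list of k character vectors
#'   of subject ids), `k`, `seed`.
#' @export
kfold_split <- function(subjects, k = 10L, age_bin_width = 10, seed = 1L) {
  stopifnot(all(c("subject_id", "age_years", "sex") %in% names(subjects)))
  n <- nrow(subjects)
  k <- as.integer(k)
  if (n < k) stop("fewer subjects than folds")
  subjects <- subjects[order(subjects$subject_id), ]
  stratum <- paste0(floor(subjects$age_years / age_bin_width), "_",
                    subjects$sex)
  folds <- vector("list", k)
  load <- integer(k)
  with_seed(seed, {
    for (s in unique(sort(stratum))) {
      ids <- subjects$subject_id[stratum == s]
      ids <- ids[sample.int(length(ids))]
      m <- length(ids)
      counts <- rep(m %/% k, k)
      rem <- m %% k
      if (rem > 0L) {
        # remainders go to the currently lightest folds
        give <- order(load, seq_len(k))[seq_len(rem)]
        counts[give] <- counts[give] + 1L
      }
      at <- 0L
      for (f in seq_len(k)) {
        if (counts[f] > 0L) {
          folds[[f]] <- c(folds[[f]], ids[(at + 1L):(at + counts[f])])
          at <- at + counts[f]
        }
      }
      load <- load + counts
    }
  })
  structure(list(folds = lapply(folds, sort), k = k, seed = as.integer(seed),
                 age_bin_width = age_bin_width),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k=%d  sizes: %s  seed %d\n", x$k,
              paste(lengths(x$folds), collapse = ", "), x$seed))
  invisible(x)
}

#' Per-fold metric report
#'
#' @param per_fold data frame with columns `fold`, `n`, `mae`, `pearson`,
#'   `ccc`.
#' @param predictions data frame with `subject_id`, `fold`, `true_age`,
#'   `predicted_age`.
#' @param tag configuration label (`mandible`, `femur`, `late`, `early`,
#'   `middle`, ...).
#' @return List of class `metric_report` with an `aggregate` row of
#'   mean +/- std (population std across folds, unweighted mean).
#' @export
metric_report <- function(per_fold, predictions, tag = "model") {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  aggregate <- data.frame(
    metric = c("mae", "pearson", "ccc"),
    mean = c(mean(per_fold$mae), mean(per_fold$pearson), mean(per_fold$ccc)),
    sd = c(pop_sd(per_fold$mae), pop_sd(per_fold$pearson),
           pop_sd(per_fold$ccc))
  )
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 predictions = predictions, tag = tag),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s  (%d folds, %d subjects)\n", x$tag,
              nrow(x$per_fold), nrow(x$predictions)))
  print(x$per_fold, row.names = FALSE, digits = 4)
  a <- x$aggregate
  cat(sprintf("Means +/- std:  MAE %.2f +/- %.2f   rho %.3f +/- %.3f   CCC %.3f +/- %.3f\n",
              a$mean[1], a$sd[1], a$mean[2], a$sd[2], a$mean[3], a$sd[3]))
  invisible(x)
}

#' Predicted-versus-actual scatter table
#'
#' One row per subject with the identity-line residual
#' `predicted - true`; the residual mean equals the difference of the
#' prediction and truth means.
#'
#' @param y true ages; @param yhat predicted ages;
#' @param ids optional subject ids.
#' @return Data frame `subject_id`, `true_age`, `predicted_age`,
#'   `residual`.
#' @export
scatter_data <- function(y, yhat, ids = NULL) {
  check_eval_vector(y, yhat, min_n = 1L)
  data.frame(subject_id = ids %||% seq_along(y),
             true_age = y, predicted_age = yhat, residual = yhat - y)
}

# Train the model(s) of one CV fold and return test-fold predictions.
fit_fold <- function(net_cfg, tr_cfg, records, train_ids, test_ids,
                     fold_seed) {
  byid <- stats::setNames(records, vapply(records, `[[`, character(1), "id"))
  stopifnot(length(intersect(train_ids, test_ids)) == 0L)  # leakage guard
  pool <- byid[train_ids]
  # inner stratified split for the scheduler / best-epoch selection
  pool_df <- data.frame(
    subject_id = train_ids,
    age_years = vapply(pool, `[[`, numeric(1), "age_years"),
    sex = vapply(pool, `[[`, numeric(1), "sex"))
  k_inner <- min(length(train_ids),
                 max(2L, as.integer(round(1 / tr_cfg$val_fraction))))
  inner <- kfold_split(pool_df, k = k_inner, seed = fold_seed)
  val_ids <- inner$folds[[1L]]
  fit_ids <- setdiff(train_ids, val_ids)
  stopifnot(length(intersect(c(fit_ids, val_ids), test_ids)) == 0L)
  tr_cfg$seed <- fold_seed

  train_one <- function(cfg) {
    res <- train(model_build(cfg),
                 prepare_dataset(byid[fit_ids], cfg),
                 prepare_dataset(byid[val_ids], cfg), tr_cfg)
    res$model
  }
  if (net_cfg$fusion == "late") {
    cfg_m <- network_config(backbone = net_cfg$mandible_backbone,
                            fusion = "none", modality = "mandible",
                            use_gender = net_cfg$use_gender,
                            scale = net_cfg$scale,
                            shape_scale = net_cfg$shape_scale,
                            seed = net_cfg$seed + 1L)
    cfg_f <- network_config(backbone = net_cfg$femur_backbone,
                            fusion = "none", modality = "femur",
                            use_gender = net_cfg$use_gender,
                            scale = net_cfg$scale,
                            shape_scale = net_cfg$shape_scale,
                            seed = net_cfg$seed + 2L)
    mm <- train_one(cfg_m)
    mf <- train_one(cfg_f)
    pm <- predict_dataset(mm, prepare_dataset(byid[test_ids], cfg_m))
    pf <- predict_dataset(mf, prepare_dataset(byid[test_ids], cfg_f))
    fuse_late(pm, pf)
  } else {
    m <- train_one(net_cfg)
    predict_dataset(m, prepare_dataset(byid[test_ids], net_cfg))
  }
}

#' Cross-validated training and evaluation
#'
#' For every fold of the plan, trains the configured model on the remaining
#' folds (with an inner stratified train/validation split driving the
#' learning-rate schedule and best-epoch selection) and evaluates MAE,
#' Pearson correlation, and CCC on the held-out fold. No test-fold subject
#' ever enters its model's training or inner-validation data; this is
#' asserted, not assumed.
#'
#' @param records subject records from [cohort_records()].
#' @param net_cfg a [network_config()].
#' @param tr_cfg a [train_config()].
#' @param plan a [kfold_split()] plan over the same subjects.
#' @return A [metric_report()].
#' @export
cross_validate <- function(records, net_cfg, tr_cfg, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- vapply(records, `[[`, character(1), "id")
  ages <- stats::setNames(vapply(records, `[[`, numeric(1), "age_years"), ids)
  per_fold <- list()
  preds <- list()
  for (f in seq_len(plan$k)) {
    test_ids <- plan$folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    yhat <- tryCatch(
      fit_fold(net_cfg, tr_cfg, records, train_ids, test_ids,
               fold_seed = tr_cfg$seed + f),
      error = function(e) stop("fold ", f, " failed: ", conditionMessage(e)))
    y <- ages[test_ids]
    per_fold[[f]] <- data.frame(fold = f, n = length(y), mae = mae(y, yhat),
                                pearson = pearson(y, yhat),
                                ccc = ccc(y, yhat))
    preds[[f]] <- data.frame(subject_id = test_ids, fold = f, true_age = y,
                             predicted_age = yhat)
  }
  tag <- if (net_cfg$fusion == "none") net_cfg$modality else net_cfg$fusion
  metric_report(do.call(rbind, per_fold), do.call(rbind, preds), tag = tag)
}

#' Write a metric report to disk
#'
#' Emits the per-fold table as CSV, the aggregates as JSON, and the
#' predicted-versus-actual scatter table as CSV.
#'
#' @param report a [metric_report()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_fold, file.path(dir, "per_fold.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(tag = report$tag,
         mae = list(mean = report$aggregate$mean[1], sd = report$aggregate$sd[1]),
         pearson = list(mean = report$aggregate$mean[2], sd = report$aggregate$sd[2]),
         ccc = list(mean = report$aggregate$mean[3], sd = report$aggregate$sd[3])),
    file.path(dir, "aggregate.json"), auto_unbox = TRUE, digits = NA)
  sc <- scatter_data(report$predictions$true_age,
                     report$predictions$predicted_age,
                     report$predictions$subject_id)
  write.csv(sc, file.path(dir, "scatter.csv"), row.names = FALSE)
  invisible(dir)
}
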