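# Synthetic CT phantom cohorts. Each subject gets a femur-region and a
# mandible-region volume containing simple bone-density structures whose
# cortical density and cortical thickness decline linearly with age:
#
#   density_HU  = h0 - beta * age + delta * sex + subject offset + voxel noise
#   thickness_mm = t0 - gamma * age
#
# The femur region is a cortical-shelled cylinder (shaft) plus a spherical
# head; the mandible region is a U-shaped cortical arch per slice plus a
# small separate "neck" cylinder that the component-retention rule is
# expected to remove. Background is soft tissue (0-100 HU) inside a body
# ellipse and air (-1000 HU) outside.

#' Phantom cohort parameters
#'
#' Defaults emulate the adult post-mortem cohort the pipeline targets: ages
#' 20-70 drawn from a truncated normal with mean 49.59 and sd 11.80 years,
#' 76% male. The age signal is linear in cortical density
#' (`beta` HU/year decline) and cortical thickness (`gamma` mm/year). A
#' per-subject, per-modality density offset (`subject_sd`) makes the two
#' bones carry complementary noisy copies of the same age signal, so
#' multimodal fusion has something to gain; i.i.d. Gaussian voxel noise
#' (`noise_sd`) emulates scanner noise.
#'
#' @param n_subjects number of subjects.
#' @param age_range years, default `c(20, 70)`.
#' @param age_mean,age_sd truncated-normal age distribution (years).
#' @param sex_ratio fraction male (sex code 0), default 0.76.
#' @param h0 cortical density at age 0 (HU), default 800.
#' @param beta density decline (HU/year), default 4.
#' @param t0 cortical thickness at age 0 (mm), default 8.
#' @param gamma cortical thinning (mm/year), default 0.06.
#' @param delta additive density offset for females (HU), default -30.
#' @param noise_sd voxel noise sd (HU), default 30.
#' @param subject_sd per-subject per-modality density offset sd (HU),
#'   default 20.
#' @param spacing phantom grid spacing in mm (isotropic), default 2.
#' @param femur_grid,mandible_grid grid shapes `(z, y, x)` at `spacing`.
#' @param seed integer RNG seed.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(n_subjects = 100, age_range = c(20, 70),
                           age_mean = 49.59, age_sd = 11.80,
                           sex_ratio = 0.76,
                           h0 = 800, beta = 4, t0 = 8, gamma = 0.06,
                           delta = -30, noise_sd = 30, subject_sd = 20,
                           spacing = 2,
                           femur_grid = c(40L, 64L, 64L),
                           mandible_grid = c(12L, 64L, 64L),
                           seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
            age_mean = age_mean, age_sd = age_sd, sex_ratio = sex_ratio,
            h0 = h0, beta = beta, t0 = t0, gamma = gamma, delta = delta,
            noise_sd = noise_sd, subject_sd = subject_sd, spacing = spacing,
            femur_grid = as.integer(femur_grid),
            mandible_grid = as.integer(mandible_grid), seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  ok <- p$n_subjects >= 1 &&
    p$noise_sd >= 0 && p$subject_sd >= 0 &&
    p$sex_ratio >= 0 && p$sex_ratio <= 1 &&
    p$age_range[1] < p$age_range[2] &&
    p$t0 - p$gamma * p$age_range[2] > 0 &&
    # cortical bone must stay inside the 400-1000 HU window for the oldest,
    # lowest-density subjects
    p$h0 - p$beta * p$age_range[2] - abs(p$delta) >= 450
  if (!ok) stop("invalid phantom params")
  invisible(p)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# Squared-distance fields on the (y, x) plane of a (z, y, x) grid, in mm.
plane_r2 <- function(grid, spacing, cy, cx) {
  y <- (seq_len(grid[2]) - cy) * spacing
  x <- (seq_len(grid[3]) - cx) * spacing
  outer(y^2, x^2, `+`)
}

#' Generate one synthetic subject
#'
#' Builds the femur-region and mandible-region CT volumes for a subject of
#' the given age and sex, plus the ground-truth record of the realized
#' cortical density and thickness. Consumes the current RNG stream; use
#' [generate_cohort()] for seeded cohorts.
#'
#' @param age years.
#' @param sex 0 = male, 1 = female.
#' @param params a [phantom_params()].
#' @param subject_id character id.
#' @return List with `femur` and `mandible` ([ct_volume()]s, HU) and `truth`
#'   (one-row data frame).
#' @export
generate_subject <- function(age, sex, params, subject_id = "S0001") {
  validate_phantom_params(params)
  if (!sex %in% c(0, 1)) stop("invalid sex code")
  sp <- params$spacing
  thick <- params$t0 - params$gamma * age
  dens_f <- params$h0 - params$beta * age + params$delta * sex +
    rnorm(1, 0, params$subject_sd)
  dens_m <- params$h0 - params$beta * age + params$delta * sex +
    rnorm(1, 0, params$subject_sd)

  ## femur region: vertical cylindrical shaft + spherical head
  g <- params$femur_grid
  cy <- g[2] / 2; cx <- g[3] / 2
  r2 <- plane_r2(g, sp, cy, cx)                      # (y, x) mm^2
  shaft_outer <- 12; head_r <- 14
  vol <- array(0, g)
  body_r2 <- max(r2) * 0.55                          # soft-tissue ellipse
  zc <- (seq_len(g[1]) - 1) * sp
  head_z <- zc[g[1]] - head_r                        # head centre near top
  soft <- matrix(runif(g[2] * g[3], 0, 100), g[2], g[3])
  for (k in seq_len(g[1])) {
    slice <- ifelse(r2 <= body_r2, soft, -1000)
    if (zc[k] <= head_z - head_r * 0.2) {            # shaft band
      shell <- r2 <= shaft_outer^2 & r2 > (shaft_outer - thick)^2
      slice[shell] <- dens_f
      slice[r2 <= (shaft_outer - thick)^2] <- 150    # medullary cavity
    }
    dz2 <- (zc[k] - head_z)^2
    if (dz2 <= head_r^2) {                           # spherical head shell
      rr2 <- head_r^2 - dz2
      shell <- r2 <= rr2 & r2 > pmax(sqrt(rr2) - thick, 0)^2
      slice[shell] <- dens_f
    }
    vol[k, , ] <- slice
  }
  vol <- vol + array(rnorm(length(vol), 0, params$noise_sd), dim(vol))
  femur <- ct_volume(vol, spacing = rep(sp, 3), subject_id = subject_id)

  ## mandible region: U-shaped cortical arch + small separate neck cylinder
  g <- params$mandible_grid
  cy <- g[2] * 0.45; cx <- g[3] / 2
  yy <- matrix((seq_len(g[2]) - cy) * sp, g[2], g[3])
  r2 <- plane_r2(g, sp, cy, cx)
  arch_outer <- 20
  arch <- r2 <= arch_outer^2 & r2 > (arch_outer - 6)^2 & yy <= 0
  neck_r2 <- plane_r2(g, sp, g[2] * 0.85, cx)
  neck <- neck_r2 <= 2.5^2
  body_r2 <- max(r2) * 0.55
  vol <- array(0, g)
  soft <- matrix(runif(g[2] * g[3], 0, 100), g[2], g[3])
  for (k in seq_len(g[1])) {
    slice <- ifelse(r2 <= body_r2 | neck_r2 <= body_r2, soft, -1000)
    slice[arch] <- dens_m
    slice[neck] <- dens_m
    vol[k, , ] <- slice
  }
  vol <- vol + array(rnorm(length(vol), 0, params$noise_sd), dim(vol))
  mandible <- ct_volume(vol, spacing = rep(sp, 3), subject_id = subject_id)

  truth <- data.frame(
    subject_id = subject_id, age_years = age, sex = sex,
    femur_density_hu = dens_f, mandible_density_hu = dens_m,
    cortical_thickness_mm = thick
  )
  list(femur = femur, mandible = mandible, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws ages from the configured truncated normal and sexes from the
#' configured male fraction, generates every subject's volumes, and
#' optionally writes them out as DICOM series with a manifest and truth CSV.
#' Fully deterministic given `params$seed`.
#'
#' @param params a [phantom_params()].
#' @param out_dir if non-`NULL`, write `dicom/<id>/<modality>/` series plus
#'   `manifest.csv` and `truth.csv` under this directory.
#' @param keep_volumes if `TRUE` (default) return the generated volumes in
#'   memory; set `FALSE` with `out_dir` to keep the footprint small.
#' @return List of class `phantom_cohort`: `subjects` (list with `femur`,
#'   `mandible`, per subject, when kept), `truth` (data frame),
#'   `manifest` (data frame), `params`.
#' @export
generate_cohort <- function(params, out_dir = NULL, keep_volumes = TRUE) {
  validate_phantom_params(params)
  with_seed(params$seed, {
    n <- params$n_subjects
    ages <- rtruncnorm1(n, params$age_mean, params$age_sd,
                        params$age_range[1], params$age_range[2])
    sexes <- rbinom(n, 1, 1 - params$sex_ratio)      # 0 = male, 1 = female
    ids <- sprintf("S%04d", seq_len(n))
    subjects <- vector("list", n)
    names(subjects) <- ids
    truth <- vector("list", n)
    series_dirs <- matrix("", n, 2,
                          dimnames = list(NULL, c("femur", "mandible")))
    for (i in seq_len(n)) {
      s <- generate_subject(ages[i], sexes[i], params, subject_id = ids[i])
      truth[[i]] <- s$truth
      if (!is.null(out_dir)) {
        for (mod in c("femur", "mandible")) {
          d <- file.path(out_dir, "dicom", ids[i], mod)
          write_series(s[[mod]], d)
          series_dirs[i, mod] <- d
        }
      }
      if (keep_volumes) subjects[[i]] <- s[c("femur", "mandible")]
    }
    truth <- do.call(rbind, truth)
    manifest <- data.frame(subject_id = ids,
                           age_years = round(ages, 4), sex = sexes,
                           femur_dir = series_dirs[, "femur"],
                           mandible_dir = series_dirs[, "mandible"])
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(manifest, file.path(out_dir, "manifest.csv"),
                row.names = FALSE)
      write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    }
    structure(list(subjects = if (keep_volumes) subjects,
                   truth = truth, manifest = manifest, params = params),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> n=%d  ages %.1f-%.1f (mean %.1f)  %.0f%% male  seed %d\n",
              nrow(x$truth), min(x$truth$age_years), max(x$truth$age_years),
              mean(x$truth$age_years), 100 * mean(x$truth$sex == 0),
              x$params$seed))
  invisible(x)
}
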