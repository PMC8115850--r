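# Resampling, bone windowing, morphology, component filtering, and the
# mandible extraction chain.

test_that("resampling follows the dimension formula and preserves extent", {
  vol <- ct_volume(array(rnorm(50 * 100 * 100), c(50, 100, 100)),
                   spacing = c(2, 1, 1))
  out <- resample_isotropic(vol)
  expect_equal(dim(out$values), c(100, 100, 100))
  expect_equal(out$spacing, c(1, 1, 1))
  # physical extent preserved within one output voxel per axis
  expect_true(all(abs(dim(out$values) * out$spacing -
                        dim(vol$values) * vol$spacing) <= out$spacing))
  expect_error(resample_isotropic(vol, c(0, 1, 1)), "invalid spacing")
})

test_that("resampling an already-isotropic volume is the identity", {
  vol <- ct_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(vol)$values, vol$values)
})

test_that("resampling a constant field returns the same constant", {
  vol <- ct_volume(array(7.25, c(10, 12, 14)), spacing = c(1.7, 0.9, 1.3))
  out <- resample_isotropic(vol)
  expect_equal(max(abs(out$values - 7.25)), 0, tolerance = 1e-12)
  expect_equal(mean(out$values), 7.25)
})

test_that("resampling smooth fields preserves values within interpolation error", {
  d <- c(20, 20, 20)
  grid <- expand.grid(z = 1:20, y = 1:20, x = 1:20)
  f <- array(sin(grid$z / 4) + cos(grid$y / 5) + grid$x / 10, d)
  vol <- ct_volume(f, spacing = c(2, 2, 2))
  out <- resample_isotropic(vol, c(1, 1, 1))
  # compare at every other output voxel, which coincides with an input voxel
  expect_equal(out$values[seq(1, 39, 2), seq(1, 39, 2), seq(1, 39, 2)], f,
               tolerance = 1e-12)
})

test_that("the femur window maps 400->0, 700->0.5, 1000->1 and clamps", {
  expect_equal(hu_window(c(400, 700, 1000)), c(0, 0.5, 1))
  expect_equal(hu_window(c(-50, 1500)), c(0, 1))
  # monotone non-decreasing in HU
  hu <- sort(runif(200, -1200, 2000))
  expect_true(all(diff(hu_window(hu)) >= 0))
})

test_that("segment_femur produces the fixed femur shape with values in [0,1]", {
  p <- quiet_params()
  s <- generate_subject(40, 0, p, "F01")
  iso <- resample_isotropic(s$femur)
  bv <- segment_femur(iso)
  expect_s3_class(bv, "bone_voxel")
  expect_equal(dim(bv$values), c(112, 128, 128))
  expect_gte(min(bv$values), 0)
  expect_lte(max(bv$values), 1)
  expect_error(segment_femur(iso, region = list(zmin = 500, zmax = 600,
                                                ymin = 1, ymax = 10,
                                                xmin = 1, xmax = 10)),
               "empty region")
})

test_that("morphological opening removes small objects and keeps large ones", {
  m <- matrix(FALSE, 30, 30)
  m[15, 15] <- TRUE                       # isolated pixel
  expect_false(any(morphological_open(m)))
  sq <- matrix(FALSE, 30, 30)
  sq[6:25, 6:25] <- TRUE                  # 20x20 solid square
  expect_identical(morphological_open(sq), sq)
  expect_error(morphological_open(m, matrix(FALSE, 3, 3)), "empty")
})

test_that("opening is anti-extensive and idempotent on random masks", {
  set.seed(11)
  for (i in 1:25) {
    m <- matrix(runif(40 * 40) < 0.4, 40, 40)
    o <- morphological_open(m)
    expect_true(all(o <= m))              # anti-extensive
    expect_identical(morphological_open(o), o)  # idempotent
  }
})

test_that("component labeling honours connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[7:9, 7:9] <- TRUE
  lab <- label_components(m)
  expect_equal(sort(unname(lab$sizes)), c(4L, 9L))
  expect_equal(length(lab$sizes), 2L)
  expect_equal(length(label_components(matrix(FALSE, 5, 5))$sizes), 0L)
  diagm <- matrix(FALSE, 4, 4)
  diagm[2, 2] <- diagm[3, 3] <- TRUE      # corner-touching pixels
  expect_equal(length(label_components(diagm, connectivity = 4)$sizes), 2L)
  expect_equal(length(label_components(diagm, connectivity = 8)$sizes), 1L)
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.35, 30, 30)
    mine <- label_components(m, connectivity = 4)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(length(mine$sizes), max(ref))
    expect_equal(sort(unname(mine$sizes)),
                 sort(unname(tabulate(ref[ref > 0]))))
  }
})

test_that("retain_large_components keeps components above the size threshold", {
  m <- matrix(FALSE, 80, 120)
  m[2:41, 2:26] <- TRUE      # 1000 px
  m[2:31, 40:69] <- TRUE     # 900 px
  m[50:54, 100] <- TRUE      # 5 px
  lab <- label_components(m)
  expect_equal(sort(unname(lab$sizes)), c(5L, 900L, 1000L))
  kept <- retain_large_components(lab, min_fraction = 0.1)
  sizes_kept <- sort(unname(label_components(kept)$sizes))
  expect_equal(sizes_kept, c(900L, 1000L))  # threshold 100 removes the 5 px
  # a single component is kept unchanged; empty in -> empty out
  single <- matrix(FALSE, 10, 10); single[3:6, 3:6] <- TRUE
  expect_identical(retain_large_components(label_components(single)), single)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(retain_large_components(label_components(empty)), empty)
  # retained sizes are always a subset of input sizes; the largest survives
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(runif(50 * 50) < 0.3, 50, 50)
    lab <- label_components(m)
    if (length(lab$sizes) == 0) next
    kept <- retain_large_components(lab)
    ks <- label_components(kept)$sizes
    expect_true(all(ks %in% lab$sizes))
    expect_true(max(lab$sizes) %in% ks)
  }
})

test_that("mandible extraction keeps the arch and drops the neck fragment", {
  # constructed slice: arch of 1200 px at 800 HU, neck fragment 40 px at 700 HU
  sl <- matrix(runif(256 * 256, 0, 100), 256, 256)
  arch <- matrix(FALSE, 256, 256); arch[81:120, 61:90] <- TRUE   # 1200 px
  neck <- matrix(FALSE, 256, 256); neck[201:208, 201:205] <- TRUE # 40 px
  sl[arch] <- 800
  sl[neck] <- 700
  vol <- ct_volume(array(rep(sl, 3), c(256, 256, 3)) |> aperm(c(3, 1, 2)),
                   spacing = c(1, 1, 1))
  bv <- extract_mandible(vol)
  expect_equal(dim(bv$values), c(20, 256, 256))
  mid <- bv$values[10, , ]
  expect_true(all(mid[arch] > 0))        # arch survives
  expect_true(all(mid[neck] == 0))       # neck fragment removed
  expect_true(all(mid[!arch & !neck] == 0))
})

test_that("a pure soft-tissue volume has no mandible", {
  vol <- ct_volume(array(runif(5 * 64 * 64, 0, 100), c(5, 64, 64)),
                   spacing = c(1, 1, 1))
  expect_error(extract_mandible(vol), "empty mandible")
})

test_that("phantom mandibles produce the fixed 20 x 256 x 256 voxel", {
  s <- generate_subject(45, 1, quiet_params(), "M01")
  bv <- preprocess_volume(s$mandible, "mandible")
  expect_equal(dim(bv$values), c(20, 256, 256))
  expect_gte(min(bv$values), 0)
  expect_lte(max(bv$values), 1)
  expect_gt(mean(bv$values > 0), 0)      # some bone present
  # a z stride halves the slab's depth resolution but keeps the shape
  bv2 <- extract_mandible(resample_isotropic(s$mandible), z_stride = 2)
  expect_equal(dim(bv2$values), c(20, 256, 256))
})

test_that("bone voxel construction enforces shape and range invariants", {
  expect_error(bone_voxel(array(0.5, c(10, 10, 10)), "femur"), "shape")
  bad <- array(0.5, c(112, 128, 128)); bad[1] <- 1.5
  expect_error(bone_voxel(bad, "femur"), "outside")
  bad[1] <- NaN
  expect_error(bone_voxel(bad, "femur"), "non-finite")
})

test_that("voxels round-trip through save_voxel / load_voxel", {
  s <- generate_subject(30, 0, quiet_params(), "V01")
  bv <- preprocess_volume(s$femur, "femur")
  d <- withr::local_tempdir()
  path <- save_voxel(bv, d)
  back <- load_voxel(path)
  expect_identical(back$values, bv$values)
  expect_identical(back$modality, "femur")
  expect_identical(back$subject_id, "V01")
})
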