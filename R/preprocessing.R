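# Bone-voxel preprocessing: isotropic resampling, femur HU windowing, and the
# per-slice mandible extraction chain (threshold -> morphological opening ->
# component labeling -> large-component retention -> masking).

#' Resample a CT volume to isotropic spacing
#'
#' Scanner voxel spacing varies between post-mortem CT exports (e.g. 1.2 mm
#' slices with 1.1 mm in-plane pixels on one scanner, 0.8/1.12 mm on
#' another), which a convolutional network would otherwise have to absorb.
#' Resampling every scan to a common (default 1 x 1 x 1 mm) grid removes the
#' scanner resolution as a nuisance variable. Intensities are produced by
#' trilinear interpolation; the output grid has
#' `round(dim * spacing / target)` voxels per axis, so the physical extent is
#' preserved to within one output voxel. A volume already on the target grid
#' is returned unchanged, bit for bit.
#'
#' @param volume a [ct_volume()].
#' @param target_spacing numeric length-3 (mm, `(z, y, x)`), default
#'   `c(1, 1, 1)`.
#' @return A [ct_volume()] with the requested spacing.
#' @export
resample_isotropic <- function(volume, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(volume, "ct_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    stop("invalid spacing")
  }
  if (all(abs(volume$spacing - target_spacing) < 1e-12)) return(volume)
  d <- dim(volume$values)
  outdim <- pmax(1L, as.integer(round(d * volume$spacing / target_spacing)))
  step <- target_spacing / volume$spacing
  vals <- .resample_trilinear(volume$values, outdim, step)
  ct_volume(vals, spacing = target_spacing, origin = volume$origin,
            subject_id = volume$subject_id)
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the same structuring element: removes
#' foreground objects smaller than the structure while preserving the shape
#' of objects that contain it. Opening is anti-extensive (the output is a
#' subset of the input) and idempotent.
#'
#' @param mask logical (or 0/1) matrix.
#' @param structure logical matrix structuring element; default 3 x 3 square.
#' @return Logical matrix of the same shape.
#' @export
morphological_open <- function(mask, structure = matrix(TRUE, 3, 3)) {
  if (!any(structure)) stop("empty structuring element")
  m <- EBImage::Image(mask * 1)
  kern <- structure * 1
  out <- EBImage::dilate(EBImage::erode(m, kern), kern)
  EBImage::imageData(out) > 0.5
}

#' Label connected components of a binary mask
#'
#' Assigns a distinct positive integer to every maximal connected foreground
#' region; background stays 0. Connectivity is 8 (edge or corner adjacency)
#' by default, per axial slice.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return List with `labels` (integer matrix) and `sizes` (named integer
#'   vector of component pixel counts, names are label ids).
#' @export
label_components <- function(mask, connectivity = 8L) {
  labels <- .label_components_2d(mask, as.integer(connectivity))
  k <- max(labels)
  sizes <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  names(sizes) <- if (k > 0L) as.character(seq_len(k)) else character(0)
  list(labels = labels, sizes = sizes)
}

#' Retain large labeled components
#'
#' Keeps every component whose pixel count is at least `min_fraction` of the
#' largest component's; the largest component always survives. This is the
#' rule that strips neck-bone fragments from mandible slices while keeping
#' the mandibular arch.
#'
#' @param labeled output of [label_components()] (or a compatible list).
#' @param min_fraction components smaller than this fraction of the largest
#'   are dropped (default 0.1).
#' @return Logical mask of the retained components.
#' @export
retain_large_components <- function(labeled, min_fraction = 0.1) {
  labels <- labeled$labels
  sizes <- labeled$sizes
  if (length(sizes) == 0L) return(labels > 0L)
  keep <- as.integer(names(sizes))[sizes >= min_fraction * max(sizes)]
  matrix(labels %in% keep, nrow = nrow(labels))
}

# Resolve a region argument to index ranges. `region` is either "auto",
# NULL (whole volume), or a list with zmin/zmax/ymin/ymax/xmin/xmax
# (1-based, inclusive). The "auto" heuristic picks an axial band by
# fractional height of the stack: mandible near the top of a head-first
# whole-body stack, femur in the mid-shaft band.
resolve_region <- function(volume, region, modality,
                           auto_bands = list(femur = c(0.55, 0.75),
                                             mandible = c(0.85, 1.00))) {
  d <- dim(volume$values)
  if (is.null(region)) {
    return(list(z = 1:d[1L], y = 1:d[2L], x = 1:d[3L]))
  }
  if (identical(region, "auto")) {
    band <- auto_bands[[modality]]
    z0 <- max(1L, as.integer(ceiling(band[1L] * d[1L])))
    z1 <- min(d[1L], as.integer(ceiling(band[2L] * d[1L])))
    return(list(z = z0:z1, y = 1:d[2L], x = 1:d[3L]))
  }
  z <- max(1L, region$zmin):min(d[1L], region$zmax)
  y <- max(1L, region$ymin):min(d[2L], region$ymax)
  x <- max(1L, region$xmin):min(d[3L], region$xmax)
  if (region$zmin > d[1L] || region$zmax < 1L ||
      region$ymin > d[2L] || region$ymax < 1L ||
      region$xmin > d[3L] || region$xmax < 1L) {
    stop("empty region")
  }
  list(z = z, y = y, x = x)
}

#' Segment the femur into a fixed-shape normalized bone voxel
#'
#' Windows the cortical-bone density range: intensities are mapped by
#' `clamp((HU - 400) / 600, 0, 1)`, so 400 HU (the lower edge of femoral
#' cortical bone) maps to 0 and 1000 HU to 1, with everything outside the
#' window clamped. The windowed region is then centre-cropped or
#' symmetrically zero-padded to the fixed femur shape 112 x 128 x 128.
#'
#' @param volume a [ct_volume()] resampled to 1 mm isotropic spacing.
#' @param region `NULL` (whole volume), `"auto"` (axial-band heuristic), or
#'   an explicit box `list(zmin, zmax, ymin, ymax, xmin, xmax)`.
#' @param window HU window edges, default `c(400, 1000)`.
#' @return A [bone_voxel()] with `modality = "femur"`.
#' @export
segment_femur <- function(volume, region = NULL, window = c(400, 1000)) {
  stopifnot(inherits(volume, "ct_volume"))
  idx <- resolve_region(volume, region, "femur")
  sub <- volume$values[idx$z, idx$y, idx$x, drop = FALSE]
  vals <- hu_window(sub, window[1L], window[2L])
  bone_voxel(fit_to_shape(vals, MODALITY_SHAPES$femur),
             modality = "femur", subject_id = volume$subject_id)
}

#' Extract the mandible into a fixed-shape masked bone voxel
#'
#' Per axial slice: centre-crop to 256 x 256, threshold at 400 HU to drop
#' soft tissue, apply morphological opening to remove speckle, label
#' connected components, retain only components comparable in size to the
#' largest (which removes neck-bone fragments), and multiply the resulting
#' mask into the cropped HU slice. Bone-bearing slices are then stacked, a
#' central slab of exactly 20 slices is selected (zero-padded along z when
#' fewer exist), and intensities are window-normalized to `[0, 1]` with the
#' same 400-1000 HU map used for the femur.
#'
#' @param volume a [ct_volume()] resampled to 1 mm isotropic spacing.
#' @param region as in [segment_femur()]; default `NULL` (whole volume).
#' @param threshold bone threshold in HU (default 400).
#' @param min_fraction component retention rule, see
#'   [retain_large_components()].
#' @param structure structuring element for the opening.
#' @param connectivity labeling connectivity (default 8).
#' @param window HU window for the final normalization.
#' @param z_stride keep every `z_stride`-th bone-bearing slice before slab
#'   selection (default 1). A 20-slice slab at 1 mm cannot span a whole
#'   mandible; a stride of 2-3 trades z resolution for coverage.
#' @return A [bone_voxel()] with `modality = "mandible"` (20 x 256 x 256).
#' @export
extract_mandible <- function(volume, region = NULL, threshold = 400,
                             min_fraction = 0.1,
                             structure = matrix(TRUE, 3, 3),
                             connectivity = 8L, window = c(400, 1000),
                             z_stride = 1L) {
  stopifnot(inherits(volume, "ct_volume"))
  idx <- resolve_region(volume, region, "mandible")
  sub <- volume$values[idx$z, idx$y, idx$x, drop = FALSE]
  nz <- dim(sub)[1L]
  target_xy <- MODALITY_SHAPES$mandible[2:3]

  masked <- array(0, c(nz, target_xy))
  has_bone <- logical(nz)
  for (k in seq_len(nz)) {
    slice <- fit_to_shape(array(sub[k, , ], c(1L, dim(sub)[2:3])),
                          c(1L, target_xy), fill = -1024)[1L, , ]
    mask <- slice >= threshold
    if (any(mask)) {
      mask <- morphological_open(mask, structure)
      if (any(mask)) {
        lab <- label_components(mask, connectivity)
        mask <- retain_large_components(lab, min_fraction)
      }
    }
    has_bone[k] <- any(mask)
    masked[k, , ] <- ifelse(mask, slice, 0)
  }
  if (!any(has_bone)) stop("empty mandible")

  # central slab of bone-bearing slices, exactly 20 after crop/pad along z
  bone_idx <- which(has_bone)
  span <- seq.int(min(bone_idx), max(bone_idx), by = as.integer(z_stride))
  slab <- masked[span, , , drop = FALSE]
  slab <- fit_to_shape(slab, MODALITY_SHAPES$mandible)
  vals <- hu_window(slab, window[1L], window[2L])
  bone_voxel(vals, modality = "mandible", subject_id = volume$subject_id)
}

#' Preprocess one subject's CT volume into a bone voxel
#'
#' Convenience wrapper chaining [resample_isotropic()] with
#' [segment_femur()] or [extract_mandible()].
#'
#' @param volume a [ct_volume()] at native spacing.
#' @param modality `"femur"` or `"mandible"`.
#' @param region region specification passed through.
#' @param ... further arguments to the modality-specific extractor.
#' @return A [bone_voxel()].
#' @export
preprocess_volume <- function(volume, modality = c("femur", "mandible"),
                              region = NULL, ...) {
  modality <- match.arg(modality)
  iso <- resample_isotropic(volume)
  switch(modality,
         femur = segment_femur(iso, region = region, ...),
         mandible = extract_mandible(iso, region = region, ...))
}

#' Save / load a bone voxel with a JSON sidecar
#'
#' Voxels are stored as a compressed serialized array plus a small JSON
#' sidecar recording modality, shape, window and provenance, one pair of
#' files per subject and modality.
#'
#' @param voxel a [bone_voxel()].
#' @param dir output directory.
#' @return `save_voxel`: invisibly, the data file path. `load_voxel`: the
#'   [bone_voxel()].
#' @export
save_voxel <- function(voxel, dir) {
  stopifnot(inherits(voxel, "bone_voxel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(voxel$subject_id, "_", voxel$modality))
  saveRDS(voxel$values, paste0(stem, ".rds"), compress = "gzip")
  jsonlite::write_json(
    list(subject_id = voxel$subject_id, modality = voxel$modality,
         shape = dim(voxel$values), window_hu = c(400, 1000),
         mean_intensity = mean(voxel$values)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(stem, ".rds"))
}

#' @rdname save_voxel
#' @param path path to a saved `_<modality>.rds` voxel file.
#' @export
load_voxel <- function(path) {
  sidecar <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  bone_voxel(readRDS(path), modality = sidecar$modality,
             subject_id = sidecar$subject_id)
}
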