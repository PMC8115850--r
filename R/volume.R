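#' CT volume container
#'
#' A `ct_volume` holds a rank-3 scalar grid of radiodensities in Hounsfield
#' units together with its physical geometry. Axis order is `(z, y, x)`
#' throughout the package: the first array dimension indexes axial slices, so
#' a "112 x 128 x 128" volume has 112 slices. Spacing is in millimetres per
#' voxel along `(z, y, x)`.
#'
#' @param values numeric 3D array of Hounsfield units, axes `(z, y, x)`.
#' @param spacing numeric length-3, voxel spacing in mm along `(z, y, x)`;
#'   all components must be strictly positive.
#' @param origin numeric length-3, physical position (mm) of voxel
#'   `[1, 1, 1]`, in the same `(z, y, x)` order.
#' @param subject_id character scalar identifying the scanned subject.
#'
#' @return An object of class `ct_volume`: a list with elements `values`,
#'   `spacing`, `origin`, `subject_id`.
#' @examples
#' v <- ct_volume(array(0, c(4, 8, 8)), spacing = c(2, 1, 1))
#' dim(v$values)
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      subject_id = "unknown") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a rank-3 array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("invalid spacing")
  }
  if (any(dim(values) < 1L)) stop("degenerate volume")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         subject_id = as.character(subject_id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> subject=%s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$subject_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

# Fixed voxel shapes per modality, axis order (z, y, x).
MODALITY_SHAPES <- list(
  femur = c(112L, 128L, 128L),
  mandible = c(20L, 256L, 256L)
)

#' Fixed-shape normalized bone voxel
#'
#' A `bone_voxel` is the network-ready representation of one bone of one
#' subject: a fixed-shape array (femur `112 x 128 x 128`, mandible
#' `20 x 256 x 256`, axes `(z, y, x)`) with intensities window-normalized to
#' `[0, 1]`. Construction enforces the shape and range invariants.
#'
#' @param values numeric 3D array with the exact shape of `modality`.
#' @param modality `"femur"` or `"mandible"`.
#' @param subject_id character scalar.
#' @return An object of class `bone_voxel`.
#' @export
bone_voxel <- function(values, modality = c("femur", "mandible"),
                       subject_id = "unknown") {
  modality <- match.arg(modality)
  want <- MODALITY_SHAPES[[modality]]
  if (!is.array(values) || length(dim(values)) != 3L ||
      !all(dim(values) == want)) {
    stop(sprintf("bone_voxel: %s shape must be %s", modality,
                 paste(want, collapse = "x")))
  }
  if (anyNA(values) || any(!is.finite(values))) stop("bone_voxel: non-finite values")
  if (min(values) < 0 || max(values) > 1) stop("bone_voxel: values outside [0,1]")
  structure(
    list(values = values, modality = modality,
         subject_id = as.character(subject_id)),
    class = "bone_voxel"
  )
}

#' @export
print.bone_voxel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bone_voxel> %s subject=%s  %d x %d x %d  mean intensity %.4f\n",
              x$modality, x$subject_id, d[1], d[2], d[3], mean(x$values)))
  invisible(x)
}

#' Map Hounsfield units to the unit interval by a bone window
#'
#' Linear rescaling of the cortical-bone window: `lo` HU maps to 0, `hi` HU
#' maps to 1, values outside are clamped. With the default 400-1000 HU window
#' this sends 400 to 0, 700 to 0.5 and 1000 to 1.
#'
#' @param hu numeric vector or array of Hounsfield units.
#' @param lo,hi window edges in HU (default 400 and 1000).
#' @return Same shape as `hu`, values in `[0, 1]`.
#' @export
hu_window <- function(hu, lo = 400, hi = 1000) {
  if (hi <= lo) stop("invalid window")
  pmin(pmax((hu - lo) / (hi - lo), 0), 1)
}

# Centre-crop or symmetrically zero-pad a rank-3 array to `shape`.
# When the needed crop/pad is odd, the extra voxel goes to the trailing side.
fit_to_shape <- function(values, shape, fill = 0) {
  d <- dim(values)
  out <- array(fill, shape)
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (a in 1:3) {
    if (d[a] >= shape[a]) {
      off <- (d[a] - shape[a]) %/% 2
      src[[a]] <- seq.int(off + 1L, off + shape[a])
      dst[[a]] <- seq_len(shape[a])
    } else {
      off <- (shape[a] - d[a]) %/% 2
      src[[a]] <- seq_len(d[a])
      dst[[a]] <- seq.int(off + 1L, off + d[a])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- values[src[[1]], src[[2]], src[[3]]]
  out
}
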