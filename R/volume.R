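#' Image and label volume containers
#'
#' Minimal 3D volume containers shared by every stage of the pipeline. A
#' volume is a 3D array plus its physical geometry: isotropic-or-not voxel
#' spacing in mm, a physical origin, and an orthonormal axis-direction
#' matrix. Label volumes additionally carry a label table mapping integer
#' ids to names.
#'
#' @param voxels 3D numeric (image) or integer (label) array.
#' @param spacing_mm positive length-3 numeric, voxel size per axis in mm.
#' @param origin_mm length-3 numeric, physical position of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction matrix (default identity).
#' @return An object of class `image_volume` or `label_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(0.2, 0.2, 0.2),
                         origin_mm = c(0, 0, 0), orientation = diag(3)) {
  stopifnot(length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) stop("image_volume: all voxel values must be finite")
  if (!all(spacing_mm > 0)) stop("image_volume: spacing must be strictly positive")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("image_volume: orientation must be orthonormal")
  structure(list(voxels = voxels,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 orientation = orientation),
            class = "image_volume")
}

#' @param label_table named integer vector mapping label name -> id; must
#'   cover every nonzero value present in `voxels`.
#' @rdname image_volume
#' @export
label_volume <- function(voxels, label_table, spacing_mm = c(0.2, 0.2, 0.2),
                         origin_mm = c(0, 0, 0), orientation = diag(3)) {
  stopifnot(length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0L)) stop("label_volume: labels must be non-negative")
  present <- setdiff(unique(as.vector(voxels)), 0L)
  if (!all(present %in% label_table))
    stop("label_volume: voxel values not in label table: ",
         paste(setdiff(present, label_table), collapse = ", "))
  obj <- image_volume(array(0, dim(voxels)), spacing_mm, origin_mm, orientation)
  obj$voxels <- voxels
  obj$label_table <- label_table
  class(obj) <- c("label_volume", "image_volume")
  obj
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm\n", class(x)[1],
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  if (!is.null(x$label_table))
    cat("  labels:", paste(sprintf("%s=%d", names(x$label_table), x$label_table),
                           collapse = ", "), "\n")
  invisible(x)
}

vol_dim <- function(vol) dim(vol$voxels)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

stop_if_geometry_mismatch <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) stop(what, ": grid geometry mismatch")
  invisible(TRUE)
}

## continuous 0-based voxel coords -> physical mm
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(ijk)
  sweep(t(vol$orientation %*% t(sweep(ijk, 2, vol$spacing_mm, `*`))),
        2, vol$origin_mm, `+`)
}

world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  sweep(t(t(vol$orientation) %*% t(sweep(xyz, 2, vol$origin_mm, `-`))),
        2, vol$spacing_mm, `/`)
}

## Gaussian smoothing with sigma in mm (converted per-axis to voxels)
smooth_volume <- function(arr, spacing_mm, sigma_mm) {
  d <- dim(arr)
  out <- .gauss3_cpp(as.numeric(arr), as.integer(d), sigma_mm / spacing_mm)
  array(out, d)
}

binary_mask <- function(lab, ids) {
  array(lab$voxels %in% as.integer(ids), dim(lab$voxels))
}

#' Euclidean distance and feature transform
#'
#' Distance (mm) from every voxel to the nearest `TRUE` voxel of `sites`,
#' with the linear index of that nearest site. Thin wrapper over a
#' Felzenszwalb-Huttenlocher transform with anisotropic spacing.
#'
#' @param sites logical 3D array of site voxels.
#' @param spacing_mm per-axis voxel size.
#' @return list with `dist` (3D array, mm) and `feature` (3D integer array of
#'   1-based linear indices, 0 where no site exists).
#' @export
distance_transform <- function(sites, spacing_mm = c(1, 1, 1)) {
  d <- dim(sites)
  res <- .edt_cpp(as.logical(sites), as.integer(d), as.numeric(spacing_mm))
  list(dist = array(sqrt(res$dist2), d), feature = array(res$feature, d))
}

## boundary voxels under the half-open convention: labeled voxels with at
## least one unlabeled 6-neighbor (faces at the array border count)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb_all
}

## label inventories used throughout
#' @export
GUIDE_LABELS <- c(background = 0L, mtl_gray_medial = 1L, mtl_gray_lateral = 2L,
                  srlm = 3L, artifact = 4L)

#' @export
SUBREGION_LABELS <- c(SUB = 1L, CA1 = 2L, CA2 = 3L, CA3 = 4L, DG = 5L,
                      presubiculum = 6L, parasubiculum = 7L, HATA = 8L,
                      SRLM = 9L, ERC = 10L, BA35 = 11L, BA36 = 12L,
                      TE = 13L, TF_TH = 14L, unknown = 99L)
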