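#' Triangulated surface mesh
#'
#' @param vertices n x 3 physical coordinates (mm).
#' @param triangles m x 3 1-based vertex indices.
#' @param vertex_fields named list of per-vertex scalar vectors.
#' @param structure_tag `"MTL"` or `"SRLM"`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_fields = list(),
                         structure_tag = "MTL") {
  vertices <- as.matrix(vertices); triangles <- as.matrix(triangles)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  for (f in vertex_fields) stopifnot(length(f) == nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_fields = vertex_fields, structure_tag = structure_tag),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %s> %d vertices, %d triangles, fields: %s\n",
              x$structure_tag, nrow(x$vertices), nrow(x$triangles),
              paste(names(x$vertex_fields), collapse = ", ")))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], ] - v[tr[, 1], ]
  b <- v[tr[, 3], ] - v[tr[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area (mm^2)
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

## unique vertex-vertex edges of the triangulation
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE) |>
    igraph::add_vertices(max(0, nrow(mesh$vertices) - max(mesh$triangles)))
}

laplacian_smooth <- function(vertices, edges, iters = 2, lambda = 0.5) {
  n <- nrow(vertices)
  for (it in seq_len(iters)) {
    acc <- matrix(0, n, 3); cnt <- numeric(n)
    for (c in 1:2) {
      i <- edges[, c]; j <- edges[, 3 - c]
      for (ax in 1:3) acc[, ax] <- acc[, ax] + tabulate_sum(i, vertices[j, ax], n)
      cnt <- cnt + tabulate(i, n)
    }
    has <- cnt > 0
    mean_nb <- acc[has, ] / cnt[has]
    vertices[has, ] <- (1 - lambda) * vertices[has, ] + lambda * mean_nb
  }
  vertices
}

tabulate_sum <- function(idx, vals, n) {
  ## rowsum drops empty groups; pad every index with a zero contribution
  as.numeric(rowsum(c(vals, numeric(n)), c(idx, seq_len(n))))
}

## iso-surface of a binary mask: Gaussian-smoothed indicator, marching
## tetrahedra at 0.5, light Laplacian smoothing; coordinates in mm
mask_surface <- function(mask, geom, sigma_vox = 1, level = 0.5,
                         smooth_iters = 2, tag = "MTL") {
  if (!any(mask)) stop("mask_surface: empty mask")
  d <- dim(mask)
  sm <- array(.gauss3_cpp(as.numeric(mask), as.integer(d), rep(sigma_vox, 3)), d)
  mc <- .mtetra_cpp(as.numeric(sm), as.integer(d), level)
  if (nrow(mc$vertices) == 0) stop("mask_surface: empty iso-surface")
  v <- mc$vertices; tr <- mc$triangles
  mesh0 <- surface_mesh(v, tr, structure_tag = tag)
  v <- laplacian_smooth(v, mesh_edges(mesh0), iters = smooth_iters)
  ## drop degenerate triangles
  mesh <- surface_mesh(voxel_to_world(geom, v), tr, structure_tag = tag)
  keep <- triangle_areas(mesh) > 1e-10
  mesh$triangles <- mesh$triangles[keep, , drop = FALSE]
  mesh
}

#' Extract template surfaces for the MTL gray sheet and the SRLM
#'
#' Iso-surfaces of the template guide masks (the two collateral-sulcus
#' banks merged for the MTL), lightly smoothed. If the atlas carries a
#' consensus subregion segmentation, each vertex is tagged with its nearest
#' subregion label so clusters can be reported anatomically.
#'
#' @param atlas an `atlas`.
#' @return list(MTL = [surface_mesh()], SRLM = [surface_mesh()]).
#' @export
extract_template_surfaces <- function(atlas) {
  g <- atlas$template_guide_labels
  mtl_mask <- binary_mask(g, c(GUIDE_LABELS[["mtl_gray_medial"]],
                               GUIDE_LABELS[["mtl_gray_lateral"]],
                               GUIDE_LABELS[["artifact"]]))
  srlm_mask <- binary_mask(g, GUIDE_LABELS[["srlm"]])
  out <- list(MTL = mask_surface(mtl_mask, g, tag = "MTL"),
              SRLM = mask_surface(srlm_mask, g, tag = "SRLM"))
  if (!is.null(atlas$template_subregions)) {
    sub <- atlas$template_subregions
    for (nm in names(out)) {
      out[[nm]]$vertex_fields$subregion <-
        nearest_label_at(sub, world_to_voxel(sub, out[[nm]]$vertices))
    }
  }
  out
}

## nearest nonzero label id at continuous voxel coordinates
nearest_label_at <- function(lab, ijk) {
  d <- vol_dim(lab)
  ft <- distance_transform(lab$voxels != 0L, lab$spacing_mm)$feature
  ## sample the feature transform with nearest-voxel lookup
  i <- pmin(pmax(round(ijk[, 1]), 0), d[1] - 1)
  j <- pmin(pmax(round(ijk[, 2]), 0), d[2] - 1)
  k <- pmin(pmax(round(ijk[, 3]), 0), d[3] - 1)
  lin <- 1 + i + d[1] * (j + d[2] * k)
  feat <- ft[lin]
  out <- rep(0L, nrow(ijk))
  out[feat > 0] <- lab$voxels[feat[feat > 0]]
  out
}

#' Voronoi skeleton of a binary mask
#'
#' Medial elements are extracted as ridges of the Euclidean distance
#' transform: a tissue voxel is kept when the nearest-boundary (generator)
#' points of the voxel and of one of its 6-neighbors are separated by more
#' than `prune_ratio` times the local inscribed radius, and the voxel's
#' radius is not smaller than that neighbor's. Larger `prune_ratio` prunes
#' more aggressively (monotonically fewer elements).
#'
#' @param mask logical array or binary [label_volume()].
#' @param prune_ratio generator-separation to inscribed-radius cutoff
#'   (default 1.6).
#' @param spacing_mm voxel size (taken from the volume when given).
#' @return `skeleton`: `points` (world mm), `voxels` (linear indices),
#'   `radius_mm`, `adjacency` (edge matrix among skeleton elements).
#' @export
voronoi_skeleton <- function(mask, prune_ratio = 1.6, spacing_mm = NULL) {
  geom <- NULL
  if (inherits(mask, "image_volume")) {
    geom <- mask; spacing_mm <- mask$spacing_mm; mask <- mask$voxels != 0L
  }
  if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  if (!any(mask)) stop("voronoi_skeleton: empty mask")
  d <- dim(mask)
  ed <- distance_transform(!mask, spacing_mm)
  ## inscribed radius to the tissue surface. The voxel EDT reaches
  ## background voxel centers (half a voxel beyond a flat surface, less on
  ## staircased curved ones); a subvoxel-accurate distance is obtained from
  ## the 0.5 iso-surface of the smoothed indicator, with the EDT minus half
  ## a voxel as fallback for masks too small to carry an iso-surface.
  r <- pmax(ed$dist - 0.5 * mean(spacing_mm), 0.25 * mean(spacing_mm))
  iso <- tryCatch({
    sm <- array(.gauss3_cpp(as.numeric(mask), as.integer(d), c(1, 1, 1)), d)
    mc <- .mtetra_cpp(as.numeric(sm), as.integer(d), 0.5)
    if (nrow(mc$vertices) >= 4) {
      margin <- max(ed$dist[mask]) / mean(spacing_mm) + 2
      sp <- .splat_cpp(mc$vertices, rep(0, nrow(mc$vertices)), margin, as.integer(d))
      array(sp$dist, d) * mean(spacing_mm)
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(iso)) {
    ok <- is.finite(iso)
    r[ok] <- pmax(iso[ok], 0.25 * mean(spacing_mm))
  }
  ft <- ed$feature      # nearest background voxel (generator proxy)
  ## world coordinates of each voxel's generator
  gen_xyz <- function(lin) {
    lin0 <- lin - 1L
    i <- lin0 %% d[1]; j <- (lin0 %/% d[1]) %% d[2]; k <- lin0 %/% (d[1] * d[2])
    cbind(i * spacing_mm[1], j * spacing_mm[2], k * spacing_mm[3])
  }
  keep <- array(FALSE, d)
  strides <- c(1L, d[1], d[1] * d[2])
  lin_all <- which(mask)
  G <- matrix(NA_real_, prod(d), 3)
  G[lin_all, ] <- gen_xyz(ft[lin_all])
  for (ax in 1:3) {
    ## neighbor in +ax direction, both voxels inside the mask
    idx <- which(mask & ft > 0)
    pos <- ((idx - 1L) %/% strides[ax]) %% d[ax]
    ok <- pos < d[ax] - 1L
    idx <- idx[ok]
    nb <- idx + strides[ax]
    inmask <- mask[nb]
    idx <- idx[inmask]; nb <- nb[inmask]
    sep2 <- rowSums((G[idx, , drop = FALSE] - G[nb, , drop = FALSE])^2)
    ## subtended-angle test at each side of the pair: the two generators,
    ## seen from the element, must subtend at least the angle equivalent to
    ## a separation of prune_ratio times the spoke length (law of cosines);
    ## a ~2-voxel separation floor suppresses staircase generator pairs
    cos_max <- 1 - min(prune_ratio, 2)^2 / 2   # sep/spoke = 2 sin(theta/2)
    floor2 <- (1.9 * mean(spacing_mm))^2
    vox_xyz <- function(lin) {
      lin0 <- lin - 1L
      cbind((lin0 %% d[1]) * spacing_mm[1],
            ((lin0 %/% d[1]) %% d[2]) * spacing_mm[2],
            (lin0 %/% (d[1] * d[2])) * spacing_mm[3])
    }
    Xi <- vox_xyz(idx); Xn <- vox_xyz(nb)
    for (side in 1:2) {
      x <- if (side == 1) Xi else Xn
      self <- if (side == 1) idx else nb
      other <- if (side == 1) nb else idx
      a2 <- rowSums((G[self, , drop = FALSE] - x)^2)
      b2 <- rowSums((G[other, , drop = FALSE] - x)^2)
      cosang <- (a2 + b2 - sep2) / (2 * sqrt(pmax(a2 * b2, 1e-18)))
      ## a genuine medial element sees both generators at spoke lengths
      ## close to its inscribed radius; staircase fakes under tangent
      ## curved surfaces have one short and one long spoke
      bmax <- (r[self] + 1.5 * mean(spacing_mm))^2
      pass <- sep2 > floor2 & cosang < cos_max & b2 <= bmax &
        r[self] >= r[other] - 1e-9
      keep[self[pass]] <- TRUE
    }
  }
  vox <- which(keep)
  if (length(vox)) {
    ## maximality: drop elements whose inscribed ball is contained in a
    ## larger element's ball (the medial axis consists of maximal balls;
    ## containment survivors of the ridge test are voxelization artifacts)
    lin0 <- vox - 1L
    pv <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
    rv <- r[vox] / mean(spacing_mm)
    depth <- .ball_depth_cpp(pv, rv, as.integer(d))
    contained <- depth[vox] > rv + 0.35
    vox <- vox[!contained]
  }
  if (!length(vox)) {
    ## degenerate small mask: fall back to the maximal-radius voxel
    vox <- lin_all[which.max(r[lin_all])]
  }
  lin0 <- vox - 1L
  i <- lin0 %% d[1]; j <- (lin0 %/% d[1]) %% d[2]; k <- lin0 %/% (d[1] * d[2])
  pts <- cbind(i * spacing_mm[1], j * spacing_mm[2], k * spacing_mm[3])
  if (!is.null(geom)) pts <- voxel_to_world(geom, cbind(i, j, k))
  ## adjacency among skeleton voxels (6-connectivity)
  pos_in <- integer(prod(d)); pos_in[vox] <- seq_along(vox)
  edges <- NULL
  for (ax in 1:3) {
    pos <- ((vox - 1L) %/% strides[ax]) %% d[ax]
    ok <- pos < d[ax] - 1L & keep[pmin(vox + strides[ax], prod(d))]
    if (any(ok)) edges <- rbind(edges, cbind(pos_in[vox[ok]], pos_in[vox[ok] + strides[ax]]))
  }
  structure(list(points = pts, voxels = vox, radius_mm = r[vox],
                 adjacency = edges, dim = d, spacing_mm = spacing_mm),
            class = "skeleton")
}

#' Thickness at mask boundary points from a skeleton
#'
#' Each boundary voxel (a labeled voxel with an unlabeled 6-neighbor; the
#' half-open voxel-center convention) takes twice the radius of the largest
#' skeleton inscribed ball that reaches it; boundary voxels reached by no
#' ball fall back to the nearest skeleton element.
#'
#' @param mask binary array or [label_volume()] the skeleton was built from.
#' @param skeleton a [voronoi_skeleton()] result.
#' @return data.frame with `voxel` (linear index), `i, j, k` (0-based voxel
#'   coords) and `thickness_mm`.
#' @export
thickness_from_skeleton <- function(mask, skeleton) {
  if (inherits(mask, "image_volume")) mask <- mask$voxels != 0L
  d <- dim(mask)
  stopifnot(identical(d, skeleton$dim))
  sp <- skeleton$spacing_mm
  if (max(abs(sp - sp[1])) > 1e-9)
    stop("thickness_from_skeleton: anisotropic spacing not supported")
  bnd <- boundary_voxels(mask)
  bl <- which(bnd)
  lin0 <- skeleton$voxels - 1L
  pts <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
  ## each boundary voxel takes the nearest covering skeleton element whose
  ## radius is at least 0.35x the largest covering radius there: the floor
  ## discards small residual medial branches, while "nearest" keeps the
  ## estimate local so genuine thickness steps are not smoothed away
  rv <- skeleton$radius_mm / sp[1]
  cov <- .ball_assign_cpp(pts, rv, 0.55, 0.35, as.integer(d), 0.5)
  idx <- cov$pick[bl]
  th <- numeric(length(bl))
  th[idx > 0] <- 2 * skeleton$radius_mm[idx[idx > 0]]
  if (any(th <= 0)) {
    ## fall back to the nearest skeleton element
    skel <- array(FALSE, d); skel[skeleton$voxels] <- TRUE
    ed <- distance_transform(skel, sp)
    diam <- sqrt(sum((d * sp)^2))
    miss <- which(th <= 0)
    if (any(!is.finite(ed$dist[bl[miss]])) || any(ed$dist[bl[miss]] > diam))
      stop("thickness_from_skeleton: malformed skeleton (boundary point beyond mask diameter)")
    rad_at <- numeric(prod(d)); rad_at[skeleton$voxels] <- skeleton$radius_mm
    th[miss] <- 2 * rad_at[ed$feature[bl[miss]]]
  }
  bl0 <- bl - 1L
  data.frame(voxel = bl,
             i = bl0 %% d[1], j = (bl0 %/% d[1]) %% d[2],
             k = bl0 %/% (d[1] * d[2]),
             thickness_mm = th)
}

#' Per-vertex thickness map
#'
#' @param thickness_mm numeric vector aligned to template vertices.
#' @param valid logical mask (FALSE at artifact-excluded or unsampled
#'   vertices).
#' @param specimen_id,structure identifiers.
#' @export
thickness_map <- function(thickness_mm, valid, specimen_id, structure) {
  stopifnot(length(thickness_mm) == length(valid))
  if (any(valid & !(thickness_mm > 0)))
    stop("thickness_map: thickness must be positive where valid")
  structure(list(thickness_mm = thickness_mm, valid = valid,
                 specimen_id = specimen_id, structure = structure),
            class = "thickness_map")
}

#' Sample a specimen's native-space thickness at template vertices
#'
#' Template surface vertices are mapped to the specimen's native space
#' through the atlas transforms; thickness is computed in native space by
#' Voronoi skeletonization of the specimen's own mask, and each vertex
#' takes the thickness of the nearest native boundary point within the
#' capture radius. Vertices landing in the artifact-exclusion region, or
#' with no boundary within reach, are invalid.
#'
#' @param sp [specimen()].
#' @param atlas `atlas` containing `sp$id`.
#' @param template_surface [surface_mesh()] in template space.
#' @param capture_radius_vox capture radius (voxels, default 3).
#' @param prune_ratio skeleton pruning parameter.
#' @return [thickness_map()].
#' @export
sample_specimen_thickness <- function(sp, atlas, template_surface,
                                      capture_radius_vox = 3, prune_ratio = 1.6) {
  tr <- atlas_transform(atlas, sp$id)  # errors when missing
  tag <- template_surface$structure_tag
  gl <- sp$guide_labels
  mask_ids <- if (tag == "SRLM") GUIDE_LABELS[["srlm"]] else
    c(GUIDE_LABELS[["mtl_gray_medial"]], GUIDE_LABELS[["mtl_gray_lateral"]],
      GUIDE_LABELS[["artifact"]])
  mask <- binary_mask(gl, mask_ids)
  sk <- voronoi_skeleton(image_volume_like(gl, mask), prune_ratio = prune_ratio)
  th <- thickness_from_skeleton(mask, sk)
  d <- vol_dim(gl)
  ## distance/feature to boundary points in native space
  bmask <- array(FALSE, d); bmask[th$voxel] <- TRUE
  ed <- distance_transform(bmask, gl$spacing_mm)
  th_at <- numeric(prod(d)); th_at[th$voxel] <- th$thickness_mm
  ## vertices to native voxel coords
  native_mm <- map_points_to_specimen(atlas, sp$id, template_surface$vertices)
  ijk <- world_to_voxel(gl, native_mm)
  i <- pmin(pmax(round(ijk[, 1]), 0), d[1] - 1)
  j <- pmin(pmax(round(ijk[, 2]), 0), d[2] - 1)
  k <- pmin(pmax(round(ijk[, 3]), 0), d[3] - 1)
  lin <- 1 + i + d[1] * (j + d[2] * k)
  in_grid <- ijk[, 1] > -1 & ijk[, 1] < d[1] & ijk[, 2] > -1 & ijk[, 2] < d[2] &
    ijk[, 3] > -1 & ijk[, 3] < d[3]
  cap_mm <- capture_radius_vox * max(gl$spacing_mm)
  near <- ed$dist[lin] <= cap_mm & ed$feature[lin] > 0
  in_artifact <- gl$voxels[lin] == GUIDE_LABELS[["artifact"]]
  valid <- in_grid & near & !in_artifact
  thickness <- rep(NA_real_, nrow(ijk))
  thickness[valid] <- th_at[ed$feature[lin[valid]]]
  valid <- valid & !is.na(thickness) & thickness > 0
  out <- thickness_map(thickness, valid, sp$id, tag)
  attr(out, "valid_fraction") <- mean(valid)
  out
}

## an image_volume with the geometry of `like` and the given voxels
image_volume_like <- function(like, voxels) {
  image_volume(array(as.numeric(voxels), vol_dim(like)), like$spacing_mm,
               like$origin_mm, like$orientation)
}
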