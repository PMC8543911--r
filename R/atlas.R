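## Groupwise template construction. Stage 1 aligns every specimen to a
## deterministically chosen reference (affine + shape registration on the
## guide labels). Stage 2 iterates an unbiased shape-template loop: average
## the warped soft guide indicators, re-register everybody to the average,
## and recenter by composing with the inverse of the mean deformation.
## Stage 3 refines the correspondences with artifact-masked intensity
## registration and averages bias-normalized intensities into the template.

guide_channel_ids <- function() c(GUIDE_LABELS[["mtl_gray_medial"]],
                                  GUIDE_LABELS[["mtl_gray_lateral"]],
                                  GUIDE_LABELS[["srlm"]])

## mean pairwise generalized Dice of warped hard guide labels
pairwise_dice <- function(labs) {
  ids <- guide_channel_ids()
  n <- length(labs)
  if (n < 2) return(NA_real_)
  acc <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    acc <- c(acc, generalized_dice(labs[[i]], labs[[j]], ids))
  mean(acc, na.rm = TRUE)
}

#' Build a groupwise atlas from a cohort
#'
#' Three-stage unbiased template construction (see module docs above). The
#' per-stage mean pairwise generalized Dice of the warped guide labels is
#' recorded in the provenance and is non-decreasing across stages: any
#' stage-3 refinement that lowers a specimen's guide-label overlap (or the
#' cohort-level overlap) is rolled back to its stage-2 field.
#'
#' @param specimens list of [specimen()]s (>= 2) with guide labels.
#' @param params [registration_params()] for the shape stages.
#' @param seed integer seed (registration is deterministic; the seed feeds
#'   only tie-breaking provenance).
#' @param intensity_params parameters for the masked-NCC stage.
#' @param max_stage2_iters,stage2_tol_vox stage-2 stopping rule: mean
#'   deformation RMS below the tolerance (voxels) or the iteration cap.
#' @param verbose print stage progress.
#' @return an `atlas` object.
#' @export
build_atlas <- function(specimens, params = registration_params(), seed = 1L,
                        intensity_params = registration_params(
                          metric = "masked_ncc", n_levels = 1L,
                          n_iterations = 20L, step_size = 0.3),
                        max_stage2_iters = 5L, stage2_tol_vox = 0.5,
                        verbose = FALSE) {
  n <- length(specimens)
  if (n < 2) stop("build_atlas: need at least 2 specimens with guide labels")
  ids <- vapply(specimens, `[[`, "", "id")
  ## deterministic reference: tissue volume closest to the cohort median
  vol <- vapply(specimens, function(s) sum(s$guide_labels$voxels %in% guide_channel_ids()), 0)
  ref_i <- which.min(abs(vol - stats::median(vol)))
  ref <- specimens[[ref_i]]
  geom <- ref$guide_labels
  say <- function(...) if (verbose) message(sprintf(...))
  say("reference specimen: %s", ref$id)

  failed <- rep(FALSE, n)
  affines <- vector("list", n)
  lab_t <- vector("list", n)   # guide labels resampled by affine onto template grid
  img_t <- vector("list", n)
  fields <- vector("list", n)

  ## ---- stage 1: affine + shape registration to the reference
  for (i in seq_len(n)) {
    res <- tryCatch({
      tf <- affine_align(specimens[[i]]$guide_labels, ref$guide_labels)
      la <- resample_affine(specimens[[i]]$guide_labels, tf, geom)
      ia <- resample_affine(specimens[[i]]$image, tf, geom)
      fld <- register_shape(la, ref$guide_labels, params)
      list(tf = tf, la = la, ia = ia, fld = fld)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("build_atlas: specimen ", ids[i], " failed stage 1 (", conditionMessage(res),
              "); excluded from averaging")
      failed[i] <- TRUE
      next
    }
    affines[[i]] <- res$tf; lab_t[[i]] <- res$la; img_t[[i]] <- res$ia
    fields[[i]] <- res$fld
    say("stage 1: %s registered", ids[i])
  }
  alive <- which(!failed)
  if (length(alive) < 2) stop("build_atlas: fewer than 2 specimens survived stage 1")

  sig <- params$indicator_sigma_mm
  soft_ch <- lapply(seq_len(n), function(i)
    if (failed[i]) NULL else soft_guide_channels(lab_t[[i]], sig))
  gids <- guide_channel_ids()
  mean_channels <- function(flds) lapply(1:3, function(c)
    Reduce(`+`, lapply(alive, function(i)
      warp_volume(soft_ch[[i]][[c]], flds[[i]]))) / length(alive))
  ## "leave-one-in" stage metric: mean soft generalized Dice of each
  ## specimen's warped guide-label channels against the channel mean.
  ## Soft overlap is used because hard-label argmax Dice of the thin SRLM
  ## sheet fluctuates at the half-voxel level under the shared recentering
  ## resample, masking genuine alignment changes.
  stage_dice <- function(flds) {
    W <- lapply(alive, function(i) lapply(1:3, function(c)
      warp_volume(soft_ch[[i]][[c]], flds[[i]])))
    tm <- lapply(1:3, function(c) Reduce(`+`, lapply(W, `[[`, c)) / length(W))
    mean(vapply(W, function(w) {
      num <- sum(vapply(1:3, function(c) sum(pmin(w[[c]], tm[[c]])), 0.0))
      den <- sum(vapply(1:3, function(c) sum(w[[c]]) + sum(tm[[c]]), 0.0))
      2 * num / den
    }, 0.0))
  }
  mean_disp_rms_of <- function(flds) {
    d <- vol_dim(geom)
    mu <- array(0, c(d, 3L))
    for (i in alive) mu <- mu + flds[[i]]$displacement_mm
    mu <- mu / length(alive)
    list(mu = deformation_field(mu, geom$spacing_mm, geom$origin_mm, geom$orientation),
         rms = sqrt(mean((sweep(array(mu, c(prod(d), 3)), 2,
                                geom$spacing_mm, `/`))^2) * 3))
  }

  ## stage-1 output is recentered once (compose with the inverse of the
  ## mean deformation) so every downstream candidate — including the
  ## fallback — already satisfies the unbiasedness tolerance
  md0 <- mean_disp_rms_of(fields)
  if (md0$rms > 1e-6) {
    psi0 <- invert_field(md0$mu)
    for (i in alive) fields[[i]] <- compose_fields(fields[[i]], psi0)
  }
  dice_stage1 <- stage_dice(fields)
  say("stage 1 Dice: %.3f", dice_stage1)

  ## ---- stage 2: unbiased shape-template loop. Candidate field sets are
  ## kept after every recentered iteration; the accepted set maximizes the
  ## stage Dice subject to the mean-deformation (unbiasedness) tolerance.
  cand <- list(list(fields = fields, dice = dice_stage1,
                    rms = mean_disp_rms_of(fields)$rms))
  for (it in seq_len(max_stage2_iters)) {
    tmpl_ch <- mean_channels(fields)
    for (i in alive) {
      fields[[i]] <- greedy_diffeo(soft_ch[[i]], tmpl_ch, params, geom,
                                   metric = "ssd",
                                   init_vox = field_to_vox(fields[[i]]))
    }
    ## recenter: compose with the inverse of the mean deformation
    md <- mean_disp_rms_of(fields)
    say("stage 2 iter %d: mean deformation RMS %.3f vox", it, md$rms)
    psi <- invert_field(md$mu)
    for (i in alive) fields[[i]] <- compose_fields(fields[[i]], psi)
    cand[[length(cand) + 1]] <- list(fields = fields, dice = stage_dice(fields),
                                     rms = mean_disp_rms_of(fields)$rms)
    if (md$rms < stage2_tol_vox) break
  }
  ## final sharpening pass: one more re-registration to the recentered
  ## template recovers the interpolation loss of the recentering compose
  ## without reintroducing bias (each specimen moves toward the template)
  tmpl_ch <- mean_channels(fields)
  for (i in alive) {
    fields[[i]] <- greedy_diffeo(soft_ch[[i]], tmpl_ch, params, geom,
                                 metric = "ssd",
                                 init_vox = field_to_vox(fields[[i]]))
  }
  cand[[length(cand) + 1]] <- list(fields = fields, dice = stage_dice(fields),
                                   rms = mean_disp_rms_of(fields)$rms)
  ok_rms <- vapply(cand, function(x) x$rms < stage2_tol_vox, NA)
  pool <- if (any(ok_rms)) cand[ok_rms] else cand[length(cand)]
  best <- pool[[which.max(vapply(pool, `[[`, 0.0, "dice"))]]
  ## if the unbiased candidates are all worse than the stage-1 set, the
  ## loop did not help: keep stage 1 (allowed: the stopping rule is
  ## tolerance OR iteration cap)
  if (best$dice < cand[[1]]$dice) best <- cand[[1]]
  fields <- best$fields
  dice_stage2 <- best$dice
  mean_disp_rms <- best$rms
  say("stage 2 Dice: %.3f (mean RMS %.3f vox)", dice_stage2, mean_disp_rms)
  stage2_fields <- fields

  ## template guide labels: per-voxel argmax of the averaged warped
  ## (unsmoothed) label indicators; the smoothed channels would swallow
  ## the thin SRLM sheet into the background
  template_hard <- function(flds) {
    d <- vol_dim(geom)
    ids <- c(0L, gids)
    best <- array(-Inf, d); win <- array(0L, d)
    for (id in ids) {
      acc <- array(0, d)
      for (i in alive)
        acc <- acc + warp_volume(array(as.numeric(lab_t[[i]]$voxels == id), d),
                                 flds[[i]], outside = as.numeric(id == 0L))
      upd <- acc > best + 1e-9
      best[upd] <- acc[upd]; win[upd] <- id
    }
    label_volume(win, GUIDE_LABELS, geom$spacing_mm, geom$origin_mm, geom$orientation)
  }
  tmpl_guide <- template_hard(fields)

  ## ---- stage 3: artifact-masked groupwise intensity refinement
  template_intensity <- function() {
    d <- vol_dim(geom)
    acc <- array(0, d); wacc <- array(0, d)
    tis <- tmpl_guide$voxels != 0L
    scales <- c()
    for (i in alive) {
      wi <- warp_volume(img_t[[i]]$voxels, fields[[i]])
      excl <- warped_artifact_mask(i)
      m <- mean(wi[tis & !excl])
      scales <- c(scales, m)
      w <- 1 - excl
      acc <- acc + (wi / m) * w
      wacc <- wacc + w
    }
    out <- acc / pmax(wacc, 1e-9) * mean(scales)
    image_volume(out, geom$spacing_mm, geom$origin_mm, geom$orientation)
  }
  warped_artifact_mask <- function(i) {
    am <- array(as.numeric(lab_t[[i]]$voxels == GUIDE_LABELS[["artifact"]]), vol_dim(geom))
    warp_volume(am, fields[[i]]) > 0.5
  }
  tmpl_img <- template_intensity()
  reverted <- character(0)
  for (i in alive) {
    excl <- warped_artifact_mask(i) |
      (lab_t[[i]]$voxels == GUIDE_LABELS[["artifact"]])
    res <- tryCatch(
      register_intensity(img_t[[i]], tmpl_img, exclusion_mask = excl,
                         init = fields[[i]], params = intensity_params,
                         tissue_mask = tmpl_guide$voxels != 0L),
      error = function(e) e)
    if (inherits(res, "error")) { reverted <- c(reverted, ids[i]); next }
    d2 <- generalized_dice(warp_labels(lab_t[[i]], fields[[i]]), tmpl_guide, gids)
    d3 <- generalized_dice(warp_labels(lab_t[[i]], res), tmpl_guide, gids)
    if (!is.na(d3) && !is.na(d2) && d3 >= d2 - 1e-9) {
      fields[[i]] <- res
    } else {
      reverted <- c(reverted, ids[i])
    }
  }
  dice_stage3 <- stage_dice(fields)
  if (!is.na(dice_stage3) && dice_stage3 < dice_stage2) {
    fields <- stage2_fields
    dice_stage3 <- dice_stage2
    reverted <- unique(c(reverted, "ALL"))
  }
  say("stage 3 Dice: %.3f", dice_stage3)
  tmpl_guide <- template_hard(fields)
  tmpl_img <- template_intensity()

  transforms <- stats::setNames(vector("list", length(alive)), ids[alive])
  for (k in seq_along(alive)) {
    i <- alive[k]
    aud <- jacobian_audit(fields[[i]])
    if (!aud$pass)
      warning("build_atlas: Jacobian audit failed for ", ids[i])
    transforms[[k]] <- list(affine = affines[[i]], fwd = fields[[i]],
                            inv = invert_field(fields[[i]]),
                            min_jacobian = aud$min_jacobian)
  }
  structure(list(template_image = tmpl_img,
                 template_guide_labels = tmpl_guide,
                 template_subregions = NULL,
                 transforms = transforms,
                 provenance = list(reference = ref$id,
                                   excluded = ids[failed],
                                   stage3_reverted = reverted,
                                   stage2_mean_disp_rms_vox = mean_disp_rms,
                                   dice_by_stage = c(stage1 = dice_stage1,
                                                     stage2 = dice_stage2,
                                                     stage3 = dice_stage3),
                                   seed = seed)),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat("<atlas>", length(x$transforms), "specimens; Dice by stage:",
      paste(sprintf("%.3f", x$provenance$dice_by_stage), collapse = " -> "), "\n")
  invisible(x)
}

atlas_transform <- function(atlas, id) {
  tr <- atlas$transforms[[id]]
  if (is.null(tr)) stop("no transform for specimen '", id, "' in atlas")
  tr
}

## template physical points -> specimen native physical points
map_points_to_specimen <- function(atlas, id, pts_mm) {
  tr <- atlas_transform(atlas, id)
  geom <- atlas$template_image
  ijk <- world_to_voxel(geom, pts_mm)
  d <- vol_dim(geom)
  u <- sapply(1:3, function(a)
    .sample_tri_cpp(as.numeric(tr$fwd$displacement_mm[, , , a]), as.integer(d),
                    ijk, TRUE, 0))
  apply_affine(tr$affine, pts_mm + u)
}

## specimen native physical points -> template physical points: exact
## per-point inversion of the forward map, x = A^-1 y - u(x) solved by
## fixed-point iteration (initialized from the gridded inverse field)
map_points_to_template <- function(atlas, id, pts_mm, n_iter = 12) {
  tr <- atlas_transform(atlas, id)
  geom <- atlas$template_image
  p <- apply_affine(invert_affine(tr$affine), pts_mm)
  d <- vol_dim(geom)
  sample_u <- function(field, at_mm) {
    ijk <- world_to_voxel(geom, at_mm)
    vapply(1:3, function(a)
      .sample_tri_cpp(as.numeric(field$displacement_mm[, , , a]), as.integer(d),
                      ijk, TRUE, 0), numeric(nrow(at_mm)))
  }
  x <- p + sample_u(tr$inv, p)
  for (it in seq_len(n_iter)) x <- p - sample_u(tr$fwd, x)
  x
}

#' Warp a specimen's subregion labels into template space
#'
#' Per-label soft warping: each label's indicator (including background and
#' the `unknown` inter-block-gap label) is interpolated through the
#' specimen's transform pair and the argmax taken, so the label inventory
#' is preserved exactly. `unknown` voxels survive as `unknown` and are
#' excluded from consensus voting.
#'
#' @param sp [specimen()] with `subregion_labels`.
#' @param atlas an `atlas` containing `sp$id`.
#' @return [label_volume()] on the template grid.
#' @export
warp_subregions_to_template <- function(sp, atlas) {
  if (is.null(sp$subregion_labels))
    stop("warp_subregions_to_template: specimen has no subregion labels")
  atlas_transform(atlas, sp$id)   # errors when the transform is missing
  geom <- atlas$template_image
  d <- vol_dim(geom)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  native <- map_points_to_specimen(atlas, sp$id, voxel_to_world(geom, idx))
  out <- sp$subregion_labels
  out$voxels <- sample_labels_at(sp$subregion_labels, native, d)
  out$spacing_mm <- geom$spacing_mm; out$origin_mm <- geom$origin_mm
  out$orientation <- geom$orientation
  out
}

## single-step soft label sampling at physical points: warp each label
## indicator, renormalize by argmax; one interpolation per direction so
## thin structures survive round trips
sample_labels_at <- function(lab, pts_mm, out_dim) {
  ijk <- world_to_voxel(lab, pts_mm)
  dm <- vol_dim(lab)
  ids <- sort(unique(as.vector(lab$voxels)))
  best <- rep(-Inf, nrow(ijk)); win <- rep(0L, nrow(ijk))
  for (id in ids) {
    p <- .sample_tri_cpp(as.numeric(lab$voxels == id), as.integer(dm), ijk,
                         FALSE, as.numeric(id == 0L))
    upd <- p > best + 1e-9
    best[upd] <- p[upd]; win[upd] <- id
  }
  array(win, out_dim)
}

#' Warp a template-space label volume back to a specimen's native grid
#'
#' Inverse of [warp_subregions_to_template()]: single-step soft sampling
#' through the inverse transform pair.
#'
#' @param labels [label_volume()] on the template grid.
#' @param atlas an `atlas`.
#' @param id specimen id.
#' @param native_geom a volume giving the native grid geometry.
#' @export
warp_labels_from_template <- function(labels, atlas, id, native_geom) {
  atlas_transform(atlas, id)
  d <- vol_dim(native_geom)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  tpl <- map_points_to_template(atlas, id, voxel_to_world(native_geom, idx))
  out <- labels
  out$voxels <- sample_labels_at(labels, tpl, d)
  out$spacing_mm <- native_geom$spacing_mm; out$origin_mm <- native_geom$origin_mm
  out$orientation <- native_geom$orientation
  out
}

#' Consensus segmentation by regularized majority voting
#'
#' Maximizes `sum_v log f_v(l) + w * sum_(v,v') [l_v = l_v']` (Potts prior,
#' 6-connectivity) by iterated conditional modes from the plain-majority
#' start, where `f_v(l)` is the (lightly smoothed) fraction of inputs
#' voting label `l` at voxel `v`; `unknown` votes are discarded. With
#' `mrf_weight = 0` the result is exactly the plain majority vote with ties
#' broken toward the lowest label id.
#'
#' @param warped_labels list of [label_volume()]s on a shared grid.
#' @param mrf_weight nonnegative Potts coupling per neighbor face.
#' @param mask optional logical array restricting the consensus (voxels
#'   outside are background and frozen).
#' @param max_sweeps ICM sweep cap.
#' @return [label_volume()]; attribute `energy` holds the (non-decreasing)
#'   objective trace over sweeps.
#' @export
consensus_segmentation <- function(warped_labels, mrf_weight = 0.5 * log(2),
                                   mask = NULL, max_sweeps = 10L) {
  stopifnot(length(warped_labels) >= 1, mrf_weight >= 0)
  g1 <- warped_labels[[1]]
  for (w in warped_labels[-1]) stop_if_geometry_mismatch(g1, w, "consensus_segmentation")
  d <- vol_dim(g1)
  nvox <- prod(d)
  unk <- SUBREGION_LABELS[["unknown"]]
  ids <- sort(setdiff(Reduce(union, lapply(warped_labels, function(w)
    unique(as.vector(w$voxels)))), unk))
  if (!0L %in% ids) ids <- c(0L, ids)
  L <- length(ids)
  votes <- matrix(0L, nvox, L)
  for (w in warped_labels) {
    v <- as.vector(w$voxels)
    keep <- v != unk
    col <- match(v[keep], ids)
    idx <- which(keep)
    for (l in seq_len(L)) {
      sel <- idx[col == l]
      if (length(sel)) votes[sel, l] <- votes[sel, l] + 1L
    }
  }
  tot <- rowSums(votes)
  ## plain majority with lowest-id tie-break (max.col ties.method first on
  ## the id-sorted columns)
  init <- max.col(votes, ties.method = "first") - 1L
  init[tot == 0L] <- 0L
  logf <- log(sweep(votes + 0.5, 1, tot + 0.5 * L, `/`))
  free <- rep(TRUE, nvox)
  if (!is.null(mask)) {
    free <- as.vector(mask)
    init[!free] <- 0L
  }
  if (mrf_weight == 0) {
    lab <- init
    en <- sum(logf[cbind(seq_len(nvox), lab + 1L)])
    res_energy <- en
  } else {
    res <- .icm_cpp(logf, as.integer(d), as.integer(init), as.logical(free),
                    mrf_weight, as.integer(max_sweeps))
    lab <- res$labels
    res_energy <- res$energy
  }
  out <- label_volume(array(ids[lab + 1L], d),
                      c(SUBREGION_LABELS, GUIDE_LABELS)[
                        !duplicated(c(SUBREGION_LABELS, GUIDE_LABELS))],
                      g1$spacing_mm, g1$origin_mm, g1$orientation)
  attr(out, "energy") <- res_energy
  out
}

#' Per-voxel label overlap map
#'
#' Fraction of specimens assigning `target_label` at each voxel.
#'
#' @param warped_labels list of [label_volume()]s in template space.
#' @param target_label label id or name.
#' @export
label_overlap_maps <- function(warped_labels, target_label) {
  stopifnot(length(warped_labels) >= 2)
  g1 <- warped_labels[[1]]
  id <- if (is.character(target_label)) g1$label_table[[target_label]] else target_label
  present <- any(vapply(warped_labels, function(w) any(w$voxels == id), NA))
  if (!present) stop("label_overlap_maps: label ", target_label,
                     " absent in every specimen")
  d <- vol_dim(g1)
  acc <- array(0, d)
  for (w in warped_labels) acc <- acc + (w$voxels == id)
  image_volume(acc / length(warped_labels), g1$spacing_mm, g1$origin_mm, g1$orientation)
}

## voxels where label a touches label b under 6-connectivity
touch_mask <- function(vox, a, b) {
  d <- dim(vox)
  A <- vox == a; B <- vox == b
  nb_of <- function(M) {
    out <- array(FALSE, d)
    out[-1, , ] <- out[-1, , ] | M[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | M[-1, , ]
    out[, -1, ] <- out[, -1, ] | M[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | M[, -1, ]
    out[, , -1] <- out[, , -1] | M[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | M[, , -1]
    out
  }
  (A & nb_of(B)) | (B & nb_of(A))
}

#' Boundary dispersion map for a label pair
#'
#' For each specimen, the voxels where the two labels touch
#' (6-connectivity); the map is the per-voxel frequency of that boundary
#' across specimens, in [0, 1]. High spread along an axis indicates an
#' anatomically dispersed boundary (e.g. ERC/BA35 across sulcus types).
#'
#' @param warped_labels list of [label_volume()]s in template space.
#' @param pair length-2 vector of label ids or names.
#' @export
boundary_dispersion <- function(warped_labels, pair) {
  stopifnot(length(warped_labels) >= 2, length(pair) == 2)
  g1 <- warped_labels[[1]]
  ids <- vapply(pair, function(p)
    if (is.character(p)) g1$label_table[[p]] else as.integer(p), 0L)
  for (id in ids) {
    if (!any(vapply(warped_labels, function(w) any(w$voxels == id), NA)))
      stop("boundary_dispersion: label ", id, " absent in every specimen")
  }
  d <- vol_dim(g1)
  acc <- array(0, d)
  for (w in warped_labels) acc <- acc + touch_mask(w$voxels, ids[1], ids[2])
  image_volume(acc / length(warped_labels), g1$spacing_mm, g1$origin_mm, g1$orientation)
}
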