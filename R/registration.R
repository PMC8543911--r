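#' Affine transform in physical coordinates
#'
#' The transform follows the resampling convention: it maps fixed-image
#' physical coordinates to moving-image physical coordinates,
#' `y = M x + t`, so warping evaluates `moving(M x + t)` on the fixed grid.
#'
#' @param matrix 3x3 linear part (must be invertible).
#' @param translation_mm length-3 translation.
#' @export
affine_transform <- function(matrix = diag(3), translation_mm = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(3, 3)))
  if (abs(det(matrix)) <= 1e-8) stop("affine_transform: singular linear part")
  structure(list(matrix = matrix, translation_mm = as.numeric(translation_mm)),
            class = "affine_transform")
}

apply_affine <- function(tf, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(tf$matrix), 2, tf$translation_mm, `+`)
}

invert_affine <- function(tf) {
  mi <- solve(tf$matrix)
  affine_transform(mi, -as.numeric(mi %*% tf$translation_mm))
}

#' Dense diffeomorphic deformation field
#'
#' Displacement in mm stored on the fixed grid (4D array `[nx, ny, nz, 3]`).
#' The mapping is `phi(x) = x + u(x)` in physical coordinates; warping an
#' image evaluates `moving(phi(x))` at each fixed-grid voxel.
#'
#' @param displacement_mm 4D array, last dimension the 3 components.
#' @param spacing_mm,origin_mm,orientation grid geometry.
#' @export
deformation_field <- function(displacement_mm, spacing_mm = c(0.2, 0.2, 0.2),
                              origin_mm = c(0, 0, 0), orientation = diag(3)) {
  stopifnot(length(dim(displacement_mm)) == 4L, dim(displacement_mm)[4] == 3L)
  structure(list(displacement_mm = displacement_mm,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 orientation = orientation),
            class = "deformation_field")
}

identity_field <- function(geom) {
  d <- vol_dim(geom)
  deformation_field(array(0, c(d, 3L)), geom$spacing_mm, geom$origin_mm, geom$orientation)
}

field_dim <- function(field) dim(field$displacement_mm)[1:3]

## displacement as list of 3 arrays in voxel units
field_to_vox <- function(field) {
  lapply(1:3, function(a) field$displacement_mm[, , , a] / field$spacing_mm[a])
}

vox_to_field <- function(u, geom) {
  d <- dim(u[[1]])
  disp <- array(0, c(d, 3L))
  for (a in 1:3) disp[, , , a] <- u[[a]] * geom$spacing_mm[a]
  deformation_field(disp, geom$spacing_mm, geom$origin_mm, geom$orientation)
}

field_geometry_mismatch <- function(a, b) {
  !identical(field_dim(a), field_dim(b)) ||
    max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6
}

#' Warp a volume through a deformation field
#'
#' @param vol [image_volume()] (or a bare 3D array on the field grid).
#' @param field `deformation_field` on the output (fixed) grid.
#' @param outside value for samples falling outside the moving grid.
#' @return warped array / volume matching the input type.
#' @export
warp_volume <- function(vol, field, outside = 0) {
  arr <- if (inherits(vol, "image_volume")) vol$voxels else vol
  u <- field_to_vox(field)
  d <- dim(arr)
  out <- array(.warp_cpp(as.numeric(arr), as.integer(d),
                         as.numeric(u[[1]]), as.numeric(u[[2]]), as.numeric(u[[3]]),
                         FALSE, outside), d)
  if (inherits(vol, "image_volume") && !inherits(vol, "label_volume")) {
    res <- vol; res$voxels <- out; res
  } else out
}

## per-label soft warping: warp each indicator (plus background), argmax;
## ties broken toward the lowest label id
warp_labels <- function(lab, field) {
  ids <- sort(unique(as.vector(lab$voxels)))
  d <- vol_dim(lab)
  best <- array(-Inf, d); win <- array(0L, d)
  for (id in ids) {
    p <- warp_volume(array(as.numeric(lab$voxels == id), d), field,
                     outside = as.numeric(id == 0L))
    upd <- p > best + 1e-9
    best[upd] <- p[upd]; win[upd] <- id
  }
  out <- lab; out$voxels <- win
  out
}

#' Compose / invert deformation fields
#'
#' `compose_fields(a, b)` returns the field of `phi_a o phi_b`; warping an
#' image by the result equals warping by `a` and then warping that result
#' by `b`. `invert_field` inverts by fixed-point iteration and records the
#' achieved round-trip error in attribute `roundtrip_rms_vox`.
#'
#' @param a,b `deformation_field`s on the same grid.
#' @export
compose_fields <- function(a, b) {
  if (field_geometry_mismatch(a, b)) stop("compose_fields: geometry mismatch")
  ua <- field_to_vox(a); ub <- field_to_vox(b)
  d <- field_dim(a)
  cc <- .compose_disp_cpp(lapply(ua, as.numeric), lapply(ub, as.numeric), as.integer(d))
  vox_to_field(lapply(cc, array, dim = d), a)
}

#' @param n_iter fixed-point iterations.
#' @rdname compose_fields
#' @export
invert_field <- function(a, n_iter = 25) {
  u <- field_to_vox(a)
  d <- field_dim(a)
  v <- lapply(u, function(x) -x)
  for (it in seq_len(n_iter)) {
    for (ax in 1:3) {
      s <- .warp_cpp(as.numeric(u[[ax]]), as.integer(d),
                     as.numeric(v[[1]]), as.numeric(v[[2]]), as.numeric(v[[3]]),
                     TRUE, 0)
      if (ax == 1) sx <- s else if (ax == 2) sy <- s else sz <- s
    }
    v <- list(array(-sx, d), array(-sy, d), array(-sz, d))
  }
  inv <- vox_to_field(v, a)
  rt <- compose_fields(a, inv)   # should be ~identity
  rms <- sqrt(mean(sapply(field_to_vox(rt), function(x) mean(x^2))) * 3)
  attr(inv, "roundtrip_rms_vox") <- rms
  inv
}

#' Jacobian-positivity audit
#'
#' Minimum Jacobian determinant of `x + u(x)` over interior voxels
#' (optionally restricted to a mask). A diffeomorphic field must stay > 0.
#'
#' @param field `deformation_field`.
#' @param mask optional logical array.
#' @return list with `min_jacobian` and `pass`.
#' @export
jacobian_audit <- function(field, mask = NULL) {
  u <- field_to_vox(field)
  d <- field_dim(field)
  jd <- array(.jacdet_cpp(as.numeric(u[[1]]), as.numeric(u[[2]]), as.numeric(u[[3]]),
                          as.integer(d)), d)
  interior <- array(FALSE, d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  if (!is.null(mask)) interior <- interior & mask
  mj <- if (any(interior)) min(jd[interior]) else min(jd)
  list(min_jacobian = mj, pass = mj > 0)
}

#' Registration parameters
#'
#' @param metric `"multilabel_ssd"` (shape stages) or `"masked_ncc"`.
#' @param smoothing_sigmas_mm fluid smoothing of the update field per level
#'   (coarse to fine), mm.
#' @param n_levels pyramid depth.
#' @param step_size maximum update magnitude in voxels per iteration.
#' @param n_iterations iterations per level (recycled to `n_levels`).
#' @param regularization_sigma_mm elastic smoothing of the total field, mm.
#' @param indicator_sigma_mm Gaussian sigma for soft label indicators, mm.
#' @export
registration_params <- function(metric = c("multilabel_ssd", "masked_ncc"),
                                smoothing_sigmas_mm = c(0.8, 0.6, 0.4),
                                n_levels = 3L,
                                step_size = 0.4,
                                n_iterations = c(60L, 40L, 25L),
                                regularization_sigma_mm = 0.3,
                                indicator_sigma_mm = 0.4) {
  metric <- match.arg(metric)
  stopifnot(n_levels >= 1, step_size > 0, all(smoothing_sigmas_mm > 0),
            regularization_sigma_mm >= 0, all(n_iterations >= 1))
  structure(list(metric = metric,
                 smoothing_sigmas_mm = rep_len(smoothing_sigmas_mm, n_levels),
                 n_levels = as.integer(n_levels),
                 step_size = step_size,
                 n_iterations = rep_len(as.integer(n_iterations), n_levels),
                 regularization_sigma_mm = regularization_sigma_mm,
                 indicator_sigma_mm = indicator_sigma_mm),
            class = "registration_params")
}

## ---------------------------------------------------------------------------
## affine

label_moments <- function(lab, ids) {
  d <- vol_dim(lab)
  w <- array(as.numeric(lab$voxels %in% ids), d)
  tot <- sum(w)
  if (tot == 0) stop("affine_align: empty label volume")
  idx <- which(w > 0, arr.ind = TRUE) - 1
  xyz <- voxel_to_world(lab, idx)
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  cov <- crossprod(cen) / nrow(cen)
  list(center = ctr, cov = cov, n = tot)
}

affine_cost <- function(tf, mov_ch, fix_ch, geom_fix, geom_mov) {
  d <- dim(fix_ch[[1]])
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  xyz <- voxel_to_world(geom_fix, idx)
  yzw <- apply_affine(tf, xyz)
  ijk <- world_to_voxel(geom_mov, yzw)
  tot <- 0
  dm <- dim(mov_ch[[1]])
  for (c in seq_along(fix_ch)) {
    ## clamp at the grid edge: zero-filling makes the objective
    ## discontinuous right at the identity for grid-filling structures
    mv <- .sample_tri_cpp(as.numeric(mov_ch[[c]]), as.integer(dm), ijk, TRUE, 0)
    tot <- tot + sum((as.numeric(fix_ch[[c]]) - mv)^2)
  }
  tot
}

#' Affine alignment of two label volumes
#'
#' Moment-based initialization (center of mass + principal axes) followed by
#' derivative-free minimization of the sum of squared differences between
#' Gaussian-smoothed per-label indicator maps. The achieved objective never
#' exceeds the objective at initialization.
#'
#' @param moving,fixed [label_volume()]s sharing a label inventory.
#' @param sigma_mm indicator smoothing.
#' @param max_eval optimizer budget.
#' @return [affine_transform()] mapping fixed physical coords to moving.
#' @export
affine_align <- function(moving, fixed, sigma_mm = 0.4, max_eval = 300) {
  ids <- sort(setdiff(intersect(unique(as.vector(moving$voxels)),
                                unique(as.vector(fixed$voxels))), 0L))
  ids <- setdiff(ids, GUIDE_LABELS[["artifact"]])
  if (sum(moving$voxels != 0L) == 0 || sum(fixed$voxels != 0L) == 0)
    stop("affine_align: empty label volume")
  if (!length(ids)) stop("affine_align: no shared labels")
  mm <- label_moments(moving, ids)
  fm <- label_moments(fixed, ids)
  ef <- eigen(fm$cov, symmetric = TRUE)
  em <- eigen(mm$cov, symmetric = TRUE)
  ## degenerate (near-spherical) second moments: translation-only fallback
  degen <- ef$values[1] / max(ef$values[3], 1e-12) < 1.10 ||
    em$values[1] / max(em$values[3], 1e-12) < 1.10
  if (degen) {
    warning("affine_align: degenerate principal axes; translation-only fallback")
    R0 <- diag(3)
  } else {
    ## align principal axes, fixing eigenvector signs for a proper rotation
    Vf <- ef$vectors; Vm <- em$vectors
    for (c in 1:3) if (sum(Vf[, c] * Vm[, c]) < 0) Vm[, c] <- -Vm[, c]
    R0 <- Vm %*% t(Vf)
    if (det(R0) < 0) { Vm[, 3] <- -Vm[, 3]; R0 <- Vm %*% t(Vf) }
  }
  ## downsampled soft indicator channels for the objective
  shrink <- function(arr, geom) {
    d <- dim(arr); nd <- pmax(8L, as.integer(round(d / 2)))
    a <- array(.resize_cpp(as.numeric(arr), as.integer(d), nd), nd)
    ## re-smooth at the coarse scale: trilinear sampling of undersmoothed
    ## channels biases the optimum by a fraction of a voxel
    a <- array(.gauss3_cpp(as.numeric(a), as.integer(nd), c(1, 1, 1)), nd)
    list(arr = a,
         geom = image_volume(array(0, nd),
                             spacing_mm = geom$spacing_mm * (d - 1) / pmax(nd - 1, 1),
                             origin_mm = geom$origin_mm, orientation = geom$orientation))
  }
  mk_ch <- function(lab) lapply(ids, function(id)
    smooth_volume(array(as.numeric(lab$voxels == id), vol_dim(lab)),
                  lab$spacing_mm, rep(sigma_mm, 3)))
  mov_ch0 <- mk_ch(moving); fix_ch0 <- mk_ch(fixed)
  ms <- lapply(mov_ch0, shrink, geom = moving)
  fs <- lapply(fix_ch0, shrink, geom = fixed)
  mov_ch <- lapply(ms, `[[`, "arr"); fix_ch <- lapply(fs, `[[`, "arr")
  gm <- ms[[1]]$geom; gf <- fs[[1]]$geom

  ## parameterization: translation + rotation vector + log-scales, all about
  ## the fixed centroid; transform maps fixed -> moving coords
  build_tf <- function(p, R_base) {
    rot <- p[4:6]; th <- sqrt(sum(rot^2))
    Rr <- if (th < 1e-12) diag(3) else {
      k <- rot / th; K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    S <- diag(exp(p[7:9]))
    M <- R_base %*% Rr %*% S
    t0 <- mm$center - as.numeric(M %*% fm$center) + p[1:3]
    affine_transform(M, t0)
  }
  cost <- function(p) affine_cost(build_tf(p, R0), mov_ch, fix_ch, gf, gm)
  ## full-resolution cost for the final polish (the half-resolution
  ## surrogate carries a small interpolation bias): stride-2 subsample of
  ## the full-resolution channels, sample grid precomputed once
  df <- vol_dim(fixed)
  sub <- as.matrix(expand.grid(seq(0, df[1] - 1, by = 2),
                               seq(0, df[2] - 1, by = 2),
                               seq(0, df[3] - 1, by = 2)))
  xyz_full <- voxel_to_world(fixed, sub)
  lin_sub <- 1 + sub[, 1] + df[1] * (sub[, 2] + df[2] * sub[, 3])
  fix_vals <- lapply(fix_ch0, function(ch) as.numeric(ch)[lin_sub])
  dm_full <- vol_dim(moving)
  cost_full <- function(p) {
    tf <- build_tf(p, R0)
    ijk <- world_to_voxel(moving, apply_affine(tf, xyz_full))
    tot <- 0
    for (c in seq_along(fix_vals)) {
      mv <- .sample_tri_cpp(as.numeric(mov_ch0[[c]]), as.integer(dm_full), ijk,
                            TRUE, 0)
      tot <- tot + sum((fix_vals[[c]] - mv)^2)
    }
    tot
  }
  p0 <- rep(0, 9)
  c0 <- cost(p0)
  fit <- stats::optim(p0, cost, method = "Nelder-Mead",
                      control = list(maxit = max_eval, reltol = 1e-7))
  if (degen) {
    cost_t <- function(p) cost(c(p, rep(0, 6)))
    fit <- stats::optim(rep(0, 3), cost_t, method = "Nelder-Mead",
                        control = list(maxit = max_eval))
    fit$par <- c(fit$par, rep(0, 6))
  }
  pbest <- if (fit$value < c0 - 1e-12) fit$par else p0
  cf0 <- cost_full(pbest)
  fit2 <- stats::optim(pbest, cost_full, method = "Nelder-Mead",
                       control = list(maxit = 120, reltol = 1e-8))
  best <- if (fit2$value < cf0 - 1e-12) fit2$par else pbest
  fit <- list(value = min(fit2$value, cf0))
  c0 <- cost_full(p0)
  tf <- build_tf(best, R0)
  attr(tf, "objective") <- min(fit$value, c0)
  attr(tf, "objective_init") <- c0
  tf
}

## resample a moving volume through an affine onto a fixed grid
resample_affine <- function(vol, tf, fixed_geom, nearest = FALSE, outside = 0) {
  d <- vol_dim(fixed_geom)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  ijk <- world_to_voxel(vol, apply_affine(tf, voxel_to_world(fixed_geom, idx)))
  dm <- vol_dim(vol)
  if (nearest || inherits(vol, "label_volume")) {
    ids <- sort(unique(as.vector(vol$voxels)))
    best <- rep(-Inf, nrow(ijk)); win <- rep(0L, nrow(ijk))
    for (id in ids) {
      p <- .sample_tri_cpp(as.numeric(vol$voxels == id), as.integer(dm), ijk,
                           FALSE, as.numeric(id == 0L))
      upd <- p > best + 1e-9
      best[upd] <- p[upd]; win[upd] <- id
    }
    out <- vol; out$voxels <- array(win, d)
    out$spacing_mm <- fixed_geom$spacing_mm; out$origin_mm <- fixed_geom$origin_mm
    out$orientation <- fixed_geom$orientation
    out
  } else {
    v <- .sample_tri_cpp(as.numeric(vol$voxels), as.integer(dm), ijk, FALSE, outside)
    out <- vol; out$voxels <- array(v, d)
    out$spacing_mm <- fixed_geom$spacing_mm; out$origin_mm <- fixed_geom$origin_mm
    out$orientation <- fixed_geom$orientation
    out
  }
}

## ---------------------------------------------------------------------------
## greedy diffeomorphic core

## multichannel greedy diffeomorphic registration on one pyramid.
## fixed_ch / moving_ch: lists of arrays (same dims). metric_grad returns
## list(force = list(fx, fy, fz), objective); objective is minimized.
greedy_diffeo <- function(moving_ch, fixed_ch, params, geom,
                          metric = c("ssd", "ncc"), mask = NULL,
                          init_vox = NULL) {
  metric <- match.arg(metric)
  d0 <- dim(fixed_ch[[1]])
  nlev <- params$n_levels
  objective_trace <- list()
  warned <- FALSE
  u <- NULL
  ## a provided initialization is already coarse-scale correct: refine at
  ## the finest level only, so the field is not degraded by downsampling
  levels <- if (is.null(init_vox)) seq_len(nlev) else nlev
  for (lev in levels) {
    f <- 2^(nlev - lev)
    dl <- if (f == 1) d0 else pmax(8L, as.integer(round(d0 / f)))
    scl <- (dl - 1) / (d0 - 1)
    sp_l <- geom$spacing_mm / scl
    res <- function(arr) array(.resize_cpp(as.numeric(arr), as.integer(dim(arr)),
                                           as.integer(dl)), dl)
    Fch <- lapply(fixed_ch, res)
    Mch <- lapply(moving_ch, res)
    Ml <- if (is.null(mask)) NULL else res(array(as.numeric(mask), d0)) > 0.5
    if (is.null(u)) {
      u <- lapply(1:3, function(a) array(0, dl))
    } else {
      dprev <- dim(u[[1]])
      u <- lapply(1:3, function(a) {
        arr <- array(.resize_cpp(as.numeric(u[[a]]), as.integer(dprev), as.integer(dl)), dl)
        arr * (dl[a] - 1) / (dprev[a] - 1)
      })
    }
    if (!is.null(init_vox)) {
      dprev <- dim(init_vox[[1]])
      u <- lapply(1:3, function(a) {
        arr <- array(.resize_cpp(as.numeric(init_vox[[a]]), as.integer(dprev),
                                 as.integer(dl)), dl)
        arr * (dl[a] - 1) / (dprev[a] - 1)
      })
      init_vox <- NULL
    }
    sig_fluid <- rep(params$smoothing_sigmas_mm[lev], 3) / sp_l
    sig_elast <- rep(params$regularization_sigma_mm, 3) / sp_l
    eval_obj <- function(uu) {
      Mw <- lapply(Mch, function(m)
        array(.warp_cpp(as.numeric(m), as.integer(dl),
                        as.numeric(uu[[1]]), as.numeric(uu[[2]]), as.numeric(uu[[3]]),
                        TRUE, 0), dl))
      if (metric == "ssd") {
        obj <- sum(vapply(seq_along(Fch), function(c)
          sum((Fch[[c]] - Mw[[c]])^2), 0.0))
      } else {
        a <- Mw[[1]][Ml]; b <- Fch[[1]][Ml]
        a <- a - mean(a); b <- b - mean(b)
        obj <- -sum(a * b) / sqrt(max(sum(a^2) * sum(b^2), 1e-12))
      }
      list(Mw = Mw, obj = obj)
    }
    cur <- eval_obj(u)
    lev_trace <- cur$obj
    step <- params$step_size
    halvings <- 0
    for (it in seq_len(params$n_iterations[lev])) {
      ## metric force at current warp
      fx <- array(0, dl); fy <- array(0, dl); fz <- array(0, dl)
      if (metric == "ssd") {
        for (c in seq_along(Fch)) {
          g <- .gradient3_cpp(as.numeric(cur$Mw[[c]]), as.integer(dl))
          dd <- Fch[[c]] - cur$Mw[[c]]
          fx <- fx + dd * array(g[[1]], dl)
          fy <- fy + dd * array(g[[2]], dl)
          fz <- fz + dd * array(g[[3]], dl)
        }
      } else {
        Mw <- cur$Mw[[1]]
        a <- Mw; b <- Fch[[1]]
        am <- mean(a[Ml]); bm <- mean(b[Ml])
        ac <- (a - am) * Ml; bc <- (b - bm) * Ml
        A <- sum(ac^2); B <- sum(bc^2); C <- sum(ac * bc)
        den <- sqrt(max(A * B, 1e-12))
        dmw <- (bc / den - (C / max(A, 1e-12)) * ac / den)   # d(NCC)/d(Mw)
        g <- .gradient3_cpp(as.numeric(Mw), as.integer(dl))
        fx <- dmw * array(g[[1]], dl)
        fy <- dmw * array(g[[2]], dl)
        fz <- dmw * array(g[[3]], dl)
      }
      fx <- array(.gauss3_cpp(as.numeric(fx), as.integer(dl), sig_fluid), dl)
      fy <- array(.gauss3_cpp(as.numeric(fy), as.integer(dl), sig_fluid), dl)
      fz <- array(.gauss3_cpp(as.numeric(fz), as.integer(dl), sig_fluid), dl)
      fmax <- max(sqrt(fx^2 + fy^2 + fz^2))
      if (fmax < 1e-12) break
      accepted <- FALSE
      while (!accepted && halvings <= 5) {
        delta <- list(fx * (step / fmax), fy * (step / fmax), fz * (step / fmax))
        cc <- .compose_disp_cpp(lapply(u, as.numeric), lapply(delta, as.numeric),
                                as.integer(dl))
        unew <- lapply(cc, array, dim = dl)
        if (params$regularization_sigma_mm > 0)
          unew <- lapply(unew, function(x)
            array(.gauss3_cpp(as.numeric(x), as.integer(dl), sig_elast), dl))
        jmin <- min(.jacdet_cpp(as.numeric(unew[[1]]), as.numeric(unew[[2]]),
                                as.numeric(unew[[3]]), as.integer(dl)))
        if (jmin <= 0.02) { step <- step / 2; halvings <- halvings + 1; next }
        trial <- eval_obj(unew)
        if (trial$obj <= cur$obj + 1e-12) {
          u <- unew; cur <- trial; accepted <- TRUE
          lev_trace <- c(lev_trace, cur$obj)
        } else {
          step <- step / 2; halvings <- halvings + 1
        }
      }
      if (!accepted) { warned <- TRUE; break }   # keep best-so-far at this level
    }
    objective_trace[[length(objective_trace) + 1]] <- lev_trace
  }
  field <- vox_to_field(u, geom)
  attr(field, "objective_trace") <- objective_trace
  attr(field, "nonconverged") <- warned
  field
}

soft_guide_channels <- function(lab, sigma_mm) {
  ids <- c(GUIDE_LABELS[["mtl_gray_medial"]], GUIDE_LABELS[["mtl_gray_lateral"]],
           GUIDE_LABELS[["srlm"]])
  vox <- lab$voxels
  ## artifact regions still guide shape registration (only intensity and
  ## thickness exclude them): reassign each artifact voxel to its nearest
  ## guide structure
  art <- vox == GUIDE_LABELS[["artifact"]]
  if (any(art)) {
    ft <- distance_transform(array(vox %in% ids, dim(vox)), lab$spacing_mm)$feature
    vox[art] <- vox[ft[art]]
  }
  lapply(ids, function(id)
    smooth_volume(array(as.numeric(vox == id), vol_dim(lab)),
                  lab$spacing_mm, rep(sigma_mm, 3)))
}

#' Generalized Dice overlap over a set of labels
#'
#' `2 sum_c |A_c ^ B_c| / sum_c (|A_c| + |B_c|)` over the given label ids.
#'
#' @param a,b integer arrays or label volumes.
#' @param ids label ids to pool.
#' @export
generalized_dice <- function(a, b, ids) {
  va <- if (inherits(a, "image_volume")) a$voxels else a
  vb <- if (inherits(b, "image_volume")) b$voxels else b
  num <- 0; den <- 0
  for (id in ids) {
    ia <- va == id; ib <- vb == id
    num <- num + 2 * sum(ia & ib)
    den <- den + sum(ia) + sum(ib)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Shape-based diffeomorphic registration on guide labels
#'
#' Greedy multi-resolution diffeomorphic optimization of multi-label SSD
#' over soft indicator channels for the medial collateral-sulcus bank, the
#' lateral bank, and the SRLM (the artifact label is never a channel). The
#' returned field keeps a strictly positive Jacobian; if registration would
#' lower the generalized Dice of the guide labels the identity field is
#' returned instead with a warning flag.
#'
#' @param moving,fixed [label_volume()]s with the guide-label inventory, or
#'   `fixed` may be a list of pre-built soft channel arrays (internal use by
#'   the groupwise loop) with a `geometry` entry.
#' @param params [registration_params()].
#' @return `deformation_field` with attributes `objective_trace`,
#'   `dice_before`, `dice_after`.
#' @export
register_shape <- function(moving, fixed, params = registration_params()) {
  sig <- params$indicator_sigma_mm
  mov_ch <- soft_guide_channels(moving, sig)
  if (inherits(fixed, "label_volume")) {
    fix_ch <- soft_guide_channels(fixed, sig)
    geom <- fixed
  } else {
    fix_ch <- fixed$channels
    geom <- fixed$geometry
  }
  field <- greedy_diffeo(mov_ch, fix_ch, params, geom, metric = "ssd")
  gids <- c(1L, 2L, 3L)
  if (inherits(fixed, "label_volume")) {
    d0 <- generalized_dice(warp_labels(moving, identity_field(geom)), fixed, gids)
    d1 <- generalized_dice(warp_labels(moving, field), fixed, gids)
    if (!is.na(d0) && !is.na(d1) && d1 < d0) {
      field <- identity_field(geom)
      attr(field, "nonconverged") <- TRUE
      d1 <- d0
    }
    attr(field, "dice_before") <- d0
    attr(field, "dice_after") <- d1
  }
  field
}

#' Masked intensity refinement registration
#'
#' Maximizes normalized cross-correlation between the fixed image and the
#' warped moving image over voxels outside the exclusion mask, composing the
#' update with an initial (shape-derived) field. The achieved masked NCC is
#' never below its value at the initialization.
#'
#' @param moving,fixed [image_volume()]s.
#' @param exclusion_mask logical array on the fixed grid (union of both
#'   specimens' artifact regions, mapped through `init`).
#' @param init initial `deformation_field`.
#' @param params [registration_params()]; metric forced to masked NCC.
#' @param tissue_mask optional logical array defining tissue; default is
#'   fixed-image intensity above 10% of its maximum.
#' @export
register_intensity <- function(moving, fixed, exclusion_mask = NULL,
                               init = NULL, params = registration_params(metric = "masked_ncc"),
                               tissue_mask = NULL) {
  d <- vol_dim(fixed)
  if (is.null(tissue_mask)) tissue_mask <- fixed$voxels > 0.1 * max(fixed$voxels)
  if (is.null(exclusion_mask)) exclusion_mask <- array(FALSE, d)
  if (sum(exclusion_mask & tissue_mask) > 0.9 * sum(tissue_mask))
    stop("register_intensity: insufficient unmasked tissue")
  mask <- tissue_mask & !exclusion_mask
  init_vox <- if (is.null(init)) NULL else field_to_vox(init)
  if (!is.null(init)) {
    aud <- jacobian_audit(init)
    if (!aud$pass) stop("register_intensity: init violates the diffeomorphic contract")
  }
  norm01 <- function(v) (v - min(v)) / max(max(v) - min(v), 1e-12)
  field <- greedy_diffeo(list(norm01(moving$voxels)), list(norm01(fixed$voxels)),
                         params, fixed, metric = "ncc", mask = mask,
                         init_vox = init_vox)
  ncc_of <- function(f) {
    mw <- warp_volume(moving$voxels, f)
    a <- mw[mask]; b <- fixed$voxels[mask]
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(max(sum(a^2) * sum(b^2), 1e-12))
  }
  f0 <- if (is.null(init)) identity_field(fixed) else init
  ncc0 <- ncc_of(f0); ncc1 <- ncc_of(field)
  if (ncc1 < ncc0) { field <- f0; attr(field, "nonconverged") <- TRUE; ncc1 <- ncc0 }
  attr(field, "ncc_init") <- ncc0
  attr(field, "ncc_final") <- ncc1
  field
}
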