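## Synthetic specimen generator. A specimen is a folded cortical sheet (the
## MTL gray ribbon, bent around a collateral-sulcus valley) plus a thin SRLM
## sheet, rasterized into a small isotropic grid at ex vivo resolution
## (default 0.2 mm). The sheet lives in an intrinsic (u, v) parameter space
## (u = arc length across the fold, v = anterior-posterior position); local
## thickness, subregion labels and the pathology hotspot are all defined in
## (u, v), so they correspond across specimens regardless of the individual
## fold geometry.

## ordinal pathology scale and marginals; marginals chosen once to emulate
## the published cohort summaries (mean ipsi tau ~1.5, mean TDP ~0.54)
RATING_SCALE <- c(0, 0.5, 1, 2, 3)
TAU_MARGINAL <- c(0.15, 0.12, 0.23, 0.30, 0.20)
TDP_MARGINAL <- c(0.55, 0.15, 0.18, 0.08, 0.04)

#' Cohort configuration for the synthetic generator
#'
#' @param n_specimens number of specimens (>= 2).
#' @param grid_shape voxels per axis (default 64^3).
#' @param voxel_size_mm isotropic spacing, default 0.2 (200 um).
#' @param seed RNG seed for the whole cohort.
#' @param beta_tau thinning (mm) per unit of average tau rating inside the
#'   entorhinal hotspot patch.
#' @param beta_age thinning (mm) per year of age (centered at cohort mean).
#' @param noise_sd_mm pointwise SD of the smooth thickness noise field.
#' @param age_tau_corr target Pearson correlation between age and mean tau
#'   rating (via a latent Gaussian copula).
#' @param frac_discontinuous_sulcus fraction of type-2 (shallow anterior
#'   branch) specimens.
#' @param artifact_prob probability a specimen receives an artifact region.
#' @param geo_var relative scale of random per-specimen fold-geometry
#'   perturbations (0 = identical geometry).
#' @param block_gap_prob probability a specimen's subregion map carries an
#'   inter-block gap slab (labeled `unknown`).
#' @export
cohort_config <- function(n_specimens = 29L, grid_shape = c(64L, 64L, 64L),
                          voxel_size_mm = 0.2, seed = 1L,
                          beta_tau = 0.15, beta_age = 0.01,
                          noise_sd_mm = 0.1, age_tau_corr = 0.61,
                          frac_discontinuous_sulcus = 0.35,
                          artifact_prob = 0.2, geo_var = 0.15,
                          block_gap_prob = 0.3) {
  stopifnot(n_specimens >= 2, voxel_size_mm > 0,
            frac_discontinuous_sulcus >= 0, frac_discontinuous_sulcus <= 1,
            abs(age_tau_corr) < 1)
  structure(list(n_specimens = as.integer(n_specimens),
                 grid_shape = rep_len(as.integer(grid_shape), 3L),
                 voxel_size_mm = voxel_size_mm, seed = as.integer(seed),
                 beta_tau = beta_tau, beta_age = beta_age,
                 noise_sd_mm = noise_sd_mm, age_tau_corr = age_tau_corr,
                 frac_discontinuous_sulcus = frac_discontinuous_sulcus,
                 artifact_prob = artifact_prob, geo_var = geo_var,
                 block_gap_prob = block_gap_prob),
            class = "cohort_config")
}

## fixed (u, v) raster on which ground-truth thickness is reported
TRUTH_RASTER_N <- 48L

## hotspot patch in parameter space: lies inside the ERC band. The core
## excludes a one-voxel-scale margin and is what parameter-recovery
## analyses should average over (the rim is partial-volume territory).
HOTSPOT_U <- c(0.36, 0.52)
HOTSPOT_V <- c(0.28, 0.72)

in_hotspot <- function(u, v) {
  u >= HOTSPOT_U[1] & u <= HOTSPOT_U[2] & v >= HOTSPOT_V[1] & v <= HOTSPOT_V[2]
}

in_hotspot_core <- function(u, v) {
  u >= HOTSPOT_U[1] + 0.04 & u <= HOTSPOT_U[2] - 0.04 &
    v >= HOTSPOT_V[1] + 0.08 & v <= HOTSPOT_V[2] - 0.08
}

## subregion bands along u (medial hippocampal end -> lateral neocortex)
subregion_of_uv <- function(u, v) {
  id <- integer(length(u))
  bands <- rbind(c(0.00, 0.06, SUBREGION_LABELS[["DG"]]),
                 c(0.06, 0.10, SUBREGION_LABELS[["CA3"]]),
                 c(0.10, 0.14, SUBREGION_LABELS[["CA2"]]),
                 c(0.14, 0.22, SUBREGION_LABELS[["CA1"]]),
                 c(0.22, 0.28, SUBREGION_LABELS[["SUB"]]),
                 c(0.28, 0.31, SUBREGION_LABELS[["presubiculum"]]),
                 c(0.31, 0.34, SUBREGION_LABELS[["parasubiculum"]]),
                 c(0.34, 0.56, SUBREGION_LABELS[["ERC"]]),
                 c(0.56, 0.64, SUBREGION_LABELS[["BA35"]]),
                 c(0.64, 0.80, SUBREGION_LABELS[["BA36"]]),
                 c(0.80, 1.01, SUBREGION_LABELS[["TE"]]))
  for (r in seq_len(nrow(bands)))
    id[u >= bands[r, 1] & u < bands[r, 2]] <- as.integer(bands[r, 3])
  id[v < 0.15 & u >= 0.22 & u < 0.28] <- SUBREGION_LABELS[["HATA"]]
  id[v > 0.85 & u >= 0.56] <- SUBREGION_LABELS[["TF_TH"]]
  id
}

## walk one cross-section profile at fixed v, returning sample points spaced
## ~0.35 voxel in arc length, up to total intrinsic length L (voxel units)
profile_walk <- function(nx, nz, depth, perturb, L) {
  x0 <- 0.10 * nx
  xf <- (0.38 + perturb$xf_shift) * nx
  ## valley width: wide enough that the two banks (each up to ~0.9 mm
  ## half-thickness) never fuse across the fundus
  sig <- 0.095 * nx
  xs <- seq(x0, 0.95 * nx, by = 0.35)
  zb <- (0.60 + perturb$z_shift) * nz +
    perturb$arch * nz * sin(pi * (xs - x0) / (0.85 * nx - x0))
  zs <- zb - depth * exp(-(xs - xf)^2 / (2 * sig^2))
  ds <- c(0, sqrt(diff(xs)^2 + diff(zs)^2))
  s <- cumsum(ds)
  keep <- s <= L
  list(x = xs[keep], z = zs[keep], u = s[keep] / L, medial = xs[keep] < xf)
}

## per-specimen fold geometry perturbation (intrinsic quantities untouched)
sample_perturb <- function(geo_var) {
  list(depth_scale = 1 + geo_var * stats::runif(1, -1, 1),
       arch = 0.05 * (1 + geo_var * stats::runif(1, -1, 1)),
       xf_shift = 0.02 * geo_var / 0.15 * stats::runif(1, -1, 1) * (geo_var > 0),
       z_shift = 0.03 * geo_var / 0.15 * stats::runif(1, -1, 1) * (geo_var > 0),
       y_shift = 1.5 * geo_var / 0.15 * stats::runif(1, -1, 1) * (geo_var > 0))
}

no_perturb <- function() sample_perturb(0)

#' Rasterize a folded cortical-ribbon phantom
#'
#' Builds the curved MTL gray sheet (prescribed local thickness, medial and
#' lateral collateral-sulcus banks labeled separately), a thin SRLM sheet,
#' and a T2-like intensity volume (tissue-dependent means, smooth
#' multiplicative bias, Gaussian noise). Uses the current RNG state; seed
#' with `set.seed()` for determinism.
#'
#' @param grid_shape voxels per axis.
#' @param sulcus_type 1 (deep continuous sulcus) or 2 (shallower,
#'   discontinuous anterior branch).
#' @param thickness_field scalar thickness in mm, or `function(u, v)` over
#'   the unit parameter square returning mm.
#' @param voxel_size_mm isotropic spacing.
#' @param perturb internal list of geometry perturbations.
#' @param srlm_thickness_mm thickness of the SRLM sheet.
#' @return list with `image` ([image_volume()]), `guide_labels`
#'   ([label_volume()]), `sample_index` (int array mapping voxels to center
#'   -surface samples), `samples` (data.frame u, v, halfw_mm, medial,
#'   srlm), and `truth_uv` (thickness on the fixed truth raster).
#' @export
make_ribbon_phantom <- function(grid_shape, sulcus_type = 1L, thickness_field = 1.4,
                                voxel_size_mm = 0.2, perturb = no_perturb(),
                                srlm_thickness_mm = 0.5) {
  d <- rep_len(as.integer(grid_shape), 3L)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  tfun <- if (is.function(thickness_field)) thickness_field
          else function(u, v) rep_len(thickness_field, length(u))
  ## validate thickness over the parameter domain
  ug <- seq(0, 1, length.out = 25); vg <- seq(0, 1, length.out = 25)
  tv <- tfun(rep(ug, 25), rep(vg, each = 25))
  if (any(!is.finite(tv)) || any(tv <= 0))
    stop("make_ribbon_phantom: thickness field must be strictly positive")
  tmax_vox <- max(tv) / voxel_size_mm
  ## the fold needs ~26 voxels of structural room plus the sheet thickness
  min_grid <- ceiling(26 + 1.2 * tmax_vox)
  if (min(d) < min_grid)
    stop("make_ribbon_phantom: grid too small for the fold at this thickness; ",
         "minimum grid is ", min_grid, "^3")

  L <- 0.75 * nx
  y0 <- 0.12 * ny + perturb$y_shift; y1 <- 0.88 * ny + perturb$y_shift
  ys <- seq(y0, y1, by = 0.35)
  vs <- (ys - y0) / (y1 - y0)
  base_depth <- 0.16 * nz * perturb$depth_scale
  pts <- vector("list", length(ys)); meta <- vector("list", length(ys))
  for (r in seq_along(ys)) {
    v <- vs[r]
    depth <- if (sulcus_type == 1L) {
      base_depth * (0.95 - 0.10 * cos(pi * v))
    } else {
      ## discontinuous type: anterior branch much shallower
      tt <- pmin(1, pmax(0, (v - 0.35) / 0.30))
      base_depth * (0.25 + 0.75 * (tt * tt * (3 - 2 * tt)))
    }
    pw <- profile_walk(nx, nz, depth, perturb, L)
    pts[[r]] <- cbind(pw$x, ys[r], pw$z)
    meta[[r]] <- data.frame(u = pw$u, v = v, medial = pw$medial)
  }
  P <- do.call(rbind, pts)
  M <- do.call(rbind, meta)
  halfw_mm <- tfun(M$u, M$v) / 2
  if (any(halfw_mm <= 0)) stop("make_ribbon_phantom: thickness field must be strictly positive")
  M$halfw_mm <- halfw_mm
  M$srlm <- FALSE

  ## SRLM sheet: offset below the gray sheet along the in-plane normal for
  ## the medial (hippocampal) portion of the ribbon
  srlm_sel <- which(M$u >= 0.02 & M$u <= 0.30)
  if (length(srlm_sel)) {
    rows <- srlm_sel
    ## normal from neighboring samples within the same profile row
    nrm <- t(vapply(rows, function(i) {
      j <- if (i < nrow(P) && M$v[min(i + 1, nrow(M))] == M$v[i]) i + 1 else i - 1
      tx <- P[j, 1] - P[i, 1]; tz <- P[j, 3] - P[i, 3]
      n <- c(tz, 0, -tx); n <- n / max(sqrt(sum(n^2)), 1e-9)
      if (n[3] > 0) n <- -n
      n
    }, numeric(3)))
    off_vox <- (M$halfw_mm[rows] + srlm_thickness_mm / 2) / voxel_size_mm + 1.5
    Ps <- P[rows, , drop = FALSE] + nrm * off_vox
    Ms <- M[rows, , drop = FALSE]
    Ms$halfw_mm <- srlm_thickness_mm / 2
    Ms$srlm <- TRUE
    P <- rbind(P, Ps); M <- rbind(M, Ms)
  }
  rownames(M) <- NULL

  halfw_vox <- M$halfw_mm / voxel_size_mm
  sp <- .splat_cpp(P, halfw_vox, 1.0, d)
  dist <- array(sp$dist, d); sidx <- array(sp$index, d)
  inside <- is.finite(dist) & dist <= halfw_vox[pmax(sidx, 1L)] & sidx > 0L
  is_srlm_vox <- inside & M$srlm[pmax(sidx, 1L)]
  is_gray_vox <- inside & !M$srlm[pmax(sidx, 1L)]
  medial_vox <- is_gray_vox & M$medial[pmax(sidx, 1L)]

  guide <- array(0L, d)
  guide[is_gray_vox & medial_vox] <- GUIDE_LABELS[["mtl_gray_medial"]]
  guide[is_gray_vox & !medial_vox] <- GUIDE_LABELS[["mtl_gray_lateral"]]
  guide[is_srlm_vox] <- GUIDE_LABELS[["srlm"]]
  sidx[!inside] <- 0L

  ## intensity: tissue-dependent means + smooth multiplicative bias + noise
  mu <- array(0.15, d)
  mu[is_gray_vox] <- 0.60
  mu[is_srlm_vox] <- 0.95
  bias_seed <- array(stats::rnorm(prod(pmax(d %/% 8, 2L))), pmax(d %/% 8, 2L))
  bias <- array(.resize_cpp(as.numeric(bias_seed), as.integer(dim(bias_seed)),
                            as.integer(d)), d)
  bias <- 1 + 0.08 * bias / max(abs(bias), 1e-9)
  img <- mu * bias + array(stats::rnorm(prod(d), sd = 0.03), d)

  ## ground truth on the fixed parameter raster
  n <- TRUTH_RASTER_N
  uu <- rep(seq(0, 1, length.out = n), n)
  vv <- rep(seq(0, 1, length.out = n), each = n)
  truth_uv <- matrix(tfun(uu, vv), n, n)

  sp_mm <- rep(voxel_size_mm, 3)
  list(image = image_volume(img, sp_mm),
       guide_labels = label_volume(guide, GUIDE_LABELS, sp_mm),
       sample_index = sidx,
       samples = M,
       truth_uv = truth_uv)
}

## subregion label volume from the phantom's parameter mapping, with an
## optional inter-block gap slab labeled `unknown`
subregions_from_phantom <- function(ph, block_gap = FALSE) {
  d <- vol_dim(ph$guide_labels)
  sub <- array(0L, d)
  sel <- ph$sample_index > 0L & ph$guide_labels$voxels != 0L
  si <- ph$sample_index[sel]
  lab <- subregion_of_uv(ph$samples$u[si], ph$samples$v[si])
  lab[ph$samples$srlm[si]] <- SUBREGION_LABELS[["SRLM"]]
  sub[sel] <- lab
  if (block_gap) {
    vgap <- stats::runif(1, 0.25, 0.75)
    gap <- abs(ph$samples$v[si] - vgap) < 0.03
    tmp <- sub[sel]; tmp[gap] <- SUBREGION_LABELS[["unknown"]]; sub[sel] <- tmp
  }
  label_volume(sub, SUBREGION_LABELS, ph$guide_labels$spacing_mm)
}

quantize_rating <- function(p, marginal) {
  RATING_SCALE[findInterval(p, cumsum(marginal), left.open = TRUE) + 1L]
}

## contralateral ordinal jitter: per-location symmetric +-1 step kernel;
## specimens flagged for a large discrepancy (FTLD-like asymmetry, ~15% of
## cases overall, concentrated in FTLD cases) get a coherent 2-3 step shift
## so the Bland-Altman analysis sees >1-point average-rating asymmetry
jitter_contra <- function(vals, big = FALSE) {
  idx <- match(vals, RATING_SCALE)
  if (big) {
    ## shift toward the side of the scale with room, so clamping does not
    ## erase the planted asymmetry
    dir <- if ((min(idx) - 1L) >= (5L - max(idx))) -1L else 1L
    shift <- dir * sample(2:3, 1L)
    idx <- idx + shift + sample(c(-1L, 0L, 1L), length(idx), replace = TRUE,
                                prob = c(0.15, 0.7, 0.15))
  } else {
    idx <- idx + sample(c(-1L, 0L, 1L), length(idx), replace = TRUE,
                        prob = c(0.15, 0.7, 0.15))
  }
  RATING_SCALE[pmin(pmax(idx, 1L), 5L)]
}

## latent-model calibration constants: `a` is the ordinal-quantization
## attenuation, `rho_within` the latent within-specimen correlation of the
## three MTL locations (pathology is spatially coherent within a brain)
RATING_ATTEN <- 0.9
RATING_RHO_WITHIN <- 0.9

make_rating_set <- function(age, age_range, age_tau_corr, ftld = FALSE) {
  locs <- c("ERC", "DG", "CA")
  zage <- stats::qnorm(pmin(pmax((age - age_range[1]) / diff(age_range), 1e-4), 1 - 1e-4))
  ## loading on age chosen so that corr(age, mean of 3 quantized ratings)
  ## hits the target: corr = a*lam*sqrt(3)/sqrt(1 + 2 a^2 rho_within)
  a <- RATING_ATTEN; rho <- RATING_RHO_WITHIN
  lam <- age_tau_corr * sqrt(1 + 2 * a^2 * rho) / (a * sqrt(3))
  lam <- max(-sqrt(rho), min(sqrt(rho), lam))
  gam <- sqrt(rho - lam^2)
  zspec <- stats::rnorm(1)
  z <- lam * zage + gam * zspec + sqrt(1 - rho) * stats::rnorm(3)
  tau_ipsi <- quantize_rating(stats::pnorm(z), TAU_MARGINAL)
  gam2 <- sqrt(rho)
  z2 <- gam2 * stats::rnorm(1) + sqrt(1 - rho) * stats::rnorm(3)
  tdp_ipsi <- quantize_rating(stats::pnorm(z2), TDP_MARGINAL)
  big <- stats::runif(1) < if (ftld) 0.8 else 0.10
  tau_contra <- jitter_contra(tau_ipsi, big)
  tdp_contra <- jitter_contra(tdp_ipsi, big && stats::runif(1) < 0.5)
  rating_set(data.frame(
    side = rep(c("ipsi", "contra"), each = 3),
    location = rep(locs, 2),
    tau = c(tau_ipsi, tau_contra),
    tdp43 = c(tdp_ipsi, tdp_contra)))
}

#' Generate a seeded synthetic cohort
#'
#' Each specimen's local ribbon half-width realizes the thickness model
#' `T(u,v) = T0(u,v) - beta_tau * tau * H(u,v) - beta_age * (age - mean age)
#' + eps(u,v)` where `H` is the fixed entorhinal hotspot patch in parameter
#' space, `tau` is the specimen's average ipsilateral tau rating, and `eps`
#' is a smooth field with pointwise SD `noise_sd_mm`. Ages are uniform on
#' [59, 93]; tau ratings per location arise from a latent Gaussian copula
#' with age; TDP-43 ratings are independent; contralateral ratings are the
#' ipsilateral ones plus ordinal jitter.
#'
#' @param config a [cohort_config()].
#' @return list of specimens.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_specimens
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  age_range <- c(59, 93)
  ages <- stats::runif(n, age_range[1], age_range[2])
  n_type2 <- round(config$frac_discontinuous_sulcus * n)
  type2 <- rep(FALSE, n)
  if (n_type2 > 0) type2[sample.int(n, n_type2)] <- TRUE
  ftld <- stats::runif(n) < 0.12
  ratings <- lapply(seq_len(n), function(i)
    make_rating_set(ages[i], age_range, config$age_tau_corr, ftld = ftld[i]))
  mean_age <- mean(ages)
  T0 <- function(u, v) 1.4 + 0.2 * sin(pi * u)

  specimens <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("SYN%02d", i)
    tau_avg <- average_rating(ratings[[i]], "ipsi", "tau")
    tfun <- local({
      tau_i <- tau_avg; age_i <- ages[i]
      noise <- config$noise_sd_mm
      ## freeze the specimen's noise field via captured knot values
      nz <- stats::rnorm(324)
      function(u, v) {
        base <- T0(u, v) - config$beta_tau * tau_i * in_hotspot(u, v) -
          config$beta_age * (age_i - mean_age)
        if (noise > 0) {
          ## short-range field: pointwise SD = noise exactly, correlation
          ## length ~2-3 voxels (the stated model is pointwise Gaussian
          ## noise; minimal smoothness keeps the boundary geometrically
          ## coherent without inducing cluster-scale noise structure)
          ku <- seq(0, 1, length.out = 18)
          kg <- as.matrix(expand.grid(ku, ku))
          W <- exp(-((outer(u, kg[, 1], `-`))^2 + (outer(v, kg[, 2], `-`))^2) / (2 * 0.05^2))
          base <- base + as.numeric((W %*% nz) / sqrt(rowSums(W^2))) * noise
        }
        base
      }
    })
    ## reject non-positive thickness before rasterizing
    ug <- seq(0, 1, length.out = 30)
    tv <- tfun(rep(ug, 30), rep(ug, each = 30))
    if (any(tv <= 0))
      stop("generate_cohort: thickness parameters produce T <= 0 for specimen ", id)
    perturb <- sample_perturb(config$geo_var)
    ph <- make_ribbon_phantom(config$grid_shape,
                              sulcus_type = if (type2[i]) 2L else 1L,
                              thickness_field = tfun,
                              voxel_size_mm = config$voxel_size_mm,
                              perturb = perturb)
    sub <- subregions_from_phantom(ph, block_gap = stats::runif(1) < config$block_gap_prob)
    sp <- specimen(id = id, image = ph$image, guide_labels = ph$guide_labels,
                   subregion_labels = sub, age_years = ages[i],
                   ratings = ratings[[i]],
                   sulcus_type = if (type2[i]) 2L else 1L)
    sp$truth <- list(thickness_uv = ph$truth_uv, sample_index = ph$sample_index,
                     samples = ph$samples,
                     hotspot_uv = matrix(in_hotspot(
                       rep(seq(0, 1, length.out = TRUTH_RASTER_N), TRUTH_RASTER_N),
                       rep(seq(0, 1, length.out = TRUTH_RASTER_N), each = TRUTH_RASTER_N)),
                       TRUTH_RASTER_N, TRUTH_RASTER_N))
    sp$braak_ge1 <- tau_avg > 0
    sp$ftld <- ftld[i]
    if (stats::runif(1) < config$artifact_prob)
      sp <- inject_artifact(sp, seed = config$seed + 7919L * i)
    specimens[[i]] <- sp
  }
  specimens
}

#' Specimen container
#'
#' @param id character id.
#' @param image [image_volume()].
#' @param guide_labels [label_volume()] with the guide inventory.
#' @param subregion_labels optional [label_volume()] of MTL subregions.
#' @param age_years numeric age.
#' @param ratings a [rating_set()].
#' @param sulcus_type 1 or 2.
#' @export
specimen <- function(id, image, guide_labels, subregion_labels = NULL,
                     age_years = NA_real_, ratings = NULL, sulcus_type = 1L) {
  stop_if_geometry_mismatch(image, guide_labels, "specimen")
  if (!is.null(subregion_labels)) {
    stop_if_geometry_mismatch(image, subregion_labels, "specimen")
    tissue <- guide_labels$voxels != 0L
    bad <- subregion_labels$voxels != 0L &
      subregion_labels$voxels != SUBREGION_LABELS[["unknown"]] & !tissue
    if (mean(bad) > 0.01)
      stop("specimen: subregion labels must lie inside the guide tissue")
  }
  structure(list(id = id, image = image, guide_labels = guide_labels,
                 subregion_labels = subregion_labels, age_years = age_years,
                 ratings = ratings, sulcus_type = as.integer(sulcus_type)),
            class = "specimen")
}

#' Inject an imaging artifact region
#'
#' Marks a random connected blob of 1-5% of tissue voxels with the
#' artifact-exclusion guide label and corrupts the intensities there
#' (signal dropout), emulating trapped air bubbles / tissue tears.
#'
#' @param sp a [specimen()] without an artifact region.
#' @param seed RNG seed.
#' @export
inject_artifact <- function(sp, seed = 1L) {
  if (any(sp$guide_labels$voxels == GUIDE_LABELS[["artifact"]]))
    stop("inject_artifact: specimen already has an artifact region")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tissue <- sp$guide_labels$voxels != 0L
  nt <- sum(tissue)
  frac <- stats::runif(1, 0.01, 0.05)
  target <- max(8L, round(frac * nt))
  start <- sample(which(tissue), 1L)
  blob <- .region_grow_cpp(as.logical(tissue), as.integer(vol_dim(sp$image)),
                           start, target)
  sp$guide_labels$voxels[blob] <- GUIDE_LABELS[["artifact"]]
  sp$image$voxels[blob] <- 0.05 + stats::rnorm(length(blob), sd = 0.01)
  sp$artifact_fraction <- length(blob) / nt
  sp
}

artifact_mask <- function(sp) sp$guide_labels$voxels == GUIDE_LABELS[["artifact"]]

tissue_mask <- function(sp) sp$guide_labels$voxels != 0L

#' Synthetic NFT density map
#'
#' Nonnegative smooth field over tissue whose hotspot mean increases
#' linearly with the specimen's average tau rating, standing in for
#' histology-derived tangle-density maps.
#'
#' @param sp specimen with subregion labels.
#' @param seed RNG seed.
#' @param c_tau density per unit tau inside the hotspot.
#' @export
generate_nft_density_map <- function(sp, seed = 1L, c_tau = 0.1) {
  if (is.null(sp$subregion_labels))
    stop("generate_nft_density_map: specimen lacks subregion labels")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- vol_dim(sp$image)
  tau <- average_rating(sp$ratings, "ipsi", "tau")
  tis <- tissue_mask(sp)
  ## flat base level over tissue plus a smoothed tau-dependent hotspot bump
  ## (only the bump is smoothed, so the base is not diluted at the borders)
  bump <- array(0, d)
  hs <- hotspot_voxels(sp)
  bump[hs] <- c_tau * tau
  bump <- smooth_volume(bump, sp$image$spacing_mm, rep(2 * sp$image$spacing_mm[1], 3))
  noise_seed <- array(stats::rnorm(prod(pmax(d %/% 6, 2L)), sd = 0.01), pmax(d %/% 6, 2L))
  dens <- 0.05 + bump + array(.resize_cpp(as.numeric(noise_seed),
                                          as.integer(dim(noise_seed)), as.integer(d)), d)
  dens[!tis] <- 0
  dens[dens < 0] <- 0
  out <- sp$image; out$voxels <- dens
  out
}

## voxels of a specimen inside the parameter-space hotspot patch
## (core = TRUE restricts to the interior, away from the partial-volume rim)
hotspot_voxels <- function(sp, core = FALSE) {
  if (is.null(sp$truth)) stop("hotspot_voxels: synthetic truth not available")
  d <- vol_dim(sp$image)
  hv <- array(FALSE, d)
  sel <- sp$truth$sample_index > 0L
  si <- sp$truth$sample_index[sel]
  f <- if (core) in_hotspot_core else in_hotspot
  hv[sel] <- f(sp$truth$samples$u[si], sp$truth$samples$v[si]) &
    !sp$truth$samples$srlm[si]
  hv
}

## RNG bookkeeping: save/restore global seed so generators are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
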