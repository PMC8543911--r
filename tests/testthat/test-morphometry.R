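test_that("skeleton recovers analytic mid-structures of slab and shell", {
  sp <- c(0.2, 0.2, 0.2)
  m <- array(FALSE, c(30, 30, 30)); m[4:27, 4:27, 13:17] <- TRUE   # 1.0 mm slab
  sk <- voronoi_skeleton(m, 1.6, sp)
  th <- thickness_from_skeleton(m, sk)
  ## mid-plane radius within half a voxel, away from the slab rim
  interior_el <- ((sk$voxels - 1) %% 30) >= 6 & ((sk$voxels - 1) %% 30) <= 25
  expect_lt(abs(median(sk$radius_mm[interior_el]) - 0.5), 0.1 + 1e-9)
  ## boundary thickness = w within one voxel for interior points
  bi <- th$i >= 6 & th$i <= 25 & th$j >= 6 & th$j <= 25
  expect_lt(max(abs(th$thickness_mm[bi] - 1.0)), 0.2 + 1e-9)
  expect_lt(abs(median(th$thickness_mm[bi]) - 1.0), 0.1 + 1e-9)
  expect_true(all(th$thickness_mm > 0))
  expect_true(all(sk$radius_mm > 0))

  ## spherical shell, radii 2.0 / 3.2 mm: median radius (w/2) and thickness
  d <- c(48, 48, 48)
  r <- sqrt(rowSums((as.matrix(expand.grid(0:47, 0:47, 0:47)) - 23.5)^2)) * 0.2
  shell <- array(r >= 2 & r <= 3.2, d)
  sk2 <- voronoi_skeleton(shell, 1.6, sp)
  th2 <- thickness_from_skeleton(shell, sk2)
  expect_lt(abs(median(sk2$radius_mm) - 0.6), 0.1 + 1e-9)
  expect_lt(abs(median(th2$thickness_mm) - 1.2), 0.1 + 1e-9)

  expect_error(voronoi_skeleton(array(FALSE, c(8, 8, 8))), "empty")
})

test_that("pruning is monotone in prune_ratio", {
  set.seed(9)
  d <- c(24, 24, 24)
  g <- as.matrix(expand.grid(0:23, 0:23, 0:23))
  m <- array(sqrt(rowSums((g - 11.5)^2)) < 8 + 1.5 * sin(g[, 1]), d)  # noisy blob
  counts <- vapply(c(0.6, 0.9, 1.2, 1.5, 1.8),
                   function(pr) length(voronoi_skeleton(m, pr)$voxels), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("skeleton thickness matches the inscribed-ball brute-force oracle", {
  ## random smooth masks (thresholded smoothed noise, emulating smooth
  ## anatomical surfaces at the working resolution)
  set.seed(42)
  for (rep in 1:3) {
    d <- c(20, 20, 20)
    a <- array(rnorm(prod(d)), d)
    s <- array(mtlatlas:::.gauss3_cpp(as.numeric(a), as.integer(d), c(2.5, 2.5, 2.5)), d)
    m <- s > quantile(s, 0.72)
    m[c(1, 20), , ] <- FALSE; m[, c(1, 20), ] <- FALSE; m[, , c(1, 20)] <- FALSE
    ora <- oracle_inscribed_ball_thickness(m)
    th <- thickness_from_skeleton(m, voronoi_skeleton(m, 1.6, c(1, 1, 1)))
    expect_identical(th$voxel, ora$voxel)
    expect_lte(abs(median(th$thickness_mm) - median(ora$thickness)), 0.5)
  }
})

test_that("thickness is scale-equivariant", {
  ## the same continuous shell rasterized at doubled dimensions (half the
  ## voxel size) must report the same physical thickness within 5%
  mk_shell <- function(n, vox) {
    r <- sqrt(rowSums((as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))) -
                         (n - 1) / 2)^2)) * vox
    array(r >= 2 & r <= 3.2, c(n, n, n))
  }
  s1 <- mk_shell(48, 0.2)
  s2 <- mk_shell(96, 0.1)
  m1 <- median(thickness_from_skeleton(s1, voronoi_skeleton(s1, 1.6, rep(0.2, 3)))$thickness_mm)
  m2 <- median(thickness_from_skeleton(s2, voronoi_skeleton(s2, 1.6, rep(0.1, 3)))$thickness_mm)
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("template surfaces are accurate, boundary-tight and tagged", {
  ## sphere-shell mask: outer surface area within 5% of 4 pi r^2
  d <- c(48, 48, 48)
  r <- sqrt(rowSums((as.matrix(expand.grid(0:47, 0:47, 0:47)) - 23.5)^2)) * 0.2
  ball <- array(r <= 3.4, d)
  geom <- image_volume(array(0, d), spacing_mm = c(0.2, 0.2, 0.2))
  mesh <- mtlatlas:::mask_surface(ball, geom)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 3.4^2) / (4 * pi * 3.4^2), 0.05)

  surfs <- fixture_surfaces()
  at <- fixture_atlas()   # updated with consensus subregions by fixture_surfaces
  for (tag in c("MTL", "SRLM")) {
    mesh <- surfs[[tag]]
    expect_gt(nrow(mesh$vertices), 200)
    ## every vertex within 1 voxel of the mask boundary
    ids <- if (tag == "SRLM") 3L else c(1L, 2L, 4L)
    mask <- mtlatlas:::binary_mask(at$template_guide_labels, ids)
    bnd <- mtlatlas:::boundary_voxels(mask)
    ed <- distance_transform(bnd, c(0.2, 0.2, 0.2))
    ijk <- round(mtlatlas:::world_to_voxel(at$template_guide_labels, mesh$vertices))
    ijk <- pmin(pmax(ijk, 0), 47)
    lin <- 1 + ijk[, 1] + 48 * (ijk[, 2] + 48 * ijk[, 3])
    expect_lt(quantile(ed$dist[lin], 0.99), 0.2 * 1.5 + 1e-9)
    ## subregion tags cover >= 99% of vertices
    expect_gte(mean(mesh$vertex_fields$subregion != 0), 0.99)
  }
  ## empty mask errors
  expect_error(mtlatlas:::mask_surface(array(FALSE, c(8, 8, 8)), geom), "empty mask")
})

test_that("specimen thickness sampling honors transforms, artifacts and truth", {
  at <- fixture_atlas()
  surfs <- fixture_surfaces()
  co <- fixture_cohort()
  names(co) <- vapply(co, `[[`, "", "id")

  tm <- sample_specimen_thickness(co[[names(at$transforms)[1]]], at, surfs$MTL)
  expect_s3_class(tm, "thickness_map")
  expect_gt(mean(tm$valid), 0.5)
  expect_true(all(tm$thickness_mm[tm$valid] > 0))
  ## plausible cortical thickness at the 0.2 mm working resolution
  expect_lt(abs(median(tm$thickness_mm[tm$valid]) - 1.4), 0.45)

  ## vertices mapping into an artifact blob are invalid
  sp_art <- Filter(function(s) any(s$guide_labels$voxels == 4L) &&
                     s$id %in% names(at$transforms), co)
  if (length(sp_art)) {
    sp <- sp_art[[1]]
    tma <- sample_specimen_thickness(sp, at, surfs$MTL)
    native <- mtlatlas:::map_points_to_specimen(at, sp$id, surfs$MTL$vertices)
    ijk <- round(mtlatlas:::world_to_voxel(sp$guide_labels, native))
    d <- dim(sp$guide_labels$voxels)
    inb <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
      ijk[, 3] >= 0 & ijk[, 3] < d[3]
    lin <- 1 + ijk[inb, 1] + d[1] * (ijk[inb, 2] + d[2] * ijk[inb, 3])
    in_art <- sp$guide_labels$voxels[lin] == 4L
    expect_true(all(!tma$valid[inb][in_art]))
  }

  ## missing transform errors
  spx <- co[[names(at$transforms)[1]]]
  spx$id <- "ABSENT"
  expect_error(sample_specimen_thickness(spx, at, surfs$MTL), "no transform")
})

test_that("zero-noise cohort recovers the planted thinning rate", {
  ## parameter-recovery invariant: per-vertex OLS of sampled thickness on
  ## tau over the consensus hotspot core recovers -beta_tau within 15%
  cfg <- cohort_config(n_specimens = 20L, grid_shape = c(48L, 48L, 48L), seed = 21L,
                       beta_tau = 0.25, beta_age = 0, noise_sd_mm = 0,
                       artifact_prob = 0, geo_var = 0.1)
  co <- generate_cohort(cfg)
  names(co) <- vapply(co, `[[`, "", "id")
  at <- build_atlas(co, verbose = FALSE)
  surfs <- extract_template_surfaces(at)
  ids <- names(at$transforms)
  tmaps <- lapply(co[ids], sample_specimen_thickness, atlas = at,
                  template_surface = surfs$MTL)
  tau <- vapply(co[ids], function(s)
    as.numeric(average_rating(s$ratings, "ipsi", "tau")), 0.0)
  ## consensus hotspot core: template vertices that every specimen maps
  ## into its own core patch (the rim is partial-volume territory)
  votes <- hotspot_vertex_votes(at, co, ids, surfs$MTL, core = TRUE)
  hot_verts <- which(votes == length(ids))
  expect_gte(length(hot_verts), 20)
  Y <- vapply(tmaps, function(tm) {
    y <- tm$thickness_mm; y[!tm$valid] <- NA; y
  }, numeric(length(tmaps[[1]]$thickness_mm)))
  slopes <- apply(Y[hot_verts, , drop = FALSE], 1, function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 10) return(NA_real_)
    oracle_ols(cbind(1, tau[ok]), y[ok])$beta[2]
  })
  expect_lt(abs(mean(slopes, na.rm = TRUE) - (-0.25)) / 0.25, 0.15)
  ## sampled hotspot mean thickness decreases with tau (zero-noise cohort)
  hot_mean <- colMeans(Y[hot_verts, , drop = FALSE], na.rm = TRUE)
  expect_lt(cor(hot_mean, tau), -0.8)
})
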