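test_that("identical-phantom cohort is a fixed point of atlas construction", {
  set.seed(5)
  ph <- make_ribbon_phantom(c(48, 48, 48), 1L, 1.2)
  sp <- lapply(1:3, function(i) specimen(sprintf("ID%02d", i), ph$image, ph$guide_labels))
  at <- build_atlas(sp, verbose = FALSE)
  rng <- diff(range(ph$image$voxels))
  expect_lt(mean(abs(at$template_image$voxels - ph$image$voxels)) / rng, 0.01)
  for (tr in at$transforms) {
    u <- mtlatlas:::field_to_vox(tr$fwd)
    expect_lt(sqrt(mean(u[[1]]^2 + u[[2]]^2 + u[[3]]^2) * 3), 0.25)
    expect_true(tr$min_jacobian > 0)
  }
})

test_that("stage Dice is monotone and stage 2 is unbiased on the shared cohort", {
  at <- fixture_atlas()
  d <- at$provenance$dice_by_stage
  expect_gte(d[["stage2"]], d[["stage1"]] - 1e-9)
  expect_gte(d[["stage3"]], d[["stage2"]] - 1e-9)
  expect_gte(d[["stage2"]], 0.85)
  expect_lt(at$provenance$stage2_mean_disp_rms_vox, 0.5)
  ## every stored transform passes the diffeomorphic audit
  for (tr in at$transforms) expect_gt(tr$min_jacobian, 0)
  ## template keeps all three guide structures
  expect_gt(sum(at$template_guide_labels$voxels == 3L), 100)  # SRLM survives
})

test_that("atlas construction is equivariant to specimen order", {
  co <- fixture_cohort()[1:3]
  at1 <- build_atlas(co, verbose = FALSE)
  at2 <- build_atlas(rev(co), verbose = FALSE)
  rng <- diff(range(at1$template_image$voxels))
  expect_lt(mean(abs(at1$template_image$voxels - at2$template_image$voxels)) / rng, 0.005)
})

test_that("subregion warping preserves the inventory and round-trips", {
  at <- fixture_atlas()
  co <- fixture_cohort()
  names(co) <- vapply(co, `[[`, "", "id")
  sp <- co[[names(at$transforms)[1]]]
  w <- warp_subregions_to_template(sp, at)
  expect_true(all(unique(as.vector(w$voxels)) %in% c(0L, SUBREGION_LABELS)))

  ## identity transform leaves labels unchanged
  at0 <- at
  idf <- mtlatlas:::identity_field(at$template_image)
  at0$transforms[[sp$id]]$affine <- affine_transform()
  at0$transforms[[sp$id]]$fwd <- idf
  at0$transforms[[sp$id]]$inv <- idf
  w0 <- warp_subregions_to_template(sp, at0)
  expect_identical(w0$voxels, sp$subregion_labels$voxels)

  ## all-background input maps to all-background
  spb <- sp
  spb$subregion_labels$voxels[] <- 0L
  wb <- warp_subregions_to_template(spb, at)
  expect_true(all(wb$voxels == 0L))

  ## missing transform errors
  spx <- sp; spx$id <- "NOPE"
  expect_error(warp_subregions_to_template(spx, at), "no transform")
})

test_that("subregion warping round-trips through a known diffeomorphism", {
  ## the round-trip property concerns the label warping machinery, so it is
  ## tested with a known smooth transform at the default 64^3 resolution
  ## (registration quality is audited elsewhere)
  set.seed(31)
  ph <- make_ribbon_phantom(c(64, 64, 64), 1L, 1.4)
  sp <- specimen("RT01", ph$image, ph$guide_labels,
                 subregion_labels = mtlatlas:::subregions_from_phantom(ph))
  d <- c(64, 64, 64)
  smoothf <- function() {
    a <- array(rnorm(prod(d)), d)
    s <- array(mtlatlas:::.gauss3_cpp(as.numeric(a), as.integer(d), c(6, 6, 6)), d)
    s / max(abs(s))
  }
  disp <- array(0, c(d, 3))
  for (ax in 1:3) disp[, , , ax] <- 0.2 * 1.5 * smoothf()
  fwd <- deformation_field(disp, c(0.2, 0.2, 0.2))
  expect_true(jacobian_audit(fwd)$pass)
  aff <- affine_transform(diag(3) * 1.02, c(0.3, -0.2, 0.1))
  at_stub <- structure(list(
    template_image = image_volume(array(0, d), c(0.2, 0.2, 0.2)),
    transforms = list(RT01 = list(affine = aff, fwd = fwd,
                                  inv = invert_field(fwd)))), class = "atlas")
  w <- warp_subregions_to_template(sp, at_stub)
  back <- warp_labels_from_template(w, at_stub, "RT01", sp$image)
  for (id in setdiff(unique(as.vector(sp$subregion_labels$voxels)), 0L)) {
    if (sum(sp$subregion_labels$voxels == id) < 100) next
    dc <- generalized_dice(back$voxels, sp$subregion_labels$voxels, id)
    expect_gte(dc, 0.90)
  }
})

test_that("consensus equals the brute-force majority vote at weight 0", {
  set.seed(4)
  d <- c(10, 10, 10)
  pool <- c(0L, 1L, 2L, 5L, 10L, 99L)   # includes the unknown label
  labs <- lapply(1:9, function(i)
    label_volume(array(sample(pool, prod(d), TRUE, prob = c(.3, .2, .2, .1, .1, .1)), d),
                 SUBREGION_LABELS, c(0.2, 0.2, 0.2)))
  cons <- consensus_segmentation(labs, mrf_weight = 0)
  expect_identical(as.vector(cons$voxels), oracle_majority(labs))

  ## 6 votes vs 5 at a voxel: majority wins
  v6 <- lapply(1:11, function(i)
    label_volume(array(if (i <= 6) 2L else 5L, c(3, 3, 3)), SUBREGION_LABELS,
                 c(0.2, 0.2, 0.2)))
  c65 <- consensus_segmentation(v6, mrf_weight = 0)
  expect_true(all(c65$voxels == 2L))

  ## geometry mismatch errors
  bad <- label_volume(array(0L, c(4, 4, 4)), SUBREGION_LABELS, c(0.2, 0.2, 0.2))
  expect_error(consensus_segmentation(list(labs[[1]], bad)), "geometry mismatch")
})

test_that("consensus MRF behaves like a slight regularizer", {
  ## identical coherent inputs are preserved across the documented
  ## slight-regularization range
  d <- c(8, 8, 8)
  coh <- array(1L, d); coh[5:8, , ] <- 2L; coh[, 7:8, ] <- 10L
  labs <- lapply(1:11, function(i) label_volume(coh, SUBREGION_LABELS, c(0.2, 0.2, 0.2)))
  for (w in c(0, 0.25 * log(2), 0.5 * log(2))) {
    cw <- consensus_segmentation(labs, mrf_weight = w)
    expect_identical(cw$voxels, coh)
  }

  ## crafted salt voxel: 6 votes minority at the center, absorbed at
  ## weight >= log 2 per face; checked against an energy-comparison oracle
  d5 <- c(5, 5, 5)
  labs5 <- lapply(1:11, function(i) {
    v <- array(1L, d5)
    if (i <= 6) v[3, 3, 3] <- 2L
    label_volume(v, SUBREGION_LABELS, c(0.2, 0.2, 0.2))
  })
  c0 <- consensus_segmentation(labs5, mrf_weight = 0)
  expect_equal(c0$voxels[3, 3, 3], 2L)     # plain majority keeps the salt
  cs <- consensus_segmentation(labs5, mrf_weight = log(2))
  expect_equal(cs$voxels[3, 3, 3], 1L)     # absorbed
  ## the absorbed configuration has higher objective than the majority one
  e_maj <- oracle_potts_energy(c0$voxels, labs5, log(2))
  e_icm <- oracle_potts_energy(cs$voxels, labs5, log(2))
  expect_gt(e_icm, e_maj)
  ## reported energy trace is non-decreasing (objective is maximized)
  expect_true(all(diff(attr(cs, "energy")) >= -1e-9))
})

test_that("overlap and dispersion maps summarize specimen agreement", {
  d <- c(8, 8, 8)
  mk <- function(split) {
    v <- array(0L, d)
    v[1:split, , ] <- 10L
    v[(split + 1):8, , ] <- 11L
    label_volume(v, SUBREGION_LABELS, c(0.2, 0.2, 0.2))
  }
  same <- list(mk(4), mk(4))
  ov <- label_overlap_maps(same, 10L)
  expect_true(all(ov$voxels %in% c(0, 1)))

  ## two inputs disagreeing on half the label -> 0.5 in the disagreement zone
  half <- list(mk(4), mk(6))
  ov2 <- label_overlap_maps(half, 10L)
  expect_true(all(abs(ov2$voxels[5:6, , ] - 0.5) < 1e-12))
  expect_error(label_overlap_maps(half, 12L), "absent")

  ## a boundary systematically shifted by k voxels spans >= k voxels
  shifted <- list(mk(2), mk(4), mk(6))
  disp <- boundary_dispersion(shifted, c(10L, 11L))
  xs <- which(apply(disp$voxels > 0, 1, any))
  expect_gte(diff(range(xs)), 4)
  expect_true(all(disp$voxels >= 0 & disp$voxels <= 1))
})
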