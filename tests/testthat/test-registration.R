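make_shift_pair <- function(shift = c(3L, -2L, 1L)) {
  ## phantom embedded in a larger grid with generous margins, so a voxel
  ## shift never clips content or touches the smoothing boundary zone
  set.seed(10)
  ph <- make_ribbon_phantom(c(48, 48, 48), 1L, 1.2)
  D <- c(60L, 60L, 60L)
  embed <- function(v, off) {
    out <- array(0L, D)
    out[off[1] + 1:48, off[2] + 1:48, off[3] + 1:48] <- v
    out
  }
  fixed <- label_volume(embed(ph$guide_labels$voxels, c(6, 6, 6)), GUIDE_LABELS,
                        ph$guide_labels$spacing_mm)
  moving <- label_volume(embed(ph$guide_labels$voxels, c(6, 6, 6) + shift),
                         GUIDE_LABELS, ph$guide_labels$spacing_mm)
  list(fixed = fixed, moving = moving)
}

test_that("affine alignment: identity, translation recovery, empty input", {
  pr <- make_shift_pair()
  tf0 <- affine_align(pr$fixed, pr$fixed)
  d <- dim(pr$fixed$voxels)
  ## RMS voxel displacement of the recovered transform over the grid
  idx <- as.matrix(expand.grid(seq(0, d[1] - 1, by = 6), seq(0, d[2] - 1, by = 6),
                               seq(0, d[3] - 1, by = 6))) * 0.2
  moved <- mtlatlas:::apply_affine(tf0, idx)
  expect_lt(sqrt(mean(rowSums((moved - idx)^2))) / 0.2, 1e-3)

  tf <- affine_align(pr$moving, pr$fixed)
  ## transform maps fixed coords onto moving: recovered translation = shift
  expect_lt(max(abs(tf$translation_mm / 0.2 - c(3, -2, 1))), 0.25)
  expect_lte(attr(tf, "objective"), attr(tf, "objective_init"))

  empty <- label_volume(array(0L, c(16, 16, 16)), GUIDE_LABELS)
  expect_error(affine_align(empty, pr$fixed), "empty")
})

test_that("shape registration aligns sulcus types without bank confusion", {
  set.seed(2)
  ph1 <- make_ribbon_phantom(c(48, 48, 48), 1L, 1.2)
  ph2 <- make_ribbon_phantom(c(48, 48, 48), 2L, 1.2)
  ## moving = fixed is a fixed point
  f0 <- register_shape(ph2$guide_labels, ph2$guide_labels)
  u <- mtlatlas:::field_to_vox(f0)
  expect_lt(sqrt(mean(u[[1]]^2 + u[[2]]^2 + u[[3]]^2) * 3), 0.1)

  tf <- affine_align(ph1$guide_labels, ph2$guide_labels)
  la <- mtlatlas:::resample_affine(ph1$guide_labels, tf, ph2$guide_labels)
  fld <- register_shape(la, ph2$guide_labels)
  expect_gte(attr(fld, "dice_after"), 0.85)
  expect_gte(attr(fld, "dice_after"), attr(fld, "dice_before"))
  ## objective trace is non-increasing across accepted iterations (per
  ## pyramid level; objectives at different resolutions are not comparable)
  for (tr in attr(fld, "objective_trace"))
    expect_true(all(diff(tr) <= 1e-9))
  ## diffeomorphic contract
  expect_true(jacobian_audit(fld)$pass)
  ## medial bank never maps onto the lateral bank in > 2% of bank voxels
  w <- mtlatlas:::warp_labels(la, fld)
  mm <- sum(w$voxels == 1L & ph2$guide_labels$voxels == 2L) / max(sum(w$voxels == 1L), 1)
  ml <- sum(w$voxels == 2L & ph2$guide_labels$voxels == 1L) / max(sum(w$voxels == 2L), 1)
  expect_lt(mm, 0.02)
  expect_lt(ml, 0.02)
})

test_that("artifact labels are excluded from the shape channels", {
  set.seed(6)
  ph <- make_ribbon_phantom(c(48, 48, 48), 1L, 1.2)
  ph2 <- make_ribbon_phantom(c(48, 48, 48), 2L, 1.2)
  sp <- specimen("A", ph$image, ph$guide_labels)
  spa <- inject_artifact(sp, seed = 4L)
  tf <- affine_align(ph$guide_labels, ph2$guide_labels)
  la_clean <- mtlatlas:::resample_affine(ph$guide_labels, tf, ph2$guide_labels)
  la_art <- mtlatlas:::resample_affine(spa$guide_labels, tf, ph2$guide_labels)
  f_clean <- register_shape(la_clean, ph2$guide_labels)
  f_art <- register_shape(la_art, ph2$guide_labels)
  ## compare the recovered correspondences: both fields applied to the
  ## artifact-free labels must overlap the fixed labels equally well
  gids <- c(1L, 2L, 3L)
  d_clean <- generalized_dice(mtlatlas:::warp_labels(la_clean, f_clean),
                              ph2$guide_labels, gids)
  d_art <- generalized_dice(mtlatlas:::warp_labels(la_clean, f_art),
                            ph2$guide_labels, gids)
  expect_lt(abs(d_clean - d_art), 0.02)
})

test_that("masked intensity registration improves NCC and guards its inputs", {
  set.seed(3)
  ph <- make_ribbon_phantom(c(48, 48, 48), 1L, 1.2)
  d <- c(48, 48, 48)
  img <- ph$image
  bias <- array(rep(seq(0.85, 1.15, length.out = 48), each = 48 * 48), d)
  img2 <- img
  img2$voxels <- img$voxels * bias
  fld <- register_intensity(img2, img)
  expect_gte(attr(fld, "ncc_final"), 0.95)
  expect_gte(attr(fld, "ncc_final"), attr(fld, "ncc_init"))
  expect_true(jacobian_audit(fld)$pass)

  f0 <- register_intensity(img, img)
  u <- mtlatlas:::field_to_vox(f0)
  expect_lt(sqrt(mean(u[[1]]^2 + u[[2]]^2 + u[[3]]^2) * 3), 0.1)

  expect_error(register_intensity(img, img, exclusion_mask = array(TRUE, d)),
               "insufficient unmasked tissue")
})

test_that("field composition and inversion satisfy their contracts", {
  set.seed(8)
  d <- c(32, 32, 32)
  geom <- image_volume(array(0, d), spacing_mm = c(0.2, 0.2, 0.2))
  smoothf <- function() {
    a <- array(rnorm(prod(d)), d)
    s <- array(mtlatlas:::.gauss3_cpp(as.numeric(a), as.integer(d), c(4, 4, 4)), d)
    s / max(abs(s))
  }
  disp <- array(0, c(d, 3))
  for (ax in 1:3) disp[, , , ax] <- 0.2 * 1.2 * smoothf()
  fld <- deformation_field(disp, c(0.2, 0.2, 0.2))

  idf <- mtlatlas:::identity_field(geom)
  expect_equal(compose_fields(fld, idf)$displacement_mm, fld$displacement_mm,
               tolerance = 1e-12)

  ## closed form: inverse of a pure translation
  tdisp <- array(0, c(d, 3)); tdisp[, , , 1] <- 0.4; tdisp[, , , 3] <- -0.2
  tf <- deformation_field(tdisp, c(0.2, 0.2, 0.2))
  ti <- invert_field(tf)
  expect_lt(max(abs(ti$displacement_mm[, , , 1] + 0.4)) / 0.2, 1e-3)
  expect_lt(max(abs(ti$displacement_mm[, , , 3] - 0.2)) / 0.2, 1e-3)

  inv <- invert_field(fld)
  expect_lt(attr(inv, "roundtrip_rms_vox"), 0.25)

  g2 <- deformation_field(array(0, c(16, 16, 16, 3)), c(0.2, 0.2, 0.2))
  expect_error(compose_fields(fld, g2), "geometry mismatch")
})

test_that("registration is resolution-consistent", {
  set.seed(12)
  mk <- function(dim) {
    ph1 <- make_ribbon_phantom(rep(dim, 3), 1L, 1.2)
    ph2 <- make_ribbon_phantom(rep(dim, 3), 2L, 1.2)
    tf <- affine_align(ph1$guide_labels, ph2$guide_labels)
    la <- mtlatlas:::resample_affine(ph1$guide_labels, tf, ph2$guide_labels)
    attr(register_shape(la, ph2$guide_labels), "dice_after")
  }
  d48 <- mk(48L)
  d64 <- mk(64L)
  expect_lt(abs(d48 - d64), 0.05)
})
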