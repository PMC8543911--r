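test_that("ribbon phantom geometry honors prescribed thickness and type parity", {
  set.seed(1)
  ph <- make_ribbon_phantom(c(64, 64, 64), 1L, 1.0)
  g <- ph$guide_labels$voxels
  expect_true(all(sort(unique(as.vector(g))) %in% c(0L, 1L, 2L, 3L)))
  expect_gt(sum(g == 1L), 1000)       # both banks populated
  expect_gt(sum(g == 2L), 1000)
  expect_gt(sum(g == 3L), 200)        # SRLM sheet present

  ## distance-transform thickness oracle on the gray mask: median recovers
  ## the prescribed 1.0 mm within one voxel (0.2 mm)
  mask <- array(g %in% c(1L, 2L), dim(g))
  th <- thickness_from_skeleton(mask, voronoi_skeleton(mask, 1.2, c(0.2, 0.2, 0.2)))
  expect_lt(abs(median(th$thickness_mm) - 1.0), 0.2)

  ## identical total gray volume across sulcus types (constant thickness)
  ph2 <- make_ribbon_phantom(c(64, 64, 64), 2L, 1.0)
  v1 <- sum(ph$guide_labels$voxels %in% c(1L, 2L))
  v2 <- sum(ph2$guide_labels$voxels %in% c(1L, 2L))
  expect_lt(abs(v2 - v1) / v1, 0.05)

  ## degenerate thickness and too-small grids are rejected
  expect_error(make_ribbon_phantom(c(64, 64, 64), 1L, 0), "positive")
  expect_error(make_ribbon_phantom(c(16, 16, 16), 1L, 1.0), "minimum grid")
})

test_that("cohort generation is seeded-deterministic and respects the scale", {
  cfg <- cohort_config(n_specimens = 3L, grid_shape = c(48, 48, 48), seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$image$voxels, b[[i]]$image$voxels)
    expect_identical(a[[i]]$guide_labels$voxels, b[[i]]$guide_labels$voxels)
    expect_identical(a[[i]]$ratings$table, b[[i]]$ratings$table)
    ## rating marginals live on exactly the 5-point scale
    expect_true(all(a[[i]]$ratings$table$tau %in% c(0, 0.5, 1, 2, 3)))
    expect_true(all(a[[i]]$ratings$table$tdp43 %in% c(0, 0.5, 1, 2, 3)))
    expect_gte(a[[i]]$age_years, 59)
    expect_lte(a[[i]]$age_years, 93)
  }
})

test_that("no-effect cohort shares one truth thickness field; impossible thickness errors", {
  cfg <- cohort_config(n_specimens = 3L, grid_shape = c(48, 48, 48), seed = 3L,
                       beta_tau = 0, beta_age = 0, noise_sd_mm = 0)
  co <- generate_cohort(cfg)
  expect_equal(co[[1]]$truth$thickness_uv, co[[2]]$truth$thickness_uv)
  expect_equal(co[[2]]$truth$thickness_uv, co[[3]]$truth$thickness_uv)

  bad <- cohort_config(n_specimens = 2L, grid_shape = c(48, 48, 48), seed = 3L,
                       beta_tau = 2.0, noise_sd_mm = 0)   # 2 mm/unit * tau 3 > T0
  expect_error(generate_cohort(bad), "T <= 0.*SYN")
})

test_that("ground-truth recovery closure: hotspot OLS slope equals -beta_tau", {
  cfg <- cohort_config(n_specimens = 12L, grid_shape = c(48, 48, 48), seed = 5L,
                       beta_tau = 0.2, beta_age = 0, noise_sd_mm = 0)
  co <- generate_cohort(cfg)
  tau <- vapply(co, function(s) as.numeric(average_rating(s$ratings, "ipsi", "tau")), 0.0)
  hot <- co[[1]]$truth$hotspot_uv
  y <- vapply(co, function(s) mean(s$truth$thickness_uv[hot]), 0.0)
  fit <- oracle_ols(cbind(1, tau), y)
  expect_lt(abs(fit$beta[2] - (-0.2)), 1e-6)
})

test_that("age-tau copula lands near the published correlation", {
  co <- generate_cohort(cohort_config(n_specimens = 30L, grid_shape = c(48, 48, 48),
                                      seed = 1L, age_tau_corr = 0.61))
  tau <- vapply(co, function(s) as.numeric(average_rating(s$ratings, "ipsi", "tau")), 0.0)
  age <- vapply(co, function(s) s$age_years, 0.0)
  r <- cor(age, tau)
  expect_gte(r, 0.46)
  expect_lte(r, 0.76)
})

test_that("artifact injection marks a seeded, bounded blob and is one-shot", {
  co <- fixture_cohort()
  sp <- Filter(function(s) !any(s$guide_labels$voxels == 4L), co)[[1]]
  a1 <- inject_artifact(sp, seed = 99L)
  a2 <- inject_artifact(sp, seed = 99L)
  expect_identical(a1$guide_labels$voxels, a2$guide_labels$voxels)
  frac <- a1$artifact_fraction
  expect_gte(frac, 0.009)
  expect_lte(frac, 0.051)
  ## guide labels elsewhere unchanged
  keep <- a1$guide_labels$voxels != 4L
  expect_identical(a1$guide_labels$voxels[keep], sp$guide_labels$voxels[keep])
  expect_error(inject_artifact(a1, seed = 1L), "already has")
})

test_that("NFT density maps are nonnegative, seeded, and tau-null at rating 0", {
  co <- fixture_cohort()
  sp <- co[[1]]
  m1 <- generate_nft_density_map(sp, seed = 3L)
  m2 <- generate_nft_density_map(sp, seed = 3L)
  expect_identical(m1$voxels, m2$voxels)
  expect_true(all(m1$voxels >= 0))
  ## zero-tau specimen: hotspot means indistinguishable from baseline
  sp0 <- sp
  sp0$ratings <- rating_set(data.frame(side = rep(c("ipsi", "contra"), each = 3),
                                       location = rep(c("ERC", "DG", "CA"), 2),
                                       tau = 0, tdp43 = 0))
  hs <- mtlatlas:::hotspot_voxels(sp0)
  base <- mtlatlas:::tissue_mask(sp0) & !hs
  hot_means <- base_means <- numeric(20)
  for (k in 1:20) {
    m <- generate_nft_density_map(sp0, seed = 100L + k)
    hot_means[k] <- mean(m$voxels[hs])
    base_means[k] <- mean(m$voxels[base])
  }
  expect_gt(t.test(hot_means, base_means)$p.value, 0.01)
})
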