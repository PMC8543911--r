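mk_ratings <- function(ipsi_tau, contra_tau = ipsi_tau, ipsi_tdp = rep(0, 3),
                       contra_tdp = ipsi_tdp) {
  rating_set(data.frame(side = rep(c("ipsi", "contra"), each = 3),
                        location = rep(c("ERC", "DG", "CA"), 2),
                        tau = c(ipsi_tau, contra_tau),
                        tdp43 = c(ipsi_tdp, contra_tdp)))
}

test_that("average_rating and grade mapping follow the ordinal scale", {
  expect_equal(as.numeric(average_rating(mk_ratings(c(0.5, 1, 2)), "ipsi", "tau")),
               mean(c(0.5, 1, 2)))
  expect_equal(as.numeric(average_rating(mk_ratings(c(3, 3, 3)), "ipsi", "tau")), 3)
  ## "moderate" maps to 2 before averaging
  expect_equal(rating_from_grade(c("none", "rare", "mild", "moderate", "severe")),
               c(0, 0.5, 1, 2, 3))
  ## missing handling
  r <- mk_ratings(c(1, NA, 2))
  av <- average_rating(r, "ipsi", "tau")
  expect_equal(as.numeric(av), 1.5)
  expect_equal(attr(av, "n_missing"), 1L)
  expect_error(average_rating(mk_ratings(c(NA, NA, NA)), "ipsi", "tau"), "missing")
  ## off-scale values rejected at construction
  expect_error(mk_ratings(c(0.7, 1, 2)), "must lie on")
})

test_that("cohort selection applies age, exclusion and low-TDP filters", {
  mk_spec <- function(id, age, tau, tdp) list(id = id, age_years = age,
                                              ratings = mk_ratings(rep(tau, 3),
                                                                   ipsi_tdp = rep(tdp, 3)))
  specs <- list(mk_spec("A", 44, 1, 0), mk_spec("B", 45, 2, 0.5),
                mk_spec("C", 60, 0, 0), mk_spec("D", 70, 1, 2),
                mk_spec("E", 80, 2, 0.5), mk_spec("F", 65, 3, 0),
                mk_spec("G", 75, 0.5, 1), mk_spec("H", 85, 1, 0),
                mk_spec("I", 62, 2, 3))
  des <- select_cohort(specs, "full_age_tdp")
  ## the two under-59 cases are dropped
  expect_false(any(c("A", "B") %in% des$ids))
  expect_equal(des$pathology, "tau_avg")
  expect_equal(colnames(des$X), c("intercept", "tau_avg", "age", "tdp_avg"))

  low <- select_cohort(specs, "low_tdp_age_only")
  tdps <- vapply(specs, function(s) as.numeric(average_rating(s$ratings, "ipsi", "tdp43")), 0.0)
  names(tdps) <- vapply(specs, `[[`, "", "id")
  expect_true(all(tdps[low$ids] < 1))

  tdp_des <- select_cohort(specs, "tdp_effect")
  expect_equal(tdp_des$pathology, "tdp_avg")

  ## constant pathology column after filtering -> rank error naming it
  const <- lapply(specs[3:9], function(s) { s$ratings$table$tau <- 1; s })
  expect_error(select_cohort(const, "full_age_only"), "tau_avg")
})

test_that("vertex-wise GLM matches exact fits and the normal-equations oracle", {
  ## exact linear relation, no covariates: beta recovered, residual 0
  tau <- c(0, 0.5, 1, 2, 3, 1, 2)
  specs <- lapply(seq_along(tau), function(i)
    list(id = sprintf("S%d", i), age_years = 70, ratings = mk_ratings(rep(tau[i], 3))))
  tm <- lapply(seq_along(tau), function(i)
    thickness_map(rep(2 - 0.3 * tau[i], 4), rep(TRUE, 4), sprintf("S%d", i), "MTL"))
  des <- structure(list(X = cbind(intercept = 1, tau_avg = tau),
                        ids = sprintf("S%d", seq_along(tau)),
                        pathology = "tau_avg", variant = "custom"),
                   class = "design_matrix")
  g <- fit_vertexwise_glm(tm, des)
  expect_equal(g$beta[2, ], rep(-0.3, 4), tolerance = 1e-10)

  ## random designs vs explicit (X'X)^-1 X'y on 50 vertices
  set.seed(5)
  n <- 24; V <- 50
  X <- cbind(intercept = 1, tau_avg = runif(n, 0, 3), age = runif(n, 60, 90))
  Y <- 1.5 + matrix(rnorm(n * V, sd = 0.1), n, V)
  tms <- lapply(1:n, function(i) thickness_map(Y[i, ], rep(TRUE, V), sprintf("T%02d", i), "MTL"))
  dms <- structure(list(X = X, ids = sprintf("T%02d", 1:n), pathology = "tau_avg",
                        variant = "custom"), class = "design_matrix")
  gg <- fit_vertexwise_glm(tms, dms)
  for (v in seq_len(V)) {
    o <- oracle_ols(X, Y[, v])
    expect_lt(abs(gg$t[v] - o$t[2]), 1e-8)
    expect_lt(max(abs(gg$beta[, v] - o$beta)), 1e-8)
  }

  ## null p-values are uniform (KS)
  set.seed(6)
  Vn <- 500; nn <- 30
  Xn <- cbind(intercept = 1, tau_avg = runif(nn, 0, 3))
  Yn <- 1.4 + matrix(rnorm(nn * Vn, sd = 0.1), nn, Vn)
  tmn <- lapply(1:nn, function(i) thickness_map(Yn[i, ], rep(TRUE, Vn), sprintf("N%02d", i), "MTL"))
  dmn <- structure(list(X = Xn, ids = sprintf("N%02d", 1:nn), pathology = "tau_avg",
                        variant = "custom"), class = "design_matrix")
  gn <- fit_vertexwise_glm(tmn, dmn)
  expect_gt(ks.test(gn$p, "punif")$p.value, 0.01)
})

test_that("available-case GLM handles artifact-invalid vertices per vertex", {
  set.seed(7)
  n <- 16; V <- 30
  X <- cbind(intercept = 1, tau_avg = runif(n, 0, 3))
  Y <- 1.4 + matrix(rnorm(n * V, sd = 0.1), n, V)
  valid <- matrix(TRUE, n, V)
  valid[1:6, 1:10] <- FALSE          # pattern A: 10 rows
  valid[, V] <- FALSE; valid[1:4, V] <- TRUE  # too few -> invalid vertex
  tms <- lapply(1:n, function(i) {
    th <- Y[i, ]; th[!valid[i, ]] <- 0.5
    thickness_map(th, valid[i, ], sprintf("P%02d", i), "MTL")
  })
  dms <- structure(list(X = X, ids = sprintf("P%02d", 1:n), pathology = "tau_avg",
                        variant = "custom"), class = "design_matrix")
  g <- fit_vertexwise_glm(tms, dms)
  expect_false(g$valid[V])
  expect_true(all(g$valid[1:(V - 1)]))
  o <- oracle_ols(X[7:n, ], Y[7:n, 3])
  expect_lt(abs(g$t[3] - o$t[2]), 1e-8)
  expect_equal(g$df[3], length(7:n) - 2)
})

test_that("cluster permutation correction is seeded, calibrated and consistent", {
  mesh <- fixture_flat_mesh(40, 30)
  sim <- simulate_thickness_maps(mesh, 22, 0.3, 0.1, seed = 12)
  design <- select_cohort(sim$specimens, "full_age_only")
  ct1 <- cluster_permutation_correction(sim$tmaps, design, mesh,
                                        n_permutations = 199, seed = 42)
  ct2 <- cluster_permutation_correction(sim$tmaps, design, mesh,
                                        n_permutations = 199, seed = 42)
  expect_identical(ct1$table, ct2$table)
  ## corrected p monotone non-increasing in mass
  tab <- ct1$table
  expect_true(all(diff(tab$corrected_p[order(-tab$mass)]) >= -1e-12))
  expect_true(all(tab$corrected_p >= 1 / 200 & tab$corrected_p <= 1))
  ## the planted hotspot (left edge of the flat mesh) is the top cluster
  top <- ct1$clusters[[1]]
  expect_gt(mean(sim$hotspot[top]), 0.8)
  expect_lt(tab$corrected_p[1], 0.05)
  ## thinning is a negative tau coefficient with and without the covariate
  g1 <- fit_vertexwise_glm(sim$tmaps, design)
  g2 <- fit_vertexwise_glm(sim$tmaps, select_cohort(sim$specimens, "full_age_tdp"))
  hot <- which(sim$hotspot)
  expect_lt(mean(g1$beta[2, hot]), 0)
  expect_lt(mean(g2$beta[2, hot]), 0)
  ## no supra-threshold vertex -> empty table, not an error
  flat <- lapply(sim$tmaps, function(tm) { tm$thickness_mm[] <- 1.4; tm })
  ct0 <- cluster_permutation_correction(flat, design, mesh,
                                        n_permutations = 99, seed = 1)
  expect_equal(nrow(ct0$table), 0)
})

test_that("Freedman-Lane with intercept-only nuisance equals outcome permutation", {
  ## with no covariates beyond the intercept, permuting reduced-model
  ## residuals and adding back the fit is exactly a permutation of y
  mesh <- fixture_flat_mesh(10, 10)
  set.seed(33)
  n <- 12; V <- nrow(mesh$vertices)
  tau <- runif(n, 0, 3)
  Y <- 1.4 + matrix(rnorm(n * V, sd = 0.1), n, V)
  tms <- lapply(1:n, function(i) thickness_map(Y[i, ], rep(TRUE, V), sprintf("F%02d", i), "MTL"))
  des <- structure(list(X = cbind(intercept = 1, tau_avg = tau),
                        ids = sprintf("F%02d", 1:n), pathology = "tau_avg",
                        variant = "custom"), class = "design_matrix")
  ct <- cluster_permutation_correction(tms, des, mesh, n_permutations = 99, seed = 77)
  ## oracle: simple permutation of y with the same RNG protocol
  set.seed(77)
  null_max <- numeric(99)
  edges <- mtlatlas:::mesh_edges(mesh)
  for (b in 1:99) {
    pi_g <- sample.int(n)
    Yp <- (1.4 * 0 + Y[pi_g, , drop = FALSE] - matrix(colMeans(Y), n, V, byrow = TRUE)) +
      matrix(colMeans(Y), n, V, byrow = TRUE)   # permuting centered residuals + mean = permuted y
    ts <- vapply(seq_len(V), function(v) oracle_ols(des$X, Yp[, v])$t[2], 0.0)
    pv <- 2 * pt(abs(ts), n - 2, lower.tail = FALSE)
    cm <- mtlatlas:::cluster_masses(edges, ts, pv, 0.01)
    null_max[b] <- if (length(cm$mass)) max(cm$mass) else 0
  }
  expect_equal(ct$null_max, null_max, tolerance = 1e-8)
})

test_that("Bland-Altman limits and asymmetry counts are exact", {
  specs <- list(
    list(id = "S1", ratings = mk_ratings(c(3, 3, 3), c(0, 0, 0)), ftld = TRUE),
    list(id = "S2", ratings = mk_ratings(c(1, 1, 1), c(1, 1, 1))),
    list(id = "S3", ratings = mk_ratings(c(2, 2, 2), c(1, 1, 1))),
    list(id = "S4", ratings = mk_ratings(c(0.5, 0.5, 0.5), c(1, 1, 1))))
  ba <- bland_altman(specs, "tau")
  ## severe asymmetric case: ipsi 3, contra 0 -> difference 3
  expect_equal(ba$per_specimen$diff[ba$per_specimen$id == "S1"], 3)
  expect_true(ba$per_specimen$ftld[ba$per_specimen$id == "S1"])
  m <- mean(c(3, 0, 1, -0.5)); s <- sd(c(3, 0, 1, -0.5))
  expect_equal(ba$summary$mean_diff, m)
  expect_equal(ba$summary$lower, m - 2 * s)
  expect_equal(ba$summary$upper, m + 2 * s)

  ## identical sides -> zero limits
  same <- list(list(id = "A", ratings = mk_ratings(c(1, 2, 3))),
               list(id = "B", ratings = mk_ratings(c(0, 0.5, 1))))
  ba0 <- bland_altman(same, "tau")
  expect_equal(ba0$summary$mean_diff, 0)
  expect_equal(ba0$summary$upper, 0)

  ## constructed SD(diff) = 0.5 (diffs 0, 0.5, 1) -> limits at mean +- 1.0
  sd5 <- list(list(id = "A", ratings = mk_ratings(c(1, 1, 1), c(1, 1, 1))),
              list(id = "B", ratings = mk_ratings(c(1, 1, 1), c(0.5, 0.5, 0.5))),
              list(id = "C", ratings = mk_ratings(c(1, 1, 1), c(0, 0, 0))))
  ba5 <- bland_altman(sd5, "tau")
  expect_equal(sd(ba5$per_specimen$diff), 0.5)
  expect_equal(ba5$summary$upper, ba5$summary$mean_diff + 1.0)
  expect_equal(ba5$summary$lower, ba5$summary$mean_diff - 1.0)

  expect_error(bland_altman(specs[1], "tau"), "fewer than 2")

  ## strict-threshold boundary: diffs {0, 0.5, 1.0, 1.5} -> count 1
  ## (contralateral averages 2, 1.5, 1, 0.5 built from on-scale values)
  contra_sets <- list(c(2, 2, 2), c(0.5, 1, 3), c(1, 1, 1), c(0, 0.5, 1))
  bspecs <- lapply(seq_along(contra_sets), function(i)
    list(id = sprintf("B%d", i), ratings = mk_ratings(rep(2, 3), contra_sets[[i]])))
  ac <- asymmetry_count(bspecs, "tau", threshold = 1)
  expect_equal(ac$count, 1L)
  expect_equal(ac$percent_display, 25)
  expect_equal(asymmetry_count(bspecs, "tau", threshold = 99)$count, 0L)
  ## 5 of 28 displays as 18%
  expect_equal(round(100 * 5 / 28), 18)
})

test_that("cohort summary conventions", {
  one <- list(list(id = "X", age_years = 70, ratings = mk_ratings(c(3, 3, 3)),
                   braak_ge1 = TRUE))
  s1 <- cohort_summary(one)
  expect_equal(s1$tau_mean, 3)
  expect_equal(s1$tau_sd, 0)      # single specimen: SD reported as 0
  expect_equal(s1$braak_ge1_frac, 1)
})

test_that("region correlation matches the covariance-formula oracle", {
  set.seed(8)
  ids <- sprintf("R%02d", 1:12)
  d <- c(8, 8, 8)
  region <- list(hot = list(voxels = array(rep(c(TRUE, FALSE), c(64, prod(d) - 64)), d),
                            vertices = 1:50))
  nft_vals <- runif(length(ids), 0.1, 1)
  nft_maps <- setNames(lapply(nft_vals, function(v)
    image_volume(array(v, d))), ids)
  tmaps <- lapply(seq_along(ids), function(i)
    thickness_map(rep(2 - 0.5 * nft_vals[i], 100), rep(TRUE, 100), ids[i], "MTL"))
  tab <- region_summary_correlation(nft_maps, tmaps, region)
  expect_equal(tab$r, -1, tolerance = 1e-10)

  ## textbook covariance formula on noisy data
  tmaps2 <- lapply(seq_along(ids), function(i)
    thickness_map(rep(2 - 0.5 * nft_vals[i], 100) + (i %% 3) * 0.05,
                  rep(TRUE, 100), ids[i], "MTL"))
  tab2 <- region_summary_correlation(nft_maps, tmaps2, region)
  x <- nft_vals
  y <- vapply(seq_along(ids), function(i) median(tmaps2[[i]]$thickness_mm[1:50]), 0.0)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab2$r, r_oracle, tolerance = 1e-10)

  ## partial correlation given age attenuates an age-driven association
  ages <- setNames(60 + 30 * nft_vals + rnorm(12, sd = 2), ids)
  tab3 <- region_summary_correlation(nft_maps, tmaps2, region, ages = ages)
  expect_true(is.finite(tab3$r_partial_age))
  expect_lte(abs(tab3$r_partial_age), 1)

  ## permuted pairing de-correlates at n = 12
  set.seed(9)
  cnt <- 0
  for (k in 1:100) {
    perm <- sample(seq_along(ids))
    tabp <- region_summary_correlation(setNames(nft_maps[perm], names(nft_maps)),
                                       tmaps2, region)
    if (abs(tabp$r) < 0.5) cnt <- cnt + 1
  }
  expect_gte(cnt, 90)

  ## constant inputs error
  cmaps <- setNames(lapply(ids, function(i) image_volume(array(1, d))), ids)
  expect_error(region_summary_correlation(cmaps, tmaps2, region), "constant")
})

test_that("contralateral ratings reproduce the ipsilateral cluster locations", {
  mesh <- fixture_flat_mesh(40, 30)
  sim <- simulate_thickness_maps(mesh, 24, 0.3, 0.1, seed = 19)
  ## contralateral = ipsilateral plus small ordinal jitter
  set.seed(20)
  scale5 <- c(0, 0.5, 1, 2, 3)
  specs <- lapply(sim$specimens, function(s) {
    tb <- s$ratings$table
    ii <- match(tb$tau[tb$side == "contra"], scale5)
    ii <- pmin(pmax(ii + sample(c(-1L, 0L, 1L), 3, TRUE, c(.1, .8, .1)), 1L), 5L)
    tb$tau[tb$side == "contra"] <- scale5[ii]
    s$ratings <- rating_set(tb)
    s
  })
  d_ipsi <- select_cohort(specs, "full_age_only")
  d_contra <- select_cohort(specs, "contralateral")
  ct_i <- cluster_permutation_correction(sim$tmaps, d_ipsi, mesh,
                                         n_permutations = 199, seed = 5)
  ct_c <- cluster_permutation_correction(sim$tmaps, d_contra, mesh,
                                         n_permutations = 199, seed = 5)
  expect_gt(nrow(ct_i$table), 0)
  expect_gt(nrow(ct_c$table), 0)
  a <- ct_i$clusters[[1]]; b <- ct_c$clusters[[1]]
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac, 0.5)
})
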