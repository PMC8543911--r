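## Independent oracles and shared fixtures. Oracles are deliberately
## brute-force and share no code path with the package internals they
## check (beyond trivial utilities).

## 0-based voxel coordinates of linear indices
lin_to_ijk <- function(lin, d) {
  l0 <- lin - 1L
  cbind(l0 %% d[1], (l0 %/% d[1]) %% d[2], l0 %/% (d[1] * d[2]))
}

## boundary voxels by explicit 6-neighbor scan (independent of the package
## implementation)
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (lin in which(mask)) {
    ijk <- lin_to_ijk(lin, d)[1, ]
    onb <- FALSE
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- ijk; q[ax] <- q[ax] + s
      if (any(q < 0) || any(q >= d)) { onb <- TRUE; next }
      if (!mask[q[1] + 1, q[2] + 1, q[3] + 1]) onb <- TRUE
    }
    out[lin] <- onb
  }
  out
}

## brute-force inscribed-ball thickness oracle: per boundary voxel, twice
## the largest radius among interior voxels whose inscribed ball reaches
## it. Radii are brute-force minimum distances to the boundary-face
## midpoints of the mask (the surface between voxel centers).
oracle_inscribed_ball_thickness <- function(mask, spacing = 1) {
  d <- dim(mask)
  ## boundary face midpoints
  faces <- NULL
  for (lin in which(mask)) {
    ijk <- lin_to_ijk(lin, d)[1, ]
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- ijk; q[ax] <- q[ax] + s
      outside <- any(q < 0) || any(q >= d) || !mask[q[1] + 1, q[2] + 1, q[3] + 1]
      if (outside) {
        f <- ijk; f[ax] <- f[ax] + s / 2
        faces <- rbind(faces, f)
      }
    }
  }
  interior <- which(mask)
  Pi <- lin_to_ijk(interior, d)
  rad <- vapply(seq_along(interior), function(q)
    sqrt(min(rowSums(sweep(faces, 2, Pi[q, ])^2))), 0.0)
  bl <- which(oracle_boundary(mask))
  Pb <- lin_to_ijk(bl, d)
  th <- vapply(seq_len(nrow(Pb)), function(q) {
    d2 <- rowSums(sweep(Pi, 2, Pb[q, ])^2)
    2 * max(rad[d2 <= (rad + 0.55)^2])
  }, 0.0)
  list(voxel = bl, thickness = th * spacing)
}

## closed-form OLS via explicit normal equations
oracle_ols <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  list(beta = as.numeric(b), se = sqrt(s2 * diag(XtXi)), df = df,
       t = as.numeric(b) / sqrt(s2 * diag(XtXi)))
}

## plain per-voxel majority vote with lowest-id tie-break
oracle_majority <- function(label_volumes, unknown = 99L) {
  votes <- sapply(label_volumes, function(l) as.vector(l$voxels))
  apply(votes, 1, function(v) {
    v <- v[v != unknown]
    if (!length(v)) return(0L)
    tb <- table(v)
    min(as.integer(names(tb)[tb == max(tb)]))
  })
}

## Potts + log-vote energy of a labeling (independent formulation)
oracle_potts_energy <- function(lab_arr, label_volumes, weight, unknown = 99L) {
  d <- dim(lab_arr)
  votes <- sapply(label_volumes, function(l) as.vector(l$voxels))
  ids <- sort(setdiff(unique(as.vector(votes)), unknown))
  if (!0L %in% ids) ids <- c(0L, ids)
  L <- length(ids)
  en <- 0
  lv <- as.vector(lab_arr)
  for (v in seq_along(lv)) {
    vv <- votes[v, ]; vv <- vv[vv != unknown]
    cnt <- sum(vv == lv[v])
    en <- en + log((cnt + 0.5) / (length(vv) + 0.5 * L))
  }
  for (ax in 1:3) {
    str <- c(1, d[1], d[1] * d[2])[ax]
    pos <- ((seq_along(lv) - 1) %/% str) %% d[ax]
    sel <- which(pos < d[ax] - 1)
    en <- en + weight * sum(lv[sel] == lv[sel + str])
  }
  en
}

## ------------------------------------------------------------------
## shared expensive fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(cohort_config(
      n_specimens = 5L, grid_shape = c(48L, 48L, 48L), seed = 11L,
      noise_sd_mm = 0.05, artifact_prob = 0.4))
  }
  .fixtures$cohort
}

fixture_atlas <- function() {
  if (is.null(.fixtures$atlas)) {
    .fixtures$atlas <- build_atlas(fixture_cohort(), verbose = FALSE)
  }
  .fixtures$atlas
}

fixture_surfaces <- function() {
  if (is.null(.fixtures$surfaces)) {
    at <- fixture_atlas()
    cohort <- fixture_cohort()
    names(cohort) <- vapply(cohort, `[[`, "", "id")
    with_sub <- Filter(function(s) s$id %in% names(at$transforms), cohort)
    warped <- lapply(with_sub, warp_subregions_to_template, atlas = at)
    at$template_subregions <- consensus_segmentation(
      warped, mrf_weight = 0.5 * log(2),
      mask = at$template_guide_labels$voxels != 0L)
    .fixtures$atlas <- at
    .fixtures$surfaces <- extract_template_surfaces(at)
  }
  .fixtures$surfaces
}

## a small synthetic flat surface with grid adjacency, for stats tests
## that do not need the full pipeline geometry
fixture_flat_mesh <- function(nu = 20, nv = 15) {
  vid <- function(i, j) (j - 1) * nu + i
  verts <- as.matrix(expand.grid(x = seq_len(nu), y = seq_len(nv)))
  verts <- cbind(verts, 0)
  tris <- NULL
  for (j in seq_len(nv - 1)) for (i in seq_len(nu - 1)) {
    tris <- rbind(tris, c(vid(i, j), vid(i + 1, j), vid(i, j + 1)),
                  c(vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1)))
  }
  surface_mesh(verts, tris, structure_tag = "MTL")
}

## simulate vertex thickness maps directly from the generator's linear
## model on an arbitrary mesh (reduced-scale stats harness)
simulate_thickness_maps <- function(mesh, n, beta_tau, noise_sd, seed,
                                    hotspot_frac = 0.15, beta_age = 0) {
  set.seed(seed)
  V <- nrow(mesh$vertices)
  hot <- rep(FALSE, V)
  hot[mesh$vertices[, 1] <= quantile(mesh$vertices[, 1], hotspot_frac)] <- TRUE
  age <- runif(n, 59, 93)
  tau <- sample(c(0, 0.5, 1, 2, 3), n, TRUE, prob = c(.15, .12, .23, .3, .2))
  tdp <- sample(c(0, 0.5, 1, 2, 3), n, TRUE, prob = c(.55, .15, .18, .08, .04))
  tmaps <- lapply(seq_len(n), function(i) {
    th <- 1.4 - beta_tau * tau[i] * hot - beta_age * (age[i] - mean(age)) +
      rnorm(V, sd = noise_sd)
    thickness_map(pmax(th, 0.05), rep(TRUE, V), sprintf("S%02d", i), "MTL")
  })
  specs <- lapply(seq_len(n), function(i) {
    rs <- rating_set(data.frame(side = rep(c("ipsi", "contra"), each = 3),
                                location = rep(c("ERC", "DG", "CA"), 2),
                                tau = rep(tau[i], 6), tdp43 = rep(tdp[i], 6)))
    list(id = sprintf("S%02d", i), age_years = age[i], ratings = rs)
  })
  list(tmaps = tmaps, specimens = specs, hotspot = hot,
       tau = tau, age = age, tdp = tdp)
}

## count, per template vertex, the specimens that place it inside their
## (core) hotspot patch; vertices are mapped to each specimen's nearest
## tissue voxel (surface vertices round to just-outside voxels otherwise)
hotspot_vertex_votes <- function(at, co, ids, mesh, core = TRUE) {
  votes <- rep(0, nrow(mesh$vertices))
  for (id in ids) {
    s <- co[[id]]
    hv <- mtlatlas:::hotspot_voxels(s, core = core)
    ft <- distance_transform(s$guide_labels$voxels != 0L,
                             s$guide_labels$spacing_mm)$feature
    native <- mtlatlas:::map_points_to_specimen(at, id, mesh$vertices)
    ijk <- round(mtlatlas:::world_to_voxel(s$guide_labels, native))
    d <- dim(hv)
    ijk <- pmin(pmax(ijk, 0), matrix(d - 1, nrow(ijk), 3, byrow = TRUE))
    lin <- 1 + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
    nearest <- ft[lin]
    votes <- votes + (nearest > 0 & hv[pmax(nearest, 1L)])
  }
  votes
}
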