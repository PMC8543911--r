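#' Build the analysis design matrix for a cohort variant
#'
#' Applies the cohort filters used by the thickness analyses (age >= 59,
#' explicit id exclusions, low-TDP subsetting) and assembles the requested
#' covariate columns. The tau analyses model thickness on tau plus age
#' (optionally TDP-43); the TDP analysis models thickness on TDP-43 with
#' age and tau as covariates; the contralateral variant swaps in the
#' contralateral ratings.
#'
#' @param specimens list of [specimen()]s.
#' @param variant one of `"full_age_tdp"`, `"full_age_only"`,
#'   `"low_tdp_age_only"`, `"tdp_effect"`, `"contralateral"`, `"custom"`.
#' @param age_min age filter (default 59; younger cases are excluded as
#'   outliers).
#' @param exclude_ids explicit specimen ids to drop.
#' @return `design_matrix`: `X` (with intercept), `ids`, `pathology`
#'   (tested column name), `variant`.
#' @export
select_cohort <- function(specimens,
                          variant = c("full_age_tdp", "full_age_only",
                                      "low_tdp_age_only", "tdp_effect",
                                      "contralateral", "custom"),
                          age_min = 59, exclude_ids = character()) {
  variant <- match.arg(variant)
  side <- if (variant == "contralateral") "contra" else "ipsi"
  rows <- lapply(specimens, function(s) {
    tau <- tryCatch(as.numeric(average_rating(s$ratings, side, "tau")),
                    error = function(e) NA_real_)
    tdp <- tryCatch(as.numeric(average_rating(s$ratings, side, "tdp43")),
                    error = function(e) NA_real_)
    data.frame(id = s$id, age = s$age_years, tau_avg = tau, tdp_avg = tdp)
  })
  df <- do.call(rbind, rows)
  df <- df[df$age >= age_min & !(df$id %in% exclude_ids), , drop = FALSE]
  if (variant == "low_tdp_age_only") df <- df[!is.na(df$tdp_avg) & df$tdp_avg < 1, , drop = FALSE]
  cols <- switch(variant,
                 full_age_tdp = c("tau_avg", "age", "tdp_avg"),
                 full_age_only = c("tau_avg", "age"),
                 low_tdp_age_only = c("tau_avg", "age"),
                 tdp_effect = c("tdp_avg", "age", "tau_avg"),
                 contralateral = c("tau_avg", "age", "tdp_avg"),
                 custom = c("tau_avg", "age", "tdp_avg"))
  pathology <- cols[1]
  df <- df[stats::complete.cases(df[, cols, drop = FALSE]), , drop = FALSE]
  if (nrow(df) < length(cols) + 2)
    stop("select_cohort: too few specimens after filtering (", nrow(df), ")")
  X <- cbind(intercept = 1, as.matrix(df[, cols, drop = FALSE]))
  rownames(X) <- df$id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    ## name an offending column: one whose removal restores full rank
    for (c in rev(seq_len(ncol(X))[-1])) {
      if (qr(X[, -c, drop = FALSE])$rank == qrX$rank)
        stop("select_cohort: design is rank-deficient; offending column '",
             colnames(X)[c], "'")
    }
    stop("select_cohort: design is rank-deficient")
  }
  structure(list(X = X, ids = df$id, pathology = pathology, variant = variant),
            class = "design_matrix")
}

## stack thickness maps (one per specimen, same structure) into an
## n_specimens x n_vertices matrix with NA at invalid vertices
thickness_matrix <- function(tmaps, ids) {
  by_id <- stats::setNames(tmaps, vapply(tmaps, `[[`, "", "specimen_id"))
  miss <- setdiff(ids, names(by_id))
  if (length(miss)) stop("thickness maps missing for: ", paste(miss, collapse = ", "))
  Y <- t(vapply(ids, function(id) {
    tm <- by_id[[id]]
    out <- tm$thickness_mm
    out[!tm$valid] <- NA_real_
    out
  }, numeric(length(tmaps[[1]]$thickness_mm))))
  Y
}

## per-validity-pattern OLS machinery shared by the GLM and the permutations
glm_patterns <- function(Y, X, test_col, min_extra = 3L) {
  p <- ncol(X)
  valid <- !is.na(Y)
  nv <- colSums(valid)
  usable <- nv >= p + min_extra
  pat_key <- apply(valid, 2, function(v) paste(as.integer(v), collapse = ""))
  pats <- list()
  for (key in unique(pat_key[usable])) {
    verts <- which(pat_key == key & usable)
    rows <- which(valid[, verts[1]])
    XtXi <- solve(crossprod(X[rows, , drop = FALSE]))
    A <- XtXi %*% t(X[rows, , drop = FALSE])
    pats[[key]] <- list(verts = verts, rows = rows, A = A,
                        c_test = XtXi[test_col, test_col],
                        df = length(rows) - p)
  }
  list(patterns = pats, usable = usable, n_per_vertex = nv)
}

pattern_tstats <- function(Y, X, pats, test_col) {
  V <- ncol(Y)
  tstat <- rep(NA_real_, V); beta_all <- matrix(NA_real_, ncol(X), V)
  df_out <- rep(NA_real_, V)
  for (pt in pats$patterns) {
    Yr <- Y[pt$rows, pt$verts, drop = FALSE]
    B <- pt$A %*% Yr
    fit <- X[pt$rows, , drop = FALSE] %*% B
    rss <- colSums((Yr - fit)^2)
    sigma2 <- rss / max(pt$df, 1)
    se <- sqrt(pmax(sigma2 * pt$c_test, 1e-300))
    tstat[pt$verts] <- B[test_col, ] / se
    beta_all[, pt$verts] <- B
    df_out[pt$verts] <- pt$df
  }
  list(t = tstat, beta = beta_all, df = df_out)
}

#' Vertex-wise GLM of thickness on pathology burden
#'
#' Ordinary least squares at every template vertex, available-case over the
#' specimens valid there; a vertex needs at least `ncol(X) + 3` valid
#' specimens. The t statistic and two-sided p refer to the design's
#' pathology column with per-vertex residual degrees of freedom.
#'
#' @param tmaps list of [thickness_map()]s, one per specimen, one structure.
#' @param design a [select_cohort()] result.
#' @return `glm_result`: `beta` (p x V), `t`, `p`, `valid`, `n_per_vertex`,
#'   `df`.
#' @export
fit_vertexwise_glm <- function(tmaps, design) {
  X <- design$X
  Y <- thickness_matrix(tmaps, design$ids)
  test_col <- match(design$pathology, colnames(X))
  pats <- glm_patterns(Y, X, test_col)
  ts <- pattern_tstats(Y, X, pats, test_col)
  pval <- 2 * stats::pt(abs(ts$t), df = ts$df, lower.tail = FALSE)
  structure(list(beta = ts$beta, t = ts$t, p = pval,
                 valid = pats$usable & !is.na(ts$t),
                 n_per_vertex = pats$n_per_vertex, df = ts$df,
                 pathology = design$pathology, design = design),
            class = "glm_result")
}

## connected components of the supra-threshold vertex set, built on the
## (small) induced subgraph only — called once per permutation
cluster_masses <- function(edges, tstat, pval, thr) {
  supra <- which(!is.na(pval) & pval < thr)
  if (!length(supra)) return(list(clusters = list(), mass = numeric(0)))
  idx <- integer(max(c(edges, supra)))
  idx[supra] <- seq_along(supra)
  e <- edges[idx[edges[, 1]] > 0 & idx[edges[, 2]] > 0, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(cbind(idx[e[, 1]], idx[e[, 2]])))
  comp <- igraph::components(g)
  cl <- split(supra, comp$membership)
  list(clusters = cl, mass = vapply(cl, function(v) sum(abs(tstat[v])), 0.0))
}

#' Cluster-level permutation correction (Freedman-Lane)
#'
#' Observed clusters are formed by thresholding the uncorrected p-map on
#' the surface graph; the null distribution of the maximum cluster mass
#' (sum of |t| over the cluster) is built by permuting the residuals of
#' the reduced model (all covariates except the pathology column), adding
#' back the reduced-model fit, and refitting. Corrected
#' p = (1 + #\{null max >= observed mass\}) / (n_permutations + 1).
#'
#' @param tmaps list of [thickness_map()]s.
#' @param design [select_cohort()] result.
#' @param mesh the template [surface_mesh()] providing vertex adjacency
#'   (and optional `subregion` vertex field for anatomical reporting).
#' @param forming_threshold_p two-sided uncorrected threshold (default 0.01).
#' @param n_permutations at least 99 (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @return `cluster_table`: data.frame of clusters (size, mass,
#'   corrected_p, dominant subregion, significant / trend flags), plus the
#'   observed `glm` and permutation metadata.
#' @export
cluster_permutation_correction <- function(tmaps, design, mesh,
                                           forming_threshold_p = 0.01,
                                           n_permutations = 1000L, seed = 1L) {
  stopifnot(n_permutations >= 99)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- design$X
  Y <- thickness_matrix(tmaps, design$ids)
  test_col <- match(design$pathology, colnames(X))
  pats <- glm_patterns(Y, X, test_col)
  obs <- pattern_tstats(Y, X, pats, test_col)
  pobs <- 2 * stats::pt(abs(obs$t), df = obs$df, lower.tail = FALSE)
  edges <- mesh_edges(mesh)
  obs_cl <- cluster_masses(edges, obs$t, pobs, forming_threshold_p)

  ## reduced-model fits and residuals per pattern (Freedman-Lane)
  red <- lapply(pats$patterns, function(pt) {
    Z <- X[pt$rows, -test_col, drop = FALSE]
    Yr <- Y[pt$rows, pt$verts, drop = FALSE]
    H <- Z %*% solve(crossprod(Z)) %*% t(Z)
    list(fit = H %*% Yr, resid = Yr - H %*% Yr)
  })
  n <- nrow(X)
  null_max <- numeric(n_permutations)
  Yp <- Y
  for (b in seq_len(n_permutations)) {
    pi_g <- sample.int(n)
    for (key in names(pats$patterns)) {
      pt <- pats$patterns[[key]]
      ## induced permutation of this pattern's rows, coherent with pi_g
      sub <- pi_g[pi_g %in% pt$rows]
      loc <- match(sub, pt$rows)
      Yp[pt$rows, pt$verts] <- red[[key]]$fit + red[[key]]$resid[loc, , drop = FALSE]
    }
    ts <- pattern_tstats(Yp, X, pats, test_col)
    pv <- 2 * stats::pt(abs(ts$t), df = ts$df, lower.tail = FALSE)
    cm <- cluster_masses(edges, ts$t, pv, forming_threshold_p)
    null_max[b] <- if (length(cm$mass)) max(cm$mass) else 0
  }
  sub_tag <- mesh$vertex_fields$subregion
  tab <- if (length(obs_cl$mass)) {
    data.frame(
      cluster_id = seq_along(obs_cl$mass),
      n_vertices = vapply(obs_cl$clusters, length, 0L),
      mass = obs_cl$mass,
      corrected_p = vapply(obs_cl$mass, function(m)
        (1 + sum(null_max >= m)) / (n_permutations + 1), 0.0),
      dominant_subregion = vapply(obs_cl$clusters, function(v) {
        if (is.null(sub_tag)) return(NA_character_)
        ids <- sub_tag[v]; ids <- ids[ids != 0]
        if (!length(ids)) return(NA_character_)
        names(SUBREGION_LABELS)[match(as.integer(names(which.max(table(ids)))),
                                      SUBREGION_LABELS)]
      }, ""))
  } else {
    data.frame(cluster_id = integer(0), n_vertices = integer(0),
               mass = numeric(0), corrected_p = numeric(0),
               dominant_subregion = character(0))
  }
  tab$significant <- tab$corrected_p < 0.05
  tab$trend <- tab$corrected_p < 0.10
  ord <- order(-tab$mass)
  tab <- tab[ord, , drop = FALSE]
  structure(list(table = tab,
                 clusters = obs_cl$clusters[ord],
                 glm = list(t = obs$t, p = pobs, valid = pats$usable),
                 forming_threshold_p = forming_threshold_p,
                 n_permutations = n_permutations, seed = seed,
                 null_max = null_max),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d clusters (threshold p<%g, %d permutations)\n",
              nrow(x$table), x$forming_threshold_p, x$n_permutations))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Region-level correlation of NFT burden with median thickness
#'
#' For each hotspot region, Pearson correlation between the per-specimen
#' mean NFT density over the region's voxel support and the per-specimen
#' median thickness over the region's surface vertices; optionally the
#' partial correlation controlling for age (both variables residualized on
#' age, with degrees of freedom n - 3).
#'
#' @param nft_maps named list (by specimen id) of [image_volume()] NFT
#'   density maps in template space.
#' @param tmaps list of [thickness_map()]s in template space.
#' @param hotspot_regions named list; each entry has `voxels` (logical
#'   array) and `vertices` (indices into the template surface).
#' @param ages optional named numeric vector of ages for the partial
#'   correlation.
#' @return data.frame (region, n, r, p, r_partial_age, p_partial_age).
#' @export
region_summary_correlation <- function(nft_maps, tmaps, hotspot_regions,
                                       ages = NULL) {
  ids <- intersect(names(nft_maps),
                   vapply(tmaps, `[[`, "", "specimen_id"))
  if (length(ids) < 4) stop("region_summary_correlation: need >= 4 specimens")
  by_id <- stats::setNames(tmaps, vapply(tmaps, `[[`, "", "specimen_id"))
  out <- NULL
  for (rn in names(hotspot_regions)) {
    reg <- hotspot_regions[[rn]]
    nft <- vapply(ids, function(id) mean(nft_maps[[id]]$voxels[reg$voxels]), 0.0)
    thick <- vapply(ids, function(id) {
      tm <- by_id[[id]]
      v <- reg$vertices[tm$valid[reg$vertices]]
      if (!length(v)) return(NA_real_)
      stats::median(tm$thickness_mm[v])
    }, 0.0)
    ok <- stats::complete.cases(nft, thick)
    nft <- nft[ok]; thick <- thick[ok]
    if (stats::sd(nft) == 0 || stats::sd(thick) == 0)
      stop("region_summary_correlation: constant input vector in region ", rn)
    ct <- stats::cor.test(nft, thick)
    rp <- pp <- NA_real_
    if (!is.null(ages)) {
      a <- ages[ids[ok]]
      rn_ <- stats::resid(stats::lm(nft ~ a))
      rt_ <- stats::resid(stats::lm(thick ~ a))
      r2 <- sum(rn_ * rt_) / sqrt(sum(rn_^2) * sum(rt_^2))
      dfp <- length(a) - 3
      tv <- r2 * sqrt(dfp / max(1 - r2^2, 1e-12))
      rp <- r2; pp <- 2 * stats::pt(abs(tv), dfp, lower.tail = FALSE)
    }
    out <- rbind(out, data.frame(region = rn, n = sum(ok),
                                 r = unname(ct$estimate), p = ct$p.value,
                                 r_partial_age = rp, p_partial_age = pp))
  }
  out
}
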