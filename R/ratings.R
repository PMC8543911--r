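#' Semi-quantitative pathology rating set
#'
#' Ordinal tau and TDP-43 severity ratings on the 5-point scale
#' {0 none, 0.5 rare, 1 mild, 2 moderate, 3 severe}, assessed at three MTL
#' locations (ERC, DG, CA) on the scanned (ipsilateral) and opposite
#' (contralateral) hemispheres. Missing entries are `NA`.
#'
#' @param table data.frame with columns `side` (`ipsi`/`contra`),
#'   `location` (`ERC`/`DG`/`CA`), `tau`, `tdp43`.
#' @export
rating_set <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("side", "location", "tau", "tdp43") %in% names(table)))
  if (!all(table$side %in% c("ipsi", "contra")))
    stop("rating_set: side must be 'ipsi' or 'contra'")
  if (!all(table$location %in% c("ERC", "DG", "CA")))
    stop("rating_set: location must be ERC, DG or CA")
  for (col in c("tau", "tdp43")) {
    v <- table[[col]]
    if (!all(is.na(v) | v %in% RATING_SCALE))
      stop("rating_set: ", col, " ratings must lie on {0, 0.5, 1, 2, 3}")
  }
  structure(list(table = table), class = "rating_set")
}

#' Map a verbal severity grade to its numeric rating
#'
#' @param grade one of "none", "rare", "mild", "moderate", "severe".
#' @export
rating_from_grade <- function(grade) {
  m <- c(none = 0, rare = 0.5, mild = 1, moderate = 2, severe = 3)
  out <- m[match(grade, names(m))]
  if (any(is.na(out))) stop("rating_from_grade: unknown grade")
  unname(out)
}

#' Average pathology rating across the three MTL locations
#'
#' The mean of the non-missing location ratings for one side and pathology;
#' this is the per-specimen general burden measure used throughout the
#' thickness analyses.
#'
#' @param ratings a [rating_set()].
#' @param side `"ipsi"` or `"contra"`.
#' @param pathology `"tau"` or `"tdp43"`.
#' @return scalar mean; attribute `n_missing` reports missing locations.
#' @export
average_rating <- function(ratings, side = "ipsi", pathology = c("tau", "tdp43")) {
  pathology <- match.arg(pathology)
  df <- ratings$table
  v <- df[[pathology]][df$side == side]
  if (length(v) == 0 || all(is.na(v)))
    stop("average_rating: all three locations missing for ", side, "/", pathology)
  out <- mean(v, na.rm = TRUE)
  attr(out, "n_missing") <- sum(is.na(v))
  out
}

both_sides_avg <- function(ratings, pathology) {
  df <- ratings$table
  f <- function(s) {
    v <- df[[pathology]][df$side == s]
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  c(ipsi = f("ipsi"), contra = f("contra"))
}

#' Bland-Altman agreement of ipsilateral vs contralateral ratings
#'
#' Per specimen, the difference (ipsi - contra) of the average rating is
#' plotted against the two-side mean; the summary reports the mean
#' difference and limits of agreement at mean +/- 2 SD.
#'
#' @param ratings_list list of [rating_set()]s (or specimens with a
#'   `$ratings` entry); an optional `ftld` logical attribute/field per
#'   specimen is carried through.
#' @param pathology `"tau"` or `"tdp43"`.
#' @return `bland_altman_result`: data.frame `per_specimen` (mean, diff,
#'   ftld) and `summary` (mean_diff, lower, upper, sd_diff, n).
#' @export
bland_altman <- function(ratings_list, pathology = c("tau", "tdp43")) {
  pathology <- match.arg(pathology)
  rows <- lapply(seq_along(ratings_list), function(i) {
    x <- ratings_list[[i]]
    rs <- if (inherits(x, "rating_set")) x else x$ratings
    av <- both_sides_avg(rs, pathology)
    data.frame(id = if (!is.null(x$id)) x$id else as.character(i),
               mean = mean(av), diff = av[["ipsi"]] - av[["contra"]],
               ftld = isTRUE(x$ftld))
  })
  per <- do.call(rbind, rows)
  per <- per[stats::complete.cases(per[, c("mean", "diff")]), ]
  if (nrow(per) < 2) stop("bland_altman: fewer than 2 complete ipsi/contra pairs")
  m <- mean(per$diff); s <- stats::sd(per$diff)
  structure(list(per_specimen = per,
                 summary = data.frame(mean_diff = m, lower = m - 2 * s,
                                      upper = m + 2 * s, sd_diff = s,
                                      n = nrow(per))),
            class = "bland_altman_result")
}

#' Count specimens with asymmetric pathology ratings
#'
#' Specimens whose |ipsi - contra| average rating difference strictly
#' exceeds `threshold`; the fraction is over specimens with both sides
#' available, with display rounding to a whole percent.
#'
#' @inheritParams bland_altman
#' @param threshold strict cutoff on the absolute difference (default 1).
#' @return list(count, fraction, percent_display, n).
#' @export
asymmetry_count <- function(ratings_list, pathology = c("tau", "tdp43"),
                            threshold = 1) {
  pathology <- match.arg(pathology)
  stopifnot(threshold > 0)
  diffs <- vapply(ratings_list, function(x) {
    rs <- if (inherits(x, "rating_set")) x else x$ratings
    av <- both_sides_avg(rs, pathology)
    av[["ipsi"]] - av[["contra"]]
  }, 0.0)
  diffs <- diffs[!is.na(diffs)]
  count <- sum(abs(diffs) > threshold)
  frac <- if (length(diffs)) count / length(diffs) else NA_real_
  list(count = count, fraction = frac,
       percent_display = if (is.na(frac)) NA else round(100 * frac),
       n = length(diffs))
}

#' Cohort demographic and pathology summary
#'
#' n, mean +/- SD of average ipsilateral tau and TDP-43 ratings, age
#' summaries, and the fraction of specimens with Braak-equivalent tau
#' involvement (a `braak_ge1` field where provided). SD of a single
#' specimen is reported as 0 by convention.
#'
#' @param specimens list of specimens.
#' @return one-row data.frame.
#' @export
cohort_summary <- function(specimens) {
  stopifnot(length(specimens) >= 1)
  tau <- vapply(specimens, function(s) as.numeric(average_rating(s$ratings, "ipsi", "tau")), 0.0)
  tdp <- vapply(specimens, function(s) as.numeric(average_rating(s$ratings, "ipsi", "tdp43")), 0.0)
  age <- vapply(specimens, function(s) s$age_years, 0.0)
  braak <- vapply(specimens, function(s) isTRUE(s$braak_ge1), NA)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  data.frame(n = length(specimens),
             tau_mean = mean(tau), tau_sd = sd0(tau),
             tdp_mean = mean(tdp), tdp_sd = sd0(tdp),
             age_mean = mean(age), age_min = min(age), age_max = max(age),
             braak_ge1_frac = if (all(is.na(braak))) NA_real_ else mean(braak, na.rm = TRUE))
}
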