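#' Pipeline configuration
#'
#' One JSON-serializable object holding every tunable of the end-to-end
#' chain; unknown keys are rejected so configs stay trustworthy, and the
#' effective config is always echoed into the run report (no silent
#' defaults).
#'
#' @param out_dir output directory.
#' @param cohort named list of [cohort_config()] arguments.
#' @param registration named list of [registration_params()] arguments.
#' @param morphometry list(prune_ratio, capture_radius_vox).
#' @param stats list(variant, forming_threshold_p, n_permutations).
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @param write_volumes write NIfTI/VTK artifacts (disable for quick runs).
#' @export
pipeline_config <- function(out_dir = "mtlatlas_out",
                            cohort = list(n_specimens = 8L, grid_shape = c(48L, 48L, 48L)),
                            registration = list(),
                            morphometry = list(prune_ratio = 1.6, capture_radius_vox = 3),
                            stats = list(variant = "full_age_tdp",
                                         forming_threshold_p = 0.01,
                                         n_permutations = 500L),
                            seed = 1L, write_volumes = TRUE) {
  cfg <- list(out_dir = out_dir, cohort = cohort, registration = registration,
              morphometry = morphometry, stats = stats, seed = as.integer(seed),
              write_volumes = write_volumes,
              version = as.character(utils::packageVersion("mtlatlas")))
  validate_config_keys(cfg$cohort, names(formals(cohort_config)), "cohort")
  validate_config_keys(cfg$registration, names(formals(registration_params)), "registration")
  validate_config_keys(cfg$morphometry, c("prune_ratio", "capture_radius_vox"), "morphometry")
  validate_config_keys(cfg$stats, c("variant", "forming_threshold_p", "n_permutations"),
                       "stats")
  structure(cfg, class = "pipeline_config")
}

validate_config_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("pipeline_config: unknown ", where, " keys: ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' @param path JSON path.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  top <- setdiff(names(x), c(names(formals(pipeline_config)), "version"))
  if (length(top)) stop("read_pipeline_config: unknown keys: ", paste(top, collapse = ", "))
  args <- x[intersect(names(x), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' @param config a `pipeline_config`.
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

stage_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 10000L + k

#' Run the full analysis pipeline
#'
#' simulate -> build-atlas -> consensus -> thickness -> glm -> agreement.
#' Every stage logs its key metrics into a machine-readable report
#' (`report.json` under `out_dir`); a stage failure marks the stage failed
#' and skips everything downstream.
#'
#' @param config [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return the report, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[3]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = unclass(config), stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      say("stage %s FAILED: %s", name, conditionMessage(res))
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     wall_s = round(proc.time()[3] - t0, 2))
      failed <<- TRUE
      return(NULL)
    }
    report$stages[[name]] <<- c(list(status = "ok",
                                     wall_s = round(proc.time()[3] - t0, 2)),
                                res$metrics)
    say("stage %s ok (%.1fs)", name, proc.time()[3] - t0)
    res$value
  }

  ## simulate
  cohort <- run_stage("simulate", function() {
    args <- config$cohort
    args$seed <- stage_seed(config$seed, 1L)
    cc <- do.call(cohort_config, args)
    sp <- generate_cohort(cc)
    if (config$write_volumes) {
      cdir <- file.path(config$out_dir, "cohort")
      dir.create(cdir, showWarnings = FALSE)
      for (s in sp) {
        write_volume(s$image, file.path(cdir, paste0(s$id, "_img.nii.gz")))
        write_volume(s$guide_labels, file.path(cdir, paste0(s$id, "_guide.nii.gz")))
        if (!is.null(s$subregion_labels))
          write_volume(s$subregion_labels, file.path(cdir, paste0(s$id, "_subregions.nii.gz")))
      }
      write_ratings_csv(sp, file.path(cdir, "ratings.csv"))
    }
    names(sp) <- vapply(sp, `[[`, "", "id")
    list(value = sp, metrics = list(n_specimens = length(sp),
                                    n_type2 = sum(vapply(sp, `[[`, 0L, "sulcus_type") == 2L)))
  })

  atlas <- run_stage("build_atlas", function() {
    params <- do.call(registration_params, config$registration)
    at <- build_atlas(cohort, params, seed = stage_seed(config$seed, 2L),
                      verbose = verbose)
    if (config$write_volumes) {
      adir <- file.path(config$out_dir, "atlas")
      dir.create(adir, showWarnings = FALSE)
      write_volume(at$template_image, file.path(adir, "template.nii.gz"))
      write_volume(at$template_guide_labels, file.path(adir, "template_guide.nii.gz"))
      for (id in names(at$transforms)) {
        write_deformation_field(at$transforms[[id]]$fwd,
                                file.path(adir, sprintf("warp_%s_fwd.nii.gz", id)))
        write_deformation_field(at$transforms[[id]]$inv,
                                file.path(adir, sprintf("warp_%s_inv.nii.gz", id)))
        write_affine(at$transforms[[id]]$affine,
                     file.path(adir, sprintf("affine_%s.txt", id)))
      }
      jsonlite::write_json(at$provenance, file.path(adir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(value = at,
         metrics = list(dice_by_stage = as.list(at$provenance$dice_by_stage),
                        excluded = at$provenance$excluded))
  })

  run_stage("consensus", function() {
    with_sub <- Filter(function(s) !is.null(s$subregion_labels) &&
                         s$id %in% names(atlas$transforms), cohort)
    warped <- lapply(with_sub, warp_subregions_to_template, atlas = atlas)
    cons <- consensus_segmentation(
      warped, mrf_weight = 0.5 * log(2),
      mask = atlas$template_guide_labels$voxels != 0L)
    atlas$template_subregions <<- cons
    if (config$write_volumes)
      write_volume(cons, file.path(config$out_dir, "atlas", "template_subregions.nii.gz"))
    list(value = cons,
         metrics = list(n_inputs = length(warped),
                        energy_final = utils::tail(attr(cons, "energy"), 1)))
  })

  surf_th <- run_stage("thickness", function() {
    surfaces <- extract_template_surfaces(atlas)
    tmaps <- list()
    for (tag in c("MTL", "SRLM")) {
      tmaps[[tag]] <- lapply(cohort[names(atlas$transforms)], function(s)
        sample_specimen_thickness(s, atlas, surfaces[[tag]],
                                  capture_radius_vox = config$morphometry$capture_radius_vox,
                                  prune_ratio = config$morphometry$prune_ratio))
    }
    if (config$write_volumes) {
      write_mesh_vtk(surfaces$MTL, file.path(config$out_dir, "surface_MTL.vtk"))
      write_mesh_vtk(surfaces$SRLM, file.path(config$out_dir, "surface_SRLM.vtk"))
      rows <- do.call(rbind, lapply(c("MTL", "SRLM"), function(tag)
        do.call(rbind, lapply(tmaps[[tag]], function(tm)
          data.frame(vertex_id = seq_along(tm$thickness_mm) - 1L,
                     specimen_id = tm$specimen_id, structure = tag,
                     thickness_mm = tm$thickness_mm, valid = tm$valid)))))
      utils::write.csv(rows, file.path(config$out_dir, "thickness.csv"), row.names = FALSE)
    }
    vf <- mean(vapply(tmaps$MTL, function(tm) mean(tm$valid), 0.0))
    list(value = list(surfaces = surfaces, tmaps = tmaps),
         metrics = list(n_vertices_mtl = nrow(surfaces$MTL$vertices),
                        n_vertices_srlm = nrow(surfaces$SRLM$vertices),
                        mean_valid_fraction_mtl = round(vf, 4)))
  })

  glm_res <- run_stage("glm", function() {
    design <- select_cohort(cohort[names(atlas$transforms)],
                            variant = config$stats$variant)
    ct <- cluster_permutation_correction(
      surf_th$tmaps$MTL, design, surf_th$surfaces$MTL,
      forming_threshold_p = config$stats$forming_threshold_p,
      n_permutations = config$stats$n_permutations,
      seed = stage_seed(config$seed, 5L))
    if (config$write_volumes)
      utils::write.csv(ct$table, file.path(config$out_dir, "clusters_MTL.csv"),
                       row.names = FALSE)
    list(value = ct,
         metrics = list(n_clusters = nrow(ct$table),
                        n_significant = sum(ct$table$significant),
                        cluster_table = ct$table))
  })

  run_stage("agreement", function() {
    ba <- bland_altman(cohort, "tau")
    asym <- asymmetry_count(cohort, "tau", threshold = 1)
    summ <- cohort_summary(cohort)
    if (config$write_volumes) {
      utils::write.csv(ba$per_specimen, file.path(config$out_dir, "bland_altman_tau.csv"),
                       row.names = FALSE)
      utils::write.csv(summ, file.path(config$out_dir, "cohort_summary.csv"),
                       row.names = FALSE)
    }
    list(value = list(ba = ba, asym = asym, summary = summ),
         metrics = list(mean_diff = ba$summary$mean_diff,
                        loa = c(ba$summary$lower, ba$summary$upper),
                        asymmetry_count = asym$count,
                        asymmetry_percent = asym$percent_display,
                        cohort_summary = summ))
  })

  report$ok <- !failed
  report$wall_s <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
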