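#' Stem ROI at a designed phantom stem location
#'
#' Builds the single-slice stem mask for a phantom tract design: a
#' `(2 pad + 1)^2` voxel window centered on the stem-center voxel, in-plane
#' with the tract's stem orientation. This plays the role of the manually
#' drawn ROI that strictly encompasses the exposed stem; because the
#' simulator funnels all tract streamlines through the central voxel and
#' routes the claustro-cortical bypass decoys far from it, the default
#' 1-voxel pad encloses the stem and excludes the bypass.
#'
#' @param atlas Phantom atlas from [build_phantom_atlas()].
#' @param tract_design One element of [default_tracts()].
#' @param hemisphere `"left"` or `"right"`.
#' @param pad In-plane padding in voxels.
#' @param operator Operator tag stored on the ROI.
#' @return A [stem_roi()].
#' @export
phantom_stem_roi <- function(atlas, tract_design, hemisphere, pad = 1L,
                             operator = "designed") {
  center <- tract_design$stem_center[[hemisphere]]
  v <- floor(drop(world_to_voxel(matrix(center, ncol = 3), atlas$affine)) + 0.5)
  axis <- orientation_axis(tract_design$orientation)
  inplane <- setdiff(1:3, axis)
  offs <- expand.grid(a = -pad:pad, b = -pad:pad)
  vox <- matrix(rep(v, each = nrow(offs)), ncol = 3)
  vox[, inplane[1]] <- vox[, inplane[1]] + offs$a
  vox[, inplane[2]] <- vox[, inplane[2]] + offs$b
  stem_roi(voxels = vox, grid_dim = dim(atlas$grid), affine = atlas$affine,
           orientation = tract_design$orientation,
           tract_tag = tract_design$name, hemisphere = hemisphere,
           operator = operator)
}

default_pipeline_config <- function() {
  list(n_subjects = 10L, seed = 1L, n_per_hemisphere = 200L,
       broken_fraction = 0.2,
       decoys = list(short = 50L, gm_confined = 40L, u_fiber = 30L,
                     cerebellar = 20L, interhemispheric = 10L,
                     stem_bypass = 100L),
       alpha = 0.05, min_length_mm = 10, tracts = c("IFOF", "UF"))
}

#' Run the full stem-based dissection pipeline on a simulated cohort
#'
#' Sequences every stage end to end: phantom atlas construction and modal
#' dilation, cohort simulation, per-subject tractogram preparation (with
#' removal tallies), stem-based extraction per tract and hemisphere (with
#' extraction tallies), termination tallies, cohort NTDS, false-positive
#' thresholding, adjusted scores, presence percentages, territory tests and
#' asymmetry tests. All tables are written as TSV, a machine-readable JSON
#' summary and a log of every tally are written alongside, and the resolved
#' configuration is copied into the run directory. Deterministic given the
#' configuration and seed.
#'
#' @param config A named list (missing entries take defaults: 10 subjects,
#'   200 streamlines per tract and hemisphere, broken fraction 0.2, default
#'   decoy counts, alpha 0.05) or the path to a YAML/JSON file of the same.
#' @param out_dir Output run directory (created; must not exist unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the run summary (also written as JSON).
#' @export
run_pipeline <- function(config = list(), out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  if (dir.exists(out_dir) && !overwrite) {
    stop("output directory exists: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logit <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  logit("building phantom atlas")
  spec <- stage("atlas", phantom_spec())
  atlas <- stage("atlas", build_phantom_atlas(spec))
  dilated <- stage("dilate", modal_dilate(atlas, 1L))
  tracts <- default_tracts(spec, n_per_hemisphere = cfg$n_per_hemisphere)
  tracts <- tracts[cfg$tracts]
  cohort <- stage("cohort", cohort_spec(
    spec, n_subjects = cfg$n_subjects, seed = cfg$seed, tracts = tracts,
    broken_fraction = cfg$broken_fraction,
    decoys = unlist(cfg$decoys)))
  params <- prep_params(min_length_mm = cfg$min_length_mm)

  prep_tallies <- list()
  extract_tallies <- list()
  tallies <- stats::setNames(vector("list", length(tracts)), names(tracts))
  for (tn in names(tracts)) tallies[[tn]] <- vector("list", cfg$n_subjects)

  for (s in seq_len(cfg$n_subjects)) {
    logit("subject ", s, ": simulating")
    sim <- stage("simulate", simulate_subject(atlas, cohort, s))
    prep <- stage("prepare", prepare_tractogram(sim$tractogram, atlas, dilated,
                                                params))
    logit("subject ", s, ": removed ",
          paste(prep$tally$rule, prep$tally$n_removed, sep = "=",
                collapse = ", "))
    prep_tallies[[s]] <- dplyr::mutate(prep$tally, subject = s,
                                       .before = 1)
    for (tn in names(tracts)) {
      tr <- tracts[[tn]]
      rules <- default_extraction_rules(atlas, tn)
      eps <- list()
      for (h in c("left", "right")) {
        stem <- phantom_stem_roi(atlas, tr, h)
        ex <- stage("extract", extract_tract(sim$tractogram, stem, rules,
                                             atlas, dilated))
        logit("subject ", s, ": ", tn, " ", h, " ",
              paste(ex$tally$outcome, ex$tally$n, sep = "=", collapse = ", "))
        extract_tallies[[length(extract_tallies) + 1L]] <-
          dplyr::mutate(ex$tally, subject = s, tract = tn, hemisphere = h,
                        .before = 1)
        eps[[h]] <- ex$endpoints
      }
      tallies[[tn]][[s]] <- tally_terminations(dplyr::bind_rows(eps),
                                               atlas$table)
    }
  }

  readr::write_tsv(dplyr::bind_rows(prep_tallies),
                   file.path(out_dir, "prepare_tally.tsv"))
  readr::write_tsv(dplyr::bind_rows(extract_tallies),
                   file.path(out_dir, "extraction_tally.tsv"))

  summary <- list(config = cfg, tracts = list())
  for (tn in names(tracts)) {
    logit("cohort statistics: ", tn)
    ntds <- stage("ntds", compute_ntds(tallies[[tn]]))
    thr <- stage("threshold", fp_threshold(ntds, tracts[[tn]]$fp_region))
    adj <- adjust_ntds(ntds, thr)
    presence <- presence_percentages(adj)
    terr <- stage("territory", territory_test(adj, alpha = cfg$alpha))
    ai <- asymmetry_table(ntds)
    ai_test <- stage("asymmetry", asymmetry_test(ai, alpha = cfg$alpha))
    readr::write_tsv(ntds, file.path(out_dir, paste0("ntds_", tn, ".tsv")))
    readr::write_tsv(adj, file.path(out_dir, paste0("adjusted_", tn, ".tsv")))
    readr::write_tsv(presence, file.path(out_dir, paste0("presence_", tn, ".tsv")))
    readr::write_tsv(terr, file.path(out_dir, paste0("territories_", tn, ".tsv")))
    readr::write_tsv(ai_test, file.path(out_dir, paste0("asymmetry_", tn, ".tsv")))
    summary$tracts[[tn]] <- list(
      fp_region = attr(thr, "fp_region"),
      threshold = thr$threshold[1],
      n_territories = sum(terr$territory),
      territories = paste(terr$region[terr$territory],
                          terr$hemisphere[terr$territory]),
      n_significant_asymmetries = sum(ai_test$significant))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logit("pipeline complete: ", out_dir)
  invisible(summary)
}

#' Default extraction rules for a phantom tract
#'
#' IFOF: exclude streamlines traversing the temporal pole. UF: exclude
#' streamlines with any point posterior to a coronal plane behind the stem
#' (too posteriorly oriented). Both discard insula and subcortical
#' terminations from analysis and retain broken streamlines.
#'
#' @param atlas Phantom atlas (for label lookup and stem geometry).
#' @param tract `"IFOF"` or `"UF"`.
#' @return An [extraction_rules()].
#' @export
default_extraction_rules <- function(atlas, tract = c("IFOF", "UF")) {
  tract <- match.arg(tract)
  if (tract == "IFOF") {
    tpo <- atlas$table$id[atlas$table$name == "TPO"]
    extraction_rules(exclusion_labels = tpo)
  } else {
    # UF streamlines hook forward; anything reaching far posterior is not UF.
    # The phantom UF never goes posterior of the posterior CGM face, so the
    # plane sits just behind it.
    extraction_rules(exclusion_plane = list(axis = "y", coordinate = -72,
                                            side = "posterior"))
  }
}
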