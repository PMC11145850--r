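## End-to-end pipeline: mask -> tile -> QC -> stain normalisation ->
## (tumour-mask restriction in resection mode) -> tile scoring -> patient
## aggregation -> Youden calibration -> evaluation -> survival. Biopsy mode
## tiles with 75% overlap and aggregates at the 99th percentile; resection
## mode tiles without overlap, restricts tiles to an externally supplied
## tumour mask, and aggregates at the 75th percentile.

#' Pipeline configuration
#'
#' @param mode `"biopsy"` or `"resection"`. Biopsy mode defaults to 75%
#'   tile overlap, resection mode enforces no overlap and requires tumour
#'   masks.
#' @param mask a [mask_config()].
#' @param tiles a [tile_config()]; its `overlap` defaults by mode.
#' @param stain a [stain_config()].
#' @param aggregation an [aggregation_config()]; percentile defaults by
#'   mode.
#' @param scorer a scorer function, a list of scorer functions (ensemble),
#'   or a registered scorer name.
#' @param calibration_grades which grade column calibrates the Youden
#'   threshold: `"resection"` (default, mirroring calibration against the
#'   resected-tumour grade) or `"biopsy"`. Only patients graded NHG1 or
#'   NHG3 there enter calibration; the threshold is then applied to all
#'   patients including NHG2 and ungraded.
#' @param min_tumour_coverage minimum tumour-mask coverage per tile in
#'   resection mode.
#' @param seed master seed for every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("biopsy", "resection"),
                            mask = mask_config(),
                            tiles = NULL,
                            stain = stain_config(),
                            aggregation = NULL,
                            scorer = "oracle",
                            calibration_grades = c("resection", "biopsy"),
                            min_tumour_coverage = 0.5,
                            seed = 1) {
  mode <- match.arg(mode)
  calibration_grades <- match.arg(calibration_grades)
  tiles <- tiles %||% tile_config(overlap = if (mode == "biopsy") 0.75 else 0)
  aggregation <- aggregation %||% aggregation_config(mode)
  if (mode == "resection" && tiles$overlap != 0)
    stop_config("tiles$overlap", "must be 0 in resection mode")
  structure(list(mode = mode, mask = mask, tiles = tiles, stain = stain,
                 aggregation = aggregation, scorer = scorer,
                 calibration_grades = calibration_grades,
                 min_tumour_coverage = min_tumour_coverage, seed = seed),
            class = "pipeline_config")
}

## content checksum used in run manifests (stable across sessions)
obj_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

resolve_ensemble <- function(scorer) {
  if (is.character(scorer)) scorer <- get_scorer(scorer)
  if (is.function(scorer)) scorer <- list(scorer)
  stopifnot(all(vapply(scorer, is.function, TRUE)))
  scorer
}

with_stage <- function(stage, item, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed on '%s': %s",
                 stage, item, conditionMessage(e)), call. = FALSE))
}

#' Restrict tiles to an external tumour mask
#'
#' In resection mode only the tiles lying in invasive cancer regions are
#' kept; the region mask comes from an external segmentation (a mask file
#' per slide), not from this package. A tile is kept iff its footprint's
#' mask coverage is at least `min_coverage`.
#'
#' @param tiles list of `wsi_tile`.
#' @param masks named list (by slide id) of lists with `grid` (logical
#'   matrix) and `downsample` (integer scale to level-0).
#' @param min_coverage minimum footprint coverage (default 0.5).
#' @return the kept tiles.
#' @export
intersect_tumour_mask <- function(tiles, masks, min_coverage = 0.5) {
  keep <- vapply(tiles, function(t) {
    m <- masks[[t$slide_id]]
    if (is.null(m))
      stop(sprintf("missing tumour mask for slide '%s'", t$slide_id))
    footprint_coverage(m$grid, m$downsample, t$x, t$y, t$foot) >= min_coverage
  }, logical(1))
  tiles[keep]
}

## One slide through mask -> tile -> QC -> stain-norm; returns normalised
## kept tiles plus stage bookkeeping.
process_slide <- function(slide, config) {
  mask <- with_stage("tissue_mask", slide$slide_id,
                     compute_tissue_mask(slide, config$mask))
  org <- with_stage("tile_enumeration", slide$slide_id,
                    enumerate_tile_origins(mask, config$tiles,
                                           native_mpp = slide$mpp))
  tiles <- lapply(seq_len(nrow(org)), function(i)
    extract_tile(slide, c(org$x[i], org$y[i]), config$tiles,
                 coverage = org$coverage[i]))
  kept <- with_stage("qc_filter", slide$slide_id,
                     qc_filter(tiles, config$tiles))
  normalized <- kept
  if (length(kept) > 0) {
    prof <- with_stage("stain_estimation", slide$slide_id,
                       estimate_stain_profile(kept, config$stain,
                                              seed = derive_seed(config$seed,
                                                                 slide$slide_id)))
    normalized <- lapply(kept, normalize_tile, source = prof,
                         reference = config$stain$reference_profile)
  } else prof <- NULL
  list(mask = mask,
       manifest = tile_manifest(tiles,
                                kept = vapply(tiles, `[[`, numeric(1),
                                              "lap_var") >= config$tiles$min_lap_var),
       tiles = normalized, stain_profile = prof)
}

#' Run the full pipeline on a cohort
#'
#' Executes every stage in order on all slides, aggregates tile scores per
#' patient, calibrates the Youden threshold on the configured calibration
#' grades (NHG1 vs NHG3), assigns risk groups to every scored patient,
#' evaluates agreement on the calibration cohort, and fits the risk-group
#' survival model. Rerunning with an identical config and cohort reproduces
#' identical outputs.
#'
#' @param cohort list with `slides` (list of `slide_image`, each carrying
#'   `patient_id`) and `clinical` (the clinical table), as produced by
#'   [generate_cohort()].
#' @param config a [pipeline_config()].
#' @param tumour_masks named list of tumour masks (resection mode only); see
#'   [intersect_tumour_mask()].
#' @return object of class `wsi_run`: list with `config`, `threshold`,
#'   `tile_manifest`, `tile_scores`, `patient_scores`, `calls`,
#'   `evaluation`, `survival`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         tumour_masks = NULL) {
  stopifnot(length(cohort$slides) >= 1, is.data.frame(cohort$clinical))
  if (config$mode == "resection" && is.null(tumour_masks))
    stop("resection mode requires tumour masks")
  ensemble <- resolve_ensemble(config$scorer)

  manifests <- list()
  scores <- list()
  slide_sums <- list()
  with_seed(derive_seed(config$seed, "pipeline"), {
    for (sl in cohort$slides) {
      ps <- process_slide(sl, config)
      tiles <- ps$tiles
      if (config$mode == "resection" && length(tiles) > 0)
        tiles <- with_stage("tumour_mask_intersection", sl$slide_id,
                            intersect_tumour_mask(tiles, tumour_masks,
                                                  config$min_tumour_coverage))
      sc <- if (length(tiles) > 0)
        with_stage("tile_scoring", sl$slide_id, score_tiles(tiles, ensemble))
      else data.frame(slide_id = character(), x = integer(), y = integer(),
                      p_high = numeric())
      if (nrow(sc) > 0) sc$patient_id <- sl$patient_id
      manifests[[sl$slide_id]] <- ps$manifest
      scores[[sl$slide_id]] <- sc
      slide_sums[[sl$slide_id]] <-
        list(n_candidates = nrow(ps$manifest),
             n_kept = length(ps$tiles), n_scored = nrow(sc),
             tissue_fraction = ps$mask$tissue_fraction)
    }
  })
  tile_scores <- do.call(rbind, scores[vapply(scores, nrow, 0L) > 0])
  if (is.null(tile_scores) || nrow(tile_scores) == 0)
    stop("pipeline stage 'aggregation' failed: no QC-passing tiles in cohort")

  agg <- config$aggregation
  patient_scores <- do.call(rbind, lapply(split(tile_scores,
                                                tile_scores$patient_id),
    function(d) data.frame(patient_id = d$patient_id[1],
                           n_tiles = nrow(d),
                           score = aggregate_patient_score(d$p_high, agg),
                           stringsAsFactors = FALSE)))
  rownames(patient_scores) <- NULL

  ## Youden calibration on the configured NHG1/NHG3 cohort
  grade_col <- paste0(config$calibration_grades, "_nhg")
  clin <- cohort$clinical
  cal <- merge(patient_scores, clin[, c("patient_id", grade_col)],
               by = "patient_id")
  cal <- cal[!is.na(cal[[grade_col]]) & cal[[grade_col]] %in% c(1, 3), ]
  if (length(unique(cal[[grade_col]])) < 2)
    stop("pipeline stage 'calibration' failed: need both NHG1 and NHG3 ",
         "patients in the calibration cohort")
  cal_labels <- as.integer(cal[[grade_col]] == 3)
  thr <- with_stage("calibration", grade_col,
                    youden_threshold(cal$score, cal_labels))
  agg$threshold <- thr
  calls <- call_patients(patient_scores, agg)

  ## evaluation on the calibration cohort
  cal_calls <- calls$risk_group[match(cal$patient_id, calls$patient_id)]
  evaluation <- with_stage("evaluation", grade_col, {
    roc <- roc_auc(cal$score, cal_labels)
    ct <- confusion_table(ifelse(cal_labels == 1, "high", "low"), cal_calls)
    list(roc = roc, threshold = thr, confusion = ct,
         kappa = cohens_kappa(ct), agreement = agreement_stats(ct),
         n_calibration = nrow(cal))
  })

  ## survival of the risk groups
  records <- merge(clin, calls[, c("patient_id", "risk_group")],
                   by = "patient_id")
  surv <- with_stage("survival", "cohort", {
    list(km = km_estimate(records),
         cox = tryCatch(cox_fit(records, adjust_age = TRUE),
                        error = function(e) e$message))
  })

  structure(list(config = config, threshold = thr,
                 tile_manifest = do.call(rbind, manifests),
                 tile_scores = tile_scores,
                 patient_scores = patient_scores, calls = calls,
                 evaluation = evaluation, survival = surv,
                 manifest = list(seed = config$seed, mode = config$mode,
                                 slides = slide_sums,
                                 config_echo = unclass_config(config),
                                 checksum_scores = obj_checksum(tile_scores),
                                 checksum_calls = obj_checksum(calls))),
            class = "wsi_run")
}

## JSON-serialisable copy of a config tree: strips S3 classes and replaces
## closures (scorers) by a marker.
unclass_config <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(unclass(x), unclass_config))
  if (is.matrix(x)) return(unclass(x))
  x
}

#' @export
print.wsi_run <- function(x, ...) {
  cat(sprintf("<wsi_run: %s mode, %d patients, %d tiles, threshold %.3f>\n",
              x$config$mode, nrow(x$patient_scores), nrow(x$tile_scores),
              x$threshold))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), kappa %.2f (%s), agreement %.1f%%\n",
              x$evaluation$roc$auc, x$evaluation$roc$auc_ci95[1],
              x$evaluation$roc$auc_ci95[2], x$evaluation$kappa$kappa,
              x$evaluation$kappa$band, x$evaluation$agreement$percent_agreement))
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' Tile manifest, tile scores and patient calls as CSV; evaluation, survival
#' and the run manifest as JSON.
#'
#' @param run a `wsi_run`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$tile_manifest, file.path(dir, "tile_manifest.csv"),
            row.names = FALSE)
  write.csv(run$tile_scores, file.path(dir, "tile_scores.csv"),
            row.names = FALSE)
  write.csv(run$calls, file.path(dir, "patient_calls.csv"), row.names = FALSE)
  ev <- run$evaluation
  jsonlite::write_json(
    list(auc = ev$roc$auc, auc_ci95 = ev$roc$auc_ci95,
         threshold = ev$threshold, kappa = ev$kappa$kappa,
         kappa_ci95 = ev$kappa$ci95, band = ev$kappa$band,
         sensitivity = ev$agreement$sensitivity,
         specificity = ev$agreement$specificity,
         percent_agreement = ev$agreement$percent_agreement,
         confusion = unclass(ev$confusion)),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  sv <- run$survival
  jsonlite::write_json(
    list(km = sv$km$curves,
         cox = if (inherits(sv$cox, "cox_fit"))
           cox_forest_rows(sv$cox) else sv$cox),
    file.path(dir, "survival.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
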