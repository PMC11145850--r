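test_that("pipeline configuration enforces the mode geometry", {
  pc_b <- pipeline_config("biopsy")
  expect_equal(pc_b$tiles$overlap, 0.75)
  expect_equal(pc_b$aggregation$percentile, 99)
  pc_r <- pipeline_config("resection")
  expect_equal(pc_r$tiles$overlap, 0)
  expect_equal(pc_r$aggregation$percentile, 75)
  expect_error(pipeline_config("resection", tiles = tile_config(overlap = 0.75)),
               "overlap")
})

test_that("tumour-mask intersection keeps exactly the covered tiles", {
  mk <- function(x, y) structure(list(slide_id = "s", x = x, y = y, foot = 64L,
                                      pixels = NULL, lap_var = 1000,
                                      mask_coverage = 1), class = "wsi_tile")
  tiles <- list(mk(0L, 0L), mk(64L, 0L), mk(128L, 0L), mk(192L, 0L))
  ones <- list(s = list(grid = matrix(TRUE, 32, 32), downsample = 8))
  zeros <- list(s = list(grid = matrix(FALSE, 32, 32), downsample = 8))
  expect_length(intersect_tumour_mask(tiles, ones), 4)
  expect_length(intersect_tumour_mask(tiles, zeros), 0)
  # half-plane mask: keep iff footprint coverage >= 0.5, checked by brute force
  half <- matrix(FALSE, 32, 32); half[, 1:16] <- TRUE    # x < 128 is tumour
  hp <- list(s = list(grid = half, downsample = 8))
  kept <- intersect_tumour_mask(tiles, hp, min_coverage = 0.5)
  cov <- vapply(tiles, function(t) {
    full <- half[ceiling(1:256 / 8), ceiling(1:256 / 8)]
    mean(full[(t$y + 1):(t$y + 64), (t$x + 1):(t$x + 64)])
  }, numeric(1))
  expect_equal(vapply(kept, `[[`, integer(1), "x"),
               vapply(tiles, `[[`, integer(1), "x")[cov >= 0.5])
  # missing mask reported by slide
  expect_error(intersect_tumour_mask(tiles, list(other = ones$s)),
               "missing tumour mask for slide 's'")
})

test_that("the pipeline recovers latent classes with a noiseless oracle", {
  co <- small_cohort(n = 6, seed = 15)
  pc <- pipeline_config("biopsy",
                        tiles = tile_config(overlap = 0.75,
                                            min_mask_coverage = 0.35),
                        scorer = oracle_scorer(noise_sd = 0), seed = 2)
  run <- suppressWarnings(run_pipeline(co, pc))
  expect_equal(run$evaluation$roc$auc, 1)
  conc <- merge(run$calls, co$truth)
  expect_true(all(conc$risk_group == conc$latent_class))
  expect_equal(nrow(run$calls), 6)
  # stage order bookkeeping: every slide appears in the manifest
  expect_setequal(unique(run$tile_manifest$slide_id), names(co$slides))
})

test_that("reruns with the same config are byte-identical", {
  co <- small_cohort(n = 4, seed = 23)
  pc <- pipeline_config("biopsy",
                        tiles = tile_config(overlap = 0.75,
                                            min_mask_coverage = 0.35),
                        scorer = oracle_scorer(noise_sd = 0.2), seed = 5)
  r1 <- suppressWarnings(run_pipeline(co, pc))
  r2 <- suppressWarnings(run_pipeline(co, pc))
  expect_identical(r1$tile_scores, r2$tile_scores)
  expect_identical(r1$calls, r2$calls)
  expect_identical(r1$manifest$checksum_scores, r2$manifest$checksum_scores)
  expect_identical(r1$manifest$checksum_calls, r2$manifest$checksum_calls)
})

test_that("biopsy and resection modes differ by stride and percentile", {
  co <- small_cohort(n = 4, seed = 31, slide_px = 1024)
  masks <- lapply(co$slides, function(sl)
    list(grid = matrix(TRUE, 64, 64), downsample = 16))
  pc_b <- pipeline_config("biopsy",
                          tiles = tile_config(overlap = 0.75,
                                              min_mask_coverage = 0.35),
                          scorer = oracle_scorer(), seed = 3)
  pc_r <- pipeline_config("resection",
                          tiles = tile_config(overlap = 0,
                                              min_mask_coverage = 0.35),
                          scorer = oracle_scorer(), seed = 3)
  rb <- suppressWarnings(run_pipeline(co, pc_b))
  rr <- suppressWarnings(run_pipeline(co, pc_r, tumour_masks = masks))
  expect_gt(nrow(rb$tile_scores), nrow(rr$tile_scores))
  expect_equal(rb$calls$mode[1], "biopsy")
  expect_equal(rr$calls$mode[1], "resection")
  # recorded aggregation percentiles follow the mode
  expect_equal(rb$config$aggregation$percentile, 99)
  expect_equal(rr$config$aggregation$percentile, 75)
})

test_that("run artifacts are written and round-trip", {
  co <- small_cohort(n = 4, seed = 42)
  pc <- pipeline_config("biopsy",
                        tiles = tile_config(overlap = 0.75,
                                            min_mask_coverage = 0.35),
                        scorer = oracle_scorer(), seed = 11)
  run <- suppressWarnings(run_pipeline(co, pc))
  d <- tempfile("artifacts")
  write_run_artifacts(run, d)
  expect_true(all(file.exists(file.path(d,
    c("tile_manifest.csv", "tile_scores.csv", "patient_calls.csv",
      "evaluation.json", "survival.json", "run_manifest.json")))))
  ev <- jsonlite::read_json(file.path(d, "evaluation.json"),
                            simplifyVector = TRUE)
  expect_equal(ev$auc, run$evaluation$roc$auc)
  calls <- read.csv(file.path(d, "patient_calls.csv"))
  expect_equal(nrow(calls), nrow(run$calls))
})

test_that("cohort artifacts can be written to disk as plain text/PNG", {
  co <- generate_cohort(cohort_config(n_patients = 2,
                                      slides_per_patient_range = c(1, 1),
                                      slide_px = 128, seed = 3))
  d <- tempfile("cohort")
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "clinical.csv")))
  sid <- names(co$slides)[1]
  img <- png::readPNG(file.path(d, paste0(sid, ".png"))) * 255
  expect_equal(round(img), co$slides[[1]]$pixels, ignore_attr = TRUE)
})

test_that("yaml cohort configs mirror the constructor fields", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 5", "class_prevalence: 0.4", "seed: 99",
               "slide_px: 256"), f)
  cfg <- read_cohort_config(f)
  expect_equal(cfg$n_patients, 5)
  expect_equal(cfg$class_prevalence, 0.4)
  expect_equal(cfg$slide_px, 256)
  expect_equal(cfg$slides_per_patient_range, c(1, 7))   # default preserved
})
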