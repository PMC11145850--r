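test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_patients = 3, slides_per_patient_range = c(1, 2),
                       slide_px = 256, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$slides, `[[`, "pixels"),
                   lapply(b$slides, `[[`, "pixels"))
  # one clinical row per patient, every patient has at least one slide
  expect_equal(nrow(a$clinical), 3)
  expect_setequal(unique(vapply(a$slides, `[[`, character(1), "patient_id")),
                  a$clinical$patient_id)
})

test_that("noise-free labels are a deterministic function of the latent class", {
  cfg <- cohort_config(n_patients = 60, grade2_fraction = 0,
                       ungraded_biopsy_fraction = 0, seed = 3)
  co <- generate_cohort(cfg, render_slides = FALSE)
  expect_true(all(co$clinical$biopsy_nhg %in% c(1, 3)))
  expect_equal(co$clinical$biopsy_nhg,
               ifelse(co$truth$latent_class == "high", 3L, 1L))
  expect_equal(co$clinical$resection_nhg,
               ifelse(co$truth$latent_class == "high", 3L, 1L))
})

test_that("grade labels respect the latent-class band constraints", {
  co <- generate_cohort(cohort_config(n_patients = 300, grade2_fraction = 0.5,
                                      seed = 11), render_slides = FALSE)
  high <- co$truth$latent_class == "high"
  expect_true(all(co$clinical$resection_nhg[high] %in% c(2, 3)))
  expect_true(all(co$clinical$resection_nhg[!high] %in% c(1, 2)))
  expect_false(any(is.na(co$clinical$resection_nhg)))
  # grade2_fraction controls the NHG2 share
  expect_lt(abs(mean(co$clinical$resection_nhg == 2) - 0.5), 0.1)
})

test_that("latent prevalence matches the binomial model", {
  co <- generate_cohort(cohort_config(n_patients = 200, class_prevalence = 0.5,
                                      seed = 1), render_slides = FALSE)
  p_hat <- mean(co$truth$latent_class == "high")
  se <- sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("rendered slides honour blur and stain-jitter switches", {
  sl0 <- render_slide("low", blur_fraction = 0, stain_jitter = 0,
                      seed = 2, slide_px = 256)
  expect_false(any(sl0$truth$blur))
  expect_equal(sl0$truth$stain_vectors, reference_stain_vectors(),
               tolerance = 1e-12)
  sl1 <- render_slide("low", blur_fraction = 0.2, stain_jitter = 10,
                      seed = 2, slide_px = 256)
  expect_gt(mean(sl1$truth$blur), 0)
  expect_gt(angle_deg(sl1$truth$stain_vectors[, 1],
                      reference_stain_vectors()[, 1]), 0.5)
})

test_that("tissue covers at least 5% of the slide and background is white", {
  for (s in 1:4) {
    sl <- render_slide(if (s %% 2) "low" else "high", seed = s, slide_px = 256)
    expect_gt(mean(sl$truth$tissue), 0.05)
    bg <- !sl$truth$tissue
    expect_equal(unique(as.vector(sl$pixels[, , 1][bg])), 255)
  }
})

test_that("nucleus blob density separates the classes (connected components)", {
  counts <- vapply(1:20, function(s) {
    lo <- render_slide("low", seed = s, blur_fraction = 0, slide_px = 256)
    hi <- render_slide("high", seed = s + 100, blur_fraction = 0, slide_px = 256)
    blob_rate <- function(sl) {
      max(EBImage::bwlabel(sl$truth$nuclei)) / sum(sl$truth$tissue)
    }
    c(blob_rate(lo), blob_rate(hi))
  }, numeric(2))
  expect_gt(mean(counts[2, ] > counts[1, ]), 0.85)
  expect_gt(mean(counts[2, ]) / mean(counts[1, ]), 1.5)
})

test_that("survival generator matches its exponential model", {
  lat <- rep(c("low", "high"), each = 400)
  sv <- generate_survival(lat, baseline_hazard = 5e-4, hr_high = 2,
                          censor_time = 3650, seed = 9)
  expect_true(all(sv$rfs_days > 0))
  expect_true(all(sv$event %in% 0:1))
  # administrative censoring edge: near-zero horizon censors everyone
  sv0 <- generate_survival(lat, baseline_hazard = 5e-4, hr_high = 2,
                           censor_time = 1e-6, seed = 9)
  expect_true(all(sv0$event == 0))
  expect_true(all(sv0$rfs_days == 1e-6))
  expect_error(generate_survival(character(0)), "empty cohort")
})

test_that("null hazard ratio gives well-calibrated log-rank p-values", {
  ps <- vapply(1:40, function(s) {
    lat <- rep(c("low", "high"), each = 60)
    sv <- generate_survival(lat, baseline_hazard = 4e-4, hr_high = 1,
                            censor_time = 3650, seed = s)
    d <- data.frame(sv, grp = lat)
    sd1 <- survival::survdiff(survival::Surv(rfs_days, event) ~ grp, data = d)
    pchisq(sd1$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.3)   # roughly uniform, mean near 0.5
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(slides_per_patient_range = c(0, 3)),
               "slides_per_patient_range")
  expect_error(cohort_config(class_prevalence = 1.2), "class_prevalence")
  expect_error(cohort_config(mpp = -1), "mpp")
  expect_error(render_slide("mid", seed = 1), "latent_class")
})

test_that("labelled training tiles carry a class-ordered density signal", {
  tt <- render_training_tiles(30, tile_px = 96, seed = 2)
  d <- vapply(tt$tiles, `[[`, numeric(1), "truth_density")
  y <- tt$labels == "high"
  expect_gt(mean(d[y]), mean(d[!y]))
  expect_true(all(vapply(tt$tiles, function(t) all(dim(t$pixels) == c(96, 96, 3)),
                         logical(1))))
})
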