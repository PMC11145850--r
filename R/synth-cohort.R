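## Synthetic H&E-like slide cohorts with linked clinical tables.
##
## The generator emulates the statistical structure the downstream pipeline
## assumes: slides carry tissue regions of one of two latent morphology
## classes ("low" / "high" risk) drawn on a white background, coloured by
## Beer-Lambert mixing of haematoxylin and eosin stain vectors with per-slide
## angular stain jitter, with optional localised blur; the clinical table
## links grade labels and exponential survival times to the latent class
## through an explicit label-noise model and nothing else.

## Nuclei cover roughly these fractions of the tissue area per latent class;
## the 3x density contrast is the class signal a tile scorer can learn.
NUCLEI_AREA_FRAC <- c(low = 0.015, high = 0.045)

## sd of the Gaussian noise added to the latent risk before grade banding
LABEL_SIGMA <- 0.5

#' Configuration of a synthetic slide cohort
#'
#' Defaults describe the emulated study conditions: one to seven biopsy
#' slides per patient, roughly balanced latent classes, about half of
#' patients carrying the intermediate (NHG2) label, a quarter of biopsies
#' ungraded, 20x working resolution (0.454 um/px), and an exponential
#' recurrence model with a true hazard ratio of 2 between latent classes.
#'
#' @param n_patients number of patients.
#' @param slides_per_patient_range inclusive integer interval within 1..7.
#' @param class_prevalence probability of the latent high-risk class.
#' @param grade2_fraction probability a patient's grade label is NHG2.
#' @param ungraded_biopsy_fraction probability the biopsy NHG is missing.
#' @param blur_fraction fraction of tissue area rendered blurred per slide.
#' @param stain_jitter angular perturbation (degrees) of the reference stain
#'   vectors, drawn per slide.
#' @param mpp microns per pixel of generated slides.
#' @param slide_px edge length of generated slides in pixels.
#' @param baseline_hazard exponential event rate per day for the low class.
#' @param hr_high hazard ratio of the latent high class versus low.
#' @param censor_time administrative censoring time in days.
#' @param seed master RNG seed; all randomness is derived from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          slides_per_patient_range = c(1, 7),
                          class_prevalence = 0.5,
                          grade2_fraction = 0.5,
                          ungraded_biopsy_fraction = 0.25,
                          blur_fraction = 0.1,
                          stain_jitter = 5,
                          mpp = 0.454,
                          slide_px = 4096,
                          baseline_hazard = 7e-5,
                          hr_high = 2.0,
                          censor_time = 3650,
                          seed = 1) {
  cfg <- list(n_patients = n_patients,
              slides_per_patient_range = slides_per_patient_range,
              class_prevalence = class_prevalence,
              grade2_fraction = grade2_fraction,
              ungraded_biopsy_fraction = ungraded_biopsy_fraction,
              blur_fraction = blur_fraction,
              stain_jitter = stain_jitter,
              mpp = mpp, slide_px = slide_px,
              baseline_hazard = baseline_hazard, hr_high = hr_high,
              censor_time = censor_time, seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_patients)) stop_config("n_patients", "must be a positive count")
  r <- cfg$slides_per_patient_range
  if (length(r) != 2 || any(r != round(r)) || r[1] > r[2] || r[1] < 1 || r[2] > 7)
    stop_config("slides_per_patient_range", "must be an integer interval within [1, 7]")
  for (f in c("class_prevalence", "grade2_fraction",
              "ungraded_biopsy_fraction", "blur_fraction"))
    if (!is_prob(cfg[[f]])) stop_config(f, "must be a probability in [0, 1]")
  if (!is.numeric(cfg$stain_jitter) || cfg$stain_jitter < 0)
    stop_config("stain_jitter", "must be a non-negative angle in degrees")
  if (!is.numeric(cfg$mpp) || cfg$mpp <= 0) stop_config("mpp", "must be > 0")
  if (!is_count(cfg$slide_px) || cfg$slide_px < 64)
    stop_config("slide_px", "must be an integer >= 64")
  if (!is.numeric(cfg$baseline_hazard) || cfg$baseline_hazard <= 0)
    stop_config("baseline_hazard", "must be > 0")
  if (!is.numeric(cfg$hr_high) || cfg$hr_high <= 0)
    stop_config("hr_high", "must be > 0")
  if (!is.numeric(cfg$censor_time) || cfg$censor_time <= 0)
    stop_config("censor_time", "must be > 0")
  invisible(cfg)
}

#' Read a cohort configuration from a YAML file
#'
#' Field names mirror the arguments of [cohort_config()].
#'
#' @param path path to a YAML file.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(cohort_config)))
  do.call(cohort_config, vals[keep])
}

## Rotate each column of a 3 x k matrix by `degrees` about a random axis
## (Rodrigues' formula), then clip tiny negatives and renormalise, so that
## jittered stain vectors remain valid unit vectors in optical-density space.
jitter_stain_vectors <- function(vectors, degrees) {
  if (degrees == 0) return(vectors)
  theta <- degrees * pi / 180
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  out <- R %*% vectors
  out <- pmax(out, 0)
  sweep(out, 2, sqrt(colSums(out^2)), "/")
}

## Logical ellipse mask on an h x w grid.
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / rx)^2 + (v / ry)^2 <= 1
}

## Stamp filled ellipses (nuclei) onto a logical mask; each nucleus only
## touches its bounding box, so cost is linear in total nucleus area.
stamp_nuclei <- function(mask, centers_y, centers_x, ry, rx, theta) {
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_along(centers_y)) {
    r <- ceiling(max(ry[i], rx[i]))
    y0 <- max(1L, centers_y[i] - r); y1 <- min(h, centers_y[i] + r)
    x0 <- max(1L, centers_x[i] - r); x1 <- min(w, centers_x[i] + r)
    if (y0 > y1 || x0 > x1) next
    yy <- matrix((y0:y1) - centers_y[i], y1 - y0 + 1, x1 - x0 + 1)
    xx <- matrix((x0:x1) - centers_x[i], y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
    u <- cos(theta[i]) * xx + sin(theta[i]) * yy
    v <- -sin(theta[i]) * xx + cos(theta[i]) * yy
    hit <- (u / rx[i])^2 + (v / ry[i])^2 <= 1
    mask[y0:y1, x0:x1] <- mask[y0:y1, x0:x1] | hit
  }
  mask
}

gaussian_blur_rgb <- function(px, sigma) {
  for (k in 1:3)
    px[, , k] <- EBImage::imageData(EBImage::gblur(px[, , k], sigma = sigma))
  px
}

#' Render one synthetic H&E-like slide
#'
#' The slide contains an elliptical tissue region (plus satellites) on a
#' white background. Pixels are produced by Beer-Lambert mixing of two stain
#' vectors: haematoxylin concentration is high inside Poisson-scattered dark
#' elliptical "nuclei" whose density per unit tissue area is the latent class
#' signal, and eosin concentration carries per-pixel texture noise so that
#' sharp tissue has a high Laplacian variance. Ground-truth tissue, nucleus
#' and blur masks, the jittered stain vectors and the nucleus area fraction
#' are attached as side-channel metadata under `$truth`.
#'
#' @param latent_class `"low"` or `"high"`.
#' @param blur_fraction fraction of the tissue area rendered blurred.
#' @param stain_jitter angular perturbation of the stain vectors in degrees.
#' @param mpp microns per pixel.
#' @param seed RNG seed for the slide content.
#' @param slide_px slide edge length in pixels.
#' @param slide_id identifier stored on the slide.
#' @param stain_seed optional separate seed for the stain-jitter axis, so two
#'   renders can share content but differ in stain (defaults to `seed`).
#' @return an object of class `slide_image` with elements `slide_id`,
#'   `pixels` (h x w x 3 array on the 0-255 scale), `mpp` and `truth`.
#' @export
render_slide <- function(latent_class, blur_fraction = 0.1, stain_jitter = 5,
                         mpp = 0.454, seed = 1, slide_px = 1024,
                         slide_id = "S1", stain_seed = NULL) {
  if (!latent_class %in% c("low", "high"))
    stop_config("latent_class", "must be 'low' or 'high'")
  h <- w <- as.integer(slide_px)

  vecs <- with_seed(derive_seed(stain_seed %||% seed, "stain"),
                    jitter_stain_vectors(reference_stain_vectors(), stain_jitter))

  with_seed(derive_seed(seed, "content"), {
    ## tissue: one dominant ellipse plus a couple of satellites
    tissue <- ellipse_mask(h, w,
                           cy = h * runif(1, 0.45, 0.55),
                           cx = w * runif(1, 0.45, 0.55),
                           ry = h * runif(1, 0.40, 0.46),
                           rx = w * runif(1, 0.38, 0.45),
                           theta = runif(1, 0, pi))
    for (s in seq_len(sample(0:2, 1))) {
      tissue <- tissue | ellipse_mask(h, w,
                                      cy = h * runif(1, 0.15, 0.85),
                                      cx = w * runif(1, 0.15, 0.85),
                                      ry = h * runif(1, 0.05, 0.12),
                                      rx = w * runif(1, 0.05, 0.12),
                                      theta = runif(1, 0, pi))
    }
    tissue_area <- sum(tissue)

    ## nuclei: Poisson count targeting the class-specific area fraction
    r_mean <- 2.6 / mpp                      # ~2.6 um nucleus radius
    mean_area <- pi * r_mean^2
    lambda <- NUCLEI_AREA_FRAC[[latent_class]] * tissue_area / mean_area
    n_nuc <- rpois(1, lambda)
    nuclei <- matrix(FALSE, h, w)
    if (n_nuc > 0) {
      idx <- sample(which(tissue), n_nuc, replace = TRUE)
      cy <- (idx - 1L) %% h + 1L
      cx <- (idx - 1L) %/% h + 1L
      ry <- runif(n_nuc, 0.75, 1.25) * r_mean
      rx <- runif(n_nuc, 0.75, 1.25) * r_mean
      nuclei <- stamp_nuclei(nuclei, cy, cx, ry, rx, runif(n_nuc, 0, pi))
      nuclei <- nuclei & tissue
    }

    ## Beer-Lambert composition in optical density. Nuclei are almost pure
    ## haematoxylin and plain stroma almost pure eosin, so the slide's OD
    ## cloud has the near-pure extreme directions Macenko estimation relies
    ## on; the per-pixel concentration noise gives sharp tissue the fine
    ## texture the Laplacian-variance QC expects.
    cH <- tissue * pmax(0.04 + 0.03 * matrix(runif(h * w, -1, 1), h, w), 0.005)
    cH[nuclei] <- 1.0
    cE <- tissue * (0.35 + 0.12 * matrix(runif(h * w, -1, 1), h, w))
    cE[nuclei] <- cE[nuclei] * 0.05
    px <- array(0, dim = c(h, w, 3))
    for (k in 1:3) px[, , k] <- vecs[k, 1] * cH + vecs[k, 2] * cE
    px <- 256 * 10^(-px) - 1

    ## localised blur inside the tissue
    blur <- matrix(FALSE, h, w)
    if (blur_fraction > 0) {
      r_b <- sqrt(blur_fraction * tissue_area / pi)
      ctr <- sample(which(tissue), 1)
      blur <- ellipse_mask(h, w,
                           cy = (ctr - 1L) %% h + 1L,
                           cx = (ctr - 1L) %/% h + 1L,
                           ry = r_b * runif(1, 0.8, 1.2),
                           rx = r_b * runif(1, 0.8, 1.2),
                           theta = runif(1, 0, pi)) & tissue
      if (any(blur)) {
        ## blur only the bounding box of the region (plus kernel margin)
        rr <- range(which(rowSums(blur) > 0)); cc <- range(which(colSums(blur) > 0))
        r0 <- max(1, rr[1] - 16); r1 <- min(h, rr[2] + 16)
        c0 <- max(1, cc[1] - 16); c1 <- min(w, cc[2] + 16)
        soft <- gaussian_blur_rgb(px[r0:r1, c0:c1, , drop = FALSE], sigma = 4)
        sub <- blur[r0:r1, c0:c1]
        for (k in 1:3) {
          ch <- px[r0:r1, c0:c1, k]; ch[sub] <- soft[, , k][sub]
          px[r0:r1, c0:c1, k] <- ch
        }
      }
    }
    px <- round(pmin(pmax(px, 0), 255))

    structure(list(slide_id = slide_id, pixels = px, mpp = mpp,
                   truth = list(latent_class = latent_class,
                                tissue = tissue, nuclei = nuclei, blur = blur,
                                stain_vectors = vecs,
                                nuclei_frac = sum(nuclei) / tissue_area)),
              class = "slide_image")
  })
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image %s: %d x %d px @ %.3f um/px, latent %s>\n",
              x$slide_id, nrow(x$pixels), ncol(x$pixels), x$mpp,
              x$truth$latent_class %||% "?"))
  invisible(x)
}

## Grade labels from the latent class: a noisy copy of the latent risk is
## banded so that each class is relabelled NHG2 with probability g2, NHG1
## (low) or NHG3 (high) otherwise. The high class never reaches NHG1 nor the
## low class NHG3, mirroring a design in which the intermediate grade mixes
## both latent classes.
nhg_from_latent <- function(z, g2) {
  eps <- rnorm(length(z), 0, LABEL_SIGMA)
  is2 <- ifelse(z == 1,
                eps < LABEL_SIGMA * qnorm(g2),
                eps > LABEL_SIGMA * qnorm(1 - g2))
  ifelse(is2, 2L, ifelse(z == 1, 3L, 1L))
}

#' Render labelled training tiles
#'
#' Small all-tissue tiles with class-specific nucleus density and the same
#' Beer-Lambert colouring as [render_slide()], for training and testing
#' tile scorers at desk scale.
#'
#' @param n_per_class tiles per latent class.
#' @param tile_px tile edge length (default 64).
#' @param mpp microns per pixel.
#' @param stain_jitter per-tile stain perturbation in degrees.
#' @param seed RNG seed.
#' @return list with `tiles` (list of `wsi_tile` carrying `truth_density`
#'   and `latent_class`) and `labels` (character vector).
#' @export
render_training_tiles <- function(n_per_class, tile_px = 64, mpp = 0.454,
                                  stain_jitter = 0, seed = 1) {
  with_seed(derive_seed(seed, "training_tiles"), {
    r_mean <- 2.6 / mpp
    mean_area <- pi * r_mean^2
    classes <- rep(c("low", "high"), each = n_per_class)
    tiles <- lapply(seq_along(classes), function(i) {
      cls <- classes[i]
      vecs <- jitter_stain_vectors(reference_stain_vectors(), stain_jitter)
      n_nuc <- rpois(1, NUCLEI_AREA_FRAC[[cls]] * tile_px^2 / mean_area)
      nuclei <- matrix(FALSE, tile_px, tile_px)
      if (n_nuc > 0)
        nuclei <- stamp_nuclei(nuclei,
                               sample(tile_px, n_nuc, TRUE),
                               sample(tile_px, n_nuc, TRUE),
                               runif(n_nuc, 0.75, 1.25) * r_mean,
                               runif(n_nuc, 0.75, 1.25) * r_mean,
                               runif(n_nuc, 0, pi))
      cH <- pmax(0.04 + 0.03 * matrix(runif(tile_px^2, -1, 1), tile_px), 0.005)
      cH[nuclei] <- 1.0
      cE <- 0.35 + 0.12 * matrix(runif(tile_px^2, -1, 1), tile_px)
      cE[nuclei] <- cE[nuclei] * 0.05
      px <- array(0, dim = c(tile_px, tile_px, 3))
      for (k in 1:3) px[, , k] <- vecs[k, 1] * cH + vecs[k, 2] * cE
      px <- round(pmin(pmax(256 * 10^(-px) - 1, 0), 255))
      structure(list(slide_id = sprintf("train_%s_%d", cls, i),
                     x = 0L, y = 0L, foot = tile_px, pixels = px,
                     lap_var = laplacian_variance(px), mask_coverage = 1,
                     truth_density = mean(nuclei), latent_class = cls),
                class = "wsi_tile")
    })
    list(tiles = tiles, labels = classes)
  })
}

#' Simulate recurrence-free survival for a cohort
#'
#' Event times follow an exponential model with hazard
#' `baseline_hazard * hr_high^[latent_class == "high"]`, administratively
#' censored at `censor_time`. Time-to-event is measured in days from
#' diagnosis; `event = 1` marks recurrence or death, `0` censoring.
#'
#' @param latent_class character vector of `"low"` / `"high"` per patient.
#' @param baseline_hazard event rate per day for the low class (> 0).
#' @param hr_high hazard ratio of the high class (> 0).
#' @param censor_time administrative censoring time in days.
#' @param seed RNG seed.
#' @return data.frame with columns `rfs_days` (> 0) and `event` (0/1).
#' @export
generate_survival <- function(latent_class, baseline_hazard = 7e-5,
                              hr_high = 2.0, censor_time = 3650, seed = 1) {
  if (length(latent_class) == 0) stop("empty cohort: no patients to simulate")
  stopifnot(all(latent_class %in% c("low", "high")))
  if (baseline_hazard <= 0) stop_config("baseline_hazard", "must be > 0")
  if (hr_high <= 0) stop_config("hr_high", "must be > 0")
  if (censor_time <= 0) stop_config("censor_time", "must be > 0")
  with_seed(derive_seed(seed, "survival"), {
    haz <- baseline_hazard * hr_high^(latent_class == "high")
    t_event <- rexp(length(haz), rate = haz)
    data.frame(rfs_days = pmin(t_event, censor_time),
               event = as.integer(t_event <= censor_time))
  })
}

#' Generate a complete synthetic cohort
#'
#' Produces rendered slides, a clinical table and the latent ground truth,
#' all derived deterministically from `config$seed`. The latent truth is the
#' only channel linking slides and labels: with `grade2_fraction = 0` and
#' `ungraded_biopsy_fraction = 0` the grade columns are a deterministic
#' function of the latent class.
#'
#' @param config a [cohort_config()].
#' @param render_slides if `FALSE`, skip slide rendering and return an empty
#'   slide list (clinical-only simulation for survival studies).
#' @return list with elements `slides` (list of `slide_image`), `clinical`
#'   (data.frame: patient_id, biopsy_nhg, resection_nhg, er_status,
#'   her2_status, age, rfs_days, event) and `truth` (data.frame: patient_id,
#'   latent_class, true_log_hazard).
#' @export
generate_cohort <- function(config = cohort_config(), render_slides = TRUE) {
  validate_cohort_config(config)
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  lab <- with_seed(derive_seed(config$seed, "labels"), {
    z <- rbinom(n, 1, config$class_prevalence)
    biopsy <- nhg_from_latent(z, config$grade2_fraction)
    resection <- nhg_from_latent(z, config$grade2_fraction)
    biopsy[runif(n) < config$ungraded_biopsy_fraction] <- NA_integer_
    er <- ifelse(runif(n) < ifelse(z == 1, 0.75, 0.90), "pos", "neg")
    her2 <- ifelse(runif(n) < ifelse(z == 1, 0.18, 0.08), "pos", "neg")
    er[runif(n) < 0.02] <- NA_character_
    her2[runif(n) < 0.02] <- NA_character_
    age <- round(pmin(pmax(rnorm(n, 62, 12), 30), 92))
    n_slides <- sample(seq(config$slides_per_patient_range[1],
                           config$slides_per_patient_range[2]),
                       n, replace = TRUE)
    list(z = z, biopsy = biopsy, resection = resection, er = er, her2 = her2,
         age = age, n_slides = n_slides)
  })
  latent <- ifelse(lab$z == 1, "high", "low")

  surv <- generate_survival(latent, config$baseline_hazard, config$hr_high,
                            config$censor_time,
                            seed = derive_seed(config$seed, "rfs"))

  clinical <- data.frame(patient_id = pid,
                         biopsy_nhg = lab$biopsy,
                         resection_nhg = lab$resection,
                         er_status = lab$er, her2_status = lab$her2,
                         age = lab$age,
                         rfs_days = surv$rfs_days, event = surv$event,
                         stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = pid, latent_class = latent,
                      true_log_hazard = log(config$hr_high) * lab$z,
                      stringsAsFactors = FALSE)

  slides <- list()
  if (render_slides) {
    for (i in seq_len(n)) {
      for (j in seq_len(lab$n_slides[i])) {
        sid <- sprintf("%s_S%d", pid[i], j)
        sl <- render_slide(latent[i],
                           blur_fraction = config$blur_fraction,
                           stain_jitter = config$stain_jitter,
                           mpp = config$mpp,
                           seed = derive_seed(config$seed, sid),
                           slide_px = config$slide_px, slide_id = sid)
        sl$patient_id <- pid[i]
        slides[[sid]] <- sl
      }
    }
  }
  list(slides = slides, clinical = clinical, truth = truth)
}

#' Write cohort artifacts to disk
#'
#' Slides are written as flat PNG, truth masks as single-channel PNG, and the
#' clinical table as CSV with the standard header.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "latent_truth.csv"), row.names = FALSE)
  for (sl in cohort$slides) {
    png::writePNG(sl$pixels / 255, file.path(dir, paste0(sl$slide_id, ".png")))
    png::writePNG(sl$truth$tissue * 1,
                  file.path(dir, paste0(sl$slide_id, "_tissue.png")))
    png::writePNG(sl$truth$blur * 1,
                  file.path(dir, paste0(sl$slide_id, "_blur.png")))
  }
  invisible(dir)
}
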