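# Fixtures are generated in code; nothing is read from disk.

# A slide whose pixels are a white background with one axis-aligned
# H&E-coloured rectangular block covering `frac` of the area.
he_block_slide <- function(px = 512, frac = 0.25, mpp = 0.454,
                           cH = 0.3, cE = 0.4) {
  V <- reference_stain_vectors()
  side <- round(px * sqrt(frac))
  img <- array(255, dim = c(px, px, 3))
  rows <- seq_len(side) + 16
  cols <- seq_len(side) + 16
  for (k in 1:3) {
    od <- V[k, 1] * cH + V[k, 2] * cE
    img[rows, cols, k] <- round(256 * 10^(-od) - 1)
  }
  structure(list(slide_id = "block", pixels = img, mpp = mpp), class = "slide_image")
}

# Tiles produced by pure Beer-Lambert mixing of a known stain basis with
# independent non-negative random concentrations.
beer_lambert_tiles <- function(V, n_tiles = 30, px = 64, c_max = c(1, 1)) {
  lapply(seq_len(n_tiles), function(i) {
    cH <- runif(px * px, 0, c_max[1])
    cE <- runif(px * px, 0, c_max[2])
    od <- cbind(cH, cE) %*% t(V)
    array(round(pmin(pmax(256 * 10^(-od) - 1, 0), 255)), c(px, px, 3))
  })
}

# Minimal tile stub carrying only oracle truth metadata.
stub_tile <- function(density, slide_id = "stub", x = 0L, y = 0L) {
  structure(list(slide_id = slide_id, x = x, y = y, foot = 1L,
                 pixels = NULL, lap_var = 0, mask_coverage = 1,
                 truth_density = density), class = "wsi_tile")
}

# A tissue_mask object built directly from a logical grid.
mask_from_grid <- function(grid, downsample, slide_dim = dim(grid) * downsample) {
  structure(list(grid = grid, downsample = downsample,
                 tissue_fraction = mean(grid), slide_dim = slide_dim),
            class = "tissue_mask")
}

# Brute-force tile placement: expand the mask to level-0 pixels and test
# every stride-aligned origin by counting tissue pixels in the footprint.
brute_force_origins <- function(grid, ds, slide_dim, tile_px, stride,
                                min_cov) {
  h <- slide_dim[1]; w <- slide_dim[2]
  full <- matrix(FALSE, h, w)
  gh <- nrow(grid) * ds; gw <- ncol(grid) * ds
  full[seq_len(min(h, gh)), seq_len(min(w, gw))] <-
    grid[ceiling(seq_len(min(h, gh)) / ds), ceiling(seq_len(min(w, gw)) / ds)]
  out <- NULL
  if (w < tile_px || h < tile_px)
    return(data.frame(x = integer(), y = integer()))
  for (y in seq(0, h - tile_px, by = stride))
    for (x in seq(0, w - tile_px, by = stride)) {
      cov <- mean(full[(y + 1):(y + tile_px), (x + 1):(x + tile_px)])
      if (cov >= min_cov) out <- rbind(out, c(x, y))
    }
  if (is.null(out)) return(data.frame(x = integer(), y = integer()))
  data.frame(x = out[, 1], y = out[, 2])
}

# AUC by exhaustive pair counting (ties count one half).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden threshold by direct search over the same candidate set.
exhaustive_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec - 1 > best_j + 1e-12) {
      best_j <- sens + spec - 1; best_t <- t
    }
  }
  list(threshold = best_t, J = best_j)
}

angle_deg <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi

with_seed_age <- function(seed, n) {
  set.seed(seed)
  round(pmin(pmax(rnorm(n, 62, 10), 30), 90))
}

small_cohort <- function(n = 6, seed = 5, slide_px = 896, g2 = 0.2,
                         ungraded = 0.1) {
  generate_cohort(cohort_config(
    n_patients = n, slides_per_patient_range = c(1, 2), slide_px = slide_px,
    grade2_fraction = g2, ungraded_biopsy_fraction = ungraded,
    blur_fraction = 0.08, stain_jitter = 5, seed = seed))
}
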