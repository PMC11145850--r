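test_that("stride arithmetic follows round-half-up of tile_px*(1-overlap)", {
  expect_equal(wsirisk:::tile_stride(tile_config(overlap = 0.75)), 150)
  expect_equal(wsirisk:::tile_stride(tile_config(overlap = 0)), 598)
  expect_equal(wsirisk:::tile_stride(tile_config(tile_px = 100, overlap = 0.75)), 25)
})

test_that("exact-fit regions produce the expected origin grids", {
  cfg0 <- tile_config(overlap = 0, min_mask_coverage = 1)
  m1 <- mask_from_grid(matrix(TRUE, 299, 299), 2, c(598, 598))
  expect_equal(nrow(enumerate_tile_origins(m1, cfg0)), 1)
  expect_equal(enumerate_tile_origins(m1, cfg0)[1, c("x", "y")],
               data.frame(x = 0L, y = 0L))
  # 1196^2 all-tissue block, 75% overlap, stride 150 -> 4 origins per axis
  cfg75 <- tile_config(overlap = 0.75, min_mask_coverage = 1)
  m2 <- mask_from_grid(matrix(TRUE, 299, 299), 4, c(1196, 1196))
  org <- enumerate_tile_origins(m2, cfg75)
  expect_equal(nrow(org), 16)
  expect_setequal(unique(org$x), c(0, 150, 300, 450))
  bf <- brute_force_origins(matrix(TRUE, 299, 299), 4, c(1196, 1196),
                            598, 150, 1)
  expect_equal(org[, c("x", "y")], bf, ignore_attr = TRUE)
  # empty mask -> empty result
  m0 <- mask_from_grid(matrix(FALSE, 100, 100), 8)
  expect_equal(nrow(enumerate_tile_origins(m0, tile_config(tile_px = 64))), 0)
})

test_that("enumeration equals brute-force placement on random masks", {
  set.seed(77)
  for (i in 1:30) {
    gd <- matrix(runif(20 * 20) < runif(1, 0.2, 0.8), 20, 20)
    ds <- sample(c(2, 4, 5), 1)
    dim0 <- c(20 * ds + sample(0:3, 1), 20 * ds + sample(0:3, 1))
    tp <- sample(c(12, 16, 24), 1)
    ov <- sample(c(0, 0.5, 0.75), 1)
    mc <- runif(1, 0.1, 0.9)
    cfg <- tile_config(tile_px = tp, overlap = ov, min_mask_coverage = mc)
    m <- mask_from_grid(gd, ds, dim0)
    got <- enumerate_tile_origins(m, cfg)
    want <- brute_force_origins(gd, ds, dim0, tp, wsirisk:::tile_stride(cfg), mc)
    expect_equal(got[, c("x", "y")], want, ignore_attr = TRUE)
  }
})

test_that("row-major ordering and in-bounds footprints always hold", {
  m <- mask_from_grid(matrix(TRUE, 50, 40), 8)
  cfg <- tile_config(tile_px = 64, overlap = 0.75, min_mask_coverage = 0.5)
  org <- enumerate_tile_origins(m, cfg)
  expect_true(all(diff(org$y) >= 0))
  expect_true(all(org$x + 64 <= 40 * 8))
  expect_true(all(org$y + 64 <= 50 * 8))
})

test_that("tile counts at 75% vs 0% overlap follow stride arithmetic", {
  m <- mask_from_grid(matrix(TRUE, 250, 250), 16, c(4000, 4000))
  n75 <- nrow(enumerate_tile_origins(m, tile_config(overlap = 0.75,
                                                    min_mask_coverage = 0.9)))
  n0 <- nrow(enumerate_tile_origins(m, tile_config(overlap = 0,
                                                   min_mask_coverage = 0.9)))
  expect_equal(n75, (floor((4000 - 598) / 150) + 1)^2)
  expect_equal(n0, (floor((4000 - 598) / 598) + 1)^2)
  expect_gt(n75 / n0, 10)  # approaches (598/150)^2 ~ 15.9 on large regions
})

test_that("native-resolution extraction is a pure crop", {
  set.seed(3)
  px <- array(round(runif(64 * 64 * 3, 0, 255)), c(64, 64, 3))
  sl <- structure(list(slide_id = "s", pixels = px, mpp = 0.454),
                  class = "slide_image")
  cfg <- tile_config(tile_px = 16)
  t1 <- extract_tile(sl, c(8, 24), cfg)
  expect_identical(t1$pixels, px[25:40, 9:24, , drop = FALSE])
  expect_error(extract_tile(sl, c(60, 0), cfg), "out of bounds")
})

test_that("40x to 20x extraction is an exact 2x2 block average", {
  # constant 2x2 blocks at 0.227 um/px recover exactly at 0.454
  set.seed(5)
  base <- array(round(runif(16 * 16 * 3, 0, 255)), c(16, 16, 3))
  up <- base[rep(1:16, each = 2), rep(1:16, each = 2), , drop = FALSE]
  sl <- structure(list(slide_id = "s40", pixels = up, mpp = 0.227),
                  class = "slide_image")
  t1 <- extract_tile(sl, c(0, 0), tile_config(tile_px = 16, target_mpp = 0.454))
  expect_equal(t1$pixels, base, tolerance = 1e-12)
  expect_equal(t1$foot, 32L)
})

test_that("laplacian variance matches a direct convolution oracle", {
  # constant tile -> exactly zero
  expect_equal(laplacian_variance(array(137, c(32, 32, 3))), 0)
  # single impulse: hand convolution over the valid region
  g <- matrix(0, 9, 9); g[5, 5] <- 80
  conv <- matrix(0, 7, 7)
  for (i in 2:8) for (j in 2:8)
    conv[i - 1, j - 1] <- g[i - 1, j] + g[i + 1, j] + g[i, j - 1] +
      g[i, j + 1] - 4 * g[i, j]
  expect_equal(laplacian_variance(g), mean((conv - mean(conv))^2))
  # grayscale uses 601 luma: pure-channel tiles scale by the luma weight
  px <- array(0, c(16, 16, 3)); px[8, 8, 1] <- 100
  pg <- matrix(0, 16, 16); pg[8, 8] <- 100 * 0.299
  expect_equal(laplacian_variance(px), laplacian_variance(pg))
})

test_that("gaussian blur strictly lowers the laplacian variance", {
  set.seed(10)
  tiles <- render_training_tiles(4, tile_px = 96, seed = 31)$tiles
  for (t in tiles) {
    soft <- wsirisk:::gaussian_blur_rgb(t$pixels, sigma = 3)
    expect_lt(laplacian_variance(soft), laplacian_variance(t$pixels))
  }
})

test_that("QC keeps exactly the tiles at or above the cutoff", {
  mk <- function(lv) structure(list(slide_id = "s", x = 0L, y = 0L,
                                    pixels = NULL, lap_var = lv,
                                    mask_coverage = 1), class = "wsi_tile")
  tiles <- lapply(c(0, 499.9, 500, 10000), mk)
  kept <- qc_filter(tiles, tile_config(min_lap_var = 500))
  expect_length(kept, 2)
  expect_equal(attr(kept, "n_dropped"), 2)
  expect_setequal(vapply(kept, `[[`, numeric(1), "lap_var"), c(500, 10000))
  # permutation invariance and idempotence
  kept_rev <- qc_filter(rev(tiles), tile_config(min_lap_var = 500))
  expect_setequal(vapply(kept_rev, `[[`, numeric(1), "lap_var"), c(500, 10000))
  expect_length(qc_filter(kept, tile_config(min_lap_var = 500)), 2)
})

test_that("truth-blurred tiles are dropped at the default cutoff", {
  sl <- render_slide("high", blur_fraction = 0.35, stain_jitter = 0,
                     seed = 19, slide_px = 768)
  m <- compute_tissue_mask(sl, mask_config())
  cfg <- tile_config(tile_px = 128, min_mask_coverage = 0.9)
  org <- enumerate_tile_origins(m, cfg)
  tiles <- lapply(seq_len(nrow(org)), function(i)
    extract_tile(sl, c(org$x[i], org$y[i]), cfg))
  blur <- vapply(tiles, `[[`, numeric(1), "truth_blur")
  lv <- vapply(tiles, `[[`, numeric(1), "lap_var")
  expect_gt(sum(blur == 1), 3)
  expect_gte(mean(lv[blur == 1] < 500), 0.9)
  expect_gte(mean(lv[blur == 0] >= 500), 0.9)
})
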