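## Tile enumeration and extraction over the tissue mask. Biopsy geometry
## uses 75% overlap between consecutive tiles on both axes (stride 150 px
## for the default 598 px tile, rounding 149.5 half-up); resection geometry
## uses no overlap. Blur/quality control thresholds the variance of the
## 3x3 Laplacian response of the grayscale tile at 500 on the 0-255 scale.

#' Tile extraction configuration
#'
#' @param tile_px tile edge length in pixels at the target resolution
#'   (default 598).
#' @param target_mpp microns per pixel at extraction (default 0.454, i.e.
#'   20x).
#' @param overlap fractional overlap between consecutive tiles; 0.75 for
#'   biopsies, 0 for resections.
#' @param min_lap_var QC cutoff on the Laplacian variance; tiles strictly
#'   below it are excluded (default 500).
#' @param min_mask_coverage minimum fraction of the tile footprint that must
#'   be tissue for the tile to be emitted (default 0.5).
#' @return an object of class `tile_config`.
#' @export
tile_config <- function(tile_px = 598, target_mpp = 0.454, overlap = 0.75,
                        min_lap_var = 500, min_mask_coverage = 0.5) {
  if (!is_count(tile_px)) stop_config("tile_px", "must be a positive integer")
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1)
    stop_config("overlap", "must be in [0, 1)")
  if (!is.numeric(min_lap_var) || min_lap_var < 0)
    stop_config("min_lap_var", "must be >= 0")
  if (!is_prob(min_mask_coverage))
    stop_config("min_mask_coverage", "must be in [0, 1]")
  if (!is.numeric(target_mpp) || target_mpp <= 0)
    stop_config("target_mpp", "must be > 0")
  structure(list(tile_px = tile_px, target_mpp = target_mpp,
                 overlap = overlap, min_lap_var = min_lap_var,
                 min_mask_coverage = min_mask_coverage),
            class = "tile_config")
}

## Stride in target-resolution pixels: round half-up of tile_px*(1-overlap)
## (598 * 0.25 = 149.5 -> 150).
tile_stride <- function(config) {
  max(1L, as.integer(floor(config$tile_px * (1 - config$overlap) + 0.5)))
}

## Level-0 scale factor: how many native pixels per target pixel.
level0_scale <- function(native_mpp, target_mpp) {
  s <- target_mpp / native_mpp
  if (s < 1 - 1e-9)
    stop("slide resolution is coarser than the target; upsampling unsupported")
  s
}

## Exact tissue coverage of the half-open footprint [x, x+foot) x [y, y+foot)
## (level-0, 0-based) against a mask grid at integer downsample ds: each grid
## cell is weighted by the number of level-0 pixels of the footprint it
## covers. Pixels beyond the grid (slide edge remainders) count as
## non-tissue.
footprint_coverage <- function(grid, ds, x, y, foot) {
  axis_weights <- function(a, n_cells) {
    j0 <- max(1L, floor(a / ds) + 1L)
    j1 <- min(n_cells, ceiling((a + foot) / ds))
    if (j1 < j0) return(NULL)
    j <- j0:j1
    w <- pmin(j * ds, a + foot) - pmax((j - 1) * ds, a)
    list(j = j, w = w)
  }
  cw <- axis_weights(x, ncol(grid))
  rw <- axis_weights(y, nrow(grid))
  if (is.null(cw) || is.null(rw)) return(0)
  sum(rw$w * (grid[rw$j, cw$j, drop = FALSE] %*% cw$w)) / foot^2
}

#' Enumerate tile origins over a tissue mask
#'
#' Origins lie on a regular grid with stride
#' `round(tile_px * (1 - overlap))` (scaled to level-0 pixels when the slide
#' is scanned finer than the target resolution), starting at `(0, 0)`,
#' restricted to footprints fully inside the slide. A tile is emitted iff
#' the tissue fraction of its footprint is at least `min_mask_coverage`.
#' Ordering is row-major (y outer, x inner) and deterministic.
#'
#' @param mask a `tissue_mask`.
#' @param config a [tile_config()].
#' @param native_mpp native microns per pixel of the slide (default: the
#'   target, i.e. level-0 extraction).
#' @return data.frame with columns `x`, `y` (level-0, 0-based top-left
#'   corners) and `coverage`.
#' @export
enumerate_tile_origins <- function(mask, config = tile_config(),
                                   native_mpp = config$target_mpp) {
  s <- level0_scale(native_mpp, config$target_mpp)
  foot <- as.integer(round(config$tile_px * s))
  stride <- as.integer(round(tile_stride(config) * s))
  h <- mask$slide_dim[1]; w <- mask$slide_dim[2]
  if (w < foot || h < foot)
    return(data.frame(x = integer(), y = integer(), coverage = numeric()))
  xs <- seq(0L, w - foot, by = stride)
  ys <- seq(0L, h - foot, by = stride)
  out <- vector("list", length(xs) * length(ys))
  k <- 0
  for (y in ys) for (x in xs) {
    cov <- footprint_coverage(mask$grid, mask$downsample, x, y, foot)
    if (cov >= config$min_mask_coverage) {
      k <- k + 1
      out[[k]] <- c(x, y, cov)
    }
  }
  if (k == 0)
    return(data.frame(x = integer(), y = integer(), coverage = numeric()))
  m <- do.call(rbind, out[seq_len(k)])
  data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2]), coverage = m[, 3])
}

#' Variance of the Laplacian response of a tile
#'
#' The tile is converted to grayscale with ITU-R 601 luma weights
#' (0.299/0.587/0.114) on the 0-255 scale and convolved with the 3x3
#' Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]`; the population variance of
#' the valid-region response is returned. Low values indicate blur or
#' featureless content.
#'
#' @param tile a `wsi_tile` or an h x w x 3 array on the 0-255 scale.
#' @return non-negative scalar.
#' @export
laplacian_variance <- function(tile) {
  px <- if (is.list(tile)) tile$pixels else tile
  g <- if (length(dim(px)) == 3) luma(px) else px
  h <- nrow(g); w <- ncol(g)
  if (h < 3 || w < 3) return(0)
  ctr <- g[2:(h - 1), 2:(w - 1)]
  L <- g[1:(h - 2), 2:(w - 1)] + g[3:h, 2:(w - 1)] +
       g[2:(h - 1), 1:(w - 2)] + g[2:(h - 1), 3:w] - 4 * ctr
  mean((L - mean(L))^2)
}

#' Extract one tile from a slide
#'
#' When the slide is scanned finer than the target resolution (e.g. 40x scan
#' for a 20x target), the level-0 source window of size
#' `tile_px * target_mpp / native_mpp` is reduced to `tile_px` by area
#' averaging (exact block mean for integer factors, bilinear resampling
#' otherwise). At native resolution extraction is a pure crop. The tile's
#' Laplacian variance, tissue coverage and - when the slide carries
#' generator ground truth - the true nucleus area fraction and blur overlap
#' of its footprint are recorded.
#'
#' @param slide a `slide_image`.
#' @param origin length-2 vector `c(x, y)`: level-0, 0-based top-left corner.
#' @param config a [tile_config()].
#' @param coverage optional precomputed tissue coverage to store.
#' @return an object of class `wsi_tile`: list with `slide_id`, `x`, `y`,
#'   `pixels`, `lap_var`, `mask_coverage`, and optionally `truth_density`,
#'   `truth_blur`.
#' @export
extract_tile <- function(slide, origin, config = tile_config(),
                         coverage = NA_real_) {
  s <- level0_scale(slide$mpp, config$target_mpp)
  foot <- as.integer(round(config$tile_px * s))
  x <- as.integer(origin[1]); y <- as.integer(origin[2])
  h <- nrow(slide$pixels); w <- ncol(slide$pixels)
  if (x < 0 || y < 0 || x + foot > w || y + foot > h)
    stop(sprintf("tile origin (%d, %d) with footprint %d px is out of bounds (%d x %d)",
                 x, y, foot, h, w))
  win <- slide$pixels[(y + 1):(y + foot), (x + 1):(x + foot), , drop = FALSE]
  px <- if (foot == config$tile_px) {
    win
  } else if (foot %% config$tile_px == 0) {
    block_mean_rgb(win, foot %/% config$tile_px)
  } else {
    rs <- EBImage::resize(win / 255, w = config$tile_px, h = config$tile_px,
                          antialias = TRUE)
    EBImage::imageData(rs) * 255
  }
  tile <- list(slide_id = slide$slide_id, x = x, y = y, foot = foot,
               pixels = px, lap_var = laplacian_variance(px),
               mask_coverage = coverage)
  if (!is.null(slide$truth)) {
    rows <- (y + 1):(y + foot); cols <- (x + 1):(x + foot)
    tile$truth_density <- mean(slide$truth$nuclei[rows, cols])
    tile$truth_blur <- mean(slide$truth$blur[rows, cols])
    tile$latent_class <- slide$truth$latent_class
  }
  structure(tile, class = "wsi_tile")
}

#' Quality-control filter on Laplacian variance
#'
#' Keeps exactly the tiles whose `lap_var` is at or above
#' `config$min_lap_var` ("lower than 500" is excluded, so the boundary is
#' kept). A pure threshold: permutation-invariant and idempotent.
#'
#' @param tiles list of `wsi_tile`.
#' @param config a [tile_config()].
#' @return the kept tiles, with attributes `n_input` and `n_dropped`.
#' @export
qc_filter <- function(tiles, config = tile_config()) {
  lv <- vapply(tiles, function(t) {
    stopifnot(!is.null(t$lap_var))
    t$lap_var
  }, numeric(1))
  keep <- lv >= config$min_lap_var
  out <- tiles[keep]
  attr(out, "n_input") <- length(tiles)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Tile manifest as a data.frame
#'
#' @param tiles list of `wsi_tile`.
#' @param kept optional logical vector marking QC-passing tiles.
#' @return data.frame with slide_id, x, y, lap_var, mask_coverage (and
#'   `kept` when given).
#' @export
tile_manifest <- function(tiles, kept = NULL) {
  df <- data.frame(
    slide_id = vapply(tiles, `[[`, character(1), "slide_id"),
    x = vapply(tiles, `[[`, integer(1), "x"),
    y = vapply(tiles, `[[`, integer(1), "y"),
    lap_var = vapply(tiles, `[[`, numeric(1), "lap_var"),
    mask_coverage = vapply(tiles, `[[`, numeric(1), "mask_coverage"),
    stringsAsFactors = FALSE)
  if (!is.null(kept)) df$kept <- kept
  df
}
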