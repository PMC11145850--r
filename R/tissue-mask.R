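## Tissue-vs-background segmentation with the dual HSV mask rule: one mask
## keeps high hue (the pink/purple H&E range), the other thresholds the
## saturation channel at Otsu's value capped at 25 (0-255 scale) so that an
## inflated automatic threshold cannot eat into weakly stained tissue.

#' Tissue mask configuration
#'
#' @param hue_cutoff pixels with HSV hue (scaled to `[0,1]`) at or above this
#'   value count as tissue in the hue mask (default 0.75).
#' @param sat_cap cap applied to the Otsu saturation threshold on the 0-255
#'   scale (default 25).
#' @param sat_cap_mode `"cap"` uses `min(otsu, sat_cap)` (default, keeps more
#'   tissue); `"add"` uses `otsu + sat_cap` (removes more).
#' @param combine how the hue and saturation masks merge: `"union"`
#'   (default) or `"intersection"`.
#' @param work_level_downsample integer downsample factor of the working
#'   raster the mask is computed on (default 16).
#' @return an object of class `mask_config`.
#' @export
mask_config <- function(hue_cutoff = 0.75, sat_cap = 25,
                        sat_cap_mode = c("cap", "add"),
                        combine = c("union", "intersection"),
                        work_level_downsample = 16) {
  sat_cap_mode <- match.arg(sat_cap_mode)
  combine <- match.arg(combine)
  if (!is_prob(hue_cutoff)) stop_config("hue_cutoff", "must be in [0, 1]")
  if (!is.numeric(sat_cap) || sat_cap < 0 || sat_cap > 255)
    stop_config("sat_cap", "must be in [0, 255]")
  if (!is_count(work_level_downsample))
    stop_config("work_level_downsample", "must be a positive integer")
  structure(list(hue_cutoff = hue_cutoff, sat_cap = sat_cap,
                 sat_cap_mode = sat_cap_mode, combine = combine,
                 work_level_downsample = work_level_downsample),
            class = "mask_config")
}

#' Otsu's threshold from a 256-bin histogram
#'
#' Returns the integer cut `t` in `[0, 255]` maximising the between-class
#' variance of the split `{bins <= t}` vs `{bins > t}`; ties are broken by
#' the lowest maximising index.
#'
#' @param histogram numeric vector of 256 non-negative counts for intensity
#'   values 0..255.
#' @return integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256 || any(histogram < 0))
    stop("histogram must be 256 non-negative counts")
  n <- sum(histogram)
  if (n == 0) stop("histogram is all zero")
  p <- histogram / n
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  w1 <- 1 - w0
  ## between-class variance; undefined (0/0) splits get 0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, 0)
  as.integer(lev[which.max(sigma_b)])
}

#' Compute the tissue mask of a slide
#'
#' The slide is block-mean downsampled to the working level, converted to
#' HSV, and two masks are formed: `hue >= hue_cutoff` and
#' `saturation > min(otsu, sat_cap)` on the 0-255 saturation scale. Their
#' union (default) is the tissue mask. Pixels with zero saturation (pure
#' greys, including the white background) have undefined hue and are always
#' background.
#'
#' @param slide a `slide_image` (or any list with `pixels` h x w x 3 on
#'   0-255).
#' @param config a [mask_config()].
#' @return object of class `tissue_mask`: list with `grid` (logical matrix
#'   at the working level), `downsample`, `tissue_fraction`, `slide_dim`
#'   (level-0 `c(h, w)`), `sat_threshold` and the config echo.
#' @export
compute_tissue_mask <- function(slide, config = mask_config()) {
  px <- slide$pixels
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  ds <- config$work_level_downsample
  if (nrow(px) < ds || ncol(px) < ds)
    stop(sprintf("working level %dx unavailable: slide is %d x %d px",
                 ds, nrow(px), ncol(px)))
  small <- block_mean_rgb(px, ds)
  hsv <- rgb2hsv(r = as.vector(small[, , 1]), g = as.vector(small[, , 2]),
                 b = as.vector(small[, , 3]), maxColorValue = 255)
  h <- matrix(hsv[1, ], nrow(small)); s <- matrix(hsv[2, ], nrow(small))
  s255 <- s * 255
  hist256 <- tabulate(pmin(pmax(round(s255), 0), 255) + 1L, nbins = 256)
  otsu <- otsu_threshold(hist256)
  thr <- if (config$sat_cap_mode == "cap") min(otsu, config$sat_cap)
         else otsu + config$sat_cap
  mask_sat <- s255 > thr
  mask_hue <- (h >= config$hue_cutoff) & (s255 > 0)
  grid <- if (config$combine == "union") mask_hue | mask_sat
          else mask_hue & mask_sat
  structure(list(grid = grid, downsample = ds,
                 tissue_fraction = mean(grid),
                 slide_dim = dim(px)[1:2],
                 sat_threshold = thr, otsu = otsu, config = config),
            class = "tissue_mask")
}

#' Write a tissue mask as PNG plus a JSON sidecar
#'
#' @param mask a `tissue_mask`.
#' @param path output PNG path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_tissue_mask <- function(mask, path) {
  png::writePNG(mask$grid * 1, path)
  jsonlite::write_json(list(downsample = mask$downsample,
                            tissue_fraction = mask$tissue_fraction,
                            sat_threshold = mask$sat_threshold,
                            config = unclass(mask$config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
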