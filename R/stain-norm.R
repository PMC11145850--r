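## Macenko stain normalisation. Per slide, the haematoxylin and eosin stain
## vectors are estimated once from the optical-density cloud of up to 100
## randomly sampled tiles and every tile of that slide is remapped with the
## same factor toward a reference stain basis.

#' Reference H&E stain vectors
#'
#' The widely used published unit optical-density directions for
#' haematoxylin and eosin; replaceable via [stain_config()].
#'
#' @return 3 x 2 matrix with unit columns `H`, `E` (rows R, G, B).
#' @export
reference_stain_vectors <- function() {
  m <- cbind(H = c(0.6443, 0.7167, 0.2669),
             E = c(0.0928, 0.9541, 0.2831))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Stain estimation configuration
#'
#' @param beta_od optical-density magnitude below which a pixel counts as
#'   transparent and is excluded from estimation (default 0.15).
#' @param alpha_pct robust percentile for the extreme stain angles (default
#'   1, i.e. the 1st and 99th percentile directions).
#' @param n_sample_tiles number of tiles sampled per slide for estimation
#'   (default 100).
#' @param max_pixels cap on pooled foreground pixels used for the SVD plane
#'   (subsampled per tile; default 200000).
#' @param reference_profile `stain_profile` toward which slides are mapped;
#'   default is built from [reference_stain_vectors()] with unit
#'   concentration scaling.
#' @return an object of class `stain_config`.
#' @export
stain_config <- function(beta_od = 0.15, alpha_pct = 1,
                         n_sample_tiles = 100, max_pixels = 200000,
                         reference_profile = NULL) {
  if (!is.numeric(beta_od) || beta_od <= 0) stop_config("beta_od", "must be > 0")
  if (!is.numeric(alpha_pct) || alpha_pct <= 0 || alpha_pct >= 50)
    stop_config("alpha_pct", "must be in (0, 50)")
  if (!is_count(n_sample_tiles))
    stop_config("n_sample_tiles", "must be a positive count")
  if (is.null(reference_profile))
    reference_profile <- stain_profile(reference_stain_vectors(), c(1, 1))
  structure(list(beta_od = beta_od, alpha_pct = alpha_pct,
                 n_sample_tiles = n_sample_tiles, max_pixels = max_pixels,
                 reference_profile = reference_profile),
            class = "stain_config")
}

#' Construct a stain profile
#'
#' @param stain_vectors 3 x 2 matrix of non-negative columns (haematoxylin
#'   first, identified by the larger red-channel optical-density loading);
#'   columns are normalised to unit length.
#' @param max_concentrations length-2 vector of per-stain concentration
#'   scale factors (the 99th percentile concentrations when estimated).
#' @param n_sample_tiles,seed provenance metadata.
#' @return an object of class `stain_profile`.
#' @export
stain_profile <- function(stain_vectors, max_concentrations,
                          n_sample_tiles = NA_integer_, seed = NA_integer_) {
  stopifnot(is.matrix(stain_vectors), all(dim(stain_vectors) == c(3, 2)),
            all(stain_vectors >= -1e-12), length(max_concentrations) == 2,
            all(max_concentrations > 0))
  v <- pmax(stain_vectors, 0)
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  if (v[1, 2] > v[1, 1]) {           # order H (larger red OD loading) first
    v <- v[, 2:1]
    max_concentrations <- max_concentrations[2:1]
  }
  colnames(v) <- c("H", "E")
  structure(list(stain_vectors = v,
                 max_concentrations = as.numeric(max_concentrations),
                 n_sample_tiles = n_sample_tiles, seed = seed),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>\n")
  print(round(x$stain_vectors, 4))
  cat("max concentrations:", round(x$max_concentrations, 4), "\n")
  invisible(x)
}

#' RGB to optical density
#'
#' `OD_c = -log10((I_c + 1) / 256)`: zero for white (255), maximal
#' (`log10(256) ~ 2.408`) for black, monotone decreasing in intensity. The
#' `+1` offset avoids `log(0)` and differs from the classical `I/I0`
#' convention by less than one quantisation level.
#'
#' @param rgb numeric vector/array of intensities on the 0-255 scale.
#' @return optical densities, same shape.
#' @export
optical_density <- function(rgb) {
  -log10((rgb + 1) / 256)
}

#' Optical density back to RGB
#'
#' Inverse of [optical_density()], clipped to `[0, 255]`.
#'
#' @param od non-negative optical densities.
#' @param round if `TRUE` (default) quantise to integer levels.
#' @return intensities on the 0-255 scale.
#' @export
od_to_rgb <- function(od, round = TRUE) {
  i <- 256 * 10^(-od) - 1
  i <- pmin(pmax(i, 0), 255)
  if (round) round(i) else i
}

tile_pixels <- function(tile) if (is.list(tile)) tile$pixels else tile

## n x 3 OD matrix from a tile
tile_od_matrix <- function(tile) {
  px <- tile_pixels(tile)
  matrix(optical_density(px), ncol = 3)
}

#' Estimate a slide's stain profile (Macenko)
#'
#' Samples `min(n_sample_tiles, n)` tiles without replacement, pools their
#' foreground optical-density pixels (OD magnitude above `beta_od`),
#' projects them onto the top-2 singular plane, takes the `alpha_pct` and
#' `100 - alpha_pct` percentile extreme angles as the stain directions, and
#' computes the 99th-percentile stain concentrations from non-negative
#' unmixing. Haematoxylin is ordered before eosin.
#'
#' @param tiles list of `wsi_tile` (or raw pixel arrays) from one slide.
#' @param config a [stain_config()].
#' @param seed RNG seed for tile and pixel sampling.
#' @return a [stain_profile()].
#' @export
estimate_stain_profile <- function(tiles, config = stain_config(), seed = 1) {
  stopifnot(length(tiles) >= 1)
  with_seed(derive_seed(seed, "stain_estimate"), {
    take <- sample(length(tiles), min(config$n_sample_tiles, length(tiles)))
    per_tile_cap <- max(1000, ceiling(config$max_pixels / length(take)))
    od <- do.call(rbind, lapply(tiles[take], function(t) {
      m <- tile_od_matrix(t)
      fg <- sqrt(rowSums(m^2)) > config$beta_od
      m <- m[fg, , drop = FALSE]
      if (nrow(m) > per_tile_cap)
        m <- m[sample(nrow(m), per_tile_cap), , drop = FALSE]
      m
    }))
    if (nrow(od) < 500)
      stop("insufficient stained tissue: only ", nrow(od),
           " foreground pixels above the OD cutoff")
    ev <- eigen(crossprod(od), symmetric = TRUE)
    if (ev$values[2] < 1e-4 * ev$values[1])
      stop("stain basis is degenerate: optical densities span a single ",
           "direction (single-stain image?)")
    V <- ev$vectors[, 1:2]
    for (k in 1:2) if (sum(od %*% V[, k]) < 0) V[, k] <- -V[, k]
    proj <- od %*% V
    phi <- atan2(proj[, 2], proj[, 1])
    ext <- quantile(phi, c(config$alpha_pct, 100 - config$alpha_pct) / 100,
                    names = FALSE)
    vecs <- sapply(ext, function(a) V %*% c(cos(a), sin(a)))
    prof <- stain_profile(vecs, c(1, 1), n_sample_tiles = length(take),
                          seed = seed)
    conc <- unmix_concentrations(od, prof$stain_vectors)
    prof$max_concentrations <- pmax(apply(conc, 2, quantile, 0.99), 1e-6)
    prof
  })
}

## Non-negative unmixing of an n x 3 OD matrix against a 3 x 2 stain basis:
## least-squares via the pseudo-inverse, clipped at zero.
unmix_concentrations <- function(od, vectors) {
  pinv <- solve(crossprod(vectors), t(vectors))
  pmax(od %*% t(pinv), 0)
}

#' Normalise a tile toward a reference stain basis
#'
#' The tile is unmixed against the source slide's stain vectors, per-stain
#' concentrations are rescaled by
#' `reference$max_concentrations / source$max_concentrations`, and the tile
#' is re-composited with the reference vectors. The source profile is
#' computed once per slide and reused for every tile of that slide.
#'
#' @param tile a `wsi_tile` or pixel array on the 0-255 scale.
#' @param source the slide's [stain_profile()].
#' @param reference the reference [stain_profile()].
#' @return the tile with normalised pixels (same type as the input).
#' @export
normalize_tile <- function(tile, source, reference) {
  stopifnot(inherits(source, "stain_profile"),
            inherits(reference, "stain_profile"))
  px <- tile_pixels(tile)
  dm <- dim(px)
  od <- matrix(optical_density(px), ncol = 3)
  conc <- unmix_concentrations(od, source$stain_vectors)
  conc <- sweep(conc, 2,
                reference$max_concentrations / source$max_concentrations, "*")
  out <- array(od_to_rgb(conc %*% t(reference$stain_vectors)), dim = dm)
  if (is.list(tile)) {
    tile$pixels <- out
    tile
  } else out
}

#' Serialise a stain profile to JSON
#'
#' @param profile a `stain_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(list(stain_vectors =
                              list(H = profile$stain_vectors[, "H"],
                                   E = profile$stain_vectors[, "E"]),
                            max_concentrations = profile$max_concentrations,
                            n_sample_tiles = profile$n_sample_tiles,
                            seed = profile$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
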