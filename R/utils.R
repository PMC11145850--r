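#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils head tail write.csv read.csv
#' @importFrom grDevices rgb2hsv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), matching how
#' percentages are conventionally printed in clinical tables, rather than
#' R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Deterministic stream splitting: every stochastic sub-step derives its own
## 31-bit seed from (master seed, string key) so that adding or reordering
## one stage never perturbs the draws of another.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (cp in utf8ToInt(paste0(key))) h <- (h * 31 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

## Evaluate expr with a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Block-mean downsample of a matrix by an integer factor; trailing rows and
## columns that do not fill a block are dropped (at most factor - 1 pixels).
block_mean <- function(m, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(m)
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  m <- m[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  ## sum over factor x factor blocks via two grouped row sums
  rg <- rowsum(m, rep(seq_len(nr), each = factor))
  cg <- t(rowsum(t(rg), rep(seq_len(nc), each = factor)))
  cg / factor^2
}

## Block-mean over the channels of an h x w x 3 array.
block_mean_rgb <- function(px, factor) {
  if (factor == 1) return(px)
  ch <- lapply(1:3, function(k) block_mean(px[, , k], factor))
  array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(dim(ch[[1]]), 3))
}

## Luma (ITU-R 601) grayscale from an h x w x 3 array on the 0-255 scale.
luma <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x > 0

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1

stop_config <- function(field, why) {
  stop(sprintf("invalid configuration: field '%s' %s", field, why),
       call. = FALSE)
}
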