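## Pluggable tile scoring. A scorer is any function mapping a tile to a
## probability in [0, 1] that the tile shows high-risk (NHG3-like)
## morphology; an ensemble is a list of scorers whose outputs are averaged
## per tile. The package ships a test-only oracle scorer that reads the
## generator's ground truth, and a desk-scale reference convolutional
## classifier trained with SGD under a reduce-on-plateau learning-rate
## schedule and binary cross-entropy.

#' Score tiles with an ensemble of scorers
#'
#' `p_high` is the arithmetic mean of the member probabilities; output order
#' matches input order. The mean is permutation-invariant in the members and
#' bounded by the member minimum and maximum.
#'
#' @param tiles list of `wsi_tile`.
#' @param ensemble a single scorer function or a (optionally named) list of
#'   scorer functions.
#' @return data.frame with columns `slide_id`, `x`, `y`, `p_high`.
#' @export
score_tiles <- function(tiles, ensemble) {
  if (is.function(ensemble)) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1, all(vapply(ensemble, is.function, TRUE)))
  nm <- names(ensemble) %||% as.character(seq_along(ensemble))
  nm[nm == ""] <- as.character(seq_along(ensemble))[nm == ""]
  p <- vapply(tiles, function(t) {
    probs <- vapply(seq_along(ensemble), function(j) {
      v <- ensemble[[j]](t)
      if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
        stop(sprintf("scorer contract violation: member '%s' returned %s",
                     nm[j], paste(format(v), collapse = ",")))
      v
    }, numeric(1))
    mean(probs)
  }, numeric(1))
  data.frame(
    slide_id = vapply(tiles, function(t) t$slide_id %||% NA_character_,
                      character(1)),
    x = vapply(tiles, function(t) as.integer(t$x %||% NA_integer_), integer(1)),
    y = vapply(tiles, function(t) as.integer(t$y %||% NA_integer_), integer(1)),
    p_high = p, stringsAsFactors = FALSE)
}

#' Oracle tile scorer (test double)
#'
#' Returns a scorer that reads the generator's ground-truth nucleus area
#' fraction attached to a tile (`truth_density`) and maps it through a
#' calibrated logistic curve, optionally perturbed by Gaussian noise on the
#' logit scale. A stand-in for trained network weights, usable only on
#' synthetic tiles carrying truth metadata.
#'
#' @param noise_sd standard deviation of the logit-scale Gaussian noise
#'   (0 = deterministic, perfectly class-ordered scores).
#' @param midpoint density at which the score is 0.5; defaults to the
#'   midpoint of the generator's class densities.
#' @param slope logistic slope per unit density.
#' @return a scorer function.
#' @export
oracle_scorer <- function(noise_sd = 0,
                          midpoint = mean(NUCLEI_AREA_FRAC),
                          slope = 250) {
  force(noise_sd); force(midpoint); force(slope)
  function(tile) {
    d <- tile$truth_density
    if (is.null(d) || is.na(d))
      stop("oracle scorer requires generator truth metadata on the tile")
    z <- slope * (d - midpoint)
    if (noise_sd > 0) z <- z + rnorm(1, 0, noise_sd)
    plogis(z)
  }
}

## ---- scorer registry ------------------------------------------------------

.scorer_registry <- new.env(parent = emptyenv())

#' Register / look up scorer factories by name
#'
#' The registry maps names to factory functions returning a scorer; pipeline
#' configurations refer to scorers by these names.
#'
#' @param name registry key.
#' @param factory function(...) returning a scorer function.
#' @return `register_scorer` the name (invisibly); `get_scorer` a scorer.
#' @export
register_scorer <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = .scorer_registry)
  invisible(name)
}

#' @rdname register_scorer
#' @param ... passed to the factory.
#' @export
get_scorer <- function(name, ...) {
  if (!exists(name, envir = .scorer_registry))
    stop(sprintf("unknown scorer '%s'; registered: %s", name,
                 paste(ls(.scorer_registry), collapse = ", ")))
  get(name, envir = .scorer_registry)(...)
}

#' @rdname register_scorer
#' @export
list_scorers <- function() ls(.scorer_registry)

## ---- reference mini-CNN ---------------------------------------------------

#' Training configuration for the reference model
#'
#' The optimisation recipe: stochastic gradient descent with binary
#' cross-entropy, learning rate starting at `1e-3` and halved whenever the
#' validation loss has not improved for `plateau_patience` epochs.
#'
#' @param hidden_units width of the fully connected layer after the
#'   convolutional features (default 32 at desk scale).
#' @param initial_lr initial learning rate (default `1e-3`).
#' @param lr_decay_factor multiplier applied on plateau (default 0.5).
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate decays (default 10).
#' @param n_filters convolutional filters (default 8, 5x5, stride 2).
#' @param input_px grayscale input edge length the tile is reduced to
#'   (default 32).
#' @param epochs,batch_size,momentum,val_fraction SGD bookkeeping.
#' @param seed RNG seed; training is deterministic given data and seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(hidden_units = 32, initial_lr = 1e-3,
                         lr_decay_factor = 0.5, plateau_patience = 10,
                         n_filters = 8, input_px = 32, epochs = 150,
                         batch_size = 32, momentum = 0.9,
                         val_fraction = 0.2, seed = 1) {
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1)
    stop_config("lr_decay_factor", "must be in (0, 1)")
  if (!is_count(plateau_patience))
    stop_config("plateau_patience", "must be a positive integer")
  structure(list(hidden_units = hidden_units, initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 plateau_patience = plateau_patience,
                 n_filters = n_filters, input_px = input_px,
                 epochs = epochs, batch_size = batch_size,
                 momentum = momentum, val_fraction = val_fraction,
                 seed = seed),
            class = "train_config")
}

#' Reduce-on-plateau learning-rate trajectory
#'
#' Given the sequence of validation losses, returns the learning rate in
#' force at each epoch: the rate is multiplied by `factor` as soon as the
#' loss has failed to improve on its running best for `patience` consecutive
#' epochs (the counter then resets).
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param initial_lr starting rate.
#' @param factor decay multiplier in (0, 1).
#' @param patience epochs of tolerated non-improvement.
#' @return numeric vector of the learning rate used at each epoch.
#' @export
plateau_lr <- function(val_losses, initial_lr, factor = 0.5, patience = 10) {
  lr <- initial_lr
  best <- Inf
  wait <- 0
  out <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    out[e] <- lr
    if (val_losses[e] < best - 1e-9) {
      best <- val_losses[e]
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0
      }
    }
  }
  out
}

## Grayscale input vector for the CNN: luma, block-mean reduced to at least
## input_px, cropped to input_px x input_px, scaled to [-0.5, 0.5].
prep_tile_input <- function(tile, input_px) {
  px <- tile_pixels(tile)
  g <- if (length(dim(px)) == 3) luma(px) else px
  f <- max(1L, min(nrow(g), ncol(g)) %/% input_px)
  g <- block_mean(g, f)
  if (nrow(g) < input_px || ncol(g) < input_px)
    stop(sprintf("tile too small: need >= %d px after reduction", input_px))
  as.vector(g[seq_len(input_px), seq_len(input_px)]) / 255 - 0.5
}

## column-major patch indices for a k x k kernel at stride s on an n x n image
conv_patch_index <- function(n, k, s) {
  pos <- seq(1, n - k + 1, by = s)
  offs <- as.vector(outer(0:(k - 1), 0:(k - 1) * n, "+"))   # within-patch
  starts <- as.vector(outer(pos, (pos - 1) * n, "+"))       # top-left corners
  outer(starts, offs, "+")                                  # n_pos x k^2
}

## `norm` holds the frozen feature standardisation (mean/sd of the pooled
## conv features under the initial weights); it rescales both activations
## and gradients so plain SGD at the configured rate makes progress.
cnn_forward <- function(X, par, idx, norm) {
  n <- nrow(X); n_pos <- nrow(idx)
  P <- matrix(array(X[, as.vector(idx)], c(n, n_pos, ncol(idx))),
              n * n_pos, ncol(idx))
  Z1 <- sweep(P %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  G <- rowsum(A1, rep(seq_len(n), n_pos)) / n_pos      # global average pool
  Gs <- sweep(sweep(G, 2, norm$mu, "-"), 2, norm$sd, "/")
  Z2 <- sweep(Gs %*% par$W2, 2, par$b2, "+")
  H <- pmax(Z2, 0)
  o <- as.vector(H %*% par$w3) + par$b3
  list(P = P, Z1 = Z1, Gs = Gs, Z2 = Z2, H = H, p = plogis(o))
}

cnn_backward <- function(X, y, fw, par, idx, norm) {
  n <- nrow(X); n_pos <- nrow(idx)
  d_o <- (fw$p - y) / n                           # BCE + sigmoid
  g_w3 <- as.vector(t(fw$H) %*% d_o)
  g_b3 <- sum(d_o)
  dH <- outer(d_o, par$w3) * (fw$Z2 > 0)
  g_W2 <- t(fw$Gs) %*% dH
  g_b2 <- colSums(dH)
  dG <- sweep(dH %*% t(par$W2), 2, norm$sd, "/")
  dA1 <- dG[rep(seq_len(n), n_pos), , drop = FALSE] / n_pos
  dZ1 <- dA1 * (fw$Z1 > 0)
  g_W1 <- t(fw$P) %*% dZ1
  g_b1 <- colSums(dZ1)
  list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2, w3 = g_w3, b3 = g_b3)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the reference convolutional tile classifier
#'
#' A small convolutional network (one 5x5/stride-2 convolutional layer with
#' ReLU, global average pooling, one hidden fully connected ReLU layer, and
#' a sigmoid output) trained with mini-batch SGD with momentum, binary
#' cross-entropy loss, and a learning rate halved whenever the validation
#' loss plateaus for `plateau_patience` epochs. Deterministic given data and
#' seed; trains in seconds to minutes on one CPU at synthetic fixture sizes.
#'
#' @param tiles list of `wsi_tile` (or raw pixel arrays).
#' @param labels vector of class labels: 0/1 or `"low"`/`"high"`.
#' @param config a [train_config()].
#' @return an object of class `wsi_cnn` with the fitted weights, the
#'   per-epoch learning-rate and loss history, usable via [as_scorer()].
#' @export
train_reference_model <- function(tiles, labels, config = train_config()) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "high") else as.integer(labels)
  stopifnot(length(y) == length(tiles), all(y %in% 0:1))
  if (length(unique(y)) < 2)
    stop("training requires both classes to be present")
  np <- config$input_px
  X <- t(vapply(tiles, prep_tile_input, numeric(np * np), input_px = np))
  idx <- conv_patch_index(np, 5L, 2L)

  with_seed(derive_seed(config$seed, "cnn_train"), {
    n <- nrow(X)
    n_val <- max(2L, floor(config$val_fraction * n))
    val <- sample(n, n_val)
    tr <- setdiff(seq_len(n), val)

    K <- config$n_filters; Hn <- config$hidden_units
    par <- list(W1 = matrix(rnorm(25 * K, 0, sqrt(2 / 25)), 25, K),
                b1 = numeric(K),
                W2 = matrix(rnorm(K * Hn, 0, sqrt(2 / K)), K, Hn),
                b2 = numeric(Hn),
                w3 = rnorm(Hn, 0, sqrt(1 / Hn)),
                b3 = 0)
    vel <- lapply(par, function(p) p * 0)

    ## frozen feature standardisation from the initial forward pass
    g0 <- cnn_forward(X[tr, , drop = FALSE], par,
                      idx, list(mu = rep(0, K), sd = rep(1, K)))
    mu0 <- colMeans(g0$Gs)
    sd0 <- pmax(apply(g0$Gs, 2, sd), 1e-6)
    norm <- list(mu = mu0, sd = sd0)

    lr <- config$initial_lr
    best <- Inf; wait <- 0
    lr_hist <- val_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr_hist[ep] <- lr
      ord <- sample(tr)
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        fw <- cnn_forward(X[b, , drop = FALSE], par, idx, norm)
        gr <- cnn_backward(X[b, , drop = FALSE], y[b], fw, par, idx, norm)
        for (nmp in names(par)) {
          vel[[nmp]] <- config$momentum * vel[[nmp]] - lr * gr[[nmp]]
          par[[nmp]] <- par[[nmp]] + vel[[nmp]]
        }
      }
      fv <- cnn_forward(X[val, , drop = FALSE], par, idx, norm)
      val_hist[ep] <- bce_loss(fv$p, y[val])
      ## reduce-on-plateau (same rule as plateau_lr)
      if (val_hist[ep] < best - 1e-9) {
        best <- val_hist[ep]; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$plateau_patience) {
          lr <- lr * config$lr_decay_factor; wait <- 0
        }
      }
    }
    structure(list(par = par, norm = norm, config = config, idx = idx,
                   lr_history = lr_hist, val_loss = val_hist),
              class = "wsi_cnn")
  })
}

#' Predict tile probabilities with the reference model
#'
#' @param object a `wsi_cnn`.
#' @param tiles list of tiles or pixel arrays.
#' @param ... unused.
#' @return numeric vector of `P(high | tile)`.
#' @export
predict.wsi_cnn <- function(object, tiles, ...) {
  np <- object$config$input_px
  X <- t(vapply(tiles, prep_tile_input, numeric(np * np), input_px = np))
  cnn_forward(X, object$par, object$idx, object$norm)$p
}

#' Wrap a fitted model as a scorer function
#'
#' @param model a `wsi_cnn`.
#' @return a scorer: function(tile) -> probability.
#' @export
as_scorer <- function(model) {
  force(model)
  function(tile) as.numeric(predict(model, list(tile)))
}
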