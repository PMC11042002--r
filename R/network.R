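# Trainable network construction and execution.
#
# A network instance holds its architecture_spec plus a parameter store:
# for each convolution a weight array [kh, kw, c_in, c_out] and a bias
# vector; for an inception module six such pairs; for the linear head a
# [c_in, num_classes] matrix and a bias vector.  Forward/backward run on
# the GEMM kernels in src/, batched as [h, w, c, n] arrays.

glorot_normal <- function(n, fan_in, fan_out) {
  stats::rnorm(n, mean = 0, sd = sqrt(2 / (fan_in + fan_out)))
}

init_conv <- function(kh, kw, c_in, c_out) {
  fan_in <- kh * kw * c_in
  fan_out <- kh * kw * c_out
  list(w = array(glorot_normal(kh * kw * c_in * c_out, fan_in, fan_out),
                 dim = c(kh, kw, c_in, c_out)),
       b = numeric(c_out))
}

inception_branches <- function(cfg, c_in) {
  list(p1 = c(1L, c_in, cfg$one_by_one),
       r3 = c(1L, c_in, cfg$three_reduce),
       c3 = c(3L, cfg$three_reduce, cfg$three_by_three),
       r5 = c(1L, c_in, cfg$five_reduce),
       c5 = c(5L, cfg$five_reduce, cfg$five_by_five),
       pp = c(1L, c_in, cfg$pool_proj))
}

#' Build a trainable network from an architecture spec
#'
#' Convolution and linear weights are drawn from the Glorot (Xavier)
#' normal distribution -- zero mean, variance `2 / (fan_in + fan_out)` --
#' and all biases start at zero.  Construction is deterministic given
#' `seed` and does not disturb the caller's RNG state.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer initialization seed.
#' @param input_scaling `"unit"` feeds pixel intensities in `[0, 1]` as-is;
#'   `"centered"` rescales them to `[-1, 1]` (`2x - 1`) at the input layer.
#'   Stored on the network so training, evaluation and interpretation all
#'   apply the same convention.
#' @return A `diatomnet_network` object; its stored parameter total equals
#'   `count_parameters(spec)$total` exactly.
#' @export
build_network <- function(spec, seed = 0L,
                          input_scaling = c("unit", "centered")) {
  input_scaling <- match.arg(input_scaling)
  stopifnot(inherits(spec, "architecture_spec"))
  tr <- trace_shapes(spec)
  params <- vector("list", length(spec$layers))
  with_preserved_rng({
    set.seed(seed)
    c_in <- spec$input_channels
    feat_in <- spec$input_height * spec$input_width * spec$input_channels
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      if (ly$kind == "convolution") {
        params[[i]] <- init_conv(ly$patch_height, ly$patch_width, c_in,
                                 ly$out_channels)
      } else if (ly$kind == "inception") {
        br <- inception_branches(ly$inception, c_in)
        params[[i]] <- lapply(br, function(g) init_conv(g[1], g[1], g[2], g[3]))
      } else if (ly$kind == "linear") {
        # the head consumes the flattened tensor (1 x 1 x C after a global
        # pool, but any spatial extent is accepted)
        params[[i]] <- list(
          w = matrix(glorot_normal(feat_in * ly$out_channels, feat_in,
                                   ly$out_channels),
                     feat_in, ly$out_channels),
          b = numeric(ly$out_channels))
      }
      c_in <- tr$channels[i]
      feat_in <- tr$height[i] * tr$width[i] * tr$channels[i]
    }
  })
  structure(list(spec = spec, params = params, rng_seed = as.integer(seed),
                 input_scaling = input_scaling, trace = tr),
            class = "diatomnet_network")
}

#' Number of parameters actually stored in a network
#' @param net a `diatomnet_network`.
#' @return Integer count of stored weight and bias entries.
#' @export
network_parameter_total <- function(net) {
  count_leaf <- function(p) {
    if (is.list(p)) sum(vapply(p, count_leaf, numeric(1))) else length(p)
  }
  sum(vapply(net$params[!vapply(net$params, is.null, TRUE)], count_leaf,
             numeric(1)))
}

conv_apply <- function(x, pm, ly, want_cols = FALSE) {
  kh <- dim(pm$w)[1]; kw <- dim(pm$w)[2]
  pd <- pad_for(ly$padding_mode %||% "same_like", kh, kw)
  wmat <- pm$w; dim(wmat) <- c(kh * kw * dim(pm$w)[3], dim(pm$w)[4])
  conv_forward_cpp(x, wmat, pm$b, kh, kw, ly$stride %||% 1L, pd[1], pd[2],
                   TRUE, want_cols && kh * kw > 1L)
}

cat_channels <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[3]
    out[, , (at + 1):(at + k), ] <- p
    at <- at + k
  }
  out
}

# Forward pass over a batch.  Returns logits/probabilities and, on request,
# per-layer caches for backprop or the per-layer activations for
# interpretability.  Dropout uses the current RNG stream when training.
forward_batch <- function(net, x, training = FALSE, keep_cache = FALSE,
                          keep_activations = FALSE) {
  spec <- net$spec
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != spec$input_height || d[2] != spec$input_width ||
      d[3] != spec$input_channels)
    stop(sprintf("input shape [%s] does not match spec input %dx%dx%d (h,w,c)",
                 paste(d[1:3], collapse = ","), spec$input_height,
                 spec$input_width, spec$input_channels))
  n <- d[4]
  if (identical(net$input_scaling, "centered")) x <- x * 2 - 1
  caches <- if (keep_cache) vector("list", length(spec$layers))
  acts <- if (keep_activations) vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    pm <- net$params[[i]]
    cache <- NULL
    if (ly$kind == "convolution") {
      res <- conv_apply(x, pm, ly)
      if (keep_cache) cache <- list(x = x, y = res$y, cols = res$cols)
      x <- res$y
    } else if (ly$kind == "max_pool") {
      pd <- pad_for(ly$padding_mode, ly$patch_height, ly$patch_width)
      res <- maxpool_forward_cpp(x, ly$patch_height, ly$patch_width,
                                 ly$stride, pd[1], pd[2],
                                 identical(ly$padding_mode, "none_ceil"))
      if (keep_cache) cache <- list(idx = res$idx, xdim = dim(x))
      x <- res$y
    } else if (ly$kind == "avg_pool") {
      if (keep_cache) cache <- list(xdim = dim(x))
      x <- avgpool_forward_cpp(x, ly$patch_height, ly$patch_width, ly$stride)
    } else if (ly$kind == "cross_channel_norm") {
      np <- ly$norm_params
      res <- lrn_forward_cpp(x, np$window, np$k, np$alpha, np$beta)
      if (keep_cache) cache <- list(x = x, scale = res$scale)
      x <- res$y
    } else if (ly$kind == "inception") {
      kc <- FALSE
      b1 <- conv_apply(x, pm$p1, list(stride = 1L), kc)
      r3 <- conv_apply(x, pm$r3, list(stride = 1L), kc)
      b3 <- conv_apply(r3$y, pm$c3, list(stride = 1L), kc)
      r5 <- conv_apply(x, pm$r5, list(stride = 1L), kc)
      b5 <- conv_apply(r5$y, pm$c5, list(stride = 1L), kc)
      pl <- maxpool_forward_cpp(x, 3L, 3L, 1L, 1L, 1L, FALSE)
      b4 <- conv_apply(pl$y, pm$pp, list(stride = 1L), kc)
      y <- cat_channels(list(b1$y, b3$y, b5$y, b4$y))
      if (keep_cache)
        cache <- list(x = x, b1 = b1, r3 = r3, b3 = b3, r5 = r5, b5 = b5,
                      pool = pl, b4 = b4)
      x <- y
    } else if (ly$kind == "dropout") {
      if (training) {
        mask <- array((stats::runif(length(x)) >= ly$rate) / (1 - ly$rate),
                      dim = dim(x))
        if (keep_cache) cache <- list(mask = mask)
        x <- x * mask
      } else if (keep_cache) cache <- list(mask = NULL)
    } else if (ly$kind == "linear") {
      xdim <- dim(x)
      xf <- matrix(x, nrow = prod(xdim[1:3]), ncol = n)   # features x n
      if (keep_cache) cache <- list(xf = xf, xdim = xdim)
      x <- t(pm$w) %*% xf + pm$b                          # classes x n
    } else if (ly$kind == "softmax") {
      z <- x - matrix(apply(x, 2, max), nrow(x), n, byrow = TRUE)
      e <- exp(z)
      x <- e / matrix(colSums(e), nrow(x), n, byrow = TRUE)
    }
    if (keep_cache && !is.null(cache)) caches[[i]] <- cache
    if (keep_activations) acts[[i]] <- x
  }
  list(probs = x, caches = caches, activations = acts)
}

conv_grad <- function(cache, pm, ly, dy, need_dx = TRUE) {
  kh <- dim(pm$w)[1]; kw <- dim(pm$w)[2]
  pd <- pad_for(ly$padding_mode %||% "same_like", kh, kw)
  wmat <- pm$w; dim(wmat) <- c(kh * kw * dim(pm$w)[3], dim(pm$w)[4])
  g <- conv_backward_cpp(cache$x, wmat, dy, cache$y, kh, kw,
                         ly$stride %||% 1L, pd[1], pd[2], TRUE, need_dx,
                         cache$cols)
  dim(g$dw) <- dim(pm$w)
  g
}

# Backward pass from softmax cross-entropy.  `labels` are 1-based class
# indices; returns mean loss over the batch plus gradients mirroring the
# parameter store.
backward_batch <- function(net, fw, labels) {
  spec <- net$spec
  probs <- fw$probs
  n <- ncol(probs)
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[cbind(labels, seq_len(n))], eps)))
  # d(mean CE)/d(logits) = (probs - onehot)/n  (softmax folded in)
  dy <- probs / n
  dy[cbind(labels, seq_len(n))] <- dy[cbind(labels, seq_len(n))] - 1 / n
  grads <- vector("list", length(spec$layers))
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    pm <- net$params[[i]]
    cache <- fw$caches[[i]]
    if (ly$kind == "softmax") {
      next  # folded into the cross-entropy gradient
    } else if (ly$kind == "linear") {
      dw <- cache$xf %*% t(dy)
      db <- rowSums(dy)
      dxf <- pm$w %*% dy
      grads[[i]] <- list(w = dw, b = db)
      dy <- array(dxf, dim = cache$xdim)
    } else if (ly$kind == "dropout") {
      if (!is.null(cache$mask)) dy <- dy * cache$mask
    } else if (ly$kind == "avg_pool") {
      dy <- avgpool_backward_cpp(dy, cache$xdim, ly$patch_height,
                                 ly$patch_width, ly$stride)
    } else if (ly$kind == "max_pool") {
      dy <- maxpool_backward_cpp(dy, cache$idx, cache$xdim)
    } else if (ly$kind == "cross_channel_norm") {
      np <- ly$norm_params
      dy <- lrn_backward_cpp(cache$x, cache$scale, dy, np$window, np$alpha,
                             np$beta)
    } else if (ly$kind == "convolution") {
      g <- conv_grad(cache, pm, ly, dy, need_dx = i > 1L)
      grads[[i]] <- list(w = g$dw, b = g$db)
      dy <- g$dx
    } else if (ly$kind == "inception") {
      need_dx <- i > 1L
      cs <- c(dim(cache$b1$y)[3], dim(cache$b3$y)[3], dim(cache$b5$y)[3],
              dim(cache$b4$y)[3])
      off <- cumsum(c(0, cs))
      take <- function(k) dy[, , (off[k] + 1):(off[k + 1]), , drop = FALSE]
      g1 <- conv_grad(list(x = cache$x, y = cache$b1$y, cols = cache$b1$cols),
                      pm$p1, list(stride = 1L), take(1), need_dx)
      g3b <- conv_grad(list(x = cache$r3$y, y = cache$b3$y,
                            cols = cache$b3$cols),
                       pm$c3, list(stride = 1L), take(2))
      g3r <- conv_grad(list(x = cache$x, y = cache$r3$y, cols = cache$r3$cols),
                       pm$r3, list(stride = 1L), g3b$dx, need_dx)
      g5b <- conv_grad(list(x = cache$r5$y, y = cache$b5$y,
                            cols = cache$b5$cols),
                       pm$c5, list(stride = 1L), take(3))
      g5r <- conv_grad(list(x = cache$x, y = cache$r5$y, cols = cache$r5$cols),
                       pm$r5, list(stride = 1L), g5b$dx, need_dx)
      gpp <- conv_grad(list(x = cache$pool$y, y = cache$b4$y,
                            cols = cache$b4$cols),
                       pm$pp, list(stride = 1L), take(4), need_dx)
      grads[[i]] <- list(p1 = list(w = g1$dw, b = g1$db),
                         r3 = list(w = g3r$dw, b = g3r$db),
                         c3 = list(w = g3b$dw, b = g3b$db),
                         r5 = list(w = g5r$dw, b = g5r$db),
                         c5 = list(w = g5b$dw, b = g5b$db),
                         pp = list(w = gpp$dw, b = gpp$db))
      if (need_dx) {
        dpool <- maxpool_backward_cpp(gpp$dx, cache$pool$idx, dim(cache$x))
        dy <- g1$dx + g3r$dx + g5r$dx + dpool
      } else dy <- NULL
    }
  }
  list(loss = loss, grads = grads)
}

#' Run a forward pass and produce a class prediction
#'
#' @param net a [build_network()] instance.
#' @param image a `[height, width, channels]` pixel array with intensities
#'   in `[0, 1]` matching the spec input size, or a `[h, w, c, n]` batch.
#' @param training_mode when `TRUE`, dropout is active (stochastic); at
#'   inference the pass is a pure function of parameters and input.
#' @return For a single image, a `prediction` list: `probabilities` (vector
#'   over classes, summing to 1), `predicted_class` (1-based index; argmax
#'   ties broken toward the lowest index), `confidence` (max probability).
#'   For a batch, a list of predictions.
#' @export
forward <- function(net, image, training_mode = FALSE) {
  fw <- forward_batch(net, image, training = training_mode)
  preds <- lapply(seq_len(ncol(fw$probs)), function(j) {
    p <- fw$probs[, j]
    k <- which.max(p)  # which.max returns the first (lowest-index) maximum
    structure(list(probabilities = p, predicted_class = as.integer(k),
                   confidence = p[k]),
              class = "prediction")
  })
  if (length(preds) == 1L) preds[[1]] else preds
}

#' Save / load a network checkpoint
#'
#' The archive stores the spec, initialization seed, full parameter store
#' and optional training metadata; the round trip is bit-exact.
#'
#' @param net a `diatomnet_network`; `path` a file path; `meta` optional
#'   list of training metadata stored alongside.
#' @export
save_checkpoint <- function(net, path, meta = NULL) {
  saveRDS(list(spec = net$spec, params = net$params, rng_seed = net$rng_seed,
               input_scaling = net$input_scaling,
               labels = attr(net, "labels"), meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- structure(list(spec = ck$spec, params = ck$params,
                        rng_seed = ck$rng_seed,
                        input_scaling = ck$input_scaling %||% "unit",
                        trace = trace_shapes(ck$spec)),
                   class = "diatomnet_network")
  attr(net, "meta") <- ck$meta
  if (!is.null(ck$labels)) attr(net, "labels") <- ck$labels
  net
}

# Evaluate mean cross-entropy loss and accuracy over crops (inference mode).
eval_loss_acc <- function(net, xlist, labels, batch_size = 32L) {
  n <- length(labels)
  tot_loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    xb <- bind_batch(xlist[ids])
    fw <- forward_batch(net, xb)
    p <- fw$probs
    eps <- 1e-12
    tot_loss <- tot_loss - sum(log(pmax(p[cbind(labels[ids],
                                                seq_along(ids))], eps)))
    correct <- correct + sum(apply(p, 2, which.max) == labels[ids])
  }
  list(loss = tot_loss / n, accuracy = correct / n)
}

bind_batch <- function(xlist) {
  d <- dim(xlist[[1]])
  array(unlist(xlist, use.names = FALSE), dim = c(d, length(xlist)))
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
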