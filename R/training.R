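# SGD training with momentum and early stopping.

#' Training configuration
#'
#' Defaults follow the published protocol: SGD with learning rate 1e-4,
#' momentum 0.9, mini-batches of 16, up to 300 epochs from scratch, early
#' stopping on validation loss.  The early-stopping criterion (monitor,
#' patience 10, min_delta 0, best-weight restoration) is this package's
#' own convention; the source protocol states only that early stopping
#' was used.
#'
#' @param learning_rate SGD step size (> 0).
#' @param momentum classical momentum coefficient in `[0, 1)`.
#' @param batch_size mini-batch size (last short batch is kept).
#' @param max_epochs epoch cap.
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param min_delta minimum decrease in validation loss that counts as an
#'   improvement.
#' @param seed master seed; fans out to shuffling and dropout streams.
#' @param shuffle_each_epoch reshuffle mini-batches every epoch.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9,
                         batch_size = 16L, max_epochs = 300L, patience = 10L,
                         min_delta = 0, seed = 0L,
                         shuffle_each_epoch = TRUE) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, batch_size >= 1,
            patience >= 1, max_epochs >= 1, min_delta >= 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch)),
            class = "train_config")
}

map_params <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(mapply(map_params, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  f(a, b)
}

zero_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

crops_by_split <- function(crops, manifest, split) {
  ids <- manifest$crop_id[manifest$split == split]
  idx <- match(ids, vapply(crops, `[[`, "", "crop_id"))
  if (anyNA(idx))
    stop("manifest references crop_ids absent from the crop set (split ",
         split, ")")
  crops[idx]
}

#' Train a network with SGD + momentum and early stopping
#'
#' Runs mini-batch stochastic gradient descent with classical momentum
#' (`v <- momentum * v - lr * grad; w <- w + v`) on mean cross-entropy
#' loss.  Batches are drawn in a seed-determined shuffled order each
#' epoch; validation loss and accuracy are computed once per epoch in
#' inference mode (dropout off).  Training halts at `max_epochs` or when
#' validation loss has not improved by `min_delta` for `patience` epochs;
#' the weights of the best epoch are restored in the returned network.
#'
#' @param net a [build_network()] instance.
#' @param crops list of `diatom_crop` objects covering the manifest.
#' @param manifest a `dataset_manifest` with nonempty train and validation
#'   splits.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return List with `net` (best-epoch weights) and `log` (a `train_log`
#'   data frame: epoch, train_loss, train_accuracy, val_loss,
#'   val_accuracy; attributes `best_epoch` and `stopped_epoch`).
#' @export
train_network <- function(net, crops, manifest, config = train_config(),
                          verbose = FALSE) {
  labels <- sort(unique(manifest$species))
  tr_crops <- crops_by_split(crops, manifest, "train")
  va_crops <- crops_by_split(crops, manifest, "validation")
  if (length(tr_crops) == 0) stop("empty training split")
  if (length(va_crops) == 0) stop("empty validation split")
  tr_x <- lapply(tr_crops, `[[`, "pixels")
  tr_y <- match(vapply(tr_crops, `[[`, "", "species"), labels)
  va_x <- lapply(va_crops, `[[`, "pixels")
  va_y <- match(vapply(va_crops, `[[`, "", "species"), labels)
  n <- length(tr_y)
  vel <- lapply(net$params, zero_like)
  best <- list(epoch = 0L, loss = Inf, params = net$params)
  log_rows <- list()
  stopped <- NA_integer_
  with_preserved_rng({
    set.seed(config$seed + 1L)  # shuffling + dropout stream
    for (epoch in seq_len(config$max_epochs)) {
      ord <- if (config$shuffle_each_epoch || epoch == 1L) sample.int(n)
             else seq_len(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- bind_batch(tr_x[ids])
        fw <- forward_batch(net, xb, training = TRUE, keep_cache = TRUE)
        bw <- backward_batch(net, fw, tr_y[ids])
        if (!is.finite(bw$loss))
          stop("non-finite training loss at epoch ", epoch, ", batch ",
               (start - 1) %/% config$batch_size + 1)
        for (i in seq_along(net$params)) {
          if (is.null(bw$grads[[i]])) next
          vel[[i]] <- map_params(vel[[i]], bw$grads[[i]], function(v, g)
            config$momentum * v - config$learning_rate * g)
          net$params[[i]] <- map_params(net$params[[i]], vel[[i]],
                                        function(w, v) w + v)
        }
        ep_loss <- ep_loss + bw$loss * length(ids)
        ep_correct <- ep_correct +
          sum(apply(fw$probs, 2, which.max) == tr_y[ids])
      }
      va <- eval_loss_acc(net, va_x, va_y)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n,
        train_accuracy = ep_correct / n, val_loss = va$loss,
        val_accuracy = va$accuracy)
      if (verbose)
        message(sprintf(
          "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, ep_loss / n, ep_correct / n, va$loss, va$accuracy))
      if (va$loss < best$loss - config$min_delta) {
        best <- list(epoch = epoch, loss = va$loss, params = net$params)
      } else if (epoch - best$epoch >= config$patience) {
        stopped <- epoch
        break
      }
    }
  })
  net$params <- best$params
  log <- do.call(rbind, log_rows)
  attr(log, "best_epoch") <- best$epoch
  attr(log, "stopped_epoch") <- if (is.na(stopped)) nrow(log) else stopped
  attr(log, "labels") <- labels
  class(log) <- c("train_log", "data.frame")
  attr(net, "labels") <- labels
  list(net = net, log = log)
}

#' Write a training log as delimited text
#' @param log a `train_log`; `path` a file path.
#' @export
write_train_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
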