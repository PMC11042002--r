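test_that("identical seeds and data give identical training logs", {
  spec <- tiny_spec(num_classes = 3L)
  crops <- make_toy_crops(spec, n_per_class = 8L)
  manifest <- stratified_split(crops, c(0.5, 0.25, 0.25), seed = 1)
  cfg <- train_config(learning_rate = 0.05, batch_size = 4, max_epochs = 4,
                      seed = 3)
  f1 <- train_network(build_network(spec, 0), crops, manifest, cfg)
  f2 <- train_network(build_network(spec, 0), crops, manifest, cfg)
  expect_identical(as.data.frame(f1$log), as.data.frame(f2$log))
  expect_identical(f1$net$params, f2$net$params)
})

test_that("training a softmax head matches a hand-coded gradient descent", {
  # one sample, linear + softmax only: the update has a closed form
  spec <- linear_spec(num_classes = 3L, input_w = 4L, input_h = 3L)
  crops <- make_toy_crops(spec, n_per_class = 1L, seed = 2)[1]
  crops[[1]]$species <- "class01"
  manifest <- manifest_stub(crops, "train")
  val <- crops
  val[[1]]$crop_id <- "val1"
  manifest <- rbind(manifest, manifest_stub(val, "validation"))
  class(manifest) <- c("dataset_manifest", "data.frame")
  all_crops <- c(crops, val)
  lr <- 0.1
  cfg <- train_config(learning_rate = lr, momentum = 0, batch_size = 1,
                      max_epochs = 5, seed = 0, shuffle_each_epoch = FALSE)
  net0 <- build_network(spec, seed = 6)
  fit <- train_network(net0, all_crops, manifest, cfg)
  # hand-coded: w <- w - lr * x (p - y)^T, repeated
  x <- as.vector(crops[[1]]$pixels)
  w <- net0$params[[1]]$w
  b <- net0$params[[1]]$b
  y <- c(1, 0, 0)
  losses <- numeric(5)
  for (e in 1:5) {
    z <- drop(t(w) %*% x + b)
    p <- exp(z - max(z)); p <- p / sum(p)
    losses[e] <- -log(p[1])
    g <- p - y
    w <- w - lr * outer(x, g)
    b <- b - lr * g
  }
  expect_equal(fit$log$train_loss, losses, tolerance = 1e-10)
  expect_true(all(diff(fit$log$train_loss) < 0))  # 1-sample overfit
  expect_equal(fit$net$params[[1]]$w, w, tolerance = 1e-10)
})

test_that("momentum-zero updates equal plain gradient descent", {
  spec <- tiny_spec(num_classes = 3L)
  crops <- make_toy_crops(spec, n_per_class = 4L)
  manifest <- stratified_split(crops, c(0.5, 0.25, 0.25), seed = 2)
  cfg <- train_config(learning_rate = 0.02, momentum = 0, batch_size = 12,
                      max_epochs = 1, seed = 1, shuffle_each_epoch = FALSE)
  net0 <- build_network(spec, seed = 4)
  fit <- train_network(net0, crops, manifest, cfg)
  # reproduce by applying raw gradients for the same batch sequence
  tr <- diatomnet:::crops_by_split(crops, manifest, "train")
  set.seed(cfg$seed + 1L)         # mirror the trainer's RNG stream
  ids <- sample.int(length(tr))
  net2 <- net0
  for (start in seq(1, length(tr), by = 12)) {
    sel <- ids[start:min(start + 11, length(tr))]
    xb <- diatomnet:::bind_batch(lapply(tr[sel], `[[`, "pixels"))
    labs <- match(vapply(tr[sel], `[[`, "", "species"),
                  sort(unique(manifest$species)))
    fw <- diatomnet:::forward_batch(net2, xb, training = TRUE,
                                    keep_cache = TRUE)
    bw <- diatomnet:::backward_batch(net2, fw, labs)
    step <- function(p, g) {
      if (is.null(p)) return(NULL)
      if (is.list(p)) return(mapply(step, p, g, SIMPLIFY = FALSE))
      p - cfg$learning_rate * g
    }
    net2$params <- mapply(step, net2$params, bw$grads, SIMPLIFY = FALSE)
  }
  best <- attr(fit$log, "best_epoch")
  expect_equal(best, 1L)
  expect_equal(fit$net$params, net2$params, tolerance = 1e-12)
})

test_that("early stopping halts exactly patience epochs past the best", {
  spec <- linear_spec(num_classes = 3L, input_w = 4L, input_h = 3L)
  crops <- make_toy_crops(spec, n_per_class = 4L, seed = 5)
  manifest <- stratified_split(crops, c(0.5, 0.25, 0.25), seed = 1)
  # an enormous min_delta means no epoch after the first ever "improves"
  cfg <- train_config(learning_rate = 1e-6, batch_size = 4, max_epochs = 50,
                      patience = 2, min_delta = 1e6, seed = 0)
  fit <- train_network(build_network(spec, 0), crops, manifest, cfg)
  expect_equal(attr(fit$log, "best_epoch"), 1L)
  expect_equal(attr(fit$log, "stopped_epoch"), 3L)
  expect_equal(nrow(fit$log), 3L)
})

test_that("best-epoch weights reproduce the logged best validation loss", {
  spec <- tiny_spec(num_classes = 3L)
  crops <- make_toy_crops(spec, n_per_class = 8L)
  manifest <- stratified_split(crops, c(0.5, 0.25, 0.25), seed = 3)
  cfg <- train_config(learning_rate = 0.05, batch_size = 8, max_epochs = 5,
                      seed = 2)
  fit <- train_network(build_network(spec, 1), crops, manifest, cfg)
  best <- attr(fit$log, "best_epoch")
  expect_equal(fit$log$val_loss[best], min(fit$log$val_loss))
  va <- diatomnet:::crops_by_split(crops, manifest, "validation")
  labels <- sort(unique(manifest$species))
  re <- diatomnet:::eval_loss_acc(
    fit$net, lapply(va, `[[`, "pixels"),
    match(vapply(va, `[[`, "", "species"), labels))
  expect_equal(re$loss, fit$log$val_loss[best], tolerance = 1e-12)
})

test_that("training rejects empty splits", {
  spec <- tiny_spec(num_classes = 3L)
  crops <- make_toy_crops(spec, n_per_class = 4L)
  manifest <- stratified_split(crops, c(0.5, 0.25, 0.25), seed = 1)
  m2 <- manifest[manifest$split != "validation", ]
  class(m2) <- c("dataset_manifest", "data.frame")
  expect_error(train_network(build_network(spec, 0), crops, m2,
                             train_config(max_epochs = 1)),
               "empty validation split")
})
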