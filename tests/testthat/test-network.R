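test_that("stored parameters equal the analytic count exactly", {
  spec <- default_diatomnet_spec()
  net <- build_network(spec, seed = 1)
  expect_identical(network_parameter_total(net),
                   as.numeric(count_parameters(spec)$total))
  tnet <- build_network(tiny_spec(), seed = 1)
  expect_identical(network_parameter_total(tnet),
                   as.numeric(count_parameters(tiny_spec())$total))
})

test_that("initialization is deterministic and RNG-hygienic", {
  a <- build_network(tiny_spec(), seed = 7)
  set.seed(123)
  before <- runif(3)
  b <- build_network(tiny_spec(), seed = 7)
  set.seed(123)
  expect_identical(before, runif(3))  # builder must not disturb caller RNG
  expect_identical(a$params, b$params)
  c <- build_network(tiny_spec(), seed = 8)
  expect_false(identical(a$params, c$params))
})

test_that("stem weights follow the Glorot variance 2/(fan_in + fan_out)", {
  net <- build_network(default_diatomnet_spec(), seed = 42)
  w <- net$params[[1]]$w            # 7x7x3x64: 9,408 draws
  expect_gte(length(w), 1e4 * 0.9)
  target <- 2 / (7 * 7 * 3 + 7 * 7 * 64)
  expect_lt(abs(stats::var(as.vector(w)) - target) / target, 0.10)
  expect_lt(abs(mean(w)), 3 * sqrt(target / length(w)) * 2)
  expect_true(all(net$params[[1]]$b == 0))
})

test_that("forward produces a probability vector over the classes", {
  spec <- tiny_spec(num_classes = 5L)
  net <- build_network(spec, seed = 0)
  x <- array(runif(12 * 16), dim = c(12, 16, 1))
  p <- forward(net, x)
  expect_length(p$probabilities, 5L)
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-6)
  expect_true(all(p$probabilities >= 0))
  expect_equal(p$confidence, max(p$probabilities))
  expect_equal(p$predicted_class, which.max(p$probabilities))
})

test_that("zeroed linear head on zero input gives uniform probabilities", {
  spec <- linear_spec(num_classes = 68L, input_w = 8, input_h = 4)
  net <- build_network(spec, seed = 0)
  net$params[[1]]$w[] <- 0
  x <- array(0, dim = c(4, 8, 1))
  p <- forward(net, x)
  expect_equal(p$probabilities, rep(1 / 68, 68), tolerance = 1e-12)
  expect_equal(p$predicted_class, 1L)  # argmax ties -> lowest index
})

test_that("inference is deterministic; dropout only acts in training mode", {
  net <- build_network(tiny_spec(), seed = 0)
  x <- array(runif(12 * 16), dim = c(12, 16, 1))
  expect_identical(forward(net, x)$probabilities,
                   forward(net, x)$probabilities)
  set.seed(1)
  p1 <- forward(net, x, training_mode = TRUE)$probabilities
  set.seed(2)
  p2 <- forward(net, x, training_mode = TRUE)$probabilities
  expect_false(identical(p1, p2))
})

test_that("dimension mismatches raise a shape error", {
  net <- build_network(tiny_spec(), seed = 0)
  bad <- array(0, dim = c(5, 5, 1))
  expect_error(forward(net, bad), "shape")
})

test_that("analytic gradients match central finite differences", {
  spec <- tiny_spec()
  expect_lt(count_parameters(spec)$total, 1000)
  net <- build_network(spec, seed = 3)
  set.seed(9)
  x <- array(runif(12 * 16), dim = c(12, 16, 1, 1))
  lab <- 2L
  fw <- diatomnet:::forward_batch(net, x, keep_cache = TRUE)
  bw <- diatomnet:::backward_batch(net, fw, lab)
  loss_at <- function(n2) {
    -log(diatomnet:::forward_batch(n2, x)$probs[lab, 1])
  }
  eps <- 1e-5
  max_rel <- 0
  set.seed(1)
  for (i in seq_along(net$params)) {
    if (is.null(net$params[[i]])) next
    subs <- if (!is.null(net$params[[i]]$w)) list(NULL)
            else as.list(names(net$params[[i]]))
    for (sub in subs) {
      leaf <- if (is.null(sub)) net$params[[i]] else net$params[[i]][[sub]]
      g <- if (is.null(sub)) bw$grads[[i]] else bw$grads[[i]][[sub]]
      for (part in c("w", "b")) {
        v <- leaf[[part]]
        for (k in sample(length(v), min(8, length(v)))) {
          bump <- function(delta) {
            n2 <- net
            if (is.null(sub)) n2$params[[i]][[part]][k] <- v[k] + delta
            else n2$params[[i]][[sub]][[part]][k] <- v[k] + delta
            n2
          }
          fd <- (loss_at(bump(eps)) - loss_at(bump(-eps))) / (2 * eps)
          gv <- g[[part]][k]
          if (abs(fd) > 1e-8 || abs(gv) > 1e-8)
            max_rel <- max(max_rel, abs(fd - gv) / max(abs(fd), abs(gv)))
        }
      }
    }
  }
  expect_lt(max_rel, 1e-4)
})

test_that("one small SGD step decreases the sample's cross-entropy", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 5)
  set.seed(2)
  x <- array(runif(12 * 16), dim = c(12, 16, 1, 1))
  lab <- 1L
  fw <- diatomnet:::forward_batch(net, x, keep_cache = TRUE)
  bw <- diatomnet:::backward_batch(net, fw, lab)
  lr <- 1e-2
  step <- function(p, g) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) return(mapply(step, p, g, SIMPLIFY = FALSE))
    p - lr * g
  }
  net$params <- mapply(step, net$params, bw$grads, SIMPLIFY = FALSE)
  fw2 <- diatomnet:::forward_batch(net, x)
  expect_lt(-log(fw2$probs[lab, 1]), bw$loss)
})

test_that("checkpoints round-trip bit-exactly", {
  net <- build_network(tiny_spec(), seed = 11)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path, meta = list(note = "fixture"))
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  expect_identical(back$rng_seed, net$rng_seed)
  expect_equal(attr(back, "meta")$note, "fixture")
  x <- array(runif(12 * 16), dim = c(12, 16, 1))
  expect_identical(forward(net, x)$probabilities,
                   forward(back, x)$probabilities)
})
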