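#' Branch channel budgets of a dimension-reduced inception module
#'
#' An inception module runs four parallel branches on its input -- a 1x1
#' convolution, a 1x1 "reduce" followed by a 3x3 convolution, a 1x1 "reduce"
#' followed by a 5x5 convolution, and a 3x3 max pool (stride 1, same size)
#' followed by a 1x1 projection -- and concatenates their outputs along the
#' channel axis.  The six fields are the output channel counts of the six
#' internal convolutions.
#'
#' @param one_by_one,three_reduce,three_by_three,five_reduce,five_by_five,pool_proj
#'   positive integer channel counts.
#' @return An `inception_config` object.  `concat_channels(cfg)` gives the
#'   module's output channel count (sum of the four terminal branch widths).
#' @export
inception_config <- function(one_by_one, three_reduce, three_by_three,
                             five_reduce, five_by_five, pool_proj) {
  counts <- c(one_by_one = one_by_one, three_reduce = three_reduce,
              three_by_three = three_by_three, five_reduce = five_reduce,
              five_by_five = five_by_five, pool_proj = pool_proj)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all six inception channel counts must be positive integers")
  structure(as.list(counts), class = "inception_config")
}

#' @rdname inception_config
#' @param cfg an `inception_config`.
#' @export
concat_channels <- function(cfg) {
  cfg$one_by_one + cfg$three_by_three + cfg$five_by_five + cfg$pool_proj
}

pad_for <- function(padding_mode, kh, kw) {
  if (is.list(padding_mode)) return(c(padding_mode$ph, padding_mode$pw))
  switch(padding_mode,
    same_like = c(kh %/% 2, kw %/% 2),
    none_ceil = ,
    none_floor = c(0L, 0L),
    stop("unknown padding_mode: ", padding_mode)
  )
}

new_layer <- function(kind, label, depth = 0L, ...) {
  structure(c(list(kind = kind, label = label, depth_contribution = depth),
              list(...)),
            class = "layer_spec")
}

#' Layer constructors for the architecture dialect
#'
#' Each constructor returns one `layer_spec` describing a layer of the
#' network by kind, receptive-field geometry, and channel budget.  The
#' `depth_contribution` follows the convention of counting one unit per
#' sequential learnable stage: a lone convolution counts 1, a reduce+conv
#' stem pair counts 2, an inception module counts 2, and pooling,
#' normalization, dropout and softmax count 0.
#'
#' @param out_channels output channel count (convolution / linear).
#' @param kh,kw patch (kernel) height and width in pixels.
#' @param stride stride in pixels (same in both directions).
#' @param padding_mode `"same_like"` (zero padding of `floor(k/2)`),
#'   `"none_ceil"` (no padding, ceiling division -- edge windows kept), or
#'   `"none_floor"` (no padding, floor division).
#' @param depth depth contribution (see above); the stem 1x1 convolution is
#'   given depth 0 and its 3x3 partner depth 2 so the pair counts as the
#'   table's two sequential stages.
#' @param label optional layer label used in traces and reports.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
layer_conv <- function(out_channels, kh, kw, stride = 1L,
                       padding_mode = "same_like", depth = 1L, label = NULL) {
  if (out_channels < 1 || kh < 1 || kw < 1 || stride < 1)
    stop("convolution geometry must be positive")
  new_layer("convolution",
            label %||% sprintf("conv%dx%d/%d(%d)", kh, kw, stride, out_channels),
            depth = as.integer(depth), patch_height = as.integer(kh),
            patch_width = as.integer(kw), stride = as.integer(stride),
            padding_mode = padding_mode, out_channels = as.integer(out_channels))
}

#' @rdname layer_spec
#' @export
layer_maxpool <- function(kh, kw, stride, padding_mode = "none_ceil",
                          label = NULL) {
  new_layer("max_pool", label %||% sprintf("maxpool%dx%d/%d", kh, kw, stride),
            patch_height = as.integer(kh), patch_width = as.integer(kw),
            stride = as.integer(stride), padding_mode = padding_mode)
}

#' @rdname layer_spec
#' @export
layer_avgpool <- function(kh, kw, stride = 1L, label = NULL) {
  new_layer("avg_pool", label %||% sprintf("avgpool%dx%d/%d", kh, kw, stride),
            patch_height = as.integer(kh), patch_width = as.integer(kw),
            stride = as.integer(stride), padding_mode = "none_floor")
}

#' @rdname layer_spec
#' @param window,k,alpha,beta cross-channel normalization parameters:
#'   each response is divided by `(k + alpha * S)^beta` where `S` is the sum
#'   of squares over `window` neighboring channels.
#' @export
layer_lrn <- function(window = 5L, k = 2, alpha = 1e-4, beta = 0.75,
                      label = "cross_channel_norm") {
  new_layer("cross_channel_norm", label,
            norm_params = list(window = as.integer(window), k = k,
                               alpha = alpha, beta = beta))
}

#' @rdname layer_spec
#' @param config an [inception_config()].
#' @export
layer_inception <- function(config, label = NULL) {
  stopifnot(inherits(config, "inception_config"))
  new_layer("inception",
            label %||% sprintf("inception(%s)",
                               paste(unlist(config), collapse = ",")),
            depth = 2L, inception = config)
}

#' @rdname layer_spec
#' @param rate dropout rate in `[0, 1]`.
#' @export
layer_dropout <- function(rate, label = NULL) {
  if (rate < 0 || rate > 1) stop("dropout rate must be in [0, 1]")
  new_layer("dropout", label %||% sprintf("dropout(%.2f)", rate), rate = rate)
}

#' @rdname layer_spec
#' @export
layer_linear <- function(out_channels, label = NULL) {
  new_layer("linear", label %||% sprintf("linear(%d)", out_channels),
            depth = 1L, out_channels = as.integer(out_channels))
}

#' @rdname layer_spec
#' @export
layer_softmax <- function(label = "softmax") new_layer("softmax", label)

#' Assemble an architecture specification
#'
#' An `architecture_spec` is the single declarative source of truth for a
#' network: shape tracing, parameter counting, and network construction all
#' consume it.  Spatial sizes are quoted width-first (`input_width` x
#' `input_height`), the convention of the architecture table this dialect
#' mirrors; image arrays are `[height, width, channels]`.
#'
#' @param input_width,input_height,input_channels input raster geometry.
#' @param num_classes number of output classes.
#' @param layers ordered list of [layer_spec] objects; the last two must be
#'   `layer_linear(num_classes)` then `layer_softmax()`.
#' @return An `architecture_spec` object.
#' @export
architecture_spec <- function(input_width, input_height, input_channels,
                              num_classes, layers) {
  stopifnot(input_width >= 1, input_height >= 1, input_channels >= 1,
            num_classes >= 2)
  kinds <- vapply(layers, `[[`, "", "kind")
  nl <- length(layers)
  if (nl < 2 || kinds[nl] != "softmax" || kinds[nl - 1] != "linear")
    stop("the last two layers must be linear(num_classes) then softmax")
  if (layers[[nl - 1]]$out_channels != num_classes)
    stop("final linear width (", layers[[nl - 1]]$out_channels,
         ") must equal num_classes (", num_classes, ")")
  structure(list(input_width = as.integer(input_width),
                 input_height = as.integer(input_height),
                 input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 layers = layers),
            class = "architecture_spec")
}

#' The canonical DiatomNet architecture
#'
#' DiatomNet is a lightweight inception-family network for 68-class diatom
#' crop classification: a 7x7/2 convolutional stem, cross-channel
#' normalization, a 1x1 + 3x3 convolution pair, three dimension-reduced
#' inception modules separated by 3x3/2 ceil-mode max pools, global 6x2
#' average pooling, 40% dropout, and a 68-way linear + softmax head.  Every
#' convolution (including all inception branch convolutions) is followed by
#' ReLU and carries a bias; the input is a 432x128 color crop.
#'
#' The published layer table prints the third inception module's output at
#' half its natural spatial size; since inception modules preserve spatial
#' size, this implementation inserts an explicit parameter-free 3x3/2
#' "reconciliation" max pool after the third inception so that every
#' printed output size (and the 6x2 global average pool) is reproduced.
#' Set `reconciliation_pool = FALSE` to omit it and see the discrepancy via
#' [validate_against_table()].
#'
#' @param num_classes number of species classes (default 68).
#' @param input_channels raster channel count (default 3, color micrographs).
#' @param reconciliation_pool insert the extra max pool after the third
#'   inception module (default `TRUE`).
#' @param dropout_rate dropout rate before the linear head (default 0.40).
#' @return An [architecture_spec()].
#' @examples
#' spec <- default_diatomnet_spec()
#' count_parameters(spec)$total_millions_2dp  # 1.85
#' @export
default_diatomnet_spec <- function(num_classes = 68L, input_channels = 3L,
                                   reconciliation_pool = TRUE,
                                   dropout_rate = 0.40) {
  layers <- list(
    layer_conv(64, 7, 7, stride = 2, label = "stem_conv7x7/2"),
    layer_maxpool(3, 3, 2),
    layer_lrn(),
    layer_conv(64, 1, 1, stride = 1, depth = 0, label = "stem_conv1x1"),
    layer_conv(192, 3, 3, stride = 1, depth = 2, label = "stem_conv3x3"),
    layer_maxpool(3, 3, 2),
    layer_inception(inception_config(64, 96, 128, 16, 32, 32),
                    label = "inception_1"),
    layer_maxpool(3, 3, 2),
    layer_inception(inception_config(192, 96, 208, 16, 48, 64),
                    label = "inception_2"),
    layer_maxpool(3, 3, 2),
    layer_inception(inception_config(384, 192, 384, 48, 128, 128),
                    label = "inception_3")
  )
  if (reconciliation_pool)
    layers <- c(layers, list(layer_maxpool(3, 3, 2, label = "reconciliation_pool")))
  layers <- c(layers, list(
    layer_avgpool(2, 6, 1, label = "global_avgpool6x2"),  # 6 wide x 2 high
    layer_dropout(dropout_rate),
    layer_linear(num_classes),
    layer_softmax()
  ))
  architecture_spec(432, 128, input_channels, num_classes, layers)
}

#' A depth-reduced DiatomNet for desk-scale experiments
#'
#' Keeps the full stem and the first inception module (with the canonical
#' branch widths) and replaces the rest with global average pooling and a
#' linear head.  Used throughout the test suite and the demo pipeline,
#' where training the full network would be wastefully slow.
#'
#' @param num_classes number of classes (default 5, the synthetic benchmark).
#' @param input_width,input_height,input_channels input geometry.
#' @param dropout_rate dropout before the head.
#' @return An [architecture_spec()].
#' @export
reduced_diatomnet_spec <- function(num_classes = 5L, input_width = 432L,
                                   input_height = 128L, input_channels = 3L,
                                   dropout_rate = 0.40) {
  layers <- list(
    layer_conv(64, 7, 7, stride = 2, label = "stem_conv7x7/2"),
    layer_maxpool(3, 3, 2),
    layer_lrn(),
    layer_conv(64, 1, 1, stride = 1, depth = 0, label = "stem_conv1x1"),
    layer_conv(192, 3, 3, stride = 1, depth = 2, label = "stem_conv3x3"),
    layer_maxpool(3, 3, 2),
    layer_inception(inception_config(64, 96, 128, 16, 32, 32),
                    label = "inception_1")
  )
  # global average pool over whatever spatial extent remains
  pre <- architecture_spec(input_width, input_height, input_channels,
                           num_classes,
                           c(layers, list(layer_linear(num_classes),
                                          layer_softmax())))
  tr <- trace_shapes(pre)
  last <- tr[nrow(tr) - 2L, ]
  layers <- c(layers, list(
    layer_avgpool(last$height, last$width, 1, label = "global_avgpool"),
    layer_dropout(dropout_rate),
    layer_linear(num_classes),
    layer_softmax()
  ))
  architecture_spec(input_width, input_height, input_channels, num_classes,
                    layers)
}

#' Analytic shape propagation
#'
#' Computes the output raster size of every layer without constructing a
#' network.  A convolution with `same_like` padding and stride `s` maps a
#' dimension `d` to `floor((d + 2*floor(k/2) - k)/s) + 1`; a `none_ceil`
#' pool maps `d` to `ceil((d - k)/s) + 1`; inception modules preserve
#' spatial size and emit `concat_channels` channels.
#'
#' @param spec an [architecture_spec()].
#' @return A data frame (class `shape_trace`) with one row per layer:
#'   `label`, `width`, `height`, `channels` (width-first, matching the
#'   printed table convention).
#' @export
trace_shapes <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  h <- spec$input_height; w <- spec$input_width; c <- spec$input_channels
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind %in% c("convolution", "max_pool", "avg_pool")) {
      pd <- pad_for(ly$padding_mode, ly$patch_height, ly$patch_width)
      ceil_mode <- identical(ly$padding_mode, "none_ceil")
      if (!ceil_mode && (h + 2 * pd[1] < ly$patch_height ||
                         w + 2 * pd[2] < ly$patch_width))
        stop("shape underflow at layer '", ly$label, "': patch ",
             ly$patch_height, "x", ly$patch_width, " exceeds input ",
             w, "x", h)
      hw <- conv_out_shape(c(h, w), ly$patch_height, ly$patch_width,
                           ly$stride, pd[1], pd[2], ceil_mode)
      h <- hw[1]; w <- hw[2]
      if (ly$kind == "convolution") c <- ly$out_channels
    } else if (ly$kind == "inception") {
      c <- concat_channels(ly$inception)
    } else if (ly$kind == "linear") {
      h <- 1L; w <- 1L; c <- ly$out_channels
    }
    if (h < 1 || w < 1)
      stop("shape underflow at layer '", ly$label, "'")
    rows[[i]] <- data.frame(label = ly$label, width = w, height = h,
                            channels = c)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("shape_trace", "data.frame")
  out
}

#' Learnable-parameter accounting
#'
#' Closed-form per-layer counts: a convolution holds
#' `kh*kw*c_in*c_out` weights plus `c_out` biases; a linear layer
#' `c_in*c_out + c_out`; an inception module the sum over its six internal
#' convolutions (the pool branch is parameter-free); normalization,
#' pooling, dropout and softmax contribute nothing.  Padding affects
#' shapes, never weights.
#'
#' @param spec an [architecture_spec()].
#' @return A list (class `param_report`): `per_layer` data frame with
#'   `label`, `weights`, `biases`; `total`; `total_millions_2dp`
#'   (total / 1e6 rounded to 2 decimals); `input_channels` metadata.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  tr <- trace_shapes(spec)   # validates shapes; channel inputs known
  c_in <- spec$input_channels
  feat_in <- spec$input_height * spec$input_width * spec$input_channels
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    wt <- 0; bs <- 0
    if (ly$kind == "convolution") {
      wt <- ly$patch_height * ly$patch_width * c_in * ly$out_channels
      bs <- ly$out_channels
    } else if (ly$kind == "linear") {
      wt <- feat_in * ly$out_channels   # flattened input tensor
      bs <- ly$out_channels
    } else if (ly$kind == "inception") {
      ic <- ly$inception
      branches <- rbind(
        c(1, c_in, ic$one_by_one),
        c(1, c_in, ic$three_reduce),
        c(3, ic$three_reduce, ic$three_by_three),
        c(1, c_in, ic$five_reduce),
        c(5, ic$five_reduce, ic$five_by_five),
        c(1, c_in, ic$pool_proj))
      wt <- sum(branches[, 1]^2 * branches[, 2] * branches[, 3])
      bs <- sum(branches[, 3])
    }
    rows[[i]] <- data.frame(label = ly$label, weights = wt, biases = bs)
    c_in <- tr$channels[i]
    feat_in <- tr$height[i] * tr$width[i] * tr$channels[i]
  }
  per_layer <- do.call(rbind, rows)
  total <- sum(per_layer$weights) + sum(per_layer$biases)
  structure(list(per_layer = per_layer, total = total,
                 total_millions_2dp = round(total / 1e6, 2),
                 input_channels = spec$input_channels),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat("Learnable parameters\n")
  nz <- x$per_layer[x$per_layer$weights + x$per_layer$biases > 0, ]
  print(nz, row.names = FALSE)
  cat(sprintf("total: %s (%.2f M)\n", format(x$total, big.mark = ","),
              x$total / 1e6))
  invisible(x)
}

# The printed layer table of the canonical architecture (width, height,
# channels per row), used as a regression guard.
diatomnet_table_expectations <- function() {
  data.frame(
    label = c("stem_conv7x7/2", "maxpool3x3/2", "stem_conv3x3",
              "maxpool3x3/2", "inception_1", "maxpool3x3/2", "inception_2",
              "maxpool3x3/2", "inception_3", "global_avgpool6x2",
              "dropout(0.40)", "linear(68)", "softmax"),
    width = c(216, 108, 108, 54, 54, 27, 27, 13, 6, 1, 1, 1, 1),
    height = c(64, 32, 32, 16, 16, 8, 8, 4, 2, 1, 1, 1, 1),
    channels = c(64, 64, 192, 192, 256, 256, 512, 512, 1024, 1024, 1024,
                 68, 68))
}

#' Check a shape trace against the published layer table
#'
#' Compares each row of the canonical table with the matching entry of a
#' trace of the (default) architecture.  Layers absent from the printed
#' table (the cross-channel normalization, the stem 1x1 convolution, and
#' the reconciliation pool, which the table folds into its inception row)
#' are skipped.  With the reconciliation pool enabled the discrepancy list
#' is empty.
#'
#' @param trace a [trace_shapes()] result for a DiatomNet-shaped spec.
#' @return A data frame of discrepancies (zero rows when the trace matches):
#'   `label`, `expected`, `actual`.
#' @export
validate_against_table <- function(trace) {
  exp <- diatomnet_table_expectations()
  skip <- c("cross_channel_norm", "stem_conv1x1")
  # the printed table folds the reconciliation pool into its third
  # inception row: when the pool is present, the pooled size is the row
  # to compare and the raw inception output drops out of the table
  if ("reconciliation_pool" %in% trace$label) {
    pool_at <- which(trace$label == "reconciliation_pool")
    trace <- trace[-(pool_at - 1L), , drop = FALSE]
    trace$label[trace$label == "reconciliation_pool"] <- "inception_3"
  }
  tr <- trace[!trace$label %in% skip, , drop = FALSE]
  # align sequentially: the table rows are in architecture order
  n <- min(nrow(tr), nrow(exp))
  out <- list()
  for (i in seq_len(n)) {
    e <- exp[i, ]; a <- tr[i, ]
    if (e$width != a$width || e$height != a$height || e$channels != a$channels)
      out[[length(out) + 1L]] <- data.frame(
        label = a$label,
        expected = sprintf("%d x %d x %d", e$width, e$height, e$channels),
        actual = sprintf("%d x %d x %d", a$width, a$height, a$channels))
  }
  if (nrow(tr) != nrow(exp))
    out[[length(out) + 1L]] <- data.frame(
      label = "(row count)", expected = as.character(nrow(exp)),
      actual = as.character(nrow(tr)))
  if (length(out) == 0)
    return(data.frame(label = character(), expected = character(),
                      actual = character()))
  do.call(rbind, out)
}

#' Sum of depth contributions over a spec
#'
#' @param spec an [architecture_spec()].
#' @return Integer network depth under the sequential-learnable-stage
#'   convention (DiatomNet: 10).
#' @export
network_depth <- function(spec) {
  sum(vapply(spec$layers, `[[`, integer(1), "depth_contribution"))
}

#' Serialize an architecture spec to a structured text file
#'
#' One YAML record per layer plus the input geometry, so shape and
#' parameter accounting can run on a spec exchanged as plain text.
#'
#' @param spec an [architecture_spec()]; `path` a file path.
#' @return `read_archspec` returns the reconstructed spec; the round trip
#'   is lossless.
#' @export
write_archspec <- function(spec, path) {
  enc_layer <- function(ly) {
    out <- ly[!vapply(ly, is.null, TRUE)]
    if (!is.null(out$inception)) out$inception <- unclass(out$inception)
    unclass(out)
  }
  doc <- list(input_width = spec$input_width,
              input_height = spec$input_height,
              input_channels = spec$input_channels,
              num_classes = spec$num_classes,
              layers = lapply(spec$layers, enc_layer))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_archspec
#' @param path path to a file written by `write_archspec`.
#' @export
read_archspec <- function(path) {
  doc <- yaml::read_yaml(path)
  dec_layer <- function(ly) {
    if (!is.null(ly$inception))
      ly$inception <- structure(ly$inception, class = "inception_config")
    structure(ly, class = "layer_spec")
  }
  architecture_spec(doc$input_width, doc$input_height, doc$input_channels,
                    doc$num_classes, lapply(doc$layers, dec_layer))
}

#' Full architecture inspection report
#'
#' Convenience wrapper producing the shape trace, per-layer parameter
#' table, totals, depth, and (for the canonical architecture) any layer
#' table discrepancies in one list, ready for JSON serialization.
#'
#' @param spec an [architecture_spec()] (default: the canonical DiatomNet).
#' @param check_table compare the trace against the published table
#'   (only meaningful for the default spec).
#' @return A list with `trace`, `parameters`, `total`, `total_millions_2dp`,
#'   `depth`, and `discrepancies`.
#' @export
inspect_architecture <- function(spec = default_diatomnet_spec(),
                                 check_table = TRUE) {
  tr <- trace_shapes(spec)
  pr <- count_parameters(spec)
  list(trace = tr,
       parameters = pr$per_layer,
       total = pr$total,
       total_millions_2dp = pr$total_millions_2dp,
       depth = network_depth(spec),
       discrepancies = if (check_table) validate_against_table(tr) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
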