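# Activation-map interpretability: per-layer feature maps from the most
# strongly activated channel, and input-resolution heat maps for the deep
# layer.

anchor_layer <- function(spec, which = c("early", "intermediate", "deep")) {
  which <- match.arg(which)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  convs <- which(kinds == "convolution")
  incep <- which(kinds == "inception")
  if (length(convs) == 0) stop("spec has no convolution layers")
  if (which == "early") return(convs[1])
  if (length(incep) == 0) stop("spec has no inception modules")
  if (which == "deep") return(incep[length(incep)])
  # intermediate: the second inception module when present, else the last
  if (length(incep) >= 2) incep[2] else incep[length(incep)]
}

#' Feature map of the maximally activated channel at a named depth
#'
#' Runs a forward pass retaining per-layer activations and returns the
#' spatial map of the channel with the largest activation at the chosen
#' depth.  Anchors: `early` = the first stem convolution's output,
#' `intermediate` = the second inception module's output, `deep` = the
#' last inception module's output.  "Largest activation" means the
#' largest spatial sum by default (`mode = "sum"`); `mode = "max"`
#' selects by single largest response instead.  Ties break toward the
#' lowest channel index.
#'
#' @param net a `diatomnet_network` (trained or freshly initialized).
#' @param crop a `diatom_crop` (or bare pixel array) matching the spec
#'   input size.
#' @param layer_selector `"early"`, `"intermediate"` or `"deep"`.
#' @param mode channel-selection rule, `"sum"` or `"max"`.
#' @return An `activation_map`: list with `layer_label`, `channel`
#'   (1-based), `map` (nonnegative 2-D raster at the layer's spatial
#'   resolution) and `crop_id`.
#' @export
activation_map <- function(net, crop, layer_selector = "deep",
                           mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (!layer_selector %in% c("early", "intermediate", "deep"))
    stop("invalid layer selector '", layer_selector,
         "'; valid: early, intermediate, deep")
  px <- if (inherits(crop, "diatom_crop")) crop$pixels else crop
  li <- anchor_layer(net$spec, layer_selector)
  fw <- forward_batch(net, px, keep_activations = TRUE)
  act <- fw$activations[[li]]           # [h, w, c, 1]
  score <- apply(act[, , , 1, drop = FALSE], 3,
                 if (mode == "sum") sum else max)
  ch <- which.max(score)                # first maximum: lowest-index tie-break
  structure(list(layer_label = net$spec$layers[[li]]$label,
                 channel = as.integer(ch),
                 map = act[, , ch, 1],
                 crop_id = if (inherits(crop, "diatom_crop")) crop$crop_id
                           else NA_character_),
            class = "activation_map")
}

#' Input-resolution heat map of the deep layer
#'
#' The deep-layer maximum-activation map, bilinearly upsampled to the
#' input crop's resolution and min-max normalized to `[0, 1]`.  A
#' constant activation map is returned as all zeros with the `constant`
#' flag set.
#'
#' @inheritParams activation_map
#' @return A `heat_map`: list with `map` (input-size raster in `[0, 1]`),
#'   `constant` flag, and the source `activation_map`.
#' @export
heat_map <- function(net, crop, mode = "sum") {
  am <- activation_map(net, crop, "deep", mode)
  h <- net$spec$input_height; w <- net$spec$input_width
  src <- am$map
  sx <- ncol(src) / w; sy <- nrow(src) / h
  m <- c(sx, 0, 0.5 * sx - 0.5, 0, sy, 0.5 * sy - 0.5)
  up <- warp_affine_cpp(array(src, dim = c(dim(src), 1L)), h, w, m, 1L, 0)
  up <- up[, , 1]
  rng <- range(up)
  if (diff(rng) < 1e-12) {
    structure(list(map = matrix(0, h, w), constant = TRUE, source = am),
              class = "heat_map")
  } else {
    structure(list(map = (up - rng[1]) / diff(rng), constant = FALSE,
                   source = am),
              class = "heat_map")
  }
}

#' Render a heat map (optionally overlaid on its crop) to PNG
#'
#' Presentation-only helper: maps heat to a color ramp and alpha-blends it
#' over the grayscale crop.
#'
#' @param hm a [heat_map()]; `crop` the source crop (optional);
#'   `path` output PNG; `alpha` overlay opacity.
#' @export
write_heatmap_png <- function(hm, path, crop = NULL, alpha = 0.5) {
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(hm$map)) / 255
  h <- nrow(hm$map); w <- ncol(hm$map)
  heat <- array(cols, dim = c(h, w, 3))
  out <- if (!is.null(crop)) {
    base <- crop$pixels
    (1 - alpha) * base + alpha * heat
  } else heat
  out[out < 0] <- 0; out[out > 1] <- 1
  png::writePNG(out, path)
  invisible(path)
}
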