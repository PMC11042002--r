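# Shared fixtures: tiny architecture specs and in-memory crop sets, all
# built in code at test time.

# A <1,000-parameter spec exercising every layer kind; used for gradient
# and training checks where the full architecture would be waste.
tiny_spec <- function(num_classes = 3L, input_w = 16L, input_h = 12L,
                      input_c = 1L) {
  architecture_spec(input_w, input_h, input_c, num_classes, list(
    layer_conv(4, 3, 3, stride = 1, label = "c1"),
    layer_maxpool(3, 3, 2),
    layer_lrn(window = 3),
    layer_inception(inception_config(2, 2, 3, 2, 2, 2)),
    layer_avgpool(6, 8, 1),
    layer_dropout(0.4),
    layer_linear(num_classes),
    layer_softmax()))
}

# Softmax-regression spec: linear head straight on the flattened input.
linear_spec <- function(num_classes = 3L, input_w = 6L, input_h = 4L,
                        input_c = 1L) {
  architecture_spec(input_w, input_h, input_c, num_classes, list(
    layer_linear(num_classes),
    layer_softmax()))
}

# Random labelled crops matching a spec's input geometry: class k gets mean
# intensity k / (K + 1), so the classes are linearly separable on average.
make_toy_crops <- function(spec, n_per_class = 6L, seed = 1L) {
  k <- spec$num_classes
  h <- spec$input_height; w <- spec$input_width; c <- spec$input_channels
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  crops <- list()
  for (cls in seq_len(k))
    for (i in seq_len(n_per_class)) {
      px <- array(pmin(pmax(cls / (k + 1) +
                              rnorm(h * w * c, 0, 0.05), 0), 1),
                  dim = c(h, w, c))
      crops[[length(crops) + 1L]] <- structure(
        list(crop_id = sprintf("toy%02d_%02d", cls, i), pixels = px,
             species = sprintf("class%02d", cls),
             source = list(image_id = sprintf("toy%02d_%02d", cls, i),
                           object = 1L),
             augmentation = "original", rotation_applied = 0),
        class = "diatom_crop")
    }
  crops
}

manifest_stub <- function(crops, split) {
  data.frame(crop_id = vapply(crops, `[[`, "", "crop_id"),
             path = NA_character_,
             species = vapply(crops, `[[`, "", "species"),
             augmentation = vapply(crops, `[[`, "", "augmentation"),
             split = split, stringsAsFactors = FALSE)
}

make_crop <- function(px, id = "crop1", species = "sp") {
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  structure(list(crop_id = id, pixels = px, species = species,
                 source = list(image_id = id, object = 1L),
                 augmentation = "original", rotation_applied = 0),
            class = "diatom_crop")
}

# Independent closed-form parameter sum for the canonical architecture,
# written out per layer (the oracle count_parameters must reproduce).
hand_param_total <- function(input_channels = 3L, num_classes = 68L) {
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  incep <- function(cin, p1, r3, c3, r5, c5, pp)
    conv(1, cin, p1) + conv(1, cin, r3) + conv(3, r3, c3) +
      conv(1, cin, r5) + conv(5, r5, c5) + conv(1, cin, pp)
  conv(7, input_channels, 64) +
    conv(1, 64, 64) + conv(3, 64, 192) +
    incep(192, 64, 96, 128, 16, 32, 32) +
    incep(256, 192, 96, 208, 16, 48, 64) +
    incep(512, 384, 192, 384, 48, 128, 128) +
    (1024 * num_classes + num_classes)
}
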