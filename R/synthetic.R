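# Procedural generator of diatom-like annotated micrographs.
#
# Objects are elongated capsules (a rectangle with rounded end caps whose
# elongation is a class parameter) carrying class-specific valve-like
# texture: sinusoidal striae perpendicular to the major axis plus sparse
# dark pores with a minimum-separation (Poisson-disc style) layout.  The
# goal is to reproduce the statistical structure the pipeline assumes --
# elongated textured objects at arbitrary orientations with pixel-level
# boundary annotations and unbalanced classes -- not biological realism.

#' Parameters of one synthetic diatom class
#'
#' @param base_intensity mean interior intensity in `[0, 1]`.
#' @param aspect length/width ratio of the capsule.
#' @param length_px mean object length in pixels.
#' @param stria_freq stria spatial frequency in cycles per pixel along the
#'   major axis (0 = smooth valve).
#' @param stria_amp stria modulation amplitude.
#' @param pore_density pores per 1,000 interior pixels.
#' @param cap mushroom factor of the end caps in `(0, 1]`: 1 = semicircular.
#' @return A `synth_class` parameter list.
#' @export
synth_class <- function(base_intensity = 0.6, aspect = 4, length_px = 160,
                        stria_freq = 0.1, stria_amp = 0.15,
                        pore_density = 1.0, cap = 1.0) {
  structure(list(base_intensity = base_intensity, aspect = aspect,
                 length_px = length_px, stria_freq = stria_freq,
                 stria_amp = stria_amp, pore_density = pore_density,
                 cap = cap),
            class = "synth_class")
}

#' Specification of a synthetic annotated dataset
#'
#' @param classes named list of [synth_class()] parameter sets; classes
#'   must have pairwise-distinct parameter tuples.
#' @param per_class_counts integer vector (recycled / named like `classes`)
#'   of objects per class; may be unbalanced.
#' @param canvas `c(height, width)` of each micrograph in pixels.
#' @param objects_per_image `c(min, max)` objects placed per micrograph.
#' @param orientation_range degrees; object orientations are uniform here
#'   (default 0--180).
#' @param noise_sd additive Gaussian pixel noise.
#' @param background_amp amplitude of the smooth background texture.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(classes, per_class_counts, canvas = c(360L, 480L),
                           objects_per_image = c(2L, 4L),
                           orientation_range = c(0, 180), noise_sd = 0.03,
                           background_amp = 0.04, seed = 0L) {
  if (is.null(names(classes)))
    names(classes) <- sprintf("class_%02d", seq_along(classes))
  sig <- vapply(classes, function(cl) paste(unlist(cl), collapse = "/"), "")
  if (anyDuplicated(sig)) stop("classes must have distinct parameter tuples")
  per_class_counts <- rep_len(per_class_counts, length(classes))
  if (any(per_class_counts < 1)) stop("per_class_counts must be >= 1")
  structure(list(classes = classes, per_class_counts = per_class_counts,
                 canvas = as.integer(canvas),
                 objects_per_image = as.integer(objects_per_image),
                 orientation_range = orientation_range, noise_sd = noise_sd,
                 background_amp = background_amp, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Capsule boundary polygon: length L, width W, mushroom cap factor, centered
# at the origin along +x, then rotated by theta (degrees) and translated.
capsule_polygon <- function(L, W, cap = 1, theta = 0, center = c(0, 0),
                            n_arc = 24L) {
  r <- W / 2
  half <- L / 2 - cap * r
  tt <- seq(-pi / 2, pi / 2, length.out = n_arc)
  right <- cbind(half + cap * r * cos(tt), r * sin(tt))
  left <- cbind(-half - cap * r * cos(rev(tt)), r * sin(rev(tt)))
  pg <- rbind(right, left)
  a <- theta * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(pg %*% t(rot), 2, center, "+")
}

# Render one capsule into a canvas (in place), returning the updated canvas.
# Texture coordinates follow the object's own axis, so striae stay
# perpendicular to the major axis at any orientation.
render_capsule <- function(canvas, cls, L, W, theta, center) {
  h <- nrow(canvas); w <- ncol(canvas)
  a <- theta * pi / 180
  ca <- cos(a); sa <- sin(a)
  half_ext <- 0.5 * c(abs(ca) * L + abs(sa) * W, abs(sa) * L + abs(ca) * W)
  x0 <- max(0L, floor(center[1] - half_ext[1] - 2))
  x1 <- min(w - 1L, ceiling(center[1] + half_ext[1] + 2))
  y0 <- max(0L, floor(center[2] - half_ext[2] - 2))
  y1 <- min(h - 1L, ceiling(center[2] + half_ext[2] + 2))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys)) - center[1]
  gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys)) - center[2]
  u <- ca * gx + sa * gy        # along-axis coordinate
  v <- -sa * gx + ca * gy       # across-axis coordinate
  r <- W / 2
  half <- L / 2 - cls$cap * r
  du <- pmax(abs(u) - half, 0) / cls$cap
  inside <- (du^2 + v^2) <= r^2
  if (!any(inside)) return(canvas)
  tex <- cls$base_intensity +
    cls$stria_amp * sin(2 * pi * cls$stria_freq * u) *
      cos(pi * v / W)           # striae fade toward the margins
  # sparse pores: minimum-separation dart throwing in axis coordinates
  n_pore <- max(0L, round(cls$pore_density * sum(inside) / 1000))
  if (n_pore > 0) {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    min_d2 <- (W / 6)^2
    while (nrow(pts) < n_pore && tries < 50L * n_pore) {
      cand <- c(stats::runif(1, -L / 2, L / 2), stats::runif(1, -r, r))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) > min_d2)
        pts <- rbind(pts, cand)
      tries <- tries + 1L
    }
    pore_r2 <- max(1.5, W / 30)^2
    for (i in seq_len(nrow(pts)))
      tex <- tex - 0.25 * exp(-((u - pts[i, 1])^2 + (v - pts[i, 2])^2) /
                                pore_r2)
  }
  block <- canvas[ys + 1L, xs + 1L]
  block[inside] <- pmin(pmax(tex[inside], 0), 1)
  canvas[ys + 1L, xs + 1L] <- block
  canvas
}

smooth_background <- function(h, w, amp, level = 0.85) {
  xs <- seq_len(w) / w; ys <- seq_len(h) / h
  ph <- stats::runif(4, 0, 2 * pi)
  fr <- stats::runif(4, 1, 3)
  field <- outer(ys, xs, function(y, x)
    sin(2 * pi * fr[1] * x + ph[1]) * sin(2 * pi * fr[2] * y + ph[2]) +
      0.5 * sin(2 * pi * fr[3] * (x + y) + ph[3]) +
      0.5 * sin(2 * pi * fr[4] * (x - y) + ph[4]))
  level + amp * field / 2
}

#' Generate a synthetic annotated dataset
#'
#' Places class-labelled textured capsules at sampled orientations on
#' textured noisy canvases, without overlap, and traces each boundary as a
#' polygon annotation.  Fully deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `images` (list of [annotated_image()]) and `truth`
#'   (data frame: `image_id`, `object`, `species`, `orientation_deg`,
#'   `length_px`, `width_px`, and the object center).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$canvas[1]; w <- spec$canvas[2]
  queue <- rep(names(spec$classes), times = spec$per_class_counts)
  images <- list(); truth <- list()
  with_preserved_rng({
    set.seed(spec$seed)
    queue <- sample(queue)
    img_i <- 0L
    while (length(queue) > 0) {
      img_i <- img_i + 1L
      n_obj <- min(length(queue),
                   sample(spec$objects_per_image[1]:spec$objects_per_image[2],
                          1))
      take <- queue[seq_len(n_obj)]
      queue <- queue[-seq_len(n_obj)]
      canvas <- smooth_background(h, w, spec$background_amp)
      placed <- matrix(numeric(0), 0, 3)  # center x, y, radius
      objects <- list(); rows <- list()
      for (oi in seq_along(take)) {
        sp <- take[oi]
        cls <- spec$classes[[sp]]
        L <- cls$length_px * stats::runif(1, 0.85, 1.15)
        W <- L / cls$aspect
        rad <- L / 2 + 4
        if (2 * rad > min(h, w) - 8)
          stop("canvas ", h, "x", w, " too small for objects of length ",
               round(L))
        ok <- FALSE
        for (try in 1:200) {
          theta <- stats::runif(1, spec$orientation_range[1],
                                spec$orientation_range[2])
          ctr <- c(stats::runif(1, rad + 2, w - rad - 2),
                   stats::runif(1, rad + 2, h - rad - 2))
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - ctr[1])^2 +
                       (placed[, 2] - ctr[2])^2) > placed[, 3] + rad)) {
            ok <- TRUE; break
          }
        }
        if (!ok) {
          # a crowded canvas spills its remaining objects to the next image
          queue <- c(take[oi:length(take)], queue)
          break
        }
        placed <- rbind(placed, c(ctr, rad))
        canvas <- render_capsule(canvas, cls, L, W, theta, ctr)
        pg <- capsule_polygon(L, W, cls$cap, theta, ctr)
        pg[, 1] <- pmin(pmax(pg[, 1], 0), w - 1)
        pg[, 2] <- pmin(pmax(pg[, 2], 0), h - 1)
        objects[[length(objects) + 1L]] <- list(species = sp, polygon = pg)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = sprintf("synth%04d", img_i),
          object = length(objects), species = sp,
          orientation_deg = ((theta + 90) %% 180) - 90,
          length_px = L, width_px = W, center_x = ctr[1], center_y = ctr[2])
      }
      canvas <- canvas + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      canvas <- pmin(pmax(canvas, 0), 1)
      px <- array(rep(canvas, 3), dim = c(h, w, 3))
      images[[img_i]] <- annotated_image(sprintf("synth%04d", img_i), px,
                                         objects)
      truth[[img_i]] <- do.call(rbind, rows)
    }
  })
  list(images = images, truth = do.call(rbind, truth))
}

# The five well-separated benchmark classes.  Every interior intensity
# sits well below the ~0.85 background so all objects are clearly visible,
# and the classes ladder jointly across mean intensity, stria frequency,
# pore density, and aspect ratio; the two 0.52-intensity classes are split
# by an order-of-magnitude stria-frequency difference.
easy_benchmark_classes <- function() {
  list(
    dark_smooth = synth_class(base_intensity = 0.12, aspect = 5.0,
                              length_px = 380, stria_freq = 0,
                              stria_amp = 0, pore_density = 0.2),
    shade_smooth = synth_class(base_intensity = 0.32, aspect = 5.0,
                               length_px = 380, stria_freq = 0,
                               stria_amp = 0, pore_density = 0.2),
    mid_fine_striae = synth_class(base_intensity = 0.52, aspect = 4.0,
                                  length_px = 360, stria_freq = 0.20,
                                  stria_amp = 0.30, pore_density = 0.5),
    mid_coarse_striae = synth_class(base_intensity = 0.52, aspect = 4.0,
                                    length_px = 360, stria_freq = 0.04,
                                    stria_amp = 0.30, pore_density = 0.5),
    bright_pored = synth_class(base_intensity = 0.70, aspect = 3.0,
                               length_px = 300, stria_freq = 0,
                               stria_amp = 0, pore_density = 4.0))
}

#' The canonical desk-scale benchmark: 5 classes x 100 crops
#'
#' Generates 100 crops per class at the canonical 432 x 128 input size
#' directly (objects rendered horizontally centered on their canvas, so no
#' orientation normalization is involved), with a 70/15/15 stratified
#' split.  The five classes are constructed to be well separated -- they
#' differ jointly in interior intensity, stria frequency, and aspect -- so
#' a small network learns them in a handful of epochs; this is the
#' fixture for training learnability and activation-map tests.
#'
#' @param seed integer master seed (default 0).
#' @param n_per_class crops per class (default 100).
#' @param target_height,target_width crop size (default 128 x 432).
#' @param noise_sd additive Gaussian pixel noise (default 0.03).
#' @return List with `crops` (list of `diatom_crop`s, each carrying its
#'   ground-truth interior `mask`) and `manifest` (a `dataset_manifest`).
#' @export
easy_benchmark <- function(seed = 0L, n_per_class = 100L,
                           target_height = 128L, target_width = 432L,
                           noise_sd = 0.03) {
  classes <- easy_benchmark_classes()
  crops <- list()
  with_preserved_rng({
    set.seed(seed + 1L)
    for (ci in seq_along(classes)) {
      sp <- names(classes)[ci]
      cls <- classes[[ci]]
      scale <- target_width / 432
      for (k in seq_len(n_per_class)) {
        canvas <- smooth_background(target_height, target_width, 0.04)
        L <- cls$length_px * scale * stats::runif(1, 0.85, 1.05)
        W <- min(L / cls$aspect, 0.85 * target_height)
        ctr <- c(target_width / 2 + stats::runif(1, -8, 8) * scale,
                 target_height / 2 + stats::runif(1, -6, 6) * scale)
        canvas <- render_capsule(canvas, cls, L, W, 0, ctr)
        canvas <- canvas + matrix(stats::rnorm(length(canvas), 0, noise_sd),
                                  nrow(canvas))
        canvas <- pmin(pmax(canvas, 0), 1)
        pg <- capsule_polygon(L, W, cls$cap, 0, ctr)
        mask <- polygon_mask_cpp(target_height, target_width, pg)
        crops[[length(crops) + 1L]] <- structure(
          list(crop_id = sprintf("%s_%03d", sp, k),
               pixels = array(rep(canvas, 3),
                              dim = c(target_height, target_width, 3)),
               species = sp,
               source = list(image_id = sprintf("%s_%03d", sp, k),
                             object = 1L),
               augmentation = "original", rotation_applied = 0,
               mask = mask),
          class = "diatom_crop")
      }
    }
  })
  manifest <- stratified_split(crops, c(0.70, 0.15, 0.15), seed = seed)
  list(crops = crops, manifest = manifest)
}
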