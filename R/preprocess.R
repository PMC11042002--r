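# Crop extraction and normalization.
#
# Coordinate convention (used everywhere): pixel rasters are R arrays
# [row, column(, channel)], 0-based pixel-center coordinates; polygons are
# N x 2 matrices of (x, y) = (column, row); bounding boxes are half-open.

#' Construct an annotated micrograph
#'
#' @param image_id identifier string.
#' @param pixels `[height, width, channels]` array of intensities in
#'   `[0, 1]` (a 2-D matrix is promoted to one channel).
#' @param objects list of objects, each a list with `species` (label) and
#'   `polygon` (N x 2 matrix of (x, y) pixel coordinates, at least 3
#'   vertices, inside the image bounds).
#' @return An `annotated_image`.
#' @export
annotated_image <- function(image_id, pixels, objects) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  for (ob in objects) {
    pg <- ob$polygon
    if (!is.matrix(pg) || ncol(pg) != 2 || nrow(pg) < 3)
      stop("polygon must be an N x 2 matrix with N >= 3 (image ", image_id, ")")
    if (any(pg[, 1] < -0.5 | pg[, 1] > w - 0.5 |
            pg[, 2] < -0.5 | pg[, 2] > h - 0.5))
      stop("polygon outside image bounds (image ", image_id, ")")
    if (is.null(ob$species)) stop("object without species label")
  }
  structure(list(image_id = image_id, pixels = pixels, objects = objects),
            class = "annotated_image")
}

polygon_area <- function(pg) {
  x <- pg[, 1]; y <- pg[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Orientation of a polygon's principal axis, in degrees in (-90, 90],
# from the major eigenvector of the centered vertex second-moment matrix.
polygon_orientation <- function(pg) {
  ctr <- colMeans(pg)
  m <- crossprod(sweep(pg, 2, ctr))
  ev <- eigen(m, symmetric = TRUE)
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Orientation of a binary mask by image moments
#'
#' Second-moment (inertia-tensor) orientation of the `TRUE` pixels, in
#' degrees in `(-90, 90]`; 0 means horizontal.  Used as the independent
#' check that normalized crops are horizontal.
#'
#' @param mask logical matrix.
#' @return Angle in degrees.
#' @export
mask_orientation <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - mean(idx[, 2])
  y <- idx[, 1] - mean(idx[, 1])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang > 90) ang <- ang - 180
  ang
}

dilate3x3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  rd <- mask
  rd[-h, ] <- rd[-h, ] | mask[-1, ]
  rd[-1, ] <- rd[-1, ] | mask[-h, ]
  out <- rd
  out[, -w] <- out[, -w] | rd[, -1]
  out[, -1] <- out[, -1] | rd[, -w]
  out
}

#' Extract each annotated diatom and normalize it horizontally
#'
#' For every annotated object the image is rotated so the principal axis
#' of its polygon (major eigenvector of the vertex second-moment matrix)
#' is horizontal, then cropped to the rotated polygon's bounding box.
#' Pixels outside the polygon are replaced by a background fill value --
#' the median intensity of a 2-pixel annulus just outside the boundary --
#' so the network cannot latch onto hard rotation borders.  The 180-degree
#' ambiguity of the principal axis is left as produced; the flip
#' augmentations cover both senses.
#'
#' @param annotated an [annotated_image()].
#' @return A list of `diatom_crop` objects (`augmentation = "original"`,
#'   pre-resize), one per non-degenerate object, in annotation order.
#'   Degenerate (zero-area) polygons are skipped with a warning and listed
#'   in the `skipped` attribute.
#' @export
extract_and_normalize <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_image"))
  crops <- list()
  skipped <- integer()
  for (oi in seq_along(annotated$objects)) {
    ob <- annotated$objects[[oi]]
    pg <- ob$polygon
    if (polygon_area(pg) <= 0) {
      warning("skipping degenerate (zero-area) polygon: image ",
              annotated$image_id, " object ", oi)
      skipped <- c(skipped, oi)
      next
    }
    theta <- polygon_orientation(pg)
    # rotate by -theta about the polygon centroid so the axis is horizontal
    a <- -theta * pi / 180
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)  # col-major
    ctr <- colMeans(pg)
    pg_rot <- sweep(pg, 2, ctr) %*% t(rot)
    xr <- range(pg_rot[, 1]); yr <- range(pg_rot[, 2])
    out_w <- max(1L, as.integer(ceiling(xr[2] - xr[1] + 1)))
    out_h <- max(1L, as.integer(ceiling(yr[2] - yr[1] + 1)))
    # inverse map: output pixel (q, r) -> rotated frame -> source (x, y)
    # src = R^{-1} (p_out + origin) + ctr,  R^{-1} = rot(+a)^T
    inv <- t(rot)
    m <- c(inv[1, 1], inv[1, 2],
           inv[1, 1] * xr[1] + inv[1, 2] * yr[1] + ctr[1],
           inv[2, 1], inv[2, 2],
           inv[2, 1] * xr[1] + inv[2, 2] * yr[1] + ctr[2])
    px <- warp_affine_cpp(annotated$pixels, out_h, out_w, m, 1L, 0)
    poly_out <- cbind(pg_rot[, 1] - xr[1], pg_rot[, 2] - yr[1])
    mask <- polygon_mask_cpp(out_h, out_w, poly_out)
    ring <- dilate3x3(dilate3x3(mask)) & !mask
    fill <- if (any(ring)) {
      stats::median(apply(px, 3, function(pl) pl[ring]))
    } else stats::median(px)
    for (k in seq_len(dim(px)[3])) {
      pl <- px[, , k]
      pl[!mask] <- fill
      px[, , k] <- pl
    }
    crops[[length(crops) + 1L]] <- structure(
      list(crop_id = sprintf("%s_obj%02d", annotated$image_id, oi),
           pixels = px, species = ob$species,
           source = list(image_id = annotated$image_id, object = oi),
           augmentation = "original", rotation_applied = -theta,
           mask = mask),
      class = "diatom_crop")
  }
  attr(crops, "skipped") <- skipped
  crops
}

#' Resize a crop to the canonical input size
#'
#' Direct bilinear rescale to a single fixed size; the aspect ratio is not
#' preserved.  The default 432 x 128 (width x height) is the average width
#' by average height of the source dataset's crops.
#'
#' @param crop a `diatom_crop`.
#' @param target_height,target_width target size in pixels.
#' @return The crop with `pixels` exactly `target_height x target_width`
#'   (mask resized alongside when present).
#' @export
resize_crop <- function(crop, target_height = 128L, target_width = 432L) {
  if (target_height < 1 || target_width < 1)
    stop("target size must be positive")
  d <- dim(crop$pixels)
  if (d[1] == target_height && d[2] == target_width) return(crop)
  sx <- d[2] / target_width
  sy <- d[1] / target_height
  # center-aligned sampling: src = (out + 0.5) * scale - 0.5
  m <- c(sx, 0, 0.5 * sx - 0.5, 0, sy, 0.5 * sy - 0.5)
  crop$pixels <- warp_affine_cpp(crop$pixels, as.integer(target_height),
                                 as.integer(target_width), m, 1L, 0)
  if (!is.null(crop$mask)) {
    mk <- warp_affine_cpp(array(as.numeric(crop$mask), dim = dim(crop$mask)),
                          as.integer(target_height),
                          as.integer(target_width), m, 1L, 0)
    crop$mask <- mk >= 0.5
  }
  crop
}

flip_pixels <- function(px, vflip, hflip) {
  if (vflip) px <- px[dim(px)[1]:1, , , drop = FALSE]
  if (hflip) px <- px[, dim(px)[2]:1, , drop = FALSE]
  px
}

#' The three flip augmentations
#'
#' Expands one original crop into `[original, vflip, hflip, vhflip]`
#' (vertical, horizontal, and combined flips), quadrupling the dataset.
#' Labels and source provenance are propagated; the four variants form a
#' Klein four-group under composition.
#'
#' @param crop a `diatom_crop` with `augmentation == "original"`.
#' @return List of 4 crops; augmenting an already-augmented crop is an
#'   error (prevents double counting).
#' @export
augment_flips <- function(crop) {
  if (!identical(crop$augmentation, "original"))
    stop("refusing to augment an already-augmented crop (", crop$crop_id, ")")
  variants <- list(original = c(FALSE, FALSE), vflip = c(TRUE, FALSE),
                   hflip = c(FALSE, TRUE), vhflip = c(TRUE, TRUE))
  lapply(names(variants), function(nm) {
    fl <- variants[[nm]]
    out <- crop
    out$pixels <- flip_pixels(crop$pixels, fl[1], fl[2])
    if (!is.null(crop$mask)) {
      mk <- crop$mask
      if (fl[1]) mk <- mk[nrow(mk):1, , drop = FALSE]
      if (fl[2]) mk <- mk[, ncol(mk):1, drop = FALSE]
      out$mask <- mk
    }
    out$augmentation <- nm
    if (nm != "original") out$crop_id <- paste0(crop$crop_id, "_", nm)
    out
  })
}

#' Read / write annotation JSON
#'
#' One JSON document per micrograph:
#' `{image_id, width, height, objects: [{species, polygon: [[x, y], ...]}]}`.
#' `read_annotations` validates the polygons against the image bounds.
#'
#' @param annotated an [annotated_image()]; `path` a JSON file path;
#'   `pixels` the raster to attach on read (annotation JSON carries only
#'   geometry).
#' @export
write_annotations <- function(annotated, path) {
  doc <- list(image_id = annotated$image_id,
              width = dim(annotated$pixels)[2],
              height = dim(annotated$pixels)[1],
              objects = lapply(annotated$objects, function(ob)
                list(species = ob$species,
                     polygon = unname(ob$polygon))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, pixels = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(pixels))
    pixels <- array(0, dim = c(doc$height, doc$width, 1L))
  objects <- lapply(seq_len(nrow_or_len(doc$objects)), function(i) {
    ob <- if (is.data.frame(doc$objects)) doc$objects[i, ] else doc$objects[[i]]
    pg <- ob$polygon
    if (is.list(pg) && length(pg) == 1L) pg <- pg[[1]]
    if (!is.matrix(pg)) pg <- do.call(rbind, pg)
    list(species = ob$species[[1]], polygon = unname(pg))
  })
  annotated_image(doc$image_id, pixels, objects)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read / write a crop raster as PNG
#' @param crop a `diatom_crop`; `path` output file.
#' @export
write_crop_png <- function(crop, path) {
  px <- crop$pixels
  px[px < 0] <- 0; px[px > 1] <- 1
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname write_crop_png
#' @export
read_crop_png <- function(path, crop_id = NULL, species = NA_character_) {
  px <- png::readPNG(path)
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  structure(list(crop_id = crop_id %||% tools::file_path_sans_ext(basename(path)),
                 pixels = px, species = species,
                 source = list(image_id = NA_character_, object = NA_integer_),
                 augmentation = "original", rotation_applied = 0),
            class = "diatom_crop")
}
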