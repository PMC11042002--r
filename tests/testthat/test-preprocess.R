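make_test_scene <- function(angles, seed = 4L) {
  classes <- list(a = synth_class(base_intensity = 0.4, aspect = 4,
                                  length_px = 140, stria_freq = 0.08))
  spec <- synthetic_spec(classes, length(angles), canvas = c(260, 340),
                         objects_per_image = c(1L, 1L),
                         orientation_range = c(0, 180), seed = seed)
  # regenerate with pinned orientations by drawing one object per image
  lapply(angles, function(a) {
    sp <- synthetic_spec(classes, 1L, canvas = c(260, 340),
                         objects_per_image = c(1L, 1L),
                         orientation_range = c(a, a), seed = seed)
    generate_dataset(sp)
  })
}

test_that("known-angle synthetic objects come out horizontal within 1 degree", {
  for (scene in make_test_scene(c(37, 81, 119, 164))) {
    crops <- extract_and_normalize(scene$images[[1]])
    expect_length(crops, 1L)
    ang <- mask_orientation(crops[[1]]$mask)
    expect_lt(abs(ang), 1)
  }
})

test_that("an already-horizontal rectangle needs no rotation", {
  px <- matrix(0.2, 80, 120)
  px[30:50, 20:100] <- 0.8
  rect <- cbind(c(20, 100, 100, 20), c(30, 30, 50, 50))
  ann <- annotated_image("img1", px, list(list(species = "sp",
                                               polygon = rect)))
  crops <- extract_and_normalize(ann)
  expect_lt(abs(crops[[1]]$rotation_applied), 1e-6)
  expect_lt(abs(mask_orientation(crops[[1]]$mask)), 1e-6)
})

test_that("extraction yields one crop per object with labels in order", {
  px <- matrix(0.5, 120, 200)
  sq <- function(x0, y0) cbind(c(x0, x0 + 30, x0 + 30, x0),
                               c(y0, y0, y0 + 12, y0 + 12))
  ann <- annotated_image("multi", px, list(
    list(species = "alpha", polygon = sq(10, 10)),
    list(species = "beta", polygon = sq(60, 40)),
    list(species = "gamma", polygon = sq(120, 80))))
  crops <- extract_and_normalize(ann)
  expect_length(crops, 3L)
  expect_equal(vapply(crops, `[[`, "", "species"),
               c("alpha", "beta", "gamma"))
  expect_equal(vapply(crops, function(cr) cr$source$object, 1L), 1:3)
})

test_that("degenerate polygons are skipped with a warning", {
  px <- matrix(0.5, 60, 60)
  line <- cbind(c(10, 40, 40), c(10, 10, 10))      # zero area
  ok <- cbind(c(5, 45, 45, 5), c(30, 30, 50, 50))
  ann <- annotated_image("degen", px, list(
    list(species = "bad", polygon = line),
    list(species = "good", polygon = ok)))
  expect_warning(crops <- extract_and_normalize(ann), "degenerate")
  expect_length(crops, 1L)
  expect_equal(crops[[1]]$species, "good")
  expect_equal(attr(crops, "skipped"), 1L)
})

test_that("polygon validation rejects malformed annotations", {
  px <- matrix(0, 50, 50)
  expect_error(annotated_image("x", px, list(
    list(species = "s", polygon = cbind(c(1, 2), c(1, 2))))), ">= 3")
  expect_error(annotated_image("x", px, list(
    list(species = "s",
         polygon = cbind(c(10, 60, 30), c(10, 10, 30))))), "bounds")
})

test_that("resize maps any crop to the target size", {
  cr <- make_crop(matrix(runif(260 * 860), 260, 860))
  out <- resize_crop(cr, 128, 432)
  expect_equal(dim(out$pixels)[1:2], c(128L, 432L))
  # identity resize leaves pixels untouched
  cr2 <- make_crop(matrix(runif(128 * 432), 128, 432))
  expect_identical(resize_crop(cr2, 128, 432)$pixels, cr2$pixels)
  # a constant image stays constant at any size
  cr3 <- make_crop(matrix(0.37, 93, 241))
  out3 <- resize_crop(cr3, 128, 432)
  expect_equal(range(out3$pixels), c(0.37, 0.37), tolerance = 1e-12)
  expect_error(resize_crop(cr, 0, 432), "positive")
})

test_that("bilinear resize agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  src <- matrix(runif(60 * 90), 60, 90)
  mine <- resize_crop(make_crop(src), 30, 45)$pixels[, , 1]
  ref <- EBImage::imageData(EBImage::resize(EBImage::Image(t(src)), w = 45,
                                            h = 30, filter = "bilinear"))
  expect_lt(max(abs(mine - t(ref))), 0.06)
  expect_lt(mean(abs(mine - t(ref))), 0.01)
})

test_that("flip variants form the Klein four-group and quadruple the set", {
  set.seed(8)
  px <- array(runif(20 * 30 * 3), dim = c(20, 30, 3))
  px[3, 4, 1] <- 1                              # left-right asymmetric marker
  cr <- make_crop(px, id = "asym")
  out <- augment_flips(cr)
  expect_length(out, 4L)
  expect_equal(vapply(out, `[[`, "", "augmentation"),
               c("original", "vflip", "hflip", "vhflip"))
  v <- out[[2]]$pixels; h <- out[[3]]$pixels; vh <- out[[4]]$pixels
  expect_identical(v[20:1, , ], px)              # involution
  expect_identical(h[, 30:1, ], px)
  expect_identical(vh, v[, 30:1, ])              # vhflip = hflip o vflip
  expect_identical(vh, h[20:1, , ])
  # hflip differs from the original exactly at mirrored coordinates
  expect_identical(h, px[, 30:1, ])
  # labels and provenance propagate
  expect_true(all(vapply(out, `[[`, "", "species") == "sp"))
  expect_true(all(vapply(out, function(o) o$source$image_id, "") == "asym"))
  # double augmentation is refused
  expect_error(augment_flips(out[[2]]), "already-augmented")
})

test_that("per-class counts quadruple under augmentation", {
  crops <- make_toy_crops(tiny_spec(num_classes = 3L), n_per_class = 4L)
  aug <- unlist(lapply(crops, augment_flips), recursive = FALSE)
  expect_length(aug, 4L * length(crops))
  tab_before <- table(vapply(crops, `[[`, "", "species"))
  tab_after <- table(vapply(aug, `[[`, "", "species"))
  expect_equal(as.vector(tab_after), 4L * as.vector(tab_before))
  expect_false(anyDuplicated(vapply(aug, `[[`, "", "crop_id")) > 0)
})

test_that("annotation JSON round-trips with geometry intact", {
  px <- matrix(0.5, 90, 140)
  pg <- cbind(c(12.5, 80, 80, 12.5), c(10, 10, 44.25, 44.25))
  ann <- annotated_image("rt", px, list(list(species = "sp A",
                                             polygon = pg)))
  path <- tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path, pixels = px)
  expect_equal(back$image_id, "rt")
  expect_equal(back$objects[[1]]$species, "sp A")
  expect_equal(back$objects[[1]]$polygon, pg)
})
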