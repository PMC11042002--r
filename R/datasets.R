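# Stratified splitting and manifest I/O.

#' Stratified train/validation/test split
#'
#' Splits a crop set per class: with fractions `(f1, f2, f3)` a class of
#' `n` units receives `floor(f1 * n)` training and `floor(f2 * n)`
#' validation units, the remainder going to test; if any split ends up
#' empty for a class with at least as many units as splits, one unit is
#' moved there from the largest split.  Assignment within a class is
#' random and deterministic given `seed`.
#'
#' By default the four flip variants of one source object count as a
#' single unit and land in the same split (`group_variants = TRUE`),
#' preventing near-duplicate leakage between training and test.  Set
#' `group_variants = FALSE` to assign augmented crops independently.
#'
#' @param crops list of `diatom_crop` objects.
#' @param fractions length-3 positive numeric summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed integer RNG seed.
#' @param group_variants keep flip variants of one source object together.
#' @return A `dataset_manifest`: a data frame with columns `crop_id`,
#'   `path`, `species`, `augmentation`, `split`, plus attributes
#'   `class_table` (per-class counts per split) and `seed`.
#' @export
stratified_split <- function(crops, fractions = c(0.70, 0.15, 0.15),
                             seed = 0L, group_variants = TRUE) {
  if (length(crops) == 0) stop("empty crop list: nothing to split")
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 positive numbers summing to 1")
  df <- data.frame(
    crop_id = vapply(crops, `[[`, "", "crop_id"),
    path = vapply(crops, function(cr) attr(cr, "path") %||% NA_character_, ""),
    species = vapply(crops, `[[`, "", "species"),
    augmentation = vapply(crops, `[[`, "", "augmentation"),
    source_key = vapply(crops, function(cr)
      paste(cr$source$image_id, cr$source$object, sep = ":"), ""),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$crop_id))
    stop("duplicate crop_id: ", df$crop_id[duplicated(df$crop_id)][1])
  df$split <- NA_character_
  splits <- c("train", "validation", "test")
  with_preserved_rng({
    set.seed(seed)
    for (cls in sort(unique(df$species))) {
      in_cls <- which(df$species == cls)
      units <- if (group_variants) unique(df$source_key[in_cls])
               else df$crop_id[in_cls]
      n <- length(units)
      if (n < 3)
        stop("class '", cls, "' has ", n,
             " unit(s); need at least one per split")
      n_tr <- floor(fractions[1] * n)
      n_va <- floor(fractions[2] * n)
      sizes <- c(n_tr, n_va, n - n_tr - n_va)
      for (s in which(sizes == 0)) {
        big <- which.max(sizes)
        sizes[big] <- sizes[big] - 1L
        sizes[s] <- sizes[s] + 1L
      }
      assign_units <- sample(rep(splits, times = sizes))
      key <- if (group_variants) df$source_key[in_cls] else df$crop_id[in_cls]
      df$split[in_cls] <- assign_units[match(key, units)]
    }
  })
  manifest_from_df(df[, c("crop_id", "path", "species", "augmentation",
                          "split")],
                   seed = as.integer(seed))
}

manifest_from_df <- function(df, seed = NA_integer_) {
  class_table <- as.data.frame.matrix(table(df$species, df$split))
  for (s in c("train", "validation", "test"))
    if (!s %in% names(class_table)) class_table[[s]] <- 0L
  class_table <- class_table[, c("train", "validation", "test")]
  structure(df, class_table = class_table, seed = seed,
            class = c("dataset_manifest", "data.frame"))
}

#' Write / read a dataset manifest
#'
#' Delimited UTF-8 text with a header row and one row per crop; the split
#' seed rides in a leading comment line.  The round trip is lossless and
#' row order is stable.
#'
#' @param manifest a `dataset_manifest`; `path` a file path.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#diatomnet-manifest seed=%s",
                     attr(manifest, "seed") %||% NA), con)
  utils::write.csv(as.data.frame(manifest), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  seed <- NA_integer_
  if (length(lines) && startsWith(lines[1], "#diatomnet-manifest")) {
    seed <- suppressWarnings(
      as.integer(sub(".*seed=", "", lines[1])))
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = c(crop_id = "character",
                                       path = "character",
                                       species = "character",
                                       augmentation = "character",
                                       split = "character"))
  req <- c("crop_id", "path", "species", "augmentation", "split")
  if (!all(req %in% names(df)))
    stop("manifest missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (anyDuplicated(df$crop_id))
    stop("duplicate crop_id in manifest: ",
         df$crop_id[duplicated(df$crop_id)][1])
  bad <- setdiff(unique(df$split), c("train", "validation", "test"))
  if (length(bad)) stop("unknown split token: ", paste(bad, collapse = ", "))
  manifest_from_df(df, seed = seed)
}

#' Per-class split table of a manifest
#' @param manifest a `dataset_manifest`.
#' @return Data frame of per-class counts in train/validation/test.
#' @export
class_table <- function(manifest) attr(manifest, "class_table")

#' Species distribution of the source diatom dataset
#'
#' The published per-class image counts of the 68-species river-diatom
#' dataset the architecture was designed for: 3,027 light-microscopy
#' images, heavily unbalanced (6 to 386 per species).  Used to drive
#' realistic class imbalance in the synthetic generator and as the ground
#' truth for dataset arithmetic.
#'
#' @return Data frame with `species` and `count` (68 rows).
#' @export
diatom_class_counts <- function() {
  data.frame(species = c(
    "Achnanthidium biasolettianum", "Achnanthidium minutissimum",
    "Adlafia minuscula", "Amphora inariensis", "Amphora pediculus",
    "Caloneis lancettula", "Cocconeis pseudolineata", "Cymbella cantonatii",
    "Cymbella excisa", "Cymbella excisa var. procera",
    "Cymbella excisa var. subcapitata", "Cymbopleura amphicephala",
    "Denticula kuetzingii", "Diatoma mesodon", "Diatoma moniliformis",
    "Didymosphenia geminata", "Diploneis fontanella", "Encyonema silesiacum",
    "Encyonema ventricosum", "Epithemia argus", "Epithemia goeppertiana",
    "Fragilaria recapitellata", "Frustulia vulgaris",
    "Gomphonema calcifugum", "Gomphonema drutelingense",
    "Gomphonema exilissimum", "Gomphonema micropus", "Gomphonema minutum",
    "Gomphonema olivaceum", "Gomphonema pumilum",
    "Gomphonema pumilum var. rigidum", "Gomphonema supertergestinum",
    "Gomphonema tergestinum", "Halamphora paraveneta", "Halamphora veneta",
    "Hantzschiana abundans", "Humidophila contenta", "Humidophila perpusilla",
    "Luticola nivalis", "Meridion circulare", "Navicula capitatoradiata",
    "Navicula cryptocephala", "Navicula cryptotenella",
    "Navicula cryptotenelloides", "Navicula gregaria", "Navicula lanceolata",
    "Navicula moskalii", "Navicula novaesiberica", "Navicula reichardtiana",
    "Navicula tripunctata", "Navicula trivialis", "Navicula upsaliensis",
    "Neidiomorpha binodiformis", "Nitzschia archibaldii",
    "Nitzschia hantzschiana", "Nitzschia linearis", "Nitzschia palea",
    "Nitzschia recta", "Pantocsekiella ocellata", "Pinnularia brebissonii",
    "Planothidium frequentissimum", "Planothidium lanceolatum",
    "Rhoicosphenia abbreviata", "Sellaphora radiosa",
    "Sellaphora saugerresii", "Stauroneis blazenciciae", "Surella minuta",
    "Surirella brebissonii var. kuetzingii"),
    count = c(60L, 13L, 26L, 6L, 22L, 10L, 49L, 54L, 59L, 6L, 44L, 6L, 14L,
              53L, 56L, 6L, 8L, 182L, 61L, 17L, 7L, 184L, 12L, 39L, 15L, 8L,
              16L, 15L, 386L, 11L, 33L, 14L, 85L, 33L, 40L, 10L, 53L, 35L,
              7L, 65L, 15L, 24L, 272L, 77L, 22L, 9L, 19L, 9L, 165L, 22L,
              34L, 45L, 6L, 19L, 30L, 36L, 6L, 7L, 27L, 36L, 26L, 132L, 77L,
              9L, 6L, 7L, 6L, 64L))
}
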