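#' Majority vote over one seed's pixel predictions
#'
#' Decision-2 of the pipeline: the seed is assigned the variety predicted
#' for the largest fraction of its pixels. Ties are broken toward the
#' lowest class index, deterministically (with hundreds of pixels per seed,
#' exact ties are practically impossible).
#'
#' @param pixel_labels vector/factor of per-pixel predicted classes for one
#'   seed (non-empty).
#' @param classes ordered class levels; defaults to the factor levels of
#'   `pixel_labels`.
#' @return An object of class `vote_result`: `percentages` (named,
#'   summing to 1), `final_label`, `n_pixels`.
#' @examples
#' vote(rep(c("ZH37", "ZH41"), c(60, 40)), classes = c("ZH37", "ZH41", "ZH55"))
#' @export
vote <- function(pixel_labels, classes = NULL) {
  if (length(pixel_labels) == 0L) stop("empty pixel label list")
  if (is.null(classes)) {
    pixel_labels <- as.factor(pixel_labels)
    classes <- levels(pixel_labels)
  }
  f <- factor(pixel_labels, levels = classes)
  if (anyNA(f)) stop("pixel labels outside the class list")
  counts <- table(f)
  pct <- as.numeric(counts) / length(f)
  names(pct) <- classes
  win <- which.max(pct)   # first maximum = lowest class index on ties
  structure(list(percentages = pct,
                 final_label = factor(classes[win], levels = classes),
                 n_pixels = length(f)),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("<vote_result> %s (%d pixels): %s\n",
              as.character(x$final_label), x$n_pixels,
              paste(sprintf("%s %.1f%%", names(x$percentages),
                            100 * x$percentages), collapse = ", ")))
  invisible(x)
}

#' Vote table for many seeds
#'
#' Applies [vote()] per seed and assembles the per-seed class percentages
#' and final labels into one data frame (the vote-table export format).
#'
#' @param pixel_labels per-pixel predicted classes.
#' @param seed_ids seed instance of each pixel.
#' @param classes ordered class levels.
#' @return Data frame: `seed_id`, `n_pixels`, one `pct_<class>` column per
#'   class, `final_label`. Seeds appear in order of first occurrence.
#' @export
vote_seeds <- function(pixel_labels, seed_ids, classes = NULL) {
  if (is.null(classes)) classes <- levels(as.factor(pixel_labels))
  uid <- unique(seed_ids)
  rows <- lapply(uid, function(id) {
    v <- vote(pixel_labels[seed_ids == id], classes = classes)
    out <- data.frame(seed_id = id, n_pixels = v$n_pixels)
    for (cl in classes) out[[paste0("pct_", cl)]] <- v$percentages[[cl]]
    out$final_label <- as.character(v$final_label)
    out
  })
  out <- do.call(rbind, rows)
  out$final_label <- factor(out$final_label, levels = classes)
  out
}

#' Classify every seed in a cube
#'
#' End-to-end per-seed prediction: extract the pixel spectra of each
#' labeled region, run them through the preprocessing chain, predict each
#' pixel with the trained network (Decision-1), and majority-vote within
#' each seed (Decision-2). The cube must be calibrated; if it still carries
#' bands outside the model's range it is cropped to the model's wavelength
#' window first.
#'
#' @param model a fitted [spectral_cnn()].
#' @param cube a reflectance [hsi_cube].
#' @param regions a `seed_regions` object from [label_seeds()].
#' @param preprocess apply [preprocess_pipeline()] to the extracted pixel
#'   spectra (what the reference pipeline does).
#' @return A list: `votes` (the [vote_seeds()] data frame, one row per
#'   seed), `pixel_labels` (factor, per extracted pixel), `table` (the
#'   extracted, preprocessed pixel [spectra_table]).
#' @export
classify_seeds <- function(model, cube, regions, preprocess = TRUE) {
  stopifnot(inherits(model, "spectral_cnn"), inherits(cube, "hsi_cube"))
  nb <- length(model$wavelengths)
  if (dim(cube)[3] != nb) {
    cube <- crop_bands(cube, min(model$wavelengths), max(model$wavelengths))
    if (dim(cube)[3] != nb)
      stop("cube bands cannot be matched to the model's ", nb, " bands")
  }
  tab <- extract_pixel_spectra(cube, regions)
  if (preprocess) tab <- preprocess_pipeline(tab)
  labels <- predict(model, tab, type = "class")
  list(votes = vote_seeds(labels, tab$seed_ids, classes = model$classes),
       pixel_labels = labels, table = tab)
}

#' Accuracy report
#'
#' Per-class and overall accuracy in percent, plus the confusion matrix
#' (rows = truth, columns = predicted). Per-class accuracy is the fraction
#' of that class's true instances predicted correctly.
#'
#' @param predicted,truth equal-length label vectors/factors.
#' @param classes ordered class levels; defaults to the union of levels.
#' @param set,level optional bookkeeping tags stored in the report.
#' @return An object of class `evaluation_report`: `per_class` (named, %),
#'   `overall` (%), `confusion`, `set`, `level`.
#' @export
evaluate <- function(predicted, truth, classes = NULL, set = "", level = "") {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` have different lengths")
  if (is.null(classes))
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  p <- factor(predicted, levels = classes)
  t <- factor(truth, levels = classes)
  conf <- table(truth = t, predicted = p)
  per_class <- 100 * diag(conf) / rowSums(conf)
  overall <- 100 * sum(diag(conf)) / sum(conf)
  structure(list(per_class = per_class, overall = overall, confusion = conf,
                 set = set, level = level),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  hdr <- paste0("<evaluation_report>",
                if (nzchar(x$set)) paste0(" ", x$set),
                if (nzchar(x$level)) paste0(" (", x$level, ")"))
  cat(hdr, "\n")
  cat("  accuracy (%):",
      paste(sprintf("%s %.3f", names(x$per_class), x$per_class),
            collapse = ", "),
      sprintf("| All %.3f", x$overall), "\n")
  invisible(x)
}

#' Pseudo-color prediction map
#'
#' Colors every seed pixel by its predicted variety over a black
#' background, visualizing within-seed prediction heterogeneity. Pixel
#' labels must be in the extraction order of [extract_pixel_spectra()]
#' (grouped by seed, raster order within seed) and cover all region pixels.
#'
#' @param regions a `seed_regions` object.
#' @param pixel_labels factor of predicted classes, one per region pixel.
#' @param palette named colors per class; the default follows the seed
#'   application's convention (blue/yellow/orange for ZH37/ZH41/ZH55). May
#'   be any color names or hex strings, named by class or positional.
#' @return rows x cols x 3 numeric array in \[0, 1\] (RGB).
#' @export
prediction_map <- function(regions, pixel_labels,
                           palette = c(ZH37 = "blue", ZH41 = "yellow",
                                       ZH55 = "orange")) {
  px <- .region_pixel_index(regions)
  if (length(pixel_labels) != nrow(px))
    stop("need one label per region pixel (", nrow(px), "), got ",
         length(pixel_labels))
  labels <- as.factor(pixel_labels)
  if (anyNA(labels)) stop("missing label(s) for region pixel(s)")
  classes <- levels(labels)
  if (!is.null(names(palette))) {
    if (!all(classes %in% names(palette)))
      stop("palette has no color for class(es): ",
           paste(setdiff(classes, names(palette)), collapse = ", "))
    palette <- palette[classes]
  } else if (length(palette) < length(classes)) {
    stop("palette has fewer colors than classes")
  }
  rgb <- col2rgb(palette[seq_along(classes)]) / 255
  dm <- dim(regions$label_map)
  img <- array(0, c(dm[1], dm[2], 3))
  ci <- as.integer(labels)
  for (ch in 1:3)
    img[cbind(px$row, px$col, ch)] <- rgb[ch, ci]
  img
}

#' Write an RGB image as PNG
#'
#' @param img rows x cols x 3 array in \[0, 1\], e.g. from
#'   [prediction_map()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
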