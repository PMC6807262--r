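#' Binarize a cube at a single band
#'
#' Forms the seed/background mask from the gray-scale image at one band
#' (1200 nm for the seed application: seeds are bright against the black
#' sampling plate). The threshold is chosen by Otsu's method by default, or
#' can be fixed for reproducibility.
#'
#' @param cube an [hsi_cube].
#' @param band_nm band to threshold, in nm; the nearest band is used.
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @return Logical matrix, `TRUE` on foreground. Warns (does not fail) if
#'   the mask is entirely foreground or background.
#' @export
binarize_band <- function(cube, band_nm = 1200, threshold = "otsu") {
  stopifnot(inherits(cube, "hsi_cube"))
  gray <- cube$data[, , band_index(cube, band_nm)]
  th <- if (identical(threshold, "otsu")) otsu_threshold(gray)
        else if (is.numeric(threshold) && length(threshold) == 1L) threshold
        else stop("`threshold` must be \"otsu\" or a single number")
  mask <- gray > th
  if (all(mask)) warning("mask is entirely foreground")
  if (!any(mask)) warning("mask is entirely background")
  mask
}

#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance, computed on
#' `levels` equal-width bins over the data range. Returns a threshold value
#' on the data scale; foreground is `x > threshold`.
#'
#' @param x numeric vector or matrix of gray values.
#' @param levels number of histogram bins.
#' @return Threshold value (a bin edge).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  # between-class variance for threshold after bin k
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-levels])
  breaks[k + 1L]
}

#' Label seed instances in a binary mask
#'
#' Finds 8-connected foreground components of at least `min_area` pixels and
#' labels them 1..n in raster order of each component's first pixel (row by
#' row, left to right), so labels are deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_area smallest component kept, in pixels; smaller specks are
#'   treated as plate noise.
#' @return An object of class `seed_regions`: a list with `label_map`
#'   (integer matrix, 0 = background), `n_seeds`, `areas`, and `boxes`
#'   (data frame of half-open row/col bounding intervals per seed).
#' @export
label_seeds <- function(mask, min_area = 20L) {
  mask <- mask != 0
  storage.mode(mask) <- "integer"
  lab <- label_components_cpp(mask)
  n0 <- max(lab)
  if (n0 > 0) {
    areas0 <- tabulate(lab[lab > 0], n0)
    keep <- which(areas0 >= min_area)
    remap <- integer(n0)
    remap[keep] <- seq_along(keep)   # raster order is preserved
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  n <- max(lab)
  areas <- if (n > 0) tabulate(lab[lab > 0], n) else integer()
  boxes <- if (n > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    lb <- lab[lab > 0]
    data.frame(seed_id = seq_len(n),
               row0 = tapply(idx[, 1], lb, min) - 1L,
               row1 = tapply(idx[, 1], lb, max),
               col0 = tapply(idx[, 2], lb, min) - 1L,
               col1 = tapply(idx[, 2], lb, max),
               area = areas, row.names = NULL)
  } else {
    data.frame(seed_id = integer(), row0 = integer(), row1 = integer(),
               col0 = integer(), col1 = integer(), area = integer())
  }
  structure(list(label_map = lab, n_seeds = n, areas = areas, boxes = boxes),
            class = "seed_regions")
}

#' @export
print.seed_regions <- function(x, ...) {
  cat(sprintf("<seed_regions> %d seed(s), %d x %d label map\n",
              x$n_seeds, nrow(x$label_map), ncol(x$label_map)))
  if (x$n_seeds > 0)
    cat("  areas:", paste(x$areas, collapse = ", "), "px\n")
  invisible(x)
}

# Deterministic pixel ordering used for extraction and map reconstruction:
# grouped by seed, raster order (row-major) within each seed.
.region_pixel_index <- function(regions) {
  lab <- regions$label_map
  idx <- which(lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), seed = integer()))
  lb <- lab[lab > 0]
  raster <- (idx[, 1] - 1L) * ncol(lab) + idx[, 2]
  o <- order(lb, raster)
  data.frame(row = idx[o, 1], col = idx[o, 2], seed = lb[o])
}

#' Extract pixel spectra of labeled seeds
#'
#' Pulls the full spectrum of every labeled pixel out of the cube,
#' producing a pixel-level [spectra_table] with one row per seed pixel
#' (background excluded). Rows are grouped by seed, in raster order within
#' each seed.
#'
#' @param cube an [hsi_cube], same spatial shape as the label map.
#' @param regions a `seed_regions` object from [label_seeds()].
#' @param labels optional variety label per seed (length `n_seeds`),
#'   propagated to each pixel row.
#' @return A pixel-level [spectra_table] whose `seed_ids` are region labels.
#' @export
extract_pixel_spectra <- function(cube, regions, labels = NULL) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(regions, "seed_regions"))
  dm <- dim(cube$data)
  if (!all(dm[1:2] == dim(regions$label_map)))
    stop("cube and label map have different spatial shapes")
  px <- .region_pixel_index(regions)
  flat <- matrix(cube$data, dm[1] * dm[2], dm[3])   # pixel-major
  sp <- flat[(px$col - 1L) * dm[1] + px$row, , drop = FALSE]
  row_labels <- NULL
  if (!is.null(labels)) {
    if (length(labels) != regions$n_seeds)
      stop("`labels` must have one entry per seed")
    row_labels <- as.factor(labels)[px$seed]
  }
  spectra_table(sp, cube$wavelengths, seed_ids = px$seed,
                labels = row_labels, level = "pixel")
}

#' Export a region table as CSV
#'
#' Writes seed_id, area and bounding box (half-open row/col intervals).
#'
#' @param regions a `seed_regions` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  write.csv(regions$boxes, path, row.names = FALSE)
  invisible(path)
}

#' Export a label map as a gray PNG
#'
#' Labels are stored as 8-bit gray levels (label/255), so scenes are limited
#' to 255 seeds; the CSV region table is the authoritative export.
#'
#' @param regions a `seed_regions` object.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(regions, path) {
  if (regions$n_seeds > 255L)
    stop("more than 255 seeds cannot be stored in an 8-bit label PNG")
  png::writePNG(regions$label_map / 255, path)
  invisible(path)
}
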