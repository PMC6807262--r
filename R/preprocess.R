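#' Area normalization
#'
#' Scales each spectrum so its values sum to one, removing overall
#' intensity differences between pixels (illumination, seed curvature):
#' `x_i / sum_j x_j`.
#'
#' @param x numeric vector, or matrix with one spectrum per row.
#' @return Normalized spectrum/spectra, same shape. Errors on a zero-sum
#'   spectrum.
#' @examples
#' area_normalize(c(1, 3))
#' @export
area_normalize <- function(x) {
  if (is.null(dim(x))) {
    s <- sum(x)
    if (s == 0) stop("degenerate spectrum: values sum to 0")
    return(x / s)
  }
  s <- rowSums(x)
  if (any(s == 0)) stop("degenerate spectrum: row(s) ",
                        paste(which(s == 0), collapse = ", "), " sum to 0")
  x / s
}

#' Moving-average smoothing
#'
#' Smooths each spectrum with a centered `window`-point moving average
#' (7 points by default). Interior point i is the mean of points
#' i-3..i+3; at the first and last few points, where the full window would
#' leave the spectrum, the mean is taken over the in-range part of the
#' window, which preserves length and leaves constants unchanged.
#'
#' @param x numeric vector, or matrix with one spectrum per row.
#' @param window odd window length, at most the spectrum length.
#' @return Smoothed spectrum/spectra, same shape.
#' @export
moving_average <- function(x, window = 7L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  n <- ncol(X)
  if (window > n) stop("`window` exceeds spectrum length")
  h <- window %/% 2L
  # cumulative sums with a leading zero column: S[, j+1] = sum of cols 1..j
  S <- cbind(0, t(apply(X, 1, cumsum)))
  if (nrow(X) == 1L) S <- matrix(S, nrow = 1)
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  Y <- (S[, hi + 1L, drop = FALSE] - S[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(X))
  if (vec) as.numeric(Y) else Y
}

#' Pixel-level preprocessing pipeline
#'
#' Applies the full chemometric chain to every spectrum of a pixel-level
#' table, in this order: Daubechies-6 level-3 wavelet denoising, area
#' normalization, 7-point moving-average smoothing. The chain learns
#' nothing from the data, so it is applied identically to every split.
#'
#' @param table a pixel-level [spectra_table] (object-level tables are
#'   accepted and treated the same way).
#' @param wavelet_level,window stage parameters.
#' @param wavelet_threshold passed to [wavelet_denoise()].
#' @return A [spectra_table] with transformed spectra and unchanged
#'   metadata.
#' @export
preprocess_pipeline <- function(table, wavelet_level = 3L, window = 7L,
                                wavelet_threshold = "universal") {
  stopifnot(inherits(table, "spectra_table"))
  if (nrow(table$spectra) == 0L) return(table)
  sp <- wavelet_denoise(table$spectra, level = wavelet_level,
                        threshold = wavelet_threshold)
  sp <- area_normalize(sp)
  sp <- moving_average(sp, window = window)
  spectra_table(sp, table$wavelengths, table$seed_ids,
                labels = table$labels, level = table$level)
}

#' Per-seed average spectra
#'
#' Averages the (preprocessed) pixel spectra of each seed into one
#' object-level spectrum, inheriting the seed's label. Seeds appear in
#' order of first occurrence in the pixel table.
#'
#' @param table a pixel-level [spectra_table].
#' @return An object-level [spectra_table] with one row per seed.
#' @export
average_by_seed <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  ids <- table$seed_ids
  uid <- unique(ids)
  g <- match(ids, uid)
  sums <- rowsum(table$spectra, g, reorder = TRUE)
  counts <- tabulate(g, length(uid))
  avg <- sums / counts
  labels <- NULL
  if (!is.null(table$labels)) {
    per_seed <- tapply(as.character(table$labels), g,
                       function(v) unique(v))
    bad <- vapply(per_seed, length, 1L) > 1L
    if (any(bad))
      stop("seed(s) ", paste(uid[bad], collapse = ", "),
           " carry more than one label")
    labels <- factor(unlist(per_seed), levels = levels(table$labels))
  }
  spectra_table(avg, table$wavelengths, uid, labels = labels,
                level = "object")
}
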