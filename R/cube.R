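#' Hyperspectral cube
#'
#' Container for a line-scan hyperspectral image: a 3-D array of shape
#' rows x cols x bands together with the band-center wavelengths in
#' nanometres. `kind` records whether the values are raw sensor intensity
#' or calibrated reflectance.
#'
#' @param data numeric 3-D array, rows x cols x bands.
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, length equal to `dim(data)[3]`.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `hsi_cube`.
#' @examples
#' cube <- hsi_cube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(1000, 1100, 1200))
#' dim(cube$data)
#' @export
hsi_cube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) [", length(wavelengths),
         "] does not match band dimension [", dim(data)[3L], "]")
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' Index of the band nearest a wavelength
#'
#' @param cube an [hsi_cube].
#' @param nm wavelength in nanometres.
#' @return Integer band index.
#' @export
band_index <- function(cube, nm) {
  stopifnot(inherits(cube, "hsi_cube"), is.numeric(nm), length(nm) == 1L)
  which.min(abs(cube$wavelengths - nm))
}

#' Calibrate raw intensity to reflectance
#'
#' Converts a raw cube to reflectance with white and dark reference images:
#' reflectance = (raw - dark) / (white - dark), element-wise. References may
#' be full cubes of the same shape as `raw`, or a single reference line
#' (a cols x bands matrix) recorded once and broadcast along the scan axis,
#' as line-scan instruments commonly do.
#'
#' Out-of-range reflectance values (outside \[0, 1\]) are preserved, not
#' clipped; a message reports how many there are.
#'
#' @param raw an [hsi_cube] of kind `"raw"` (kind is not enforced, so
#'   re-calibration of subsets is possible).
#' @param white,dark reference cubes ([hsi_cube] or plain array) with the
#'   same shape as `raw`, or cols x bands matrices broadcast over rows.
#' @return An [hsi_cube] of kind `"reflectance"`.
#' @examples
#' raw <- hsi_cube(array(0.5, c(2, 2, 2)), c(1000, 1100))
#' w <- array(1, c(2, 2, 2)); d <- array(0, c(2, 2, 2))
#' calibrate(raw, w, d)$data[1, 1, ]
#' @export
calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hsi_cube"))
  dm <- dim(raw$data)
  w <- .ref_array(white, dm, "white")
  d <- .ref_array(dark, dm, "dark")
  denom <- w - d
  if (any(denom == 0))
    stop("degenerate reference: white equals dark at ",
         sum(denom == 0), " element(s)")
  out <- (raw$data - d) / denom
  n_out <- sum(out < 0 | out > 1)
  if (n_out > 0)
    message(n_out, " reflectance value(s) outside [0, 1]; kept unclipped")
  hsi_cube(out, raw$wavelengths, kind = "reflectance")
}

# Coerce a reference (cube, 3-D array, or cols x bands line matrix) to the
# full shape `dm` = c(rows, cols, bands).
.ref_array <- function(ref, dm, what) {
  if (inherits(ref, "hsi_cube")) ref <- ref$data
  if (is.matrix(ref)) {
    if (!all(dim(ref) == dm[2:3]))
      stop(what, " reference line must be cols x bands (",
           dm[2], " x ", dm[3], ")")
    return(aperm(array(ref, c(dm[2], dm[3], dm[1])), c(3, 1, 2)))
  }
  if (is.array(ref) && length(dim(ref)) == 3L) {
    if (!all(dim(ref) == dm))
      stop(what, " reference shape does not match raw cube")
    return(ref)
  }
  stop(what, " reference must be an hsi_cube, 3-D array, or cols x bands matrix")
}

#' Crop a cube to a wavelength window
#'
#' Keeps the bands with `lo <= wavelength <= hi`, preserving order. The
#' instrument's full range is noisy at both ends, so analysis is normally
#' restricted to an inner window (975-1646 nm for the seed application).
#'
#' @param cube an [hsi_cube].
#' @param lo,hi window bounds in nm, inclusive.
#' @return An [hsi_cube] with the retained bands.
#' @export
crop_bands <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "hsi_cube"), lo <= hi)
  keep <- which(cube$wavelengths >= lo & cube$wavelengths <= hi)
  if (length(keep) == 0L)
    stop("no bands in [", lo, ", ", hi, "] nm; cube spans ",
         min(cube$wavelengths), "-", max(cube$wavelengths), " nm")
  hsi_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
           kind = cube$kind)
}
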