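#' Table of spectra
#'
#' The modeling currency of the pipeline: a matrix with one spectrum per
#' row, plus the wavelength grid, an optional variety label per spectrum,
#' the seed instance each spectrum belongs to, and whether rows are
#' individual pixels (`level = "pixel"`) or per-seed average spectra
#' (`level = "object"`).
#'
#' @param spectra numeric matrix, n_spectra x n_bands.
#' @param wavelengths numeric vector of band centers (nm).
#' @param seed_ids vector identifying the seed instance of each row.
#' @param labels optional factor (or vector coercible to factor) of variety
#'   labels, one per row; `NULL` for unlabeled data.
#' @param level `"pixel"` or `"object"`. Object-level tables must have one
#'   row per seed.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(spectra, wavelengths, seed_ids, labels = NULL,
                          level = c("pixel", "object")) {
  level <- match.arg(level)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(spectra) != length(wavelengths))
    stop("ncol(spectra) does not match length(wavelengths)")
  if (length(seed_ids) != nrow(spectra))
    stop("length(seed_ids) does not match nrow(spectra)")
  if (!is.null(labels)) {
    if (length(labels) != nrow(spectra))
      stop("length(labels) does not match nrow(spectra)")
    labels <- as.factor(labels)
  }
  if (level == "object" && anyDuplicated(seed_ids))
    stop("object-level tables must have exactly one row per seed_id")
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 seed_ids = seed_ids, labels = labels, level = level),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d %s-level spectra, %d bands (%.1f-%.1f nm)\n",
              nrow(x$spectra), x$level, ncol(x$spectra),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  seeds:", length(unique(x$seed_ids)), "\n")
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$spectra)

#' Subset a spectra table by row
#'
#' @param table a [spectra_table].
#' @param i row indices (integer or logical).
#' @return A [spectra_table] with the selected rows.
#' @export
subset_rows <- function(table, i) {
  stopifnot(inherits(table, "spectra_table"))
  spectra_table(table$spectra[i, , drop = FALSE], table$wavelengths,
                table$seed_ids[i],
                labels = if (is.null(table$labels)) NULL else table$labels[i],
                level = table$level)
}

#' @export
as.data.frame.spectra_table <- function(x, ...) {
  df <- data.frame(seed_id = x$seed_ids,
                   label = if (is.null(x$labels)) NA else as.character(x$labels),
                   level = x$level, stringsAsFactors = FALSE)
  sp <- as.data.frame(x$spectra)
  names(sp) <- sprintf("nm_%.10g", x$wavelengths)
  cbind(df, sp)
}

#' Write a spectra table as wide CSV
#'
#' Columns: `seed_id`, `label`, `level`, then one column per band named
#' `nm_<wavelength>`.
#'
#' @param table a [spectra_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectra table written by [write_spectra()]
#'
#' @param path CSV path.
#' @return A [spectra_table].
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  bandcols <- grepl("^nm_", names(df))
  wl <- as.numeric(sub("^nm_", "", names(df)[bandcols]))
  labels <- if (all(is.na(df$label))) NULL else factor(df$label)
  spectra_table(as.matrix(df[, bandcols, drop = FALSE]), wl, df$seed_id,
                labels = labels, level = df$level[1])
}
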