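#' Read a hyperspectral cube from disk
#'
#' Reads an ENVI-style image: a plain-text `.hdr` header next to a flat
#' binary cube. `path` may point at either file of the pair. Supported
#' interleaves are BIL, BSQ and BIP; data types 4 (float32) and 5 (float64).
#' Wavelengths are parsed from the header's `wavelength` block.
#'
#' @param path path to the header or the binary file.
#' @param format on-disk dialect; only `"envi"` is implemented.
#' @return An [hsi_cube]; `kind` is `"reflectance"` if the header carries
#'   `reflectance = 1` (written by [write_cube()]), otherwise `"raw"`.
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = "envi") {
  format <- match.arg(format, "envi")
  paths <- .envi_pair(path)
  hdr <- .parse_envi_header(paths$hdr)
  for (f in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[f]])) stop("ENVI header missing required field '", f, "'")
  S <- as.integer(hdr[["samples"]]); L <- as.integer(hdr[["lines"]])
  B <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type ", dtype,
                      " (only 4 = float32, 5 = float64)"))
  n <- S * L * B
  actual <- file.info(paths$bin)$size
  if (is.na(actual) || actual != n * size)
    stop("field 'bands'/'samples'/'lines' inconsistent with file size: header ",
         "implies ", n * size, " bytes, file has ", actual)
  con <- file(paths$bin, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  il <- tolower(hdr[["interleave"]])
  arr <- switch(il,
    bil = aperm(array(v, c(S, B, L)), c(3, 1, 2)),
    bsq = aperm(array(v, c(S, L, B)), c(2, 1, 3)),
    bip = aperm(array(v, c(B, S, L)), c(3, 2, 1)),
    stop("unsupported interleave '", hdr[["interleave"]], "'"))
  wl <- hdr[["wavelength"]]   # exact match: "wavelength units" also exists
  if (is.null(wl)) stop("ENVI header missing required field 'wavelength'")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", wl), ",")[[1]])
  if (length(wl) != B)
    stop("field 'wavelength' has ", length(wl), " entries, expected ", B)
  kind <- if (identical(trimws(hdr[["reflectance"]]), "1")) "reflectance" else "raw"
  hsi_cube(arr, wl, kind = kind)
}

#' Write a hyperspectral cube to disk
#'
#' Writes an ENVI header/binary pair. Data are stored as little-endian
#' float64 (ENVI data type 5) by default so that a read/write round trip is
#' bit-exact; the interleave is recorded in the header.
#'
#' @param cube an [hsi_cube].
#' @param path path of the binary file; the header is written as
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bil"`, `"bsq"` or `"bip"`.
#' @param data_type 5 (float64, default) or 4 (float32).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  data_type <- as.integer(data_type)
  size <- switch(as.character(data_type), "4" = 4L, "5" = 8L,
                 stop("data_type must be 4 or 5"))
  d <- dim(cube$data)
  v <- switch(interleave,
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("reflectance = ", if (cube$kind == "reflectance") 1 else 0),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, digits = 17, trim = TRUE),
                 collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = size, endian = "little")
  invisible(path)
}

# Resolve a user path to the (hdr, bin) pair.
.envi_pair <- function(path) {
  if (grepl("\\.hdr$", path)) {
    bin <- sub("\\.hdr$", "", path)
    return(list(hdr = path, bin = bin))
  }
  hdr <- paste0(path, ".hdr")
  if (!file.exists(hdr)) stop("header file not found: ", hdr)
  if (!file.exists(path)) stop("binary file not found: ", path)
  list(hdr = hdr, bin = path)
}

# Parse "key = value" pairs; multi-line { ... } blocks are joined first.
.parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # join multi-line { ... } blocks onto one line
  joined <- character()
  buf <- ""
  inblock <- FALSE
  for (ln in lines) {
    if (!inblock) {
      buf <- ln
      if (grepl("\\{", ln) && !grepl("\\}", ln)) inblock <- TRUE
      else joined <- c(joined, buf)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { inblock <- TRUE; joined <- c(joined, buf); inblock <- FALSE }
    }
  }
  kv <- joined[grepl("=", joined)]
  keys <- trimws(sub("=.*", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  out <- as.list(vals)
  names(out) <- tolower(keys)
  out
}
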