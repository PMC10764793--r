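#' Construct a hyperspectral cube
#'
#' A spectral cube is a rows x cols x bands array of non-negative
#' intensities together with the ascending per-band wavelengths in
#' nanometres and free-form header metadata. Row 0 of the on-disk image
#' is row 1 here (top of the image); indices are 1-based as usual in R.
#'
#' @param data numeric array `[rows, cols, bands]`, finite, >= 0.
#' @param wavelengths_nm strictly increasing numeric vector, one entry
#'   per band.
#' @param meta named list of free-form header fields.
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths_nm, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [rows, cols, bands]")
  d <- dim(data)
  if (d[1] < 8L || d[2] < 8L)
    stop("cube must be at least 8 x 8 pixels")
  if (!all(is.finite(data)))
    stop("cube intensities must all be finite")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != d[3])
    stop("length(wavelengths_nm) must equal the number of bands")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(
    list(data = data, wavelengths_nm = wavelengths_nm, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

# ENVI data-type codes handled by this reader/writer.
.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  # join { ... } blocks that span lines, then split into key = value
  fields <- list()
  pat <- "(?mi)^\\s*([a-z][a-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("no key = value fields found in ENVI header")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*$", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

.envi_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop(sprintf("ENVI header is missing '%s'", key))
  as.numeric(v)
}

#' Read an ENVI-dialect hyperspectral cube
#'
#' Reads a flat binary data file with a text header declaring
#' `samples`, `lines`, `bands`, `data type`, `interleave`
#' (bil/bip/bsq) and a `wavelength = { ... }` list. Header keys are
#' parsed case-insensitively. The returned cube is always in
#' row/col/band order regardless of the on-disk interleave.
#'
#' @param data_path path to the binary data file.
#' @param header_path path to the text header; by default the two
#'   common conventions are tried: `<data_path>.hdr`, then the data
#'   path with its extension replaced by `.hdr`.
#' @return a [spectral_cube()].
#' @export
read_envi_cube <- function(data_path, header_path = NULL) {
  if (is.null(header_path)) {
    cands <- unique(c(paste0(data_path, ".hdr"),
                      sub("\\.[^.]*$", ".hdr", data_path)))
    header_path <- cands[file.exists(cands)][1]
    if (is.na(header_path))
      stop(sprintf("no ENVI header found next to '%s'", data_path))
  }
  fields <- .parse_envi_header(header_path)
  samples <- as.integer(.envi_num(fields, "samples"))
  lines   <- as.integer(.envi_num(fields, "lines"))
  bands   <- as.integer(.envi_num(fields, "bands"))
  dtype   <- as.character(as.integer(.envi_num(fields, "data type")))
  interleave <- tolower(trimws(fields[["interleave"]] %||% "bsq"))
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop(sprintf("unsupported interleave '%s'", interleave))
  spec <- .envi_types[[dtype]]
  if (is.null(spec))
    stop(sprintf("unsupported ENVI data type %s", dtype))
  wl_raw <- fields[["wavelength"]]
  if (is.null(wl_raw))
    stop("ENVI header has no wavelength list")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != bands)
    stop("wavelength list length does not match band count")
  byte_order <- as.integer(fields[["byte order"]] %||% "0")
  endian <- if (byte_order == 0L) "little" else "big"

  n <- samples * lines * bands
  expected_size <- as.numeric(n) * spec$size
  actual_size <- file.info(data_path)$size
  if (is.na(actual_size) || actual_size < expected_size)
    stop(sprintf(
      "data file holds %s bytes but header implies %s (samples*lines*bands)",
      format(actual_size), format(expected_size)))
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = endian)
  # fastest-varying axis first for each interleave, then permute to
  # [lines(rows), samples(cols), bands]
  arr <- switch(interleave,
    bsq = aperm(array(raw, dim = c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw, dim = c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw, dim = c(bands, samples, lines)), c(3, 2, 1))
  )
  meta <- fields[setdiff(names(fields),
                         c("samples", "lines", "bands", "data type",
                           "interleave", "wavelength", "byte order"))]
  spectral_cube(arr * 1.0, wl, meta)
}

#' Write an ENVI-dialect hyperspectral cube
#'
#' @param cube a [spectral_cube()].
#' @param data_path output path for the binary data file.
#' @param header_path output path for the text header; defaults to
#'   `<data_path>.hdr`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data-type code: 4 (float32, default), 5
#'   (float64), 1 (uint8) or 12 (uint16). Note that float32 truncates
#'   doubles; use 5 for lossless round trips.
#' @return invisibly, `c(data = data_path, header = header_path)`.
#' @export
write_envi_cube <- function(cube, data_path,
                            header_path = paste0(data_path, ".hdr"),
                            interleave = c("bsq", "bil", "bip"),
                            data_type = 5) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  spec <- .envi_types[[as.character(as.integer(data_type))]]
  if (is.null(spec)) stop("unsupported ENVI data type for writing")
  d <- dim(cube$data)
  perm <- switch(interleave,
    bsq = c(2, 1, 3),  # samples fastest, then lines, then bands
    bil = c(2, 3, 1),  # samples, bands, lines
    bip = c(3, 2, 1)   # bands, samples, lines
  )
  flat <- as.vector(aperm(cube$data, perm))
  if (spec$what == "integer") flat <- as.integer(round(flat))
  con <- file(data_path, "wb")
  writeBin(flat, con, size = spec$size, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = { mwiphase spectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths_nm, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, header_path)
  invisible(c(data = data_path, header = header_path))
}

#' Select the band nearest a target wavelength
#'
#' Returns the band image whose wavelength is closest to `target_nm`;
#' exact distance ties are broken toward the lower wavelength. The
#' target must lie within the cube's spectral range extended by half the
#' median band spacing.
#'
#' @param cube a [spectral_cube()].
#' @param target_nm requested wavelength in nanometres.
#' @return list with `image` (rows x cols matrix), `actual_nm` (the
#'   wavelength chosen) and `band` (its index).
#' @export
select_band <- function(cube, target_nm) {
  stopifnot(inherits(cube, "spectral_cube"))
  wl <- cube$wavelengths_nm
  half_step <- if (length(wl) > 1L) stats::median(diff(wl)) / 2 else 0
  if (target_nm < min(wl) - half_step || target_nm > max(wl) + half_step)
    stop(sprintf("target %.1f nm outside spectral range [%.1f, %.1f] nm",
                 target_nm, min(wl), max(wl)))
  dist <- abs(wl - target_nm)
  idx <- order(dist, wl)[1L]   # tie -> lower wavelength
  list(image = cube$data[, , idx], actual_nm = wl[idx], band = idx)
}

#' Read a binary label mask from an 8-bit PNG
#'
#' Grayscale values above 127/255 map to label 1 (tumor); everything
#' else to 0. Multi-channel images use the first channel.
#'
#' @param path PNG file path.
#' @return integer matrix of 0/1 labels.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img > 127 / 255) * 1L
}

#' Write a binary label mask as an 8-bit PNG (255 = tumor)
#'
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
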