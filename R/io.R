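#' Read and write reflectance cubes
#'
#' Three on-disk representations are supported:
#' \describe{
#'   \item{`csv`}{Long format with header `pixel_row,pixel_col,wavelength_nm,
#'     reflectance` — lossless and human-inspectable.}
#'   \item{`envi`}{ENVI-style pair: a flat BSQ float32 binary at `path` plus a
#'     text header at `path.hdr` carrying `wavelength` and
#'     `wavelength units = nm`. Pixels absent from the cube are stored as NaN
#'     and come back masked.}
#'   \item{`geotiff`}{Multi-page 32-bit float TIFF, one page per spectral
#'     band, band-center wavelength stored in each page's ImageDescription
#'     tag. Written by a minimal uncompressed writer so that negative
#'     reflectance and the wavelength tags survive the round trip; read back
#'     with the `tiff` package. No georeferencing tags are written.}
#' }
#'
#' `format = "auto"` picks by extension: `.csv`, `.tif`/`.tiff`, ENVI
#' otherwise.
#'
#' @param path File path. For ENVI this is the binary file; the header is
#'   `path.hdr`.
#' @param format One of `"auto"`, `"csv"`, `"envi"`, `"geotiff"`.
#' @param spectra A cube tibble (see [as_cube()]).
#' @return `read_cube()` returns a cube tibble; `write_cube()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cube <- leaf_reflectance(30, c(660, 670, 680))
#' cube <- as_cube(cbind(pixel_row = 0L, pixel_col = 0L, cube))
#' write_cube(cube, f)
#' identical(dim(read_cube(f)), dim(cube))
#' @export
read_cube <- function(path, format = c("auto", "csv", "envi", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path) && !(format == "envi" && file.exists(paste0(path, ".hdr")))) {
    abort(paste0("file not found: ", path), class = "rededge_io_error")
  }
  out <- switch(format,
    csv = read_cube_csv(path),
    envi = read_cube_envi(path),
    geotiff = read_cube_tiff(path)
  )
  as_cube(out, quiet = TRUE)
}

#' @rdname read_cube
#' @export
write_cube <- function(spectra, path,
                       format = c("auto", "csv", "envi", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  spectra <- as_cube(spectra, quiet = TRUE)
  ok <- switch(format,
    csv = write_cube_csv(spectra, path),
    envi = write_cube_envi(spectra, path),
    geotiff = write_cube_tiff(spectra, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "csv" else if (ext %in% c("tif", "tiff")) "geotiff" else "envi"
}

# ---- CSV ---------------------------------------------------------------

read_cube_csv <- function(path) {
  x <- utils::read.csv(path)
  required <- c("pixel_row", "pixel_col", "wavelength_nm", "reflectance")
  if (!all(required %in% names(x))) {
    abort(paste0(
      "CSV cube must have columns ", paste(required, collapse = ", ")
    ), class = "rededge_format_error")
  }
  tibble::as_tibble(x)
}

write_cube_csv <- function(spectra, path) {
  utils::write.csv(spectra, path, row.names = FALSE)
}

# ---- ENVI --------------------------------------------------------------

envi_header_path <- function(path) {
  if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
}

write_cube_envi <- function(spectra, path) {
  if (nrow(spectra) == 0) {
    cm <- list(axis = numeric(0),
               values = matrix(numeric(0), 0, 0),
               pixels = tibble::tibble(pixel_row = integer(0),
                                       pixel_col = integer(0)))
    lines <- 0L
    samples <- 0L
  } else {
    cm <- cube_matrix(spectra)
    lines <- max(cm$pixels$pixel_row) + 1L
    samples <- max(cm$pixels$pixel_col) + 1L
  }
  nb <- length(cm$axis)
  hdr <- c(
    "ENVI",
    paste0("samples = ", samples),
    paste0("lines = ", lines),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    paste0("wavelength = {", paste(format(cm$axis, trim = TRUE), collapse = ", "), "}")
  )
  writeLines(hdr, envi_header_path(path))
  # dense grid, band-sequential; absent / masked pixels as NaN
  grid <- array(NaN, dim = c(samples, lines, max(nb, 0)))
  if (nrow(cm$pixels) > 0 && nb > 0) {
    idx <- cbind(cm$pixels$pixel_col + 1L, cm$pixels$pixel_row + 1L)
    for (b in seq_len(nb)) {
      v <- cm$values[, b]
      v[is.na(v)] <- NaN
      grid[cbind(idx, b)] <- v
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid), con, size = 4, endian = "little")
  TRUE
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", key, "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))
    if (length(m) == 0) return(NA_character_)
    trimws(sub(paste0("(?i)^", key, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?msi)^", key, "\\s*=\\s*\\{[^}]*\\}"),
                                 txt, perl = TRUE))
    if (length(m) == 0) return(NULL)
    body <- sub("^[^{]*\\{", "", m)
    body <- trimws(sub("\\}\\s*$", "", body))
    if (body == "") return(numeric(0))
    as.numeric(trimws(strsplit(body, ",")[[1]]))
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    wavelength = get_list("wavelength")
  )
}

read_cube_envi <- function(path) {
  if (grepl("\\.hdr$", path)) path <- sub("\\.hdr$", "", path)
  hdr_path <- envi_header_path(path)
  if (!file.exists(hdr_path)) {
    abort(paste0("ENVI header not found: ", hdr_path),
          class = "rededge_metadata_error")
  }
  h <- parse_envi_header(hdr_path)
  if (h$bands > 0 && is.null(h$wavelength)) {
    abort("ENVI header lacks a 'wavelength' field",
          class = "rededge_metadata_error")
  }
  if (h$bands > 0 && length(h$wavelength) != h$bands) {
    abort("ENVI wavelength list length does not match band count",
          class = "rededge_format_error")
  }
  if (h$bands > 0) check_axis(h$wavelength)
  if (!identical(h$data_type, 4L)) {
    abort("only ENVI data type 4 (float32) is supported",
          class = "rededge_format_error")
  }
  if (!identical(h$interleave, "bsq")) {
    abort("only BSQ interleave is supported", class = "rededge_format_error")
  }
  n_val <- h$samples * h$lines * h$bands
  raw_vals <- readBin(path, what = "numeric", n = n_val, size = 4,
                      endian = "little")
  if (length(raw_vals) != n_val) {
    abort("ENVI binary shorter than header promises",
          class = "rededge_format_error")
  }
  if (n_val == 0) {
    return(tibble::tibble(pixel_row = integer(0), pixel_col = integer(0),
                          wavelength_nm = numeric(0), reflectance = numeric(0)))
  }
  grid <- array(raw_vals, dim = c(h$samples, h$lines, h$bands))
  pixels <- tibble::tibble(
    pixel_row = rep(seq_len(h$lines) - 1L, each = h$samples),
    pixel_col = rep(seq_len(h$samples) - 1L, times = h$lines)
  )
  values <- matrix(NA_real_, nrow = nrow(pixels), ncol = h$bands)
  for (b in seq_len(h$bands)) {
    values[, b] <- as.vector(grid[, , b]) # sample-major within each line
  }
  pixels <- dplyr::arrange(pixels, .data$pixel_row, .data$pixel_col)
  cube_from_matrix(h$wavelength, values, pixels)
}
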