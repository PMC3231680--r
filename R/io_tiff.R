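# Multi-page float32 TIFF with per-page wavelength metadata.
#
# The installed `tiff` writer clamps values to [0, 1] and cannot set the
# ImageDescription tag, so writing is done by a minimal uncompressed
# baseline-TIFF emitter (little-endian, SampleFormat = IEEE float, one page
# per band). Reading goes through tiff::readTIFF(), which handles this
# layout fine.

write_cube_tiff <- function(spectra, path) {
  if (nrow(spectra) == 0) {
    abort("cannot write an empty cube as TIFF; use csv or envi",
          class = "rededge_io_error")
  }
  cm <- cube_matrix(spectra)
  lines <- max(cm$pixels$pixel_row) + 1L
  samples <- max(cm$pixels$pixel_col) + 1L
  idx <- cbind(cm$pixels$pixel_row + 1L, cm$pixels$pixel_col + 1L)
  pages <- lapply(seq_along(cm$axis), function(b) {
    m <- matrix(NaN, nrow = lines, ncol = samples)
    v <- cm$values[, b]
    v[is.na(v)] <- NaN
    m[idx] <- v
    m
  })
  descs <- sprintf('{"wavelength_nm":%s}', format(cm$axis, trim = TRUE))
  write_tiff_f32(pages, descs, path)
}

read_cube_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  wl <- vapply(pages, function(p) {
    d <- attr(p, "description")
    if (is.null(d)) return(NA_real_)
    parsed <- tryCatch(jsonlite::fromJSON(d), error = function(e) NULL)
    if (is.null(parsed$wavelength_nm)) NA_real_ else as.numeric(parsed$wavelength_nm)
  }, numeric(1))
  if (anyNA(wl)) {
    abort("TIFF pages lack wavelength_nm metadata in ImageDescription",
          class = "rededge_metadata_error")
  }
  check_axis(wl)
  lines <- nrow(pages[[1]])
  samples <- ncol(pages[[1]])
  pixels <- tibble::tibble(
    pixel_row = rep(seq_len(lines) - 1L, each = samples),
    pixel_col = rep(seq_len(samples) - 1L, times = lines)
  )
  values <- vapply(pages, function(p) as.vector(t(p)), numeric(lines * samples))
  cube_from_matrix(wl, values, pixels)
}

# Minimal multi-page TIFF writer: uncompressed, grayscale, 32-bit IEEE float,
# one strip per page, ImageDescription per page.
write_tiff_f32 <- function(mats, descs, path) {
  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort(paste0("cannot open for writing: ", path), class = "rededge_io_error")
  })
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  writeChar("II", con, 2, eos = NULL)
  w(42, 2)
  w(8, 4) # offset of first IFD, fixed below
  n <- length(mats)
  n_tags <- 11
  ifd_size <- 2 + n_tags * 12 + 4
  offset <- 8
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    d <- c(charToRaw(descs[[i]]), as.raw(0))
    ifd_off <- offset
    desc_off <- ifd_off + ifd_size
    data_off <- desc_off + length(d)
    meta[[i]] <- list(ifd_off = ifd_off, desc_off = desc_off,
                      data_off = data_off, desc = d)
    offset <- data_off + length(mats[[i]]) * 4
  }
  seek(con, 4)
  w(meta[[1]]$ifd_off, 4)
  entry <- function(tag, type, count, value) {
    w(tag, 2); w(type, 2); w(count, 4); w(value, 4)
  }
  for (i in seq_len(n)) {
    m <- mats[[i]]
    mt <- meta[[i]]
    seek(con, mt$ifd_off)
    w(n_tags, 2)
    entry(256, 4, 1, ncol(m))              # ImageWidth
    entry(257, 4, 1, nrow(m))              # ImageLength
    entry(258, 3, 1, 32)                   # BitsPerSample
    entry(259, 3, 1, 1)                    # no compression
    entry(262, 3, 1, 1)                    # BlackIsZero
    entry(270, 2, length(mt$desc), mt$desc_off) # ImageDescription
    entry(273, 4, 1, mt$data_off)          # StripOffsets
    entry(277, 3, 1, 1)                    # SamplesPerPixel
    entry(278, 4, 1, nrow(m))              # RowsPerStrip
    entry(279, 4, 1, length(m) * 4)        # StripByteCounts
    entry(339, 3, 1, 3)                    # SampleFormat: IEEE float
    w(if (i < n) meta[[i + 1]]$ifd_off else 0, 4)
    seek(con, mt$desc_off)
    writeBin(mt$desc, con)
    seek(con, mt$data_off)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  invisible(path)
}
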