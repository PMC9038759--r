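# Minimal 32-bit IEEE-float TIFF writer (little-endian, uncompressed,
# one strip per page, optionally multi-page). Needed because the tiff
# package reads float TIFFs but only writes integer sample formats;
# files written here are read back with tiff::readTIFF().

write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                endian = "little")
  entry <- function(tag, type, count, value) {
    w_u16(tag); w_u16(type); w_u32(count)
    if (type == 3) { w_u16(value); w_u16(0) } else w_u32(value)
  }
  # header: byte order "II", magic 42, offset of the first IFD
  writeBin(charToRaw("II"), con)
  w_u16(42L)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  data_off <- integer(length(pages))
  ifd_off <- integer(length(pages))
  for (i in seq_along(pages)) {
    data_off[i] <- offset
    nbytes <- 4L * length(pages[[i]])
    ifd_off[i] <- offset + nbytes
    offset <- ifd_off[i] + ifd_size
  }
  w_u32(ifd_off[1])
  for (i in seq_along(pages)) {
    img <- pages[[i]]
    h <- nrow(img); w <- ncol(img)
    writeBin(as.vector(t(img)), con, size = 4, endian = "little")
    w_u16(n_entries)
    entry(256L, 4L, 1L, w)                 # ImageWidth
    entry(257L, 4L, 1L, h)                 # ImageLength
    entry(258L, 3L, 1L, 32L)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: black is zero
    entry(273L, 4L, 1L, data_off[i])       # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, h)                 # RowsPerStrip
    entry(279L, 4L, 1L, 4L * h * w)        # StripByteCounts
    entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
    w_u32(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}
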