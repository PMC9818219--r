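# Minimal baseline TIFF I/O (uncompressed, 8-bit, little-endian, strip-based).
#
# The environment provides no R binding for TIFF, so the package carries the
# smallest reader/writer that round-trips its own synthetic slides and reads
# plain uncompressed grayscale/RGB TIFFs produced elsewhere. Deliberately out
# of scope (as for the pipeline itself): JPEG/JPEG2000 codecs, tiled TIFF,
# big-endian files, bit depths other than 8.

u16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16le(tag), u16le(type), u32le(count), value_raw4)
}

#' Write an 8-bit image array as an uncompressed baseline TIFF
#'
#' @param img numeric matrix (grayscale) or H x W x 3 array (RGB), values 0-255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  rgb <- length(dim(img)) == 3L
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- if (rgb) {
    as.raw(as.integer(round(clamp(aperm(img, c(3, 2, 1)), 0, 255))))
  } else {
    as.raw(as.integer(round(clamp(t(img), 0, 255))))
  }
  n_entries <- 10L
  ifd_off <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L
  bits_off <- ifd_off + ifd_size          # external BitsPerSample for RGB
  data_off <- bits_off + if (rgb) 6L else 0L
  spp <- if (rgb) 3L else 1L
  short_val <- function(v) c(u16le(v), u16le(0L))
  entries <- c(
    tiff_entry(256L, 4L, 1L, u32le(w)),
    tiff_entry(257L, 4L, 1L, u32le(h)),
    if (rgb) tiff_entry(258L, 3L, 3L, u32le(bits_off))
    else     tiff_entry(258L, 3L, 1L, short_val(8L)),
    tiff_entry(259L, 3L, 1L, short_val(1L)),
    tiff_entry(262L, 3L, 1L, short_val(if (rgb) 2L else 1L)),
    tiff_entry(273L, 4L, 1L, u32le(data_off)),
    tiff_entry(277L, 3L, 1L, short_val(spp)),
    tiff_entry(278L, 4L, 1L, u32le(h)),
    tiff_entry(279L, 4L, 1L, u32le(length(px))),
    tiff_entry(284L, 3L, 1L, short_val(1L))
  )
  out <- c(
    as.raw(c(0x49, 0x49)), u16le(42L), u32le(ifd_off),
    u16le(n_entries), entries, u32le(0L),
    if (rgb) c(u16le(8L), u16le(8L), u16le(8L)),
    px
  )
  writeBin(out, path)
  invisible(path)
}

#' Read an uncompressed baseline TIFF
#'
#' Returns a numeric matrix (grayscale) or an H x W x 3 array (RGB) with
#' values in 0-255. Only little-endian, 8-bit, uncompressed, chunky TIFFs are
#' supported; pyramidal files are read at their first directory (level 0).
#'
#' @param path file path.
#' @return pixel matrix or array.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("cannot read slide image: '%s' does not exist", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  rd16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  rd32 <- function(off) as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
    65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
  if (!(raw[1] == 0x49 && raw[2] == 0x49)) {
    stopf("unsupported TIFF byte order (only little-endian 'II' is handled)")
  }
  if (rd16(2L) != 42L) stopf("'%s' is not a TIFF file", path)
  ifd <- rd32(4L)
  n <- rd16(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2L + 12L * (i - 1L)
    tag <- rd16(e); type <- rd16(e + 2L); count <- rd32(e + 4L)
    size <- c(1L, 1L, 2L, 4L)[type]  # BYTE/ASCII/SHORT/LONG
    if (is.na(size)) next
    total <- size * count
    voff <- if (total <= 4) e + 8L else rd32(e + 8L)
    vals <- if (size == 2L) {
      vapply(seq_len(count), function(j) rd16(voff + 2L * (j - 1L)), numeric(1))
    } else if (size == 4L) {
      vapply(seq_len(count), function(j) rd32(voff + 4L * (j - 1L)), numeric(1))
    } else {
      as.numeric(raw[voff + seq_len(count)])
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stopf("TIFF missing required tag %d", tag)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  if (need(259L, 1) != 1) stopf("compressed TIFF not supported (compression=%d)", need(259L))
  spp <- need(277L, 1)
  bits <- need(258L, 8)
  if (any(bits != 8)) stopf("only 8-bit TIFF supported")
  offs <- need(273L); counts <- need(279L, w * h * spp)
  px <- raw(0)
  px <- unlist(lapply(seq_along(offs), function(i) raw[offs[i] + seq_len(counts[i])]))
  vals <- as.integer(px)
  if (spp == 3) {
    a <- array(vals, dim = c(3L, w, h))   # interleaved RGB, row-major
    aperm(a, c(3, 2, 1))
  } else {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }
}
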