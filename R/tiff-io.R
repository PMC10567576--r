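# Minimal baseline TIFF codec.
#
# No TIFF reader/writer package is available in the supported R stack, so the
# package carries its own deliberately small implementation: little-endian,
# uncompressed, single-sample (grayscale) planes, 8/16-bit unsigned integer
# or 32-bit float, multi-page, with an optional ImageDescription string on
# the first page (used by the workbench to carry OME-style channel-role and
# pixel-size metadata as JSON). This covers everything the pipeline writes
# and the formats the synthetic generator produces; it is not a general TIFF
# library.

.le <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")

.tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4L)
  pad <- raw(4L - length(value_raw))
  c(.le(tag, 2L), .le(type, 2L), .le(count, 4L), value_raw, pad)
}

#' Write a multi-page TIFF
#'
#' @param planes a single numeric matrix or a list of matrices (pages), all
#'   of the same dimensions.
#' @param path output file path.
#' @param bits 8, 16 (unsigned integer, values clamped and rounded) or 32
#'   (IEEE float).
#' @param description optional character scalar stored as the first page's
#'   ImageDescription.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(planes, path, bits = 32L, description = NULL) {
  if (is.matrix(planes)) planes <- list(planes)
  stopifnot(length(planes) >= 1L, bits %in% c(8L, 16L, 32L))
  dm <- dim(planes[[1]])
  for (p in planes) stopifnot(identical(dim(p), dm))
  h <- dm[1]; w <- dm[2]
  bytes_pp <- bits / 8L
  sample_format <- if (bits == 32L) 3L else 1L

  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0L)) else raw(0)
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, raw(1))

  n <- length(planes)
  plane_bytes <- h * w * bytes_pp
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  data_offsets <- data_off + (seq_len(n) - 1L) * plane_bytes
  ifd_off0 <- data_off + n * plane_bytes
  n_entries <- function(i) if (i == 1L && length(desc_raw)) 11L else 10L
  ifd_sizes <- vapply(seq_len(n), function(i) 2L + 12L * n_entries(i) + 4L, integer(1))
  ifd_offsets <- ifd_off0 + c(0L, cumsum(ifd_sizes))[seq_len(n)]

  encode_plane <- function(m) {
    v <- as.vector(t(m))  # row-major
    if (bits == 32L) writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
    else {
      v <- as.integer(pmin(pmax(round(v), 0), 2^bits - 1))
      if (bits == 8L) as.raw(v) else writeBin(v, raw(), size = 2L, endian = "little")
    }
  }

  make_ifd <- function(i) {
    e <- list(
      .tiff_entry(256L, 4L, 1L, .le(w, 4L)),            # ImageWidth
      .tiff_entry(257L, 4L, 1L, .le(h, 4L)),            # ImageLength
      .tiff_entry(258L, 3L, 1L, .le(bits, 2L)),         # BitsPerSample
      .tiff_entry(259L, 3L, 1L, .le(1L, 2L)),           # Compression = none
      .tiff_entry(262L, 3L, 1L, .le(1L, 2L))            # Photometric = BlackIsZero
    )
    if (i == 1L && length(desc_raw))
      e <- c(e, list(.tiff_entry(270L, 2L, length(desc_raw), .le(desc_off, 4L))))
    e <- c(e, list(
      .tiff_entry(273L, 4L, 1L, .le(data_offsets[i], 4L)),  # StripOffsets
      .tiff_entry(277L, 3L, 1L, .le(1L, 2L)),               # SamplesPerPixel
      .tiff_entry(278L, 4L, 1L, .le(h, 4L)),                # RowsPerStrip
      .tiff_entry(279L, 4L, 1L, .le(plane_bytes, 4L))       # StripByteCounts
    ))
    e <- c(e, list(.tiff_entry(339L, 3L, 1L, .le(sample_format, 2L))))
    e <- e[order(vapply(e, function(x) {
      sum(as.integer(x[1:2]) * c(1L, 256L))
    }, integer(1)))]  # entries must be tag-sorted
    nxt <- if (i < n) ifd_offsets[i + 1L] else 0L
    c(.le(length(e), 2L), do.call(c, e), .le(nxt, 4L))
  }

  out <- c(as.raw(c(0x49, 0x49, 0x2A, 0x00)), .le(ifd_offsets[1], 4L),
           desc_raw,
           do.call(c, lapply(planes, encode_plane)),
           do.call(c, lapply(seq_len(n), make_ifd)))
  writeBin(out, path)
  invisible(path)
}

.rd_int <- function(raw, off, size, signed = FALSE) {
  readBin(raw[(off + 1L):(off + size)], "integer", n = 1L, size = size,
          signed = signed || size == 4L, endian = "little")
}

#' Read a multi-page TIFF
#'
#' Supports the subset written by [write_tiff()] plus multi-strip files:
#' little- or big-endian, uncompressed, single-sample, 8/16/32-bit unsigned
#' integer or 32-bit float.
#'
#' @param path file path.
#' @return list with `planes` (list of numeric matrices) and `description`
#'   (character or `NULL`).
#' @export
read_tiff <- function(path) {
  rw <- readBin(path, "raw", file.info(path)$size)
  if (as.integer(rw[1]) == 0x4D) {  # big-endian: byte-swap by re-reading
    endian <- "big"
  } else endian <- "little"
  rd <- function(off, size, signed = FALSE)
    readBin(rw[(off + 1L):(off + size)], "integer", n = 1L, size = size,
            signed = signed || size == 4L, endian = endian)
  stopifnot(rd(2L, 2L) == 42L)
  ifd_off <- rd(4L, 4L)
  planes <- list(); description <- NULL
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  seen <- integer(0)
  while (ifd_off != 0L) {
    if (ifd_off %in% seen) stop("read_tiff: cyclic IFD chain")
    seen <- c(seen, ifd_off)
    nent <- rd(ifd_off, 2L)
    tags <- list()
    for (k in seq_len(nent)) {
      eo <- ifd_off + 2L + (k - 1L) * 12L
      tag <- rd(eo, 2L); type <- rd(eo + 2L, 2L); count <- rd(eo + 4L, 4L)
      ts <- type_size[[as.character(type)]]
      if (is.null(ts)) next
      total <- ts * count
      voff <- if (total <= 4L) eo + 8L else rd(eo + 8L, 4L)
      vals <- if (type == 2L) {
        rawToChar(rw[(voff + 1L):(voff + count - 1L)])
      } else {
        vapply(seq_len(count), function(j) rd(voff + (j - 1L) * ts, ts), numeric(1))
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257); bits <- g(258, 1L)[1]
    comp <- g(259, 1L); sf <- g(339, 1L)[1]
    if (comp != 1L) stop("read_tiff: compressed TIFF not supported")
    offs <- g(273); counts <- g(279, h * w * bits / 8L)
    if (!is.null(g(270)) && is.null(description)) description <- g(270)
    buf <- do.call(c, lapply(seq_along(offs), function(j)
      rw[(offs[j] + 1L):(offs[j] + counts[j])]))
    npx <- h * w
    v <- if (sf == 3L) {
      readBin(buf, "double", n = npx, size = 4L, endian = endian)
    } else if (bits == 8L) {
      as.integer(readBin(buf, "raw", n = npx))
    } else if (bits == 16L) {
      readBin(buf, "integer", n = npx, size = 2L, signed = FALSE, endian = endian)
    } else {
      readBin(buf, "integer", n = npx, size = 4L, endian = endian)
    }
    planes[[length(planes) + 1L]] <- matrix(as.numeric(v), nrow = h, ncol = w,
                                            byrow = TRUE)
    ifd_off <- rd(ifd_off + 2L + nent * 12L, 4L)
  }
  list(planes = planes, description = description)
}
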