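#' OCT volume container
#'
#' An OCT volume is a 3-D stack of B-scans stored as an integer array indexed
#' `[m, n, i]` where `m` is the depth row (1..M), `n` the lateral column
#' (1..N) and `i` the B-scan index (1..I). Intensities are 8-bit, in
#' `[0, 255]`. Physical voxel spacings (axial and lateral in micrometres per
#' pixel, plus the inter-slice distance in micrometres) travel with the data
#' and are only applied when results are converted to physical units.
#'
#' @param data 3-D numeric/integer array of intensities in `[0, 255]`.
#' @param spacing_axial Axial (depth) pixel size, micrometres per pixel.
#' @param spacing_lateral Lateral pixel size, micrometres per pixel.
#' @param spacing_slice Distance between consecutive B-scans, micrometres.
#' @return An object of class `oct_volume` (an integer array with a
#'   `spacing` attribute).
#' @examples
#' v <- oct_volume(array(0L, c(8, 4, 2)))
#' dim(v)
#' @export
oct_volume <- function(data, spacing_axial = 5, spacing_lateral = 11.7,
                       spacing_slice = 47) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [depth row, column, B-scan]")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  storage.mode(data) <- "integer"
  rng <- range(data)
  if (is.na(rng[1]) || rng[1] < 0L || rng[2] > 255L)
    stop("intensities must be finite and within [0, 255]")
  sp <- c(axial = spacing_axial, lateral = spacing_lateral, slice = spacing_slice)
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("spacings must be positive")
  structure(data, spacing = sp, class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<oct_volume> %d x %d x %d (rows x columns x B-scans)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: axial %.3g um/px, lateral %.3g um/px, slice %.3g um\n",
              sp[["axial"]], sp[["lateral"]], sp[["slice"]]))
  cat(sprintf("  intensity range: [%d, %d]\n", min(x), max(x)))
  invisible(x)
}

spacing_of <- function(volume) attr(volume, "spacing")

#' @export
`[.oct_volume` <- function(x, ...) {
  out <- NextMethod()
  out
}

# ---- multi-page TIFF I/O (minimal baseline subset) ----
# Uncompressed 8-bit greyscale, little-endian, one page per B-scan, one strip
# per page. No pre-installed R package reads TIFF in this toolchain, so the
# (tiny) baseline subset is implemented directly.

.w16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
.w32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

.tiff_entry <- function(con, tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field
  .w16(con, tag); .w16(con, type); .w32(con, count)
  if (type == 3L) { .w16(con, value); .w16(con, 0L) } else .w32(con, value)
}

#' Write an OCT volume as a multi-page TIFF
#'
#' One uncompressed 8-bit greyscale page per B-scan (little-endian baseline
#' TIFF). Physical spacings are not stored in the file; keep them in a
#' pipeline configuration.
#'
#' @param volume An [oct_volume()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  d <- dim(volume)
  M <- d[1]; N <- d[2]; I <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  page_bytes <- M * N
  data_off <- 8L + (0:(I - 1L)) * page_bytes
  ifd_block <- 8L + I * page_bytes
  ifd_size <- 2L + 9L * 12L + 4L
  ifd_off <- ifd_block + (0:(I - 1L)) * ifd_size
  writeBin(charToRaw("II"), con)
  .w16(con, 42L)
  .w32(con, ifd_off[1])
  for (i in seq_len(I)) {
    # scanlines are image rows: transpose the column-major slice
    writeBin(as.raw(t(unclass(volume)[, , i])), con)
  }
  for (i in seq_len(I)) {
    .w16(con, 9L)
    .tiff_entry(con, 256L, 4L, 1L, N)          # ImageWidth
    .tiff_entry(con, 257L, 4L, 1L, M)          # ImageLength
    .tiff_entry(con, 258L, 3L, 1L, 8L)         # BitsPerSample
    .tiff_entry(con, 259L, 3L, 1L, 1L)         # Compression = none
    .tiff_entry(con, 262L, 3L, 1L, 1L)         # Photometric = BlackIsZero
    .tiff_entry(con, 273L, 4L, 1L, data_off[i])# StripOffsets
    .tiff_entry(con, 277L, 3L, 1L, 1L)         # SamplesPerPixel
    .tiff_entry(con, 278L, 4L, 1L, M)          # RowsPerStrip
    .tiff_entry(con, 279L, 4L, 1L, page_bytes) # StripByteCounts
    .w32(con, if (i < I) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

.r16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
.r32 <- function(raw, off) {
  # computed in double: 4-byte unsigned values can exceed .Machine$integer.max
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

#' Read a multi-page greyscale TIFF as an OCT volume
#'
#' Supports the baseline subset written by [write_volume_tiff()]:
#' little-endian, uncompressed, 8-bit, single sample per pixel (multiple
#' strips per page are allowed).
#'
#' @param path TIFF file path.
#' @inheritParams oct_volume
#' @return An [oct_volume()].
#' @export
read_volume_tiff <- function(path, spacing_axial = 5, spacing_lateral = 11.7,
                             spacing_slice = 47) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || .r16(raw, 2) != 42L)
    stop("not a little-endian TIFF file")
  ifd <- .r32(raw, 4)
  pages <- list()
  while (ifd != 0L) {
    nent <- .r16(raw, ifd)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- .r16(raw, off); type <- .r16(raw, off + 2); count <- .r32(raw, off + 4)
      if (count == 1L) {
        val <- if (type == 3L) .r16(raw, off + 8) else .r32(raw, off + 8)
      } else {
        voff <- .r32(raw, off + 8)
        val <- if (type == 3L)
          vapply(seq_len(count) - 1L, function(k) .r16(raw, voff + 2L * k), 0L)
        else
          vapply(seq_len(count) - 1L, function(k) .r32(raw, voff + 4L * k), 0)
      }
      tags[[as.character(tag)]] <- val
    }
    if (!isTRUE(all(tags[["259"]] == 1))) stop("only uncompressed TIFF is supported")
    if (!is.null(tags[["258"]]) && any(tags[["258"]] != 8L))
      stop("only 8-bit TIFF is supported")
    if (!is.null(tags[["277"]]) && any(tags[["277"]] != 1))
      stop("only single-sample (greyscale) TIFF is supported")
    N <- tags[["256"]]; M <- tags[["257"]]
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(k) raw[(offs[k] + 1L):(offs[k] + cnts[k])]))
    pages[[length(pages) + 1L]] <- t(matrix(as.integer(bytes), nrow = N, ncol = M))
    ifd <- .r32(raw, ifd + 2L + nent * 12L)
  }
  M <- nrow(pages[[1]]); N <- ncol(pages[[1]])
  arr <- array(0L, c(M, N, length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  oct_volume(arr, spacing_axial, spacing_lateral, spacing_slice)
}

# ---- small plain-text helpers ----

#' Write a numeric matrix as CSV (rows n, columns i)
#' @param m Matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              na.strings = "NA"))
}

#' Write a matrix as a plain-text PGM (P2) preview image
#'
#' Values are linearly rescaled to 0..255; `NA` cells render as 0. PGM is
#' used for previews because it needs no graphics device or external codec.
#'
#' @param m Numeric matrix.
#' @param path Output path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path) {
  v <- as.vector(m)
  rng <- range(v, na.rm = TRUE)
  scl <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  scl[is.na(scl)] <- 0
  px <- matrix(as.integer(round(255 * scl)), nrow(m), ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
  utils::write.table(px, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
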