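## Minimal baseline TIFF codec: 16-bit unsigned grayscale, multi-page,
## little-endian, uncompressed, one strip per page. No external imaging
## package ships with the target environment, and stacks are small, so
## the format is implemented directly against the TIFF 6.0 baseline.

tiff_tag <- function(con, id, type, count, value) {
  writeBin(as.integer(c(id, type)), con, size = 2, endian = "little")
  writeBin(as.integer(c(count, value)), con, size = 4, endian = "little")
}

#' Write a 16-bit grayscale image stack as a multi-page TIFF
#'
#' @param stack numeric array `height x width x frames` (a matrix is
#'   treated as one frame). Values are rounded and clipped to 0-65535;
#'   clipping raises a warning and is recorded in the `clipped`
#'   attribute of the return value.
#' @param path output file path.
#' @return invisibly, the number of frames written, with attribute
#'   `clipped`.
#' @export
write_tiff16 <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  h <- d[1]; w <- d[2]; nf <- d[3]
  vals <- round(stack)
  clipped <- any(vals < 0) || any(vals > 65535)
  if (clipped) {
    warning("pixel values clipped to the 16-bit range")
    vals <- pmin(pmax(vals, 0), 65535)
  }
  page_bytes <- w * h * 2
  ifd0 <- 8 + nf * page_bytes
  ifd_size <- 2 + 9 * 12 + 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  for (f in seq_len(nf))      # row-major pixel order
    writeBin(as.integer(t(vals[, , f])), con, size = 2,
             endian = "little")
  for (f in seq_len(nf)) {
    writeBin(9L, con, size = 2, endian = "little")
    tiff_tag(con, 256, 3, 1, w)                    # ImageWidth
    tiff_tag(con, 257, 3, 1, h)                    # ImageLength
    tiff_tag(con, 258, 3, 1, 16)                   # BitsPerSample
    tiff_tag(con, 259, 3, 1, 1)                    # Compression: none
    tiff_tag(con, 262, 3, 1, 1)                    # Photometric: min-is-black
    tiff_tag(con, 273, 4, 1, 8 + (f - 1) * page_bytes)  # StripOffsets
    tiff_tag(con, 278, 3, 1, h)                    # RowsPerStrip
    tiff_tag(con, 279, 4, 1, page_bytes)           # StripByteCounts
    tiff_tag(con, 339, 3, 1, 1)                    # SampleFormat: uint
    nxt <- if (f < nf) ifd0 + f * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(structure(nf, clipped = clipped))
}

read_u <- function(con, size, n = 1)
  readBin(con, "integer", n = n, size = size, signed = size > 2,
          endian = "little")

#' Read a 16-bit grayscale multi-page TIFF
#'
#' Supports the baseline subset written by [write_tiff16()]
#' (little-endian, uncompressed, 16-bit grayscale, single strip).
#'
#' @param path TIFF file path.
#' @return numeric array `height x width x frames`.
#' @export
read_tiff16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (magic != "II") stop("only little-endian TIFF supported")
  if (read_u(con, 2) != 42L) stop("not a TIFF file")
  ifd_offset <- read_u(con, 4)
  frames <- list()
  while (ifd_offset != 0L) {
    seek(con, ifd_offset)
    n_tags <- read_u(con, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      id <- read_u(con, 2); type <- read_u(con, 2)
      count <- read_u(con, 4); value <- read_u(con, 4)
      tags[[as.character(id)]] <- value
    }
    ifd_offset <- read_u(con, 4)
    w <- tags[["256"]]; h <- tags[["257"]]
    if (!identical(tags[["258"]], 16L))
      stop("only 16-bit samples supported")
    if (!identical(tags[["259"]], 1L))
      stop("compressed TIFF not supported")
    seek(con, tags[["273"]])
    px <- readBin(con, "integer", n = w * h, size = 2, signed = FALSE,
                  endian = "little")
    frames[[length(frames) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
  }
  d1 <- dim(frames[[1]])
  array(unlist(frames), c(d1[1], d1[2], length(frames)))
}
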