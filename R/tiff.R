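# Minimal baseline TIFF support (little-endian, uncompressed, grayscale,
# single sample per pixel, 8/16-bit unsigned or 32-bit float, multi-page).
# No TIFF library exists in this R stack, so the subset of the format the
# pipeline needs is read and written here directly.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

#' Write a multi-page grayscale TIFF
#'
#' Pixel size is stored in the X/Y resolution tags (pixels per centimetre)
#' and round-trips through [read_image_stack()].
#'
#' @param images a [gray_image()], [binary_mask()], numeric matrix, or a
#'   list of these; masks are written as 8-bit 0/255.
#' @param path output file.
#' @param bits 8, 16 (unsigned integer) or 32 (IEEE float). Masks always
#'   use 8. Intensity data defaults to float to preserve values losslessly.
#' @param pixel_size micrometres per pixel override; taken from the objects
#'   when `NULL`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, path, bits = 32, pixel_size = NULL) {
  if (!is.list(images) || inherits(images, c("gray_image", "binary_mask")))
    images <- list(images)
  if (!bits %in% c(8, 16, 32)) stop("unsupported bit depth")
  pages <- lapply(images, function(im) {
    px <- as_pixels(im)
    ps <- pixel_size
    if (is.null(ps))
      ps <- if (inherits(im, c("gray_image", "binary_mask"))) im$pixel_size else 1
    if (is.logical(px)) {
      list(data = px * 255, bits = 8L, fmt = 1L, ps = ps)
    } else if (bits == 32) {
      list(data = px, bits = 32L, fmt = 3L, ps = ps)
    } else {
      list(data = round(px), bits = as.integer(bits), fmt = 1L, ps = ps)
    }
  })
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42)
  # layout: header(8) | per page: pixel data, rational values(16), IFD
  offset <- 8
  n_entries <- 12L
  meta <- list()
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    nbytes <- nrow(p$data) * ncol(p$data) * p$bits / 8
    data_off <- offset
    rat_off <- data_off + nbytes
    ifd_off <- rat_off + 16
    meta[[k]] <- list(data_off = data_off, rat_off = rat_off,
                      ifd_off = ifd_off)
    offset <- ifd_off + 2 + n_entries * 12 + 4
  }
  w4(meta[[1]]$ifd_off)
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    v <- as.vector(t(p$data))  # TIFF is row-major
    if (p$bits == 32 && p$fmt == 3L)
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    else
      writeBin(as.integer(v), con, size = p$bits / 8, endian = "little")
    # X and Y resolution rationals: pixels per cm = 1e4 / pixel_size_um
    num <- round(1e7 / p$ps); den <- 1000
    w4(c(num, den, num, den))
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3 && count == 1) { w2(value); w2(0) } else w4(value)
    }
    H <- nrow(p$data); W <- ncol(p$data)
    m <- meta[[k]]
    w2(n_entries)
    entry(256, 4, 1, W)                 # ImageWidth
    entry(257, 4, 1, H)                 # ImageLength
    entry(258, 3, 1, p$bits)            # BitsPerSample
    entry(259, 3, 1, 1)                 # Compression: none
    entry(262, 3, 1, 1)                 # Photometric: BlackIsZero
    entry(273, 4, 1, m$data_off)        # StripOffsets
    entry(277, 3, 1, 1)                 # SamplesPerPixel
    entry(278, 4, 1, H)                 # RowsPerStrip
    entry(279, 4, 1, H * W * p$bits / 8)  # StripByteCounts
    entry(282, 5, 1, m$rat_off)         # XResolution
    entry(283, 5, 1, m$rat_off + 8)     # YResolution
    entry(339, 3, 1, p$fmt)             # SampleFormat
    w4(if (k < length(pages)) meta[[k + 1]]$ifd_off else 0)
  }
  invisible(path)
}

read_uint <- function(raw, size, endian = "little") {
  n <- length(raw) / size
  if (size == 1) return(as.integer(raw))
  v <- readBin(raw, "integer", n = n, size = size, signed = FALSE,
               endian = endian)
  v
}

#' Read a single- or multi-page grayscale TIFF
#'
#' Supports uncompressed baseline TIFF, one sample per pixel, 8/16-bit
#' unsigned or 32-bit float, either byte order, multiple strips.
#' Intensities are returned as floats without rescaling; page order is frame
#' order. Pixel size is taken from the resolution tags when present,
#' otherwise the `pixel_size` argument is required.
#'
#' @param path TIFF file.
#' @param pixel_size fallback micrometres per pixel.
#' @param channel channel label for the returned [gray_image()]s.
#' @return List of [gray_image()] objects.
#' @export
read_image_stack <- function(path, pixel_size = NULL,
                             channel = c("phase_contrast", "fluorescence")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("I/O error: not a TIFF file")
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("I/O error: not a TIFF file")
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = endian)
  if (u16(2) != 42) stop("I/O error: bad TIFF magic")
  ifd_off <- u32(4)
  pages <- list()
  page_no <- 0
  while (ifd_off != 0) {
    page_no <- page_no + 1
    n <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      size <- TIFF_TYPE_SIZES[type] * count
      voff <- if (size <= 4) base + 8 else u32(base + 8)
      vals <- switch(as.character(type),
        "3" = vapply(seq_len(count), function(i) u16(voff + 2 * (i - 1)),
                     numeric(1)),
        "4" = vapply(seq_len(count), function(i) u32(voff + 4 * (i - 1)),
                     numeric(1)),
        "5" = vapply(seq_len(count), function(i)
          u32(voff + 8 * (i - 1)) / max(1, u32(voff + 8 * (i - 1) + 4)),
          numeric(1)),
        "1" = as.numeric(raw[(voff + 1):(voff + count)]),
        NULL)
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default))
          stop(sprintf("I/O error: page %d missing required tag %d",
                       page_no, tag))
        v <- default
      }
      v
    }
    W <- need(256); H <- need(257)
    bits <- need(258, 8); comp <- need(259, 1)
    fmt <- need(339, 1)
    if (comp != 1)
      stop(sprintf("I/O error: page %d uses compression %d (unsupported)",
                   page_no, comp))
    spp <- need(277, 1)
    if (spp != 1)
      stop(sprintf("I/O error: page %d has %d samples/pixel (grayscale only)",
                   page_no, spp))
    if (!(bits %in% c(8, 16, 32)))
      stop(sprintf("I/O error: page %d bit depth %d unsupported",
                   page_no, bits))
    offs <- need(273); counts <- need(279)
    bytes <- raw[unlist(mapply(function(o, cnt) (o + 1):(o + cnt),
                               offs, counts, SIMPLIFY = FALSE))]
    vals <- if (bits == 32 && fmt == 3)
      readBin(bytes, "numeric", n = W * H, size = 4, endian = endian)
    else
      read_uint(bytes, bits / 8, endian)
    px <- matrix(as.numeric(vals), nrow = H, ncol = W, byrow = TRUE)
    xres <- tags[["282"]]
    ps <- if (!is.null(xres) && xres > 0) 1e4 / xres else NA_real_
    pages[[page_no]] <- list(px = px, ps = ps)
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  lapply(pages, function(p) {
    ps <- p$ps
    if (is.na(ps)) {
      if (is.null(pixel_size))
        stop("configuration error: no pixel-size metadata in file and no ",
             "`pixel_size` supplied")
      ps <- pixel_size
    }
    gray_image(p$px, ps, channel)
  })
}

#' Read a TIFF as binary masks
#'
#' @param path TIFF file (any intensities; foreground = value above half the
#'   page maximum).
#' @param pixel_size fallback micrometres per pixel.
#' @return List of [binary_mask()] objects.
#' @export
read_mask_stack <- function(path, pixel_size = NULL) {
  imgs <- read_image_stack(path, pixel_size)
  lapply(imgs, function(im)
    binary_mask(im$pixels > max(im$pixels) / 2, im$pixel_size))
}
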