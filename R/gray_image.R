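#' Grayscale image container
#'
#' A `gray_image` is an integer matrix of intensities in `[0, levels - 1]`
#' with the number of gray levels recorded as an attribute. Rows are image
#' rows (y), columns are image columns (x). Mammographic sources are 8-bit
#' (`levels = 256`), which is the default throughout.
#'
#' @param pixels numeric or integer matrix of intensities.
#' @param levels number of gray levels L; intensities must lie in
#'   `[0, levels - 1]`.
#' @return an object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' gray_levels(img)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px)) stop("pixel values must be finite integers", call. = FALSE)
  if (min(px) < 0L || max(px) > levels - 1L)
    stop("pixel values must lie in [0, levels - 1]", call. = FALSE)
  structure(px, levels = levels, class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, L = %d, range [%d, %d]>\n",
              nrow(x), ncol(x), gray_levels(x), min(x), max(x)))
  invisible(x)
}

#' @rdname gray_image
#' @param img a `gray_image`.
#' @export
gray_levels <- function(img) {
  L <- attr(img, "levels")
  if (is.null(L)) 256L else as.integer(L)
}

#' @rdname gray_image
#' @param x object to test.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

as_gray_image <- function(x, levels = 256L) {
  if (is_gray_image(x)) return(x)
  gray_image(x, levels)
}

# clip + round-half-up a numeric matrix into a gray_image
quantize_to_gray <- function(x, levels = 256L) {
  v <- floor(x + 0.5)
  v[v < 0] <- 0
  v[v > levels - 1] <- levels - 1
  gray_image(matrix(as.integer(v), nrow(x), ncol(x)), levels)
}

#' Read and write single-channel images
#'
#' Reads PGM (both the ASCII `P2` and binary `P5` dialects), PNG and TIFF
#' single-channel images into a [gray_image]. Multi-channel PNG/TIFF input is
#' collapsed to luminance by channel averaging. `write_gray_image` emits the
#' format implied by the file extension (`.pgm`, `.png`, `.tif`/`.tiff`).
#'
#' @param path file path; format detected from the extension.
#' @return `read_gray_image` returns a [gray_image]; `write_gray_image`
#'   returns `path` invisibly.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1L, 2L), mean)
  quantize_to_gray(arr * 255, 256L)
}

#' @rdname read_gray_image
#' @param img a [gray_image].
#' @param ascii for PGM output, write the ASCII `P2` dialect instead of
#'   binary `P5`.
#' @export
write_gray_image <- function(img, path, ascii = FALSE) {
  img <- as_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    write_pgm(img, path, ascii = ascii)
  } else if (ext == "png") {
    png::writePNG(unclass(img) / (gray_levels(img) - 1L), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(unclass(img) / (gray_levels(img) - 1L), path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

# -- PGM: no installed package reads it, so parse the two dialects directly --

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, maxval; '#' starts a comment
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[^[:space:]]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L]); h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PGM header", call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255L) stop("16-bit binary PGM not supported", call. = FALSE)
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE, comment.char = "#")
  }
  if (length(vals) < n) stop("truncated PGM pixel data", call. = FALSE)
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE), maxval + 1L)
}

write_pgm <- function(img, path, ascii = FALSE) {
  L <- gray_levels(img)
  px <- unclass(img)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(L - 1L)), con)
    write(t(px), file = con, ncolumns = ncol(px))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(px), nrow(px), L - 1L), con,
              eos = NULL)
    writeBin(as.raw(as.vector(t(px))), con)
  }
  invisible(path)
}

#' Resize a grayscale image
#'
#' Bilinear resizing (via EBImage) used to bring images to the CNN input
#' size.
#'
#' @param img a [gray_image].
#' @param size target side length in pixels (output is `size` x `size`).
#' @return a [gray_image] of the requested size.
#' @export
resize_gray_image <- function(img, size) {
  img <- as_gray_image(img)
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("`size` must be >= 1", call. = FALSE)
  if (nrow(img) == size && ncol(img) == size) return(img)
  out <- EBImage::resize(unclass(img) * 1.0, w = size, h = size)
  quantize_to_gray(out, gray_levels(img))
}
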