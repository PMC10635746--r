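#' Median filtering for impulse-noise reduction
#'
#' Replaces each pixel by the median of its `window x window` neighbourhood.
#' This suppresses salt-and-pepper impulses while preserving edges. Borders
#' are handled by replicate padding, so the filter does not introduce
#' artificial dark rims at the image edge.
#'
#' @param img a [gray_image].
#' @param window odd window size, >= 3 (default 3, i.e. a 3 x 3
#'   neighbourhood).
#' @return the filtered [gray_image], same dimensions.
#' @examples
#' img <- gray_image(matrix(0L, 5, 5)); img[3, 3] <- 255L
#' max(median_filter(gray_image(unclass(img))))  # impulse removed
#' @export
median_filter <- function(img, window = 3L) {
  img <- as_gray_image(img)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  r <- window %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0L, h + 2L * r, w + 2L * r)
  pad[r + seq_len(h), r + seq_len(w)] <- unclass(img)
  # replicate borders
  pad[seq_len(r), ] <- pad[rep(r + 1L, r), ]
  pad[h + r + seq_len(r), ] <- pad[rep(h + r, r), ]
  pad[, seq_len(r)] <- pad[, rep(r + 1L, r)]
  pad[, w + r + seq_len(r)] <- pad[, rep(w + r, r)]
  # stack the window's shifted copies: one column per window offset
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  stk <- matrix(0L, h * w, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    stk[, o] <- pad[r + offs$dy[o] + seq_len(h), r + offs$dx[o] + seq_len(w)]
  }
  med <- apply(stk, 1L, function(v) sort.int(v)[(length(v) + 1L) %/% 2L])
  gray_image(matrix(as.integer(med), h, w), gray_levels(img))
}

#' Intensity histogram
#'
#' Counts `h(x)` of pixels at each gray level `x = 0, ..., L-1`; the counts
#' sum to the pixel count `N`.
#'
#' @param img a [gray_image].
#' @return integer vector of length `L`, named by gray level.
#' @export
img_histogram <- function(img) {
  img <- as_gray_image(img)
  L <- gray_levels(img)
  counts <- tabulate(as.vector(unclass(img)) + 1L, nbins = L)
  names(counts) <- 0:(L - 1L)
  counts
}

#' Histogram-equalization transfer function
#'
#' From the histogram `h(x)` the intensity density `p(x) = h(x)/N` and its
#' cumulative sum `c(x)` are formed; the transfer function
#' `f(x) = x0 + (x_{L-1} - x0) * c(x)` maps the input onto the full dynamic
#' range `[x0, x_{L-1}] = [0, L-1]`. `f` is monotone nondecreasing by
#' construction.
#'
#' @param img a [gray_image].
#' @return a list of class `equalize_transfer` with `f` (length-`L` numeric,
#'   `f[x + 1]` the output for input level `x`), `cdf`, `x0`, `x_max`.
#' @export
equalize_transfer <- function(img) {
  img <- as_gray_image(img)
  L <- gray_levels(img)
  h <- img_histogram(img)
  p <- h / sum(h)
  cdf <- cumsum(p)
  x0 <- 0
  x_max <- L - 1
  structure(list(f = x0 + (x_max - x0) * cdf, cdf = cdf,
                 x0 = x0, x_max = x_max),
            class = "equalize_transfer")
}

#' Histogram equalization
#'
#' Applies the [equalize_transfer()] mapping pixelwise, rounding half-up to
#' the nearest integer and clipping to `[0, L-1]`. Stretches low-contrast
#' images onto the full dynamic range.
#'
#' @param img a [gray_image].
#' @return the equalized [gray_image].
#' @examples
#' img <- gray_image(matrix(c(0L, 0L, 255L, 255L), 2, 2))
#' equalize(img)  # 0 -> 128, 255 -> 255
#' @export
equalize <- function(img) {
  img <- as_gray_image(img)
  tf <- equalize_transfer(img)
  out <- tf$f[unclass(img) + 1L]
  quantize_to_gray(matrix(out, nrow(img), ncol(img)), gray_levels(img))
}

#' Breast-region extraction by thresholding and erosion
#'
#' Binarizes the image (Otsu's threshold by default), erodes the foreground
#' with a flat diamond structuring element (city-block radius `radius`),
#' keeps the largest 8-connected component, and returns the image with the
#' background zeroed together with the binary mask. This isolates the tissue
#' region and drops small bright artifacts such as burned-in markers.
#'
#' @param img a [gray_image].
#' @param threshold binarization threshold on raw intensities; pixels
#'   strictly above it are foreground. `NULL` (default) uses Otsu's method.
#' @param radius city-block radius of the diamond structuring element
#'   (default 3).
#' @return a list with `image` (masked [gray_image]), `mask` (logical
#'   matrix) and `threshold` (the value used).
#' @export
extract_roi <- function(img, threshold = NULL, radius = 3L) {
  img <- as_gray_image(img)
  L <- gray_levels(img)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(unclass(img) / (L - 1), range = c(0, 1),
                               levels = L) * (L - 1)
  }
  fg <- unclass(img) > threshold
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "diamond")
  er <- EBImage::erode(fg * 1, kern) > 0
  if (!any(er))
    stop("empty ROI: no foreground survives erosion", call. = FALSE)
  lab <- label_components8(er)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  out <- unclass(img)
  out[!mask] <- 0L
  list(image = gray_image(out, L), mask = mask, threshold = threshold)
}

# 8-connected component labeling via a pixel graph
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  inmask <- matrix(FALSE, h, w)
  inmask[idx] <- TRUE
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  for (s in shifts) {
    r2 <- rr + s[1L]; c2 <- cc + s[2L]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    ok[ok] <- inmask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges[[length(edges) + 1L]] <-
        cbind(idx[ok], (c2[ok] - 1L) * h + r2[ok])
  }
  # map pixel linear indices to vertex ids
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(vid[em[, 1L]], vid[em[, 2L]]))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}
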