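#' GLCM computation settings
#'
#' @param distance pixel offset distance d (>= 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param levels number of quantization levels G (images are uniformly
#'   re-binned to G levels before counting; default 16).
#' @param symmetric add the transposed counts so the matrix is symmetric
#'   (default `TRUE`).
#' @param normalized scale counts to sum to 1 (default `TRUE`).
#' @param aggregate `"mean"` averages each feature over the angles,
#'   `"concat"` keeps one copy per angle.
#' @return a `glcm_spec` list.
#' @export
glcm_spec <- function(distance = 1L, angles = c(0, 45, 90, 135),
                      levels = 16L, symmetric = TRUE, normalized = TRUE,
                      aggregate = c("mean", "concat")) {
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L)
    stop("`distance` must be >= 1", call. = FALSE)
  if (!all(angles %in% c(0, 45, 90, 135)) || length(angles) < 1L)
    stop("`angles` must be a nonempty subset of {0, 45, 90, 135}",
         call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("`levels` must be >= 2", call. = FALSE)
  structure(list(distance = distance, angles = angles, levels = levels,
                 symmetric = isTRUE(symmetric),
                 normalized = isTRUE(normalized),
                 aggregate = match.arg(aggregate)),
            class = "glcm_spec")
}

#' Uniform gray-level quantization
#'
#' Re-bins intensities `[0, L-1]` into `levels` equal-width bins, returning
#' a matrix of bin indices in `0, ..., levels-1`.
#'
#' @param img a [gray_image].
#' @param levels target number of levels.
#' @return integer matrix of quantized levels.
#' @export
quantize_gray <- function(img, levels = 16L) {
  img <- as_gray_image(img)
  L <- gray_levels(img)
  if (levels > L) stop("`levels` must be <= the image's L", call. = FALSE)
  q <- floor(unclass(img) * as.numeric(levels) / L)
  q[q > levels - 1L] <- levels - 1L
  matrix(as.integer(q), nrow(img), ncol(img))
}

# row/col offsets per angle for distance d, in matrix (row downward) terms:
# 0 deg = same row, d columns right; 90 deg = d rows up; 45/135 diagonals
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angle, call. = FALSE))
}

#' Gray-level co-occurrence matrices
#'
#' Counts pairs of quantized gray levels at the configured offset for each
#' angle. With `symmetric = TRUE` the transposed counts are added; with
#' `normalized = TRUE` each matrix is scaled to sum to 1.
#'
#' @param img a [gray_image].
#' @param spec a [glcm_spec].
#' @return a named list (one `G x G` matrix per angle).
#' @examples
#' img <- gray_image(matrix(c(0L, 0L, 255L, 255L), 2, 2, byrow = TRUE))
#' compute_glcm(img, glcm_spec(angles = 0, levels = 2))
#' @export
compute_glcm <- function(img, spec = glcm_spec()) {
  q <- quantize_gray(img, spec$levels)
  G <- spec$levels
  h <- nrow(q); w <- ncol(q)
  out <- list()
  for (a in spec$angles) {
    off <- glcm_offset(a, spec$distance)
    rs <- seq_len(h); cs <- seq_len(w)
    r1 <- rs[rs + off[1L] >= 1L & rs + off[1L] <= h]
    c1 <- cs[cs + off[2L] >= 1L & cs + off[2L] <= w]
    if (length(r1) == 0L || length(c1) == 0L)
      stop("image smaller than the configured offset: no pixel pairs",
           call. = FALSE)
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + off[1L], c1 + off[2L], drop = FALSE]
    counts <- matrix(tabulate(as.vector(i) * G + as.vector(j) + 1L,
                              nbins = G * G),
                     G, G, byrow = TRUE)
    if (spec$symmetric) counts <- counts + t(counts)
    if (spec$normalized) counts <- counts / sum(counts)
    out[[paste0("deg", a)]] <- counts
  }
  out
}

#' Haralick-style texture features of a GLCM
#'
#' Computes the standard scalar texture statistics of a normalized GLCM:
#' autocorrelation, contrast, two correlation variants, cluster prominence,
#' cluster shade, dissimilarity, energy, entropy, homogeneity, maximum
#' probability, sum of squares (variance), sum average, sum variance, sum
#' entropy, difference variance, difference entropy, the two information
#' measures of correlation, inverse difference, inverse difference
#' normalized and inverse difference moment normalized (22 scalars).
#' Entropy-type terms use the `0 * log 0 = 0` convention; natural
#' logarithms throughout.
#'
#' @param glcms result of [compute_glcm()] (normalized matrices), or a
#'   single normalized matrix.
#' @param spec the [glcm_spec] used (controls angle aggregation).
#' @return a named numeric vector; with `aggregate = "concat"` names are
#'   suffixed by angle.
#' @export
haralick_features <- function(glcms, spec = glcm_spec()) {
  if (is.matrix(glcms)) glcms <- list(deg0 = glcms)
  per_angle <- lapply(glcms, function(P) {
    if (abs(sum(P) - 1) > 1e-8)
      stop("GLCM must be normalized (entries summing to 1)", call. = FALSE)
    haralick_one(P)
  })
  if (spec$aggregate == "mean" || length(per_angle) == 1L) {
    Reduce(`+`, per_angle) / length(per_angle)
  } else {
    out <- unlist(lapply(names(per_angle), function(nm) {
      v <- per_angle[[nm]]
      names(v) <- paste(names(v), nm, sep = "_")
      v
    }))
    out
  }
}

haralick_one <- function(P) {
  G <- nrow(P)
  i <- matrix(rep(seq_len(G), times = G), G, G)  # row level (1-based)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

  # distributions of i+j (2..2G) and |i-j| (0..G-1)
  psum <- vapply(2L:(2L * G), function(s) sum(P[i + j == s]), numeric(1))
  pdif <- vapply(0L:(G - 1L), function(d) sum(P[abs(i - j) == d]), numeric(1))
  ks <- 2L:(2L * G); kd <- 0L:(G - 1L)

  autoc <- sum(i * j * P)
  contrast <- sum((i - j)^2 * P)
  corr_num <- autoc - mux * muy
  correlation_m <- if (sx > 0 && sy > 0) corr_num / (sx * sy) else 0
  correlation_p <- if (sx > 0 && sy > 0)
    (sum((i - mux) * (j - muy) * P)) / (sx * sy) else 0
  cprom <- sum((i + j - mux - muy)^4 * P)
  cshade <- sum((i + j - mux - muy)^3 * P)
  dissim <- sum(abs(i - j) * P)
  energy <- sum(P^2)
  entropy <- -sum(xlogx(P))
  homog <- sum(P / (1 + (i - j)^2))
  maxp <- max(P)
  sosvh <- sum((i - mux)^2 * P)
  savgh <- sum(ks * psum)
  svarh <- sum((ks - savgh)^2 * psum)
  senth <- -sum(xlogx(psum))
  davg <- sum(kd * pdif)
  dvarh <- sum((kd - davg)^2 * pdif)
  denth <- -sum(xlogx(pdif))
  hxy <- entropy
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxpy > 0, P * log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  inf1h <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  inf2h <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  indic <- sum(P / (1 + abs(i - j)))
  idn <- sum(P / (1 + abs(i - j) / G))
  idmn <- sum(P / (1 + (i - j)^2 / G^2))

  c(autocorrelation = autoc, contrast = contrast,
    correlation_m = correlation_m, correlation_p = correlation_p,
    cluster_prominence = cprom, cluster_shade = cshade,
    dissimilarity = dissim, energy = energy, entropy = entropy,
    homogeneity = homog, max_probability = maxp,
    sum_of_squares = sosvh, sum_average = savgh, sum_variance = svarh,
    sum_entropy = senth, difference_variance = dvarh,
    difference_entropy = denth, info_correlation_1 = inf1h,
    info_correlation_2 = inf2h, inverse_difference = indic,
    inverse_difference_norm = idn, inverse_difference_moment_norm = idmn)
}

#' Texture feature table for an image collection
#'
#' Runs [compute_glcm()] + [haralick_features()] on every image with one
#' shared spec and assembles a data frame, one row per image, fixed column
#' order, with a `label` column appended when labels are given.
#'
#' @param images list of [gray_image]s (identically preprocessed).
#' @param spec a [glcm_spec].
#' @param labels optional label vector, one per image.
#' @return a data frame of features (and `label`).
#' @export
features_for_dataset <- function(images, spec = glcm_spec(), labels = NULL) {
  if (!is.null(labels) && length(labels) != length(images))
    stop("`labels` must match `images` in length", call. = FALSE)
  rows <- lapply(images, function(im)
    haralick_features(compute_glcm(im, spec), spec))
  dims <- vapply(rows, length, integer(1))
  if (length(unique(dims)) > 1L)
    stop("inconsistent feature dimensions across images", call. = FALSE)
  tab <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) tab$label <- as.character(labels)
  tab
}
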