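# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the DS enumerator works on explicit focal sets,
# the GLCM counter is a double loop over pixel pairs.

# Brute-force Dempster combination over explicit focal elements.
# Masses are length-3 (benign, malignant, ignorance); the frame variant
# decides what set "ignorance" denotes.
brute_force_combine <- function(m1, m2, variant) {
  sets <- if (variant == "classical_ds") {
    list(c("B"), c("M"), c("B", "M"))
  } else {
    list(c("B"), c("M"), c("I"))
  }
  agree <- c(0, 0, 0)
  conflict <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      inter <- intersect(sets[[i]], sets[[j]])
      w <- m1[i] * m2[j]
      if (length(inter) == 0) {
        conflict <- conflict + w
      } else {
        # attribute the product to the focal element equal to the
        # intersection
        target <- which(vapply(sets, function(s)
          setequal(s, inter), logical(1)))
        agree[target] <- agree[target] + w
      }
    }
  }
  list(k = conflict,
       mass = if (conflict < 1) agree / (1 - conflict) else rep(NA_real_, 3))
}

random_mass <- function() {
  v <- stats::rgamma(3, shape = 1)
  v / sum(v)
}

# Brute-force GLCM: double loop over all pixel pairs at the offset.
brute_force_glcm <- function(q, levels, dr, dc, symmetric = TRUE) {
  G <- levels
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        counts[q[r, cc] + 1, q[r2, c2] + 1] <-
          counts[q[r, cc] + 1, q[r2, c2] + 1] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Mean Sobel gradient magnitude in a ring around the mass boundary --
# a margin-sharpness statistic.
sobel_ring_stat <- function(img, radius, width = 6) {
  px <- unclass(img) * 1.0
  sx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- EBImage::filter2(px, sx)
  gy <- EBImage::filter2(px, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  n <- nrow(px)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  d <- sqrt((xs - n / 2)^2 + (ys - n / 2)^2)
  ring <- abs(d - radius) <= width
  mean(mag[ring])
}

# chi-square distance of an image histogram to the uniform histogram,
# aggregated over 16 coarse intensity bins (per-level chi-square on 8-bit
# images is dominated by empty levels and is not a useful contrast measure)
chisq_to_uniform <- function(img, bins = 16) {
  h <- img_histogram(img)
  grp <- rep(seq_len(bins), each = length(h) / bins)
  hb <- tapply(h, grp, sum)
  e <- sum(hb) / bins
  sum((hb - e)^2 / e)
}
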