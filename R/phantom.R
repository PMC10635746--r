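#' Specification of a synthetic mammographic phantom
#'
#' Phantoms emulate the two mass phenotypes that drive mammographic
#' diagnosis: benign masses with smooth, uniform margins (a Gaussian-blurred
#' disc) and malignant masses with sharp, needle-like spiculated margins (a
#' disc plus radial spicules). The `ignorant` class stands for normal tissue
#' and contains background texture only. Salt-and-pepper and Gaussian noise
#' mimic acquisition artifacts; noise is always applied last.
#'
#' @param image_size side length in pixels (>= 32).
#' @param class_label one of `"benign"`, `"malignant"`, `"ignorant"`.
#' @param mass_radius mass radius in pixels.
#' @param spicule_count number of radial spicules; must be >= 4 for
#'   malignant phantoms and 0 otherwise.
#' @param noise_salt_pepper_frac fraction of pixels replaced by 0 or L-1.
#' @param noise_gaussian_sigma standard deviation of additive Gaussian noise,
#'   in intensity units.
#' @param background_texture_scale correlation length (pixels) of the
#'   smoothed background texture.
#' @param seed integer RNG seed; phantoms are bit-reproducible given the seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class_label,
                         image_size = 128L,
                         mass_radius = round(image_size / 8),
                         spicule_count = if (class_label == "malignant") 8L else 0L,
                         noise_salt_pepper_frac = 0.02,
                         noise_gaussian_sigma = 6,
                         background_texture_scale = 8,
                         seed = 1L) {
  class_label <- match.arg(class_label, mass_classes())
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L)
    stop("`image_size` must be >= 32", call. = FALSE)
  if (!is.finite(mass_radius) || mass_radius <= 0)
    stop("`mass_radius` must be positive", call. = FALSE)
  spicule_count <- as.integer(spicule_count)
  if (class_label == "malignant" && spicule_count < 4L)
    stop("malignant phantoms need `spicule_count` >= 4", call. = FALSE)
  if (class_label != "malignant" && spicule_count != 0L)
    stop("`spicule_count` must be 0 unless the phantom is malignant",
         call. = FALSE)
  if (!is.finite(noise_salt_pepper_frac) || noise_salt_pepper_frac < 0 ||
      noise_salt_pepper_frac > 1)
    stop("`noise_salt_pepper_frac` must be in [0, 1]", call. = FALSE)
  if (!is.finite(noise_gaussian_sigma) || noise_gaussian_sigma < 0)
    stop("`noise_gaussian_sigma` must be >= 0", call. = FALSE)
  if (!is.finite(background_texture_scale) || background_texture_scale <= 0)
    stop("`background_texture_scale` must be positive", call. = FALSE)
  structure(list(image_size = image_size,
                 class_label = class_label,
                 mass_radius = mass_radius,
                 spicule_count = spicule_count,
                 noise_salt_pepper_frac = noise_salt_pepper_frac,
                 noise_gaussian_sigma = noise_gaussian_sigma,
                 background_texture_scale = background_texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic phantom image
#'
#' Deterministic given `spec$seed`. Construction order: background texture
#' (smoothed uniform noise), then the class-specific mass (benign: disc
#' blurred with sigma = radius/4; malignant: disc plus `spicule_count` radial
#' line segments of length 1.5 x radius), then Gaussian noise, then
#' salt-and-pepper noise.
#'
#' @param spec a [phantom_spec].
#' @return a list with elements `image` (a [gray_image]) and `label`.
#' @examples
#' ph <- generate_phantom(phantom_spec("malignant", image_size = 64, seed = 3))
#' ph$label
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  n <- spec$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  # background: smoothed uniform noise, rescaled around mid-dark tissue level
  bg <- matrix(stats::runif(n * n), n, n)
  bg <- EBImage::gblur(bg, sigma = spec$background_texture_scale / 2)
  bg <- (bg - mean(bg)) / max(stats::sd(bg), 1e-12)
  canvas <- 90 + 18 * bg

  if (spec$class_label != "ignorant") {
    r <- spec$mass_radius
    cx <- n / 2 + stats::runif(1, -n / 16, n / 16)
    cy <- n / 2 + stats::runif(1, -n / 16, n / 16)
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    mass <- matrix(0, n, n)
    mass[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1
    if (spec$class_label == "benign") {
      mass <- EBImage::gblur(mass, sigma = r / 4)
    } else {
      ang <- stats::runif(1, 0, 2 * pi / spec$spicule_count) +
        2 * pi * (seq_len(spec$spicule_count) - 1L) / spec$spicule_count
      for (a in ang) {
        t <- seq(0, 1.5 * r, by = 0.5)
        px <- round(cx + t * cos(a))
        py <- round(cy + t * sin(a))
        keep <- px >= 1 & px <= n & py >= 1 & py <= n
        mass[cbind(py[keep], px[keep])] <- 1
      }
      mass <- EBImage::gblur(mass, sigma = 0.6)
    }
    canvas <- canvas + 85 * mass
  }

  if (spec$noise_gaussian_sigma > 0)
    canvas <- canvas + stats::rnorm(n * n, 0, spec$noise_gaussian_sigma)
  canvas <- pmin(pmax(canvas, 0), 255)
  if (spec$noise_salt_pepper_frac > 0) {
    n_sp <- round(spec$noise_salt_pepper_frac * n * n)
    if (n_sp > 0) {
      idx <- sample.int(n * n, n_sp)
      half <- seq_len(n_sp) <= n_sp / 2
      canvas[idx[half]] <- 0
      canvas[idx[!half]] <- 255
    }
  }
  list(image = quantize_to_gray(matrix(canvas, n, n), 256L),
       label = spec$class_label)
}

#' Generate a balanced labelled phantom dataset
#'
#' Produces `3 * n_per_class` phantoms (one third per class) with per-image
#' seeds derived reproducibly from the master seed.
#'
#' @param n_per_class images per class (>= 1).
#' @param spec_template a [phantom_spec] whose geometry/noise settings are
#'   reused for every image (its `class_label`, `spicule_count` and `seed`
#'   are overridden per image).
#' @param seed master seed.
#' @return a list with `images` (list of [gray_image]), `labels` (factor with
#'   levels [mass_classes()]) and `seeds` (the derived per-image seeds).
#' @export
generate_phantom_dataset <- function(n_per_class,
                                     spec_template = phantom_spec("benign"),
                                     seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L)
    stop("`n_per_class` must be >= 1", call. = FALSE)
  labels <- rep(mass_classes(), each = n_per_class)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- spec_template
    sp$class_label <- labels[i]
    sp$spicule_count <- if (labels[i] == "malignant")
      max(spec_template$spicule_count, 4L) else 0L
    sp$seed <- seeds[i]
    images[[i]] <- generate_phantom(sp)$image
  }
  list(images = images,
       labels = factor(labels, levels = mass_classes()),
       seeds = seeds)
}

#' Write a phantom dataset to disk
#'
#' Images go to `<dir>/phantom_###.<format>` plus a `labels.csv` with columns
#' `filename,label`.
#'
#' @param dataset result of [generate_phantom_dataset()].
#' @param dir output directory (created if absent).
#' @param format `"pgm"` or `"png"`.
#' @return invisibly, the path of the labels CSV.
#' @export
write_phantom_dataset <- function(dataset, dir, format = c("pgm", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("phantom_%03d.%s", seq_along(dataset$images), format)
  for (i in seq_along(dataset$images))
    write_gray_image(dataset$images[[i]], file.path(dir, files[i]))
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(filename = files,
                              label = as.character(dataset$labels)),
                   lab_path, row.names = FALSE, quote = FALSE)
  invisible(lab_path)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir directory containing the images and `labels.csv`.
#' @return a list with `images` and `labels` as in
#'   [generate_phantom_dataset()].
#' @export
read_phantom_dataset <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  list(images = lapply(file.path(dir, lab$filename), read_gray_image),
       labels = factor(lab$label, levels = mass_classes()))
}

#' Simulate an aligned pair of probabilistic classification sources
#'
#' Emulates two classifiers (e.g. a texture MLP and a CNN) that emit
#' class-probability triples over benign/malignant/ignorant with controllable
#' top-class accuracy and inter-source error correlation. For each sample a
#' true label is drawn uniformly; each source errs with probability
#' `1 - accuracy`, and with `error_correlation = 1` (and equal accuracies)
#' the two sources err on exactly the same samples. The erroneous class is
#' uniform over the two wrong labels. Probability triples are Dirichlet draws
#' concentrated on the assigned class (concentration
#' `confidence_concentration`), adjusted so the argmax is always the assigned
#' class. Erroneous outputs are drawn at a third of the concentration:
#' classifier errors are low-margin events, and a simulator whose wrong
#' answers were as confident as its right ones would carry no information
#' beyond the argmax, making any decision-level fusion pointless.
#'
#' @param n_samples number of samples (>= 1).
#' @param accuracy_source1,accuracy_source2 top-class accuracies in (0, 1];
#'   1 is allowed and makes the source exact.
#' @param error_correlation in `[0, 1]`; 0 = independent error events.
#' @param confidence_concentration positive; larger = more peaked triples.
#' @param seed integer RNG seed.
#' @return a list with `truth` (factor), `source1` and `source2` (n x 3
#'   matrices with columns [mass_classes()], rows summing to 1).
#' @export
simulate_source_pair <- function(n_samples,
                                 accuracy_source1,
                                 accuracy_source2,
                                 error_correlation = 0,
                                 confidence_concentration = 8,
                                 seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("`n_samples` must be >= 1", call. = FALSE)
  for (a in c(accuracy_source1, accuracy_source2))
    if (!is.finite(a) || a <= 0 || a > 1)
      stop("accuracies must lie in (0, 1]", call. = FALSE)
  if (!is.finite(error_correlation) || error_correlation < 0 ||
      error_correlation > 1)
    stop("`error_correlation` must be in [0, 1]", call. = FALSE)
  if (!is.finite(confidence_concentration) || confidence_concentration <= 0)
    stop("`confidence_concentration` must be positive", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cls <- mass_classes()
  truth <- sample(cls, n_samples, replace = TRUE)

  # common-uniform coupling: with prob rho both sources read the same
  # uniform, giving comonotone error events; otherwise independent draws
  u_common <- stats::runif(n_samples)
  couple <- stats::runif(n_samples) < error_correlation
  u1 <- ifelse(couple, u_common, stats::runif(n_samples))
  u2 <- ifelse(couple, u_common, stats::runif(n_samples))
  err1 <- u1 > accuracy_source1
  err2 <- u2 > accuracy_source2

  assigned <- function(err) {
    out <- truth
    if (any(err)) {
      wrong <- vapply(truth[err], function(tr)
        sample(setdiff(cls, tr), 1L), character(1))
      out[err] <- wrong
    }
    out
  }
  a1 <- assigned(err1)
  a2 <- assigned(err2)

  draw <- function(assigned_cls) {
    k <- match(assigned_cls, cls)
    conc <- ifelse(assigned_cls == truth, confidence_concentration,
                   confidence_concentration / 3)
    alpha0 <- matrix(1, n_samples, 3L)
    alpha0[cbind(seq_len(n_samples), k)] <- 1 + conc
    g <- matrix(stats::rgamma(3L * n_samples, shape = as.vector(alpha0)),
                n_samples, 3L)
    p <- g / rowSums(g)
    # guarantee argmax == assigned class by swapping in the max entry
    mx <- max.col(p, ties.method = "first")
    swap <- mx != k
    if (any(swap)) {
      i <- which(swap)
      tmp <- p[cbind(i, k[i])]
      p[cbind(i, k[i])] <- p[cbind(i, mx[i])]
      p[cbind(i, mx[i])] <- tmp
    }
    colnames(p) <- cls
    p
  }
  list(truth = factor(truth, levels = cls),
       source1 = draw(a1),
       source2 = draw(a2))
}

#' Write a simulated source pair as CSV
#'
#' Columns: `sample_id, true_label, p1_benign, p1_malignant, p1_ignorant,
#' p2_benign, p2_malignant, p2_ignorant`.
#'
#' @param sim result of [simulate_source_pair()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_source_pair <- function(sim, path) {
  df <- data.frame(sample_id = seq_along(sim$truth),
                   true_label = as.character(sim$truth))
  s1 <- sim$source1; s2 <- sim$source2
  colnames(s1) <- paste0("p1_", mass_classes())
  colnames(s2) <- paste0("p2_", mass_classes())
  utils::write.csv(cbind(df, s1, s2), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulated source pair CSV
#'
#' @param path CSV written by [write_source_pair()].
#' @return a list with `truth`, `source1`, `source2`.
#' @export
read_source_pair <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  grab <- function(prefix) {
    m <- as.matrix(df[paste0(prefix, mass_classes())])
    colnames(m) <- mass_classes()
    m
  }
  list(truth = factor(df$true_label, levels = mass_classes()),
       source1 = grab("p1_"), source2 = grab("p2_"))
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
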