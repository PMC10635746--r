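test_that("co-occurrence counting matches hand enumeration", {
  const <- gray_image(matrix(100L, 4, 4))
  g <- compute_glcm(const, glcm_spec(angles = 0))
  expect_equal(sum(g$deg0), 1)
  expect_equal(max(g$deg0), 1)  # single occupied cell

  # vertical stripes 0,1: two horizontal (0,1) pairs, symmetrized
  img <- gray_image(matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE),
                    levels = 2)
  g2 <- compute_glcm(img, glcm_spec(angles = 0, levels = 2))$deg0
  expect_equal(g2, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  set.seed(3)
  r <- gray_image(matrix(sample(0:255, 64, TRUE), 8, 8))
  gs <- compute_glcm(r, glcm_spec())
  for (m in gs) {
    expect_equal(sum(m), 1)
    expect_equal(m, t(m))
  }

  expect_error(compute_glcm(gray_image(matrix(0L, 1, 1)), glcm_spec()),
               "pairs")
})

test_that("GLCM agrees with a brute-force pair counter on random images", {
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                  `135` = c(-1L, -1L))
  set.seed(42)
  for (rep in 1:20) {
    h <- sample(4:16, 1); w <- sample(4:16, 1)
    img <- gray_image(matrix(sample(0:255, h * w, TRUE), h, w))
    spec <- glcm_spec(levels = 8)
    got <- compute_glcm(img, spec)
    q <- quantize_gray(img, 8)
    for (a in names(offsets)) {
      want <- brute_force_glcm(q, 8, offsets[[a]][1], offsets[[a]][2])
      expect_equal(got[[paste0("deg", a)]], want, tolerance = 1e-12)
    }
  }
})

test_that("Haralick features take their closed-form values on simple GLCMs", {
  const <- gray_image(matrix(100L, 4, 4))
  f <- haralick_features(compute_glcm(const, glcm_spec()), glcm_spec())
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["max_probability"]], 1)

  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- haralick_features(P, glcm_spec(levels = 2))
  expect_equal(f2[["contrast"]], 1)
  expect_equal(f2[["energy"]], 0.5)

  set.seed(9)
  img <- gray_image(matrix(sample(0:255, 144, TRUE), 12, 12))
  f3 <- haralick_features(compute_glcm(img, glcm_spec()), glcm_spec())
  expect_lte(f3[["entropy"]], log(16^2))
  expect_true(all(is.finite(f3)))

  expect_error(haralick_features(matrix(1, 2, 2), glcm_spec()), "normalized")
})

test_that("features depend only on the quantized image", {
  set.seed(5)
  base <- matrix(sample(0:14, 64, TRUE), 8, 8)
  # +1 on a [0,255] scale never crosses a 16-level bin edge here
  a <- gray_image(base * 16L)
  b <- gray_image(base * 16L + 1L)
  expect_identical(quantize_gray(a, 16), quantize_gray(b, 16))
  expect_equal(haralick_features(compute_glcm(a, glcm_spec()), glcm_spec()),
               haralick_features(compute_glcm(b, glcm_spec()), glcm_spec()))
})

test_that("the feature table is deterministic and separates the mass classes", {
  ds <- generate_phantom_dataset(3, phantom_spec("benign", image_size = 48),
                                 seed = 2)
  tab <- features_for_dataset(ds$images, glcm_spec(), ds$labels)
  expect_identical(nrow(tab), 9L)
  expect_identical(tab,
                   features_for_dataset(ds$images, glcm_spec(), ds$labels))
  expect_identical(names(tab)[ncol(tab)], "label")

  # spiculated masses add high-frequency structure: higher contrast than
  # blurred benign discs at matched seeds
  diffs <- vapply(1:20, function(s) {
    mal <- generate_phantom(phantom_spec("malignant", image_size = 64,
                                         mass_radius = 8, seed = s))$image
    ben <- generate_phantom(phantom_spec("benign", image_size = 64,
                                         mass_radius = 8, seed = s))$image
    hf <- function(im) haralick_features(compute_glcm(im, glcm_spec()),
                                         glcm_spec())[["contrast"]]
    hf(mal) - hf(ben)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs > 0), 0.9)
})

test_that("concatenated aggregation keeps one feature copy per angle", {
  img <- generate_phantom(phantom_spec("benign", image_size = 48,
                                       seed = 1))$image
  spec_c <- glcm_spec(aggregate = "concat")
  f <- haralick_features(compute_glcm(img, spec_c), spec_c)
  expect_length(f, 88L)  # 22 features x 4 angles
  expect_true(any(grepl("_deg45$", names(f))))
})
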