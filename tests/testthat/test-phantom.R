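test_that("phantom generation is deterministic and respects the spec", {
  sp <- phantom_spec("benign", image_size = 64, seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$label, "benign")
  expect_s3_class(a$image, "gray_image")
  expect_true(min(a$image) >= 0 && max(a$image) <= 255)

  expect_error(phantom_spec("benign", image_size = 16), "image_size")
  expect_error(phantom_spec("malignant", spicule_count = 2), "spicule_count")
  expect_error(phantom_spec("benign", spicule_count = 3), "spicule_count")
  expect_error(phantom_spec("benign", noise_salt_pepper_frac = 1.5),
               "salt_pepper")
})

test_that("malignant margins are sharper than benign margins", {
  # margin-sharpness statistic: mean Sobel magnitude in a ring at the mass
  # boundary; spiculated masses must score higher than blurred discs
  mal <- generate_phantom(phantom_spec("malignant", image_size = 128,
                                       mass_radius = 16, spicule_count = 8,
                                       seed = 1))
  ben <- generate_phantom(phantom_spec("benign", image_size = 128,
                                       mass_radius = 16, seed = 1))
  expect_gt(sobel_ring_stat(mal$image, 16), sobel_ring_stat(ben$image, 16))
})

test_that("margin sharpness separates the classes across seeds", {
  wins <- 0L
  for (s in 1:50) {
    mal <- generate_phantom(phantom_spec("malignant", image_size = 64,
                                         mass_radius = 8, seed = s))
    ben <- generate_phantom(phantom_spec("benign", image_size = 64,
                                         mass_radius = 8, seed = s))
    if (sobel_ring_stat(mal$image, 8) > sobel_ring_stat(ben$image, 8))
      wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("salt-and-pepper noise hits the requested pixel fraction", {
  sp <- phantom_spec("ignorant", image_size = 64,
                     noise_salt_pepper_frac = 0.05,
                     noise_gaussian_sigma = 0, seed = 9)
  img <- generate_phantom(sp)$image
  # background texture stays far from the extremes, so every extreme pixel
  # is an injected impulse
  frac <- mean(img == 0 | img == 255)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("phantom datasets are balanced, deterministic and writable", {
  ds <- generate_phantom_dataset(10, phantom_spec("benign", image_size = 32),
                                 seed = 5)
  expect_length(ds$images, 30L)
  expect_equal(as.vector(table(ds$labels)), c(10L, 10L, 10L))
  ds2 <- generate_phantom_dataset(10, phantom_spec("benign", image_size = 32),
                                  seed = 5)
  expect_identical(ds$images, ds2$images)

  dir <- withr::local_tempdir()
  write_phantom_dataset(ds, dir)
  back <- read_phantom_dataset(dir)
  expect_identical(back$images[[7]], ds$images[[7]])
  expect_identical(as.character(back$labels), as.character(ds$labels))
})

test_that("simulated sources have the nominal accuracy and coupling", {
  sim <- simulate_source_pair(10000, 0.92, 0.95, seed = 7)
  expect_true(all(abs(rowSums(sim$source1) - 1) < 1e-9))
  expect_true(all(abs(rowSums(sim$source2) - 1) < 1e-9))
  acc1 <- mean(mass_classes()[max.col(sim$source1)] ==
                 as.character(sim$truth))
  expect_lt(abs(acc1 - 0.92), 0.01)

  exact <- simulate_source_pair(500, 1.0, 0.5, seed = 3)
  expect_true(all(mass_classes()[max.col(exact$source1)] ==
                    as.character(exact$truth)))

  co <- simulate_source_pair(5000, 0.9, 0.9, error_correlation = 1,
                             seed = 11)
  err1 <- mass_classes()[max.col(co$source1)] != as.character(co$truth)
  err2 <- mass_classes()[max.col(co$source2)] != as.character(co$truth)
  expect_identical(err1, err2)

  dir <- withr::local_tempdir()
  p <- file.path(dir, "sources.csv")
  write_source_pair(sim, p)
  back <- read_source_pair(p)
  expect_identical(as.character(back$truth), as.character(sim$truth))
  expect_equal(back$source1, sim$source1, tolerance = 1e-6,
               ignore_attr = TRUE)
})
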