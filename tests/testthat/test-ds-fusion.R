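test_that("probability triples map to mass functions by identity", {
  m <- probs_to_mass(c(0.7, 0.2, 0.1))
  expect_equal(unclass(m), c(benign = 0.7, malignant = 0.2,
                             ignorance = 0.1))
  m2 <- probs_to_mass(c(0.5, 0.5, 0.2))
  expect_equal(unname(unclass(m2)), c(0.5, 0.5, 0.2) / 1.2,
               tolerance = 1e-12)
  expect_equal(unname(unclass(probs_to_mass(c(1, 0, 0)))), c(1, 0, 0))
  expect_error(probs_to_mass(c(-0.1, 0.6, 0.5)), "nonnegative")
  expect_error(mass_function(0.5, 0.5, 0.5), "sum")
})

test_that("the conflict coefficient matches hand enumeration", {
  expect_equal(ds_conflict(c(1, 0, 0), c(1, 0, 0)), 0)
  m1 <- mass_function(0.8, 0.1, 0.1)
  m2 <- mass_function(0.6, 0.3, 0.1)
  expect_equal(ds_conflict(m1, m2, ds_frame("disjoint_singleton")), 0.48,
               tolerance = 1e-12)
  expect_equal(ds_conflict(m1, m2, ds_frame("classical_ds")), 0.30,
               tolerance = 1e-12)
})

test_that("Dempster combination reproduces the worked examples", {
  m1 <- mass_function(0.8, 0.1, 0.1)
  m2 <- mass_function(0.6, 0.3, 0.1)
  r <- ds_combine(m1, m2, ds_frame("disjoint_singleton"))
  expect_equal(unname(unclass(r$mass)), c(0.48, 0.03, 0.01) / 0.52,
               tolerance = 1e-12)
  expect_equal(r$k, 0.48, tolerance = 1e-12)
  expect_equal(r$K, 1 / 0.52, tolerance = 1e-12)
  expect_identical(r$label, "benign")

  rc <- ds_combine(m1, m2, ds_frame("classical_ds"))
  expect_equal(unname(unclass(rc$mass)), c(0.62, 0.07, 0.01) / 0.70,
               tolerance = 1e-12)
  expect_equal(rc$k, 0.30, tolerance = 1e-12)

  # vacuous mass is the identity under the classical reading
  vac <- mass_function(0, 0, 1)
  rv <- ds_combine(m1, vac, ds_frame("classical_ds"))
  expect_equal(unclass(rv$mass), unclass(m1), tolerance = 1e-12)

  err <- tryCatch(ds_combine(c(1, 0, 0), c(0, 1, 0)), error = identity)
  expect_s3_class(err, "ds_total_conflict")
  expect_match(conditionMessage(err), "benign")
  expect_match(conditionMessage(err), "malignant")
})

test_that("combination matches a brute-force enumerator on random masses", {
  set.seed(101)
  for (variant in c("disjoint_singleton", "classical_ds")) {
    frame <- ds_frame(variant)
    for (i in 1:250) {
      m1 <- random_mass(); m2 <- random_mass()
      want <- brute_force_combine(m1, m2, variant)
      got <- ds_combine(probs_to_mass(m1), probs_to_mass(m2), frame)
      expect_equal(got$k, want$k, tolerance = 1e-12)
      expect_equal(unname(unclass(got$mass)), want$mass, tolerance = 1e-12)
    }
  }
})

test_that("combination is commutative, normalized and agreement-monotone", {
  set.seed(55)
  for (i in 1:100) {
    m1 <- probs_to_mass(random_mass())
    m2 <- probs_to_mass(random_mass())
    for (variant in c("disjoint_singleton", "classical_ds")) {
      frame <- ds_frame(variant)
      a <- ds_combine(m1, m2, frame)
      b <- ds_combine(m2, m1, frame)
      expect_equal(unclass(a$mass), unclass(b$mass), tolerance = 1e-12)
      expect_equal(sum(a$mass), 1, tolerance = 1e-12)
      if (which.max(m1) == which.max(m2) && which.max(m1) != 3L)
        expect_identical(which.max(unclass(a$mass)), which.max(unclass(m1)))
    }
  }
})

test_that("folding over several masses is order-invariant classically", {
  set.seed(77)
  frame <- ds_frame("classical_ds")
  for (i in 1:50) {
    ms <- lapply(1:3, function(j) probs_to_mass(random_mass()))
    lr <- ds_combine_many(ms, frame)
    rl <- ds_combine_many(rev(ms), frame)
    expect_equal(unclass(lr$mass), unclass(rl$mass), tolerance = 1e-12)
  }
  single <- ds_combine_many(list(mass_function(0.2, 0.3, 0.5)))
  expect_equal(unname(unclass(single$mass)), c(0.2, 0.3, 0.5))
  expect_equal(single$k, 0)
  vacs <- lapply(1:4, function(i) mass_function(0, 0, 1))
  expect_equal(unname(unclass(ds_combine_many(vacs, frame)$mass)),
               c(0, 0, 1))
})

test_that("per-sample fusion decides labels and flags total conflicts", {
  p1 <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1))
  p2 <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.7, 0.1))
  out <- fuse_sources(p1, p2)
  expect_identical(out$decided_label, c("benign", "malignant"))
  expect_false(any(out$conflict_flag))
  expect_equal(out$m_benign + out$m_malignant + out$m_ignorance, c(1, 1),
               tolerance = 1e-12)

  conf <- fuse_sources(rbind(c(1, 0, 0)), rbind(c(0, 1, 0)))
  expect_true(conf$conflict_flag)
  expect_identical(conf$decided_label, "benign")  # equally confident: first

  empty <- fuse_sources(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3))
  expect_identical(nrow(empty), 0L)
  expect_error(fuse_sources(p1, p2[1, , drop = FALSE]), "equal length")
})

test_that("fusing independent sources beats either source alone", {
  sim <- simulate_source_pair(4000, 0.90, 0.93, error_correlation = 0,
                              seed = 13)
  fused <- fuse_sources(sim$source1, sim$source2)
  truth <- as.character(sim$truth)
  acc <- function(p) mean(mass_classes()[max.col(p)] == truth)
  expect_gt(mean(fused$decided_label == truth),
            max(acc(sim$source1), acc(sim$source2)))
})
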