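test_that("degenerate parameters give a flat plate at z = 0", {
  flat <- generateBaseSurface(extent = c(4, 4), domeRadii = c(Inf, Inf),
                              rippleAmplitude = 0,
                              undulationAmplitude = 0, spacing = 0.2)
  expect_true(all(abs(vertices(flat)[, 3]) < 1e-12))
})

test_that("surface generation is deterministic in the seed", {
  a <- generateBaseSurface(extent = c(4, 4), spacing = 0.2, seed = 77)
  b <- generateBaseSurface(extent = c(4, 4), spacing = 0.2, seed = 77)
  cc <- generateBaseSurface(extent = c(4, 4), spacing = 0.2, seed = 78)
  expect_identical(vertices(a), vertices(b))
  expect_false(identical(vertices(a), vertices(cc)))
})

test_that("the default grid matches the scanner point spacing", {
  m <- generateBaseSurface()
  expect_identical(nVertices(m), 107L * 107L)
  expect_identical(attr(m, "spacing"), 0.075)
})

test_that("adhesive profiles carry closed-form true volumes", {
  s <- seq(-4, 4, by = 0.075)
  base <- gridSurface(s, s, 0)
  cap <- addAdhesive(base, shape = "spherical_cap", dim = c(1, 0.3))
  expect_equal(cap$trueVolume, pi * 0.09 * 2.7 / 3, tolerance = 1e-12)
  # the discretized profile integrates to the closed form
  dz <- vertices(cap$mesh)[, 3] - vertices(base)[, 3]
  expect_equal(sum(dz) * 0.075^2, cap$trueVolume, tolerance = 0.01)

  pad <- addAdhesive(base, shape = "flat_pad", dim = c(2, 2, 0.1))
  expect_equal(pad$trueVolume, 0.4, tolerance = 1e-12)

  zero <- addAdhesive(base, shape = "spherical_cap", dim = c(1, 0))
  expect_identical(vertices(zero$mesh), vertices(base))
  expect_identical(zero$trueVolume, 0)

  expect_error(addAdhesive(base, center = c(3.8, 0),
                           shape = "spherical_cap", dim = c(1, 0.5)),
               "parameter error")
})

test_that("clean-up limits reproduce the exact end states", {
  s <- seq(-4, 4, by = 0.1)
  base <- gridSurface(s, s, 0)
  bonded <- addAdhesive(base, shape = "flat_pad", dim = c(2, 2, 0.4))$mesh
  full <- simulateCleanup(bonded, base, removalFraction = 1)
  expect_equal(vertices(full$mesh), vertices(base), tolerance = 1e-15)
  none <- simulateCleanup(bonded, base, removalFraction = 0)
  expect_identical(vertices(none$mesh), vertices(bonded))
  expect_identical(none$trueEVL, 0)
  half <- simulateCleanup(bonded, base, removalFraction = 0.5)
  expect_equal(vertices(half$mesh)[, 3],
               (vertices(base)[, 3] + vertices(bonded)[, 3]) / 2,
               tolerance = 1e-15)
  expect_error(
    simulateCleanup(bonded, base, removalFraction = 1,
                    dents = list(list(center = c(2, 2), r = 1,
                                      depth = 0.6))),
    "physical bound")
})

test_that("scan noise has the configured magnitude and pose bounds", {
  s <- seq(-3, 3, by = 0.1)
  base <- gridSurface(s, s, 0)
  set.seed(3)
  clean <- applyScanNoise(base, sigma = 0, poseAngleDeg = 0,
                          poseTransMm = 0)
  expect_identical(vertices(clean$mesh), vertices(base))
  expect_equal(rotationAngle(clean$pose), 0)

  set.seed(4)
  noisy <- applyScanNoise(base, sigma = 0.007, poseAngleDeg = 0,
                          poseTransMm = 0)
  disp <- sqrt(mean((vertices(noisy$mesh)[, 3] - vertices(base)[, 3])^2))
  expect_lt(abs(disp - 0.007) / 0.007, 0.10)

  set.seed(5)
  posed <- applyScanNoise(base, sigma = 0, poseAngleDeg = 2,
                          poseTransMm = 0.5)
  expect_lte(rotationAngle(posed$pose), sqrt(3) * 2 * pi / 180 + 1e-9)
  expect_true(all(abs(posed$pose@translation) <= 0.5))
})

test_that("the study generator is reproducible and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generateStudy(seed = 31, params = miniStudyParams(), dir = d1)
  s2 <- generateStudy(seed = 31, params = miniStudyParams(), dir = d2)
  expect_length(s1$triplets, 9L)
  expect_identical(nrow(s1$groundTruth), 9L)
  expect_identical(length(list.files(d1, pattern = "\\.stl$")), 27L)
  expect_identical(unname(tools::md5sum(file.path(d1, "ground_truth.csv"))),
                   unname(tools::md5sum(file.path(d2, "ground_truth.csv"))))
  expect_identical(vertices(s1$triplets[[1]]@t1),
                   vertices(s2$triplets[[1]]@t1))
  # ground-truth internal consistency
  gt <- s1$groundTruth
  expect_equal(gt$true_RAV, gt$true_dAV * gt$true_AV, tolerance = 1e-12)
  expect_true(all(gt$true_AV >= 0.1 & gt$true_AV <= 1.5))
  expect_true(all(gt$true_EVL >= 0.001 & gt$true_EVL <= 1.104))
})

test_that("full removal without noise leaves no residual adhesive", {
  st <- cachedStudy("nullcleanup", seed = 41,
                    params = c(miniStudyParams(),
                               list(sigma = 0, davMean = c(1e-9, 1e-9, 1e-9),
                                    davShape1 = 1e6)))
  tri <- st$triplets[[1]]
  al <- alignTriplet(tri)
  roi <- placeROI(signedDeviation(al@t1, al@t0))
  rep <- computeVolumeReport(al, roi, volumetryConfig(clearance = 0))
  expect_lt(rep$RAV_mm3, 1e-3)
})
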