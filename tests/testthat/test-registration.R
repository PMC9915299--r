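test_that("rigid transforms compose, invert and apply correctly", {
  t1 <- rigidTransform(rotationAboutZ(0.3), c(1, -2, 0.5))
  t2 <- rigidTransform(rotationAboutX(-0.2), c(0, 1, 2))
  m <- testSurface()
  expect_equal(vertices(applyTransform(m, identityTransform())),
               vertices(m))
  # group property: t then inverse(t)
  back <- applyTransform(applyTransform(m, t1), invertTransform(t1))
  expect_equal(vertices(back), vertices(m), tolerance = 1e-12)
  # composition order: apply(apply(m, a), b) == apply(m, b o a)
  two <- applyTransform(applyTransform(m, t1), t2)
  one <- applyTransform(m, composeTransforms(t2, t1))
  expect_equal(vertices(two), vertices(one), tolerance = 1e-12)
})

test_that("aligning a mesh to itself returns the identity", {
  m <- testSurface()
  tr <- bestFitAlign(m, m)
  expect_lt(max(abs(tr@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tr@translation)), 1e-9)
})

test_that("a known small pose is recovered on noise-free surfaces", {
  ref <- testSurface(seed = 3)
  pose <- rigidTransform(rotationAboutZ(2 * pi / 180),
                         c(0.1, -0.05, 0.02))
  moving <- applyTransform(ref, pose)
  tr <- bestFitAlign(moving, ref)
  err <- composeTransforms(tr, pose)
  expect_lt(rotationAngle(err), 1e-3)
  expect_lt(sqrt(sum(err@translation^2)), 1e-3)
})

test_that("pose recovery tolerates scanner-level Gaussian noise", {
  set.seed(11)
  ref <- testSurface(seed = 4, ext = 6, sp = 0.075)
  n0 <- applyScanNoise(ref, sigma = 0.007, poseAngleDeg = 0,
                       poseTransMm = 0)
  n1 <- applyScanNoise(ref, sigma = 0.007, poseAngleDeg = 2,
                       poseTransMm = 0.5)
  tr <- bestFitAlign(n1$mesh, n0$mesh)
  err <- composeTransforms(tr, n1$pose)
  expect_lt(rotationAngle(err), 0.01)
  expect_lt(sqrt(sum(err@translation^2)), 0.01)
  expect_lt(attr(tr, "rms"), 3 * 0.007)
})

test_that("recovery of 100 random small poses has sub-micron median error", {
  ref <- testSurface(seed = 5)
  set.seed(42)
  errs <- vapply(1:100, function(i) {
    ang <- stats::runif(3, -2, 2) * pi / 180
    pose <- rigidTransform(
      rotationAboutZ(ang[3]) %*% rotationAboutY(ang[2]) %*%
        rotationAboutX(ang[1]),
      stats::runif(3, -0.5, 0.5))
    tr <- bestFitAlign(applyTransform(ref, pose), ref, maxPoints = 1200L)
    err <- composeTransforms(tr, pose)
    c(rotationAngle(err), sqrt(sum(err@translation^2)))
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 1e-3)
  expect_lt(stats::median(errs[2, ]), 1e-3)
})

test_that("accepted ICP iterations never increase the residual", {
  set.seed(12)
  ref <- testSurface(seed = 6)
  n1 <- applyScanNoise(ref, sigma = 0.007, poseAngleDeg = 2,
                       poseTransMm = 0.5)
  tr <- bestFitAlign(n1$mesh, ref)
  hist <- attr(tr, "rmsHistory")
  expect_gte(length(hist), 2)
  expect_true(all(diff(hist) <= 1e-12))
})

test_that("masks gate the fit and tiny masks are rejected", {
  m <- testSurface()
  expect_error(bestFitAlign(m, m, mask = 1:50), "mask error.*100")
  # geometric predicate mask selects the annulus
  tr <- bestFitAlign(m, m, mask = list(center = c(0, 0, 0),
                                       minDistance = 1))
  expect_lt(max(abs(tr@translation)), 1e-9)
})

test_that("signed deviations carry the material-above convention", {
  s <- seq(-2, 2, by = 0.2)
  ref <- gridSurface(s, s, 0)
  above <- gridSurface(s, s, 0.3)
  below <- gridSurface(s, s, -0.3)
  dup <- signedDeviation(above, ref)
  expect_true(all(abs(dup@distance[dup@matched] - 0.3) < 1e-9))
  ddn <- signedDeviation(below, ref)
  expect_true(all(abs(ddn@distance[ddn@matched] + 0.3) < 1e-9))
  dz <- signedDeviation(ref, ref)
  expect_true(all(abs(dz@distance[dz@matched]) < 1e-12))
})

test_that("deviation maps are antisymmetric on smooth overlapping patches", {
  a <- testSurface(seed = 7)
  b <- applyTransform(a, rigidTransform(diag(3), c(0, 0, 0.05)))
  dab <- signedDeviation(a, b)
  dba <- signedDeviation(b, a)
  # compare summary magnitudes (vertex sets differ near edges)
  ma <- stats::median(dab@distance[dab@matched])
  mb <- stats::median(dba@distance[dba@matched])
  expect_equal(ma, -mb, tolerance = 0.01)
})

test_that("disjoint surfaces raise an error", {
  s <- seq(-1, 1, by = 0.2)
  a <- gridSurface(s, s, 0)
  b <- gridSurface(s, s, 5)
  expect_error(signedDeviation(a, b, searchRadius = 0.5), "disjoint")
})
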