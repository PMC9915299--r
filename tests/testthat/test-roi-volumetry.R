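# deviation map of a bump fixture: flat reference vs raised test surface
bumpDeviation <- function(center = c(2, 3), A = 0.3, sg = 0.5,
                          ext = 10, sp = 0.1) {
  s <- seq(-ext / 2, ext / 2, by = sp)
  ref <- gridSurface(s, s, 0, "ref")
  test <- addAdhesive(gridSurface(s, s, 0, "test"), center = center,
                      shape = "gaussian_bump", dim = c(A, sg))$mesh
  signedDeviation(test, ref)
}

test_that("the ROI centers on the adhesive signal", {
  dev <- bumpDeviation(center = c(2, 3))
  roi <- placeROI(dev)
  expect_lt(sqrt(sum((roi@center[1:2] - c(2, 3))^2)), 0.1)
  expect_equal(roi@side, 5)
  # frame of a flat field is the identity viewing direction
  expect_lt(max(abs(roi@frame[, 3] - c(0, 0, 1))), 1e-6)
})

test_that("a manual ROI override is echoed exactly", {
  dev <- bumpDeviation()
  ov <- list(center = c(1, -1, 0.25), frame = diag(3), side = 4,
             bottomZ = -2, topZ = 3)
  roi <- placeROI(dev, override = ov)
  expect_identical(roi@center, c(1, -1, 0.25))
  expect_identical(roi@side, 4)
  expect_identical(roi@bottomZ, -2)
})

test_that("a flat field with no signal fails placement", {
  s <- seq(-3, 3, by = 0.2)
  flat <- gridSurface(s, s, 0)
  dev <- signedDeviation(flat, flat)
  expect_error(placeROI(dev), "placement error")
})

test_that("clipping isolates exactly the ROI prism", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = -1, topZ = 2)
  patch <- clipToROI(flatPlate(0.5), roi)
  v <- vertices(patch)
  expect_true(all(v[, 1] >= -2.5 - 1e-9 & v[, 1] <= 2.5 + 1e-9))
  expect_true(all(v[, 2] >= -2.5 - 1e-9 & v[, 2] <= 2.5 + 1e-9))
  expect_equal(meshArea(patch), 25, tolerance = 1e-6)
  # boundary vertices introduced by the cut lie on the lateral planes
  rep <- validateMesh(patch)
  expect_false(rep$watertight)
  onplane <- abs(abs(v[, 1]) - 2.5) < 1e-9 | abs(abs(v[, 2]) - 2.5) < 1e-9
  interior <- abs(v[, 1]) < 2.5 - 1e-9 & abs(v[, 2]) < 2.5 - 1e-9
  expect_true(all(onplane | interior))
})

test_that("a mesh fully inside the ROI is unchanged by clipping", {
  roi <- roiBox(center = c(0, 0, 0), side = 8, bottomZ = -1, topZ = 2)
  small <- flatPlate(0.5, ext = 5)
  patch <- clipToROI(small, roi)
  expect_equal(nVertices(patch), nVertices(small))
  expect_equal(meshArea(patch), meshArea(small), tolerance = 1e-12)
})

test_that("a disjoint mesh raises a clip error", {
  roi <- roiBox(center = c(50, 50, 0), side = 5, bottomZ = -1, topZ = 2)
  expect_error(clipToROI(flatPlate(0.5), roi), "clip error")
})

test_that("shell closure reproduces analytic prism volumes", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  flat <- closeShell(clipToROI(flatPlate(0.5), roi), roi)
  expect_true(isWatertight(flat))
  expect_equal(enclosedVolume(flat), 12.5, tolerance = 1e-9)
  # tilted plane, mean height 0.5 over the square
  tilted <- clipToROI(flatPlate(0, ext = 10, sp = 0.25) |>
                        (\(m) {
                          m@vertices[, 3] <- 0.1 * m@vertices[, 1] + 0.5
                          m
                        })(), roi)
  expect_equal(enclosedVolume(closeShell(tilted, roi)), 12.5,
               tolerance = 1e-9)
})

test_that("a patch touching the bottom plane still closes watertight", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0.5, topZ = 2)
  sh <- closeShell(clipToROI(flatPlate(0.5), roi), roi)
  expect_true(isWatertight(sh))
  expect_gte(enclosedVolume(sh), 0)
})

test_that("Boolean self-subtraction is exactly zero", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  a <- closeShell(clipToROI(stepPlate(), roi), roi)
  expect_identical(booleanDifferenceVolume(a, a), 0)
})

test_that("the clearance-offset slab volume matches the closed form", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  a <- closeShell(clipToROI(stepPlate(height = 0.5), roi), roi)
  b <- closeShell(clipToROI(flatPlate(0.5, sp = 0.05), roi), roi)
  v <- booleanDifferenceVolume(a, b, volumetryConfig())
  expect_lt(abs(v - 0.480) / 0.480, 0.005)
  # threshold mode counts the full deviation
  vth <- booleanDifferenceVolume(a, b,
                                 volumetryConfig(clearanceMode = "threshold"))
  expect_lt(abs(vth - 0.500) / 0.500, 0.005)
})

test_that("sub-clearance deviations are suppressed in both modes", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  a <- closeShell(clipToROI(stepPlate(height = 0.015), roi), roi)
  b <- closeShell(clipToROI(flatPlate(0.5, sp = 0.05), roi), roi)
  expect_identical(booleanDifferenceVolume(a, b, volumetryConfig()), 0)
  expect_identical(
    booleanDifferenceVolume(a, b,
                            volumetryConfig(clearanceMode = "threshold")),
    0)
})

test_that("measured volume is monotone non-increasing in clearance", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  a <- closeShell(clipToROI(stepPlate(height = 0.3), roi), roi)
  b <- closeShell(clipToROI(flatPlate(0.5, sp = 0.05), roi), roi)
  for (mode in c("offset", "threshold")) {
    vols <- vapply(c(0, 0.01, 0.02, 0.05, 0.1), function(cl)
      booleanDifferenceVolume(a, b, volumetryConfig(
        clearance = cl, clearanceMode = mode)), numeric(1))
    expect_true(all(diff(vols) <= 1e-12))
  }
})

test_that("halving the integration step changes volumes by < 0.25%", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = -1, topZ = 2)
  base <- generateBaseSurface(extent = c(7, 7), spacing = 0.1, seed = 21)
  ad <- addAdhesive(base, center = c(0.2, -0.3),
                    shape = "spherical_cap", dim = c(0.8, 0.5))
  a <- closeShell(clipToROI(ad$mesh, roi), roi)
  b <- closeShell(clipToROI(base, roi), roi)
  v1 <- booleanDifferenceVolume(a, b, volumetryConfig())
  v2 <- booleanDifferenceVolume(a, b,
                                volumetryConfig(integrationStep = 0.005))
  expect_lt(abs(v1 - v2) / v2, 0.0025)
})

test_that("shells from different ROIs refuse Boolean subtraction", {
  roi1 <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  roi2 <- roiBox(center = c(0.5, 0, 0), side = 5, bottomZ = 0, topZ = 2)
  a <- closeShell(clipToROI(flatPlate(0.5), roi1), roi1)
  b <- closeShell(clipToROI(flatPlate(0.5), roi2), roi2)
  expect_error(booleanDifferenceVolume(a, b), "contract error")
})

test_that("pipeline volumes agree with the voxel-counting oracle", {
  roi <- roiBox(center = c(0, 0, 0), side = 5, bottomZ = -1, topZ = 2)
  base <- generateBaseSurface(extent = c(7, 7), spacing = 0.1, seed = 22)
  ad <- addAdhesive(base, center = c(0, 0), shape = "spherical_cap",
                    dim = c(1, 0.5))
  a <- closeShell(clipToROI(ad$mesh, roi), roi)
  b <- closeShell(clipToROI(base, roi), roi)
  for (cfg in list(volumetryConfig(),
                   volumetryConfig(clearanceMode = "threshold"))) {
    v <- booleanDifferenceVolume(a, b, cfg)
    o <- voxelOracleVolume(a, b, cfg)
    expect_lt(abs(v - o) / max(o, 1e-3), 0.005)
  }
})

test_that("an identical triplet yields zero volumes and undefined dAV", {
  base <- generateBaseSurface(extent = c(7, 7), spacing = 0.1, seed = 23)
  tri <- new("ScanTriplet", toothId = "null", group = 1L, t0 = base,
             t1 = base, t2 = base)
  roi <- roiBox(center = c(0, 0, base@vertices[1, 3]), side = 5,
                bottomZ = -2, topZ = 2)
  rep <- computeVolumeReport(tri, roi)
  expect_identical(rep$AV_mm3, 0)
  expect_identical(rep$RAV_mm3, 0)
  expect_identical(rep$EVL_mm3, 0)
  expect_true(is.na(rep$dAV))
})

test_that("known added and carved volumes are recovered per tooth", {
  base <- generateBaseSurface(extent = c(7, 7), spacing = 0.075,
                              seed = 24)
  ad <- addAdhesive(base, center = c(0.1, 0), shape = "spherical_cap",
                    dim = .capForVolume2(0.3, 0.55))
  cl <- simulateCleanup(ad$mesh, base, removalFraction = 1,
                        dents = list(list(center = c(1.6, 0.4), r = 0.45,
                                          depth = 0.42)))
  tri <- new("ScanTriplet", toothId = "gt", group = 1L, t0 = base,
             t1 = ad$mesh, t2 = cl$mesh)
  dev <- signedDeviation(tri@t1, tri@t0)
  roi <- placeROI(dev)
  # exact data: measure without clearance
  rep0 <- computeVolumeReport(tri, roi, volumetryConfig(clearance = 0))
  expect_lt(abs(rep0$AV_mm3 - ad$trueVolume) / ad$trueVolume, 0.02)
  expect_lt(rep0$RAV_mm3, 1e-3)
  expect_lt(abs(rep0$EVL_mm3 - cl$trueEVL) / cl$trueEVL, 0.02)
  # with clearance the estimate shrinks by at most clearance x footprint
  rep <- computeVolumeReport(tri, roi, volumetryConfig())
  expect_lt(rep$AV_mm3, ad$trueVolume)
  expect_gt(rep$AV_mm3, ad$trueVolume - 0.02 * 3.5)
})

test_that("half-removal yields a relative residual fraction near 0.5", {
  base <- generateBaseSurface(extent = c(7, 7), spacing = 0.075,
                              seed = 25)
  ad <- addAdhesive(base, center = c(0, 0), shape = "flat_pad",
                    dim = c(2, 2, 0.4))
  cl <- simulateCleanup(ad$mesh, base, removalFraction = 0.5)
  tri <- new("ScanTriplet", toothId = "half", group = 1L, t0 = base,
             t1 = ad$mesh, t2 = cl$mesh)
  roi <- placeROI(signedDeviation(tri@t1, tri@t0))
  rep <- computeVolumeReport(tri, roi, volumetryConfig(clearance = 0))
  expect_equal(rep$dAV, 0.5, tolerance = 0.05)
})
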