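test_that("fisherZ is the clamped arctanh: fixed point, closed form, oddness", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZ(-rs), -fisherZ(rs))
  expect_true(all(diff(fisherZ(rs)) > 0))
  expect_true(is.finite(fisherZ(1)) && is.finite(fisherZ(-1)))
  expect_error(fisherZ(1.01), "outside")
})

test_that("gray-matter mask thresholding is strict and matches a direct scan", {
  all05 <- array(0.5, dim = c(4, 4, 4))
  expect_equal(maskSize(buildGrayMask(all05, 0.2)), 64L)
  boundary <- array(0.2, dim = c(4, 4, 4))
  expect_error(buildGrayMask(boundary, 0.2), "empty")
  set.seed(31)
  prob <- array(runif(6 * 5 * 4), dim = c(6, 5, 4))
  m <- buildGrayMask(prob, 0.2)
  expect_equal(maskSize(m), sum(prob > 0.2))
  # deterministic ordering: first axis fastest
  expect_true(all(diff(maskLinearIndicesOracle(m)) > 0))
})

test_that("GFC fast path equals the brute-force all-pairs oracle", {
  set.seed(101)
  for (dims in list(c(3, 3, 3, 20), c(4, 4, 4, 50), c(6, 6, 6, 60))) {
    vs <- randomVolumeSeries(dims, seed = sum(dims))
    mask <- buildGrayMask(array(1, dim = dims[1:3]), 0.2)
    X <- matrix(vs@data, prod(dims[1:3]), dims[4])
    for (zo in c("z_of_mean_r", "mean_of_z")) {
      got <- gfcValues(computeGFC(vs, mask, zOrder = zo, blockSize = 37L))
      want <- bruteForceGFC(X, zo)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("GFC handles degenerate correlation structure finitely", {
  # identical series at every voxel: all pairwise r = 1, clamped
  base <- sin(seq_len(30))
  arr <- array(rep(base, each = 8), dim = c(2, 2, 2, 30))
  vs <- new("VolumeSeries", data = arr, affine = diag(4), tr = 2,
            subjectId = "ident")
  mask <- buildGrayMask(array(1, dim = c(2, 2, 2)), 0.2)
  g <- gfcValues(computeGFC(vs, mask))
  expect_true(all(is.finite(g)))
  expect_equal(g, rep(atanh(1 - 1e-7), 8))
  # two orthogonal series: r = 0, GFC = 0
  t2 <- seq_len(32)
  arr2 <- array(0, dim = c(2, 1, 1, 32))
  arr2[1, 1, 1, ] <- sin(2 * pi * t2 / 8)
  arr2[2, 1, 1, ] <- cos(2 * pi * t2 / 8)
  vs2 <- new("VolumeSeries", data = arr2, affine = diag(4), tr = 2,
             subjectId = "orth")
  m2 <- buildGrayMask(array(1, dim = c(2, 1, 1)), 0.2)
  expect_equal(gfcValues(computeGFC(vs2, m2)), c(0, 0), tolerance = 1e-12)
})

test_that("GFC is invariant to positive affine rescaling and flips with sign", {
  dims <- c(4, 4, 3, 40)
  vs <- randomVolumeSeries(dims, seed = 77)
  mask <- buildGrayMask(array(1, dim = dims[1:3]), 0.2)
  ref <- gfcValues(computeGFC(vs, mask))
  # a * x + b with a > 0 at one voxel leaves the map unchanged
  vs2 <- vs
  vs2@data[2, 3, 1, ] <- 2.5 * vs2@data[2, 3, 1, ] + 7
  expect_equal(gfcValues(computeGFC(vs2, mask)), ref, tolerance = 1e-9)
  # negating one voxel flips its correlations; map matches the oracle
  vs3 <- vs
  vs3@data[1, 1, 1, ] <- -vs3@data[1, 1, 1, ]
  X3 <- matrix(vs3@data, prod(dims[1:3]), dims[4])
  expect_equal(gfcValues(computeGFC(vs3, mask)), bruteForceGFC(X3),
               tolerance = 1e-10)
})

test_that("z-transform orders agree to first order for weak correlations", {
  # weakly correlated noise keeps |r| small, where atanh is near-linear
  set.seed(5)
  dims <- c(5, 5, 4, 200)
  vs <- randomVolumeSeries(dims, seed = 5)
  mask <- buildGrayMask(array(1, dim = dims[1:3]), 0.2)
  a <- gfcValues(computeGFC(vs, mask, "z_of_mean_r"))
  b <- gfcValues(computeGFC(vs, mask, "mean_of_z"))
  expect_lt(max(abs(a - b)), 0.01)
})

test_that("zero-variance voxels are rejected, then dropped on request", {
  dims <- c(3, 3, 3, 25)
  vs <- randomVolumeSeries(dims, seed = 9)
  mask <- buildGrayMask(array(1, dim = dims[1:3]), 0.2)
  expect_identical(suppressMessages(dropConstantVoxels(vs, mask)), mask)
  set.seed(12)
  kill <- sample(27, 4)
  flat <- matrix(vs@data, 27, 25)
  flat[kill, ] <- 3.14
  vs@data <- array(flat, dim = dims)
  expect_error(computeGFC(vs, mask), "zero-variance")
  shrunk <- suppressMessages(dropConstantVoxels(vs, mask))
  expect_equal(maskSize(shrunk), 27L - 4L)
  keptLin <- maskLinearIndicesOracle(shrunk)
  expect_true(!any(kill %in% keptLin))
  expect_silent(computeGFC(vs, shrunk))
})

test_that("minimal preprocessing: detrend, band-pass pass/stop behaviour", {
  dims <- c(2, 2, 1, 100)
  tt <- seq_len(100)
  mkvs <- function(series) {
    arr <- array(rep(series, each = 4), dim = dims)
    new("VolumeSeries", data = arr, affine = diag(4), tr = 2,
        subjectId = "pp")
  }
  # constant series detrends to zero
  out <- preprocessMinimal(mkvs(rep(5, 100)), detrend = TRUE)
  expect_lt(max(abs(out@data)), 1e-10)
  # 0.05 Hz sinusoid survives a 0.01-0.08 Hz band-pass (TR 2 s)
  inband <- sin(2 * pi * 0.05 * 2 * tt)
  out2 <- preprocessMinimal(mkvs(inband), bandpass = c(0.01, 0.08))
  expect_lt(max(abs(out2@data[1, 1, 1, ] - inband)), 1e-8)
  # 0.2 Hz sinusoid is rejected
  outband <- sin(2 * pi * 0.2 * 2 * tt)
  out3 <- preprocessMinimal(mkvs(outband), bandpass = c(0.01, 0.08))
  expect_lt(max(abs(out3@data)), 1e-8 * max(abs(outband)))
  expect_error(preprocessMinimal(mkvs(inband), bandpass = c(0.01, 0.3)),
               "Nyquist")
  # motion regression removes a motion-locked component exactly
  set.seed(4)
  mot <- new("MotionTrace", params = matrix(rnorm(600), 100, 6),
             subjectId = "pp")
  contaminated <- mkvs(2 * mot@params[, 1] - mot@params[, 5])
  out4 <- preprocessMinimal(contaminated, motion = mot, regressMotion = TRUE)
  expect_lt(max(abs(out4@data)), 1e-10)
})
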