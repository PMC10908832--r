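test_that("normalization maps linearly, clips, and flags degenerate ranges", {
  x <- matrix(c(0, 25, 50, 100), 2, 2)
  n <- normalizeSlice(x, 0, 100)
  expect_equal(as.vector(n), c(0, 0.25, 0.5, 1))
  expect_false(attr(n, "constant"))

  expect_equal(normalizeSlice(matrix(150, 1, 1), 0, 100)[1, 1], 1)
  expect_equal(normalizeSlice(matrix(-5, 1, 1), 0, 100)[1, 1], 0)

  k <- normalizeSlice(matrix(7, 3, 3), 7, 7)
  expect_true(all(k == 0))
  expect_true(attr(k, "constant"))
})

test_that("denormalize inverts normalize exactly on integer ranges", {
  expect_equal(denormalizeSlice(matrix(0.5, 1, 1), 0, 100, "uint16")[1, 1],
               50)
  # exhaustive roundtrip on a small range
  lo <- 3; hi <- 200
  x <- matrix(lo:hi, nrow = 1)
  back <- denormalizeSlice(normalizeSlice(x, lo, hi), lo, hi, "uint16")
  expect_identical(back, x + 0)
  # out-of-range values clamp to the dtype bounds
  expect_equal(denormalizeSlice(matrix(1.2, 1, 1), 0, 65535, "uint16")[1, 1],
               65535)
  expect_equal(denormalizeSlice(matrix(-0.2, 1, 1), 0, 255, "uint8")[1, 1],
               0)
})

test_that("intervalIndex uses the lower-closed convention with top clamp", {
  expect_identical(intervalIndex(0.5, 500), 125)
  expect_identical(intervalIndex(0, 500), 0)
  expect_identical(intervalIndex(2.0, 500), 499)
  # boundary 2i/beta belongs to interval i
  expect_identical(intervalIndex(2 * 125 / 500, 500), 125)
  expect_identical(intervalIndex(seq(0, 2, by = 0.5), 4), c(0, 1, 2, 3, 3))
})

test_that("embedBlock realizes the quantization concealment rule", {
  beta <- 500
  cover <- matrix(0, 4, 4)
  cover[1, 1] <- 2.5   # DC, must pass through untouched
  cover[2, 3] <- 0.5
  cover[3, 2] <- -0.5
  msg <- matrix(0, 4, 4)
  msg[2, 3] <- 0.25
  msg[3, 2] <- 0.25
  st <- embedBlock(cover, msg, beta)
  expect_equal(st[2, 3], (2 / 500) * (0.25 + 125))   # 0.5010
  expect_equal(st[2, 3], 0.5010)
  expect_equal(st[3, 2], -0.5010)                    # sign carried
  expect_identical(st[1, 1], cover[1, 1])            # DC bit-equal
  # m = 0 lands on the lower interval boundary
  cover2 <- matrix(0.5, 4, 4)
  st2 <- embedBlock(cover2, matrix(0, 4, 4), beta)
  expect_equal(st2[2, 2], 0.5)
})

test_that("extractBlock inverts embedBlock and is sign-invariant", {
  beta <- 500
  st <- matrix(0.1, 4, 4)
  st[2, 3] <- 0.5010
  ex <- extractBlock(st, beta)
  expect_equal(ex[2, 3], 0.25, tolerance = 1e-9)
  st[2, 3] <- -0.5010
  expect_equal(extractBlock(st, beta)[2, 3], 0.25, tolerance = 1e-9)
  # DC position is refilled from its two nearest neighbors
  expect_equal(ex[1, 1], (ex[1, 2] + ex[2, 1]) / 2)
})

test_that("embed/extract roundtrip recovers all detail positions", {
  for (beta in c(100, 500, 1000)) {
    for (s in 1:60) {
      cb <- matrix(seededRunif(16, 1000 * beta + s, -2, 2), 4, 4)
      cb[1, 1] <- seededRunif(1, 2000 * beta + s, 0, 4)
      mb <- matrix(seededRunif(16, 3000 * beta + s, 0, 1 - 2^-12), 4, 4)
      rec <- extractBlock(embedBlock(cb, mb, beta), beta)
      expect_lt(max(abs((rec - mb)[-1])), 1e-9)
      expect_lt(max(abs((rec - mb)[1, -1])), 1e-9)
    }
  }
})

test_that("embedding preserves the quantization interval index", {
  beta <- 200
  cGrid <- seq(0.0005, 1.995, length.out = 60)
  mGrid <- c(0, 0.37, 0.93, 1 - 2^-12)
  for (cv in cGrid) for (m in mGrid) {
    cb <- matrix(0, 4, 4); cb[2, 2] <- cv
    mb <- matrix(0, 4, 4); mb[2, 2] <- m
    st <- embedBlock(cb, mb, beta)
    expect_identical(intervalIndex(abs(st[2, 2]), beta),
                     intervalIndex(cv, beta))
  }
})

test_that("sign symmetry: embedding into -c extracts the same message", {
  beta <- 300
  cb <- matrix(seededRunif(16, 7, -2, 2), 4, 4)
  mb <- matrix(seededRunif(16, 8, 0, 0.99), 4, 4)
  a <- extractBlock(embedBlock(cb, mb, beta), beta)
  b <- extractBlock(embedBlock(-cb, mb, beta), beta)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("slice-level float-domain chain recovers the message exactly", {
  m <- 24; n <- 20
  cover <- matrix(seededRunif(m * n, 11), m, n)
  msg <- matrix(seededRunif(m * n, 12, 0, 1 - 2^-11), m, n)
  st <- embedSlice(cover, msg, beta = 500, range = c(0, 1),
                   dtype = "float64")
  rec <- extractSlice(st, beta = 500, range = c(0, 1), dtype = "float64",
                      medianFilter = FALSE)
  dc <- outer((seq_len(m) - 1) %% 4 == 0, (seq_len(n) - 1) %% 4 == 0, `&`)
  expect_lt(max(abs(rec - msg)[!dc]), 1e-9)
  expect_identical(dim(st), dim(cover))
})

test_that("integer end-to-end slice pair meets the expected quality", {
  v <- generatePhantom(c(64, 64, 4), seed = 3)
  cover <- volData(v)[, , 1]
  msg <- volData(v)[, , 2]
  rng <- volRange(v)
  # hiding a slice inside itself still distorts little
  stSelf <- embedSlice(cover, cover, beta = 500, range = rng)
  p <- psnr(cover, stSelf, 65535)
  expect_true(is.finite(p) && p > 40)
  # cross-slice hide + blind extract, beta = 100
  st <- embedSlice(cover, msg, beta = 100, range = rng)
  rec <- extractSlice(st, beta = 100, range = rng)
  expect_gt(ssim(msg, rec, 65535), 0.90)
})

test_that("a constant cover passes through unchanged", {
  cover <- matrix(42, 16, 16)
  msg <- waveSlice(16, 16)
  st <- embedSlice(cover, msg, beta = 500, range = NULL)
  expect_identical(st, cover)
  expect_identical(extractSlice(matrix(7, 8, 8), beta = 500),
                   matrix(7, 8, 8))
})

test_that("median filter removes impulses and respects padding modes", {
  x <- matrix(10, 9, 9)
  x[5, 5] <- 1000
  y <- medianFilter3x3(x)
  expect_equal(y[5, 5], 10)
  # interior of a constant slice stays put under both paddings
  z0 <- medianFilter3x3(matrix(7, 5, 5), "zero")
  zr <- medianFilter3x3(matrix(7, 5, 5), "replicate")
  expect_true(all(z0[2:4, 2:4] == 7))
  expect_true(all(zr == 7))
  # zero padding pulls down the corners (median of 4 values + 5 zeros)
  expect_equal(z0[1, 1], 0)
  expect_equal(medianFilter3x3(matrix(1:9, 3, 3, byrow = TRUE))[2, 2], 5)
})
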