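# Brute-force local-window SSIM, independent of the banded-matrix
# implementation: explicit loops over every fully-contained 11x11 window.
bruteSsim <- function(f, g, peakval) {
  k <- 11L
  x <- seq_len(k) - 6
  w <- exp(-x^2 / (2 * 1.5^2))
  w <- outer(w, w)
  w <- w / sum(w)
  c1 <- (0.01 * peakval)^2
  c2 <- (0.03 * peakval)^2
  vals <- c()
  for (i in seq_len(nrow(f) - k + 1)) for (j in seq_len(ncol(f) - k + 1)) {
    wf <- f[i:(i + k - 1), j:(j + k - 1)]
    wg <- g[i:(i + k - 1), j:(j + k - 1)]
    muF <- sum(w * wf); muG <- sum(w * wg)
    sFF <- sum(w * wf^2) - muF^2
    sGG <- sum(w * wg^2) - muG^2
    sFG <- sum(w * wf * wg) - muF * muG
    vals <- c(vals, ((2 * muF * muG + c1) * (2 * sFG + c2)) /
                ((muF^2 + muG^2 + c1) * (sFF + sGG + c2)))
  }
  mean(vals)
}

test_that("psnr matches its closed forms", {
  f <- matrix(100, 8, 8)
  expect_identical(psnr(f, f, 255), Inf)
  expect_equal(psnr(f, f + 1, 255), 10 * log10(255^2))
  expect_equal(psnr(f, f + 1, 255), 48.13080361, tolerance = 1e-7)
  expect_error(psnr(f, matrix(0, 4, 4), 255), "shape")
})

test_that("snr matches its closed forms and is bounded by psnr", {
  f2 <- matrix(2, 10, 10)
  expect_equal(snr(f2, f2 - 1), 10 * log10(4))
  expect_equal(snr(f2, f2 - 1), 6.020599913, tolerance = 1e-7)
  expect_identical(snr(f2, f2), Inf)
  expect_true(is.nan(snr(matrix(0, 3, 3), matrix(1, 3, 3))))
  for (s in 1:10) {
    f <- matrix(seededRunif(64, 300 + s, 0, 255), 8, 8)
    g <- matrix(seededRunif(64, 400 + s, 0, 255), 8, 8)
    expect_lte(snr(f, g), psnr(f, g, 255))
  }
})

test_that("ssim agrees with an independent implementation and the frozen oracle", {
  f <- waveSlice(32, 32)
  g <- round(f + 500 * sin(outer(1:32, 1:32, "+") / 3))
  expect_equal(ssim(f, g, 65535), 1, tolerance = 0.01)
  # frozen value computed with scikit-image (gaussian_weights=TRUE,
  # sigma=1.5, use_sample_covariance=FALSE, data_range=65535)
  expect_equal(ssim(f, g, 65535), 0.9977290228, tolerance = 1e-8)
  small_f <- f[1:14, 1:14]
  small_g <- g[1:14, 1:14]
  expect_equal(ssim(small_f, small_g, 65535),
               bruteSsim(small_f, small_g, 65535), tolerance = 1e-10)
  expect_identical(ssim(f, f, 65535), 1)
  expect_equal(ssim(f, g, 65535), ssim(g, f, 65535), tolerance = 1e-12)
  # inverted high-contrast image disagrees structurally
  h <- matrix(rep(c(5000, 60000), length.out = 16 * 16), 16, 16)
  expect_lt(ssim(h, 65535 - h, 65535), 0.5)
  expect_error(ssim(f[1:8, 1:8], g[1:8, 1:8], 65535), "11x11")
})

test_that("entropy matches closed forms and histogram invariances", {
  expect_equal(imageEntropy(matrix(7, 5, 5)), 0)
  expect_equal(imageEntropy(matrix(c(0, 40), 4, 4)), 1)
  expect_equal(imageEntropy(matrix(0:255, 16, 16)), 8)
  x <- matrix(0:255, 16, 16)
  expect_equal(imageEntropy(255 - x), imageEntropy(x))
  y <- matrix(seededRunif(400, 55, 0, 1000), 20, 20)
  expect_lte(imageEntropy(y), 8)
  expect_lte(imageEntropy(round(y / 250) * 250), log2(5) + 1e-12)
})

test_that("bit error rate counts differing bits", {
  z <- matrix(0, 4, 4)
  expect_equal(ber(z, z, "uint8"), 0)
  expect_equal(ber(z, z + 255, "uint8"), 1)
  expect_equal(ber(z, z + 1, "uint8"), 0.125)
  expect_equal(ber(z, z + 1, "uint16"), 1 / 16)
  # symmetry and a triangle-type bound
  f <- matrix(seededRunif(36, 61, 0, 65535), 6, 6)
  g <- matrix(seededRunif(36, 62, 0, 65535), 6, 6)
  h <- matrix(seededRunif(36, 63, 0, 65535), 6, 6)
  f <- round(f); g <- round(g); h <- round(h)
  expect_equal(ber(f, g, "uint16"), ber(g, f, "uint16"))
  expect_lte(ber(f, h, "uint16"),
             ber(f, g, "uint16") + ber(g, h, "uint16"))
  expect_error(ber(f, g, "float32"), "integer")
})

test_that("fiveNumber follows the linear-interpolation convention", {
  expect_equal(unname(fiveNumber(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(fiveNumber(7)), rep(7, 5))
  expect_equal(fiveNumber(1:4)[["median"]], 2.5)
  fn <- fiveNumber(c(3, 1, 4, 1, 5, 9, 2, 6))
  expect_true(fn[["q1"]] <= fn[["median"]] &&
              fn[["median"]] <= fn[["q3"]])
  expect_error(fiveNumber(numeric()), "empty")
})

test_that("psnr and snr degrade monotonically with noise variance", {
  f <- waveSlice(24, 24)
  sds <- c(10, 50, 250, 1250)
  p <- s <- numeric(length(sds))
  for (i in seq_along(sds)) {
    g <- f + matrix(withr::with_seed(70 + i,
                                     stats::rnorm(length(f), sd = sds[i])),
                    24, 24)
    p[i] <- psnr(f, g, 65535)
    s[i] <- snr(f, g)
  }
  expect_true(all(diff(p) < 0))
  expect_true(all(diff(s) < 0))
})

test_that("qualityReport aggregates per-slice metrics and writes CSV", {
  v <- generatePhantom(c(32, 32, 4), seed = 6)
  dn <- downsampleVolume(v)
  up <- upsampleVolume(dn)
  rep <- qualityReport(v, up, beta = 500)
  ps <- perSliceMetrics(rep)
  expect_setequal(unique(ps$metric),
                  c("psnr_db", "snr_db", "ssim", "entropy_bits",
                    "ber_fraction"))
  expect_identical(sort(unique(ps$slice_index)), 0:3)
  agg <- volumeMetrics(rep)
  expect_setequal(unique(agg$aggregation), c("slice-mean", "pooled"))
  sm <- agg$value[agg$metric == "ssim" & agg$aggregation == "slice-mean"]
  expect_equal(sm, mean(ps$value[ps$metric == "ssim"]))
  fn <- fiveNumberSummaries(rep)
  expect_true(all(fn$q1 <= fn$median & fn$median <= fn$q3))
  csv <- tempfile(fileext = ".csv")
  writeQualityCSV(rep, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back),
                   c("metric", "beta", "slice_index", "aggregation",
                     "value"))
  expect_identical(nrow(back), nrow(ps) + nrow(agg))
  unlink(csv)
})
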