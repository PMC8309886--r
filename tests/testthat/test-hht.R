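fs <- 100
tt <- (0:1099) / fs

test_that("envelopes bracket the signal and average out a symmetric tone", {
  x <- sin(2 * pi * 1 * tt)
  env <- envelopes(x)
  interior <- 111:989  # inner 80%
  expect_true(max(abs(env$mean[interior])) < 0.05)
  # upper >= signal >= lower at every interior extremum
  ext <- c(which(diff(sign(diff(x))) != 0) + 1)
  ext <- ext[ext > 10 & ext < 1090]
  expect_true(all(env$upper[ext] >= x[ext] - 1e-9))
  expect_true(all(env$lower[ext] <= x[ext] + 1e-9))
  # monotonic-like signals have no envelopes
  expect_null(envelopes(seq(0, 1, length.out = 100)))
})

test_that("sifting is near-idempotent on a valid IMF and splits two tones", {
  tone <- sin(2 * pi * 2 * tt)
  imf <- sift(tone)
  expect_gt(cor(imf, tone), 0.999)
  two <- sin(2 * pi * 1 * tt) + sin(2 * pi * 4 * tt)
  imf1 <- sift(two)
  expect_gt(cor(imf1, sin(2 * pi * 4 * tt)), 0.95)
})

test_that("EMD separates tone from trend and always reconstructs the input", {
  x <- sin(2 * pi * 2 * tt) + 0.5 * tt
  dec <- emd(x)
  expect_gt(cor(dec$imfs[[1]], sin(2 * pi * 2 * tt)), 0.95)
  expect_gt(cor(dec$residue, tt), 0.95)
  recon <- Reduce(`+`, dec$imfs) + dec$residue
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)

  # flat input: nothing to decompose
  expect_length(emd(rep(1, 100))$imfs, 0)

  # a rich signal capped at 3 IMFs
  rich <- sin(2 * pi * 8 * tt) + 0.7 * sin(2 * pi * 3 * tt) +
    0.5 * sin(2 * pi * 1 * tt) + 0.3 * sin(2 * pi * 0.3 * tt)
  expect_length(emd(rich, max_imfs = 3)$imfs, 3)
})

test_that("reconstruction holds on noisy segment-like signals", {
  set.seed(31)
  for (i in 1:5) {
    x <- cumsum(rnorm(600)) + sin(2 * pi * 1.5 * (1:600) / 100)
    dec <- emd(x)
    recon <- Reduce(`+`, c(dec$imfs, list(dec$residue)))
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)
  }
})

test_that("the Hilbert spectrum recovers a tone's frequency and amplitude", {
  A0 <- 1.8
  x <- A0 * sin(2 * pi * 2 * tt)
  hs <- hilbert_spectrum(x, fs)
  expect_equal(median(hs$freq), 2, tolerance = 0.02)
  expect_equal(median(sqrt(hs$energy)), A0, tolerance = 0.02)
  # doubling the amplitude quadruples the energy density
  hs2 <- hilbert_spectrum(2 * x, fs)
  expect_equal(median(hs2$energy), 4 * median(hs$energy), tolerance = 1e-6)
  expect_true(all(hs$freq >= 0 & hs$freq <= fs / 2))
  expect_length(hilbert_spectrum(rep(0, 1100), fs)$freq, 0)
})

test_that("the marginal spectrum conserves energy and localizes a tone", {
  x <- sin(2 * pi * 2 * tt)
  hs <- hilbert_spectrum(x, fs)
  mhs <- marginal_spectrum(hs, bin_width = 0.05)
  expect_equal(sum(mhs$h), sum(hs$energy) / fs, tolerance = 1e-6)
  near <- abs(mhs$freq - 2) <= 2.5 * 0.05  # 2 Hz +/- 2 bins
  expect_gt(sum(mhs$h[near]) / sum(mhs$h), 0.9)
  expect_error(marginal_spectrum(hs, bin_width = 0), "positive")
  empty <- hilbert_spectrum(rep(0, 1100), fs)
  expect_true(all(marginal_spectrum(empty)$h == 0))
})

test_that("the MHS-area centroid behaves like an area centroid", {
  mk <- function(freq, h) structure(list(freq = freq, h = h),
                                    class = "marginal_spectrum")
  expect_equal(mhs_centroid(mk(c(1, 2, 3), c(0, 5, 0))),
               c(freq = 2, energy = 5))
  expect_equal(mhs_centroid(mk(c(1, 3), c(4, 4)))[["freq"]], 2)
  expect_warning(z <- mhs_centroid(mk(1:3, c(0, 0, 0))), "zero")
  expect_equal(z, c(freq = 0, energy = 0))
  # closed-form oracle: tone of amplitude A0 over duration T
  A0 <- 1.4
  x <- A0 * sin(2 * pi * 2 * tt)
  cen <- mhs_centroid(marginal_spectrum(hilbert_spectrum(x, fs)))
  expect_equal(cen[["freq"]], 2, tolerance = 0.05)
  expect_equal(cen[["energy"]], A0^2 * 11 * 0.9, tolerance = 0.1 * A0^2 * 11)
})

test_that("hht_features composes into six centroid values per axis", {
  x <- sin(2 * pi * 2 * tt) + 0.8 * sin(2 * pi * 0.3 * tt)
  f <- suppressWarnings(hht_features(x, fs))  # two tones may yield < 3 IMFs
  expect_length(f, 6)
  expect_identical(names(f), c("IMF1_f", "IMF2_f", "IMF3_f",
                               "IMF1_e", "IMF2_e", "IMF3_e"))
  expect_equal(f[["IMF1_f"]], 2, tolerance = 0.2)
  expect_true(all(suppressWarnings(hht_features(rep(0, 1100), fs)) == 0))
})

test_that("IMF centroid frequencies are ordered fast to slow", {
  set.seed(12)
  for (i in 1:3) {
    x <- sin(2 * pi * 6 * tt + runif(1)) + sin(2 * pi * 1.5 * tt + runif(1)) +
      sin(2 * pi * 0.4 * tt + runif(1))
    f <- suppressWarnings(hht_features(x, fs))
    freqs <- f[1:3][f[1:3] > 0]
    expect_true(all(diff(freqs) <= 1e-9))
  }
})

test_that("IMF and MHS dumps round-trip through CSV", {
  x <- sin(2 * pi * 2 * tt) + 0.5 * tt
  dec <- emd(x)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_imfs_csv(dec, p1)
  back <- read.csv(p1)
  expect_equal(ncol(back), length(dec$imfs) + 1)
  expect_equal(back$IMF1, dec$imfs[[1]], tolerance = 1e-12)
  mhs <- marginal_spectrum(hilbert_spectrum(dec$imfs[[1]], fs))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_mhs_csv(mhs, p2)
  back2 <- read.csv(p2)
  expect_equal(sum(back2$h), sum(mhs$h), tolerance = 1e-9)
})

test_that("single-tone centroid frequency is within 5% for tones >= 5 cycles", {
  for (f0 in c(0.5, 1, 3, 8)) {
    x <- sin(2 * pi * f0 * tt)
    cen <- mhs_centroid(marginal_spectrum(hilbert_spectrum(x, fs)))
    expect_lt(abs(cen[["freq"]] - f0), 0.05 * f0)
  }
})
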