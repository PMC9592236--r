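tt <- function(n, tr = 2) (0:(n - 1)) * tr

test_that("bin-aligned sinusoids are recovered with unit-amplitude scaling", {
  s <- 2 * sin(2 * pi * 0.05 * tt(230))        # bin 23 of N = 230, TR = 2 s
  sp <- amplitude_spectrum(s, 2)
  expect_equal(sp$freq[23], 0.05)
  expect_equal(sp$amplitude[23], 2, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[-23]), 1e-9)
  expect_equal(amplitude_spectrum(rep(4, 64), 2)$amplitude, rep(0, 32))
  # linearity
  r <- rnorm(50)
  expect_equal(amplitude_spectrum(2 * r, 2)$amplitude,
               2 * amplitude_spectrum(r, 2)$amplitude)
  expect_error(amplitude_spectrum(c(1, NA, rep(0, 10)), 2), "finite")
  expect_error(amplitude_spectrum(1:4, 2), "8 time points")
})

test_that("Parseval's identity holds for the single-sided scaling", {
  set.seed(3)
  for (n in c(229, 230)) {                     # odd and even lengths
    x <- rnorm(n); x <- x - mean(x)
    a <- amplitude_spectrum(x, 2)$amplitude
    lhs <- 2 / n * sum(x^2)
    rhs <- if (n %% 2 == 0) {
      sum(a[-length(a)]^2) + 2 * a[length(a)]^2
    } else {
      sum(a^2)
    }
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("ALFF averages in-band amplitudes over the documented bin range", {
  s <- 2 * sin(2 * pi * 0.05 * tt(230))
  expect_equal(alff(s, 2), 2 / 65, tolerance = 1e-9)   # bins 5..69
  expect_equal(alff(rep(0, 230), 2), 0)
  hi <- sin(2 * pi * 0.20 * tt(230))                   # outside 0.01-0.15
  expect_equal(alff(hi, 2), 0, tolerance = 1e-9)
  # degree-1 homogeneity
  r <- rnorm(100)
  expect_equal(alff(3 * r, 2), 3 * alff(r, 2))
  expect_error(alff(rnorm(20), 2, band_spec(0.0001, 0.001)), "no frequency bins")
})

test_that("fALFF is a bounded amplitude fraction with two-tone value 1/2", {
  inband <- sin(2 * pi * 0.05 * tt(230)) + 0.5 * sin(2 * pi * 0.10 * tt(230))
  expect_equal(falff(inband, 2), 1, tolerance = 1e-9)
  two <- sin(2 * pi * 0.05 * tt(230)) + sin(2 * pi * 0.20 * tt(230))
  expect_equal(falff(two, 2), 0.5, tolerance = 1e-9)
  expect_equal(falff(rep(0, 230), 2), 0)   # zero denominator convention
  set.seed(8)
  for (i in 1:10) {
    v <- falff(rnorm(64), 2)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # scale invariance
  r <- rnorm(120)
  expect_equal(falff(5 * r, 2), falff(r, 2))
})

test_that("enlarging the numerator band never decreases fALFF", {
  set.seed(13)
  for (i in 1:10) {
    r <- rnorm(96)
    v1 <- falff(r, 2, band_spec(0.01, 0.08))
    v2 <- falff(r, 2, band_spec(0.01, 0.10))
    v3 <- falff(r, 2, band_spec(0.01, 0.15))
    expect_true(v1 <= v2 + 1e-12 && v2 <= v3 + 1e-12)
  }
})

test_that("white-noise fALFF matches the bin-count ratio", {
  n <- 230
  freq <- seq_len(n %/% 2) / (n * 2)
  n_num <- length(wmalff:::band_bin_index(freq, 0.01, 0.15))
  n_den <- length(wmalff:::band_bin_index(freq, 0, 0.25))
  expect_equal(c(n_num, n_den), c(65, 115))
  set.seed(99)
  vals <- replicate(300, falff(rnorm(n), 2))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - n_num / n_den), 3 * se)
})

test_that("band_spec validates its edges", {
  expect_error(band_spec(0.1, 0.05), "low < high")
  expect_error(band_spec(0.01, 0.15, 0.02, 0.25), "contain")
  expect_error(band_spec(0.01, 0.15, 0, 0.10), "contain")
})

test_that("metric maps reduce to the scalar operations inside the mask", {
  set.seed(4)
  Y <- matrix(rnorm(64 * 3), 64, 3)
  Y[, 2] <- Y[, 1]                      # two identical voxels
  b <- toy_bold(Y)
  mask <- array(c(TRUE, TRUE, TRUE), c(3, 1, 1))
  for (m in c("alff", "falff")) {
    mp <- metric_map(b, mask, m)
    f <- if (m == "alff") alff else falff
    expect_equal(mp$values[1, 1, 1], f(Y[, 1], 2))
    expect_equal(mp$values[1, 1, 1], mp$values[2, 1, 1])
    expect_equal(mp$values[3, 1, 1], f(Y[, 3], 2))
  }
  one <- array(c(TRUE, FALSE, FALSE), c(3, 1, 1))
  mp1 <- metric_map(b, one, "alff")
  expect_equal(mp1$values[1, 1, 1], alff(Y[, 1], 2))
  expect_true(all(mp1$values[2:3, 1, 1] == 0))
  expect_error(metric_map(b, array(FALSE, c(3, 1, 1)), "alff"), "empty")
})

test_that("planted amplitude deficits propagate to the ALFF map exactly", {
  an <- small_anatomy()
  lab <- small_labels()
  eff <- default_effect_spec(an, amplitude_ratio = 0.5, radius = 1)
  np <- default_noise_params(ar_sd = 0, white_sd = 0)
  pat <- simulate_subject(an, "patient", eff, 60, 2, np, seed = 31)
  ctl <- simulate_subject(an, "control", eff, 60, 2, np, seed = 31)
  wm <- lab == 2L
  mp <- metric_map(pat$bold, wm, "alff")
  mc <- metric_map(ctl$bold, wm, "alff")
  cl <- wmalff:::effect_cluster_mask(an, eff) & wm
  expect_equal(mp$values[cl], 0.5 * mc$values[cl], tolerance = 1e-9)
})

test_that("mALFF normalisation yields a unit-mean relative map", {
  an <- small_anatomy()
  mask <- small_labels() == 2L
  vals <- array(0, dim(mask)); vals[mask] <- runif(sum(mask), 0.5, 2)
  mp <- structure(list(values = vals, metric = "ALFF", band = band_spec(),
                       normalization = "raw", mask = mask, tr_s = 2),
                  class = "metric_map")
  nm <- malff_normalize(mp)
  expect_equal(mean(nm$values[mask]), 1, tolerance = 1e-6)
  # scale invariance
  mp10 <- mp; mp10$values <- mp$values * 10
  expect_equal(malff_normalize(mp10)$values, nm$values)
  cst <- mp; cst$values[mask] <- 3
  expect_true(all(malff_normalize(cst)$values[mask] == 1))
  fmap <- mp; fmap$metric <- "fALFF"
  expect_error(malff_normalize(fmap), "ALFF maps")
})

test_that("z-transformation standardises with the population SD", {
  mask <- array(c(TRUE, TRUE, FALSE), c(3, 1, 1))
  mp <- structure(list(values = array(c(1, 3, 99), c(3, 1, 1)),
                       metric = "fALFF", band = band_spec(),
                       normalization = "raw", mask = mask, tr_s = 2),
                  class = "metric_map")
  z <- ztransform_map(mp)
  expect_equal(as.numeric(z$values[, 1, 1]), c(-1, 1, 0))  # population SD = 1
  # affine invariance and forced moments
  an_mask <- array(TRUE, c(4, 4, 4))
  v <- array(rnorm(64), c(4, 4, 4))
  m1 <- structure(list(values = v, metric = "ALFF", band = band_spec(),
                       normalization = "raw", mask = an_mask, tr_s = 2),
                  class = "metric_map")
  m2 <- m1; m2$values <- 3 * v + 7
  z1 <- ztransform_map(m1); z2 <- ztransform_map(m2)
  expect_equal(z1$values, z2$values, tolerance = 1e-12)
  expect_equal(mean(z1$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z1$values^2)), 1, tolerance = 1e-12)
  cst <- m1; cst$values[] <- 5
  expect_error(ztransform_map(cst), "SD is zero")
})
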