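test_that("a pure sinusoid's power peaks at its period", {
  t <- 1:64
  x <- sin(2 * pi * t / 4)
  cw <- morlet_transform(x)
  pw <- bias_corrected_power(cw)
  # time-averaged power over in-COI cells, maximized over period
  in_coi <- outer(cw$periods, cw$coi, "<=")
  pw[!in_coi] <- NA
  prof <- rowMeans(pw, na.rm = TRUE)
  peak <- cw$periods[which.max(prof)]
  expect_gte(peak, 3.6)
  expect_lte(peak, 4.4)
})

test_that("the transform is invariant to amplitude before standardization", {
  set.seed(1)
  x <- rnorm(32)
  w1 <- morlet_transform(x)
  w2 <- morlet_transform(2 * x)
  expect_equal(w1$W, w2$W, tolerance = 1e-12)
})

test_that("FFT transform equals direct time-domain convolution", {
  # brute-force oracle: W(s, t) = sum_n xpad_n sqrt(dt/s) psi0*((n-t) dt / s)
  set.seed(2)
  x <- rnorm(16)
  cw <- morlet_transform(x)
  x_std <- (x - mean(x)) / sd(x)
  npad <- 32
  xpad <- c(x_std, rep(0, npad - 16))
  dt <- 1
  omega0 <- cw$omega0
  psi0 <- function(eta) pi^(-1 / 4) * exp(1i * omega0 * eta - eta^2 / 2)
  direct <- matrix(0 + 0i, length(cw$scales), 16)
  for (s in seq_along(cw$scales)) {
    sc <- cw$scales[s]
    for (t in 1:16) {
      eta <- ((1:npad) - t) * dt / sc
      direct[s, t] <- sum(xpad * sqrt(dt / sc) * Conj(psi0(eta)))
    }
  }
  # compare inside the COI at well-resolved scales: near period 2 (= 2 dt)
  # the Morlet peak frequency reaches the sampling Nyquist, where the
  # time-sampled wavelet aliases and the two formulations differ by design
  resolved <- outer(cw$periods, cw$coi, "<=") & cw$periods >= 4
  rel <- Mod(cw$W - direct) / pmax(Mod(direct), 1e-10)
  expect_lt(max(rel[resolved]), 1e-6)
})

test_that("transform is linear before standardization", {
  # W(a x) = a W(x) for the unstandardized kernel: check via two mixtures
  set.seed(3)
  x <- rnorm(32); y <- rnorm(32)
  # standardization removes scale, so test linearity through the identity
  # that the standardized transform of x equals that of a*x + b
  expect_equal(morlet_transform(3 * x + 0.5)$W, morlet_transform(x)$W,
               tolerance = 1e-12)
  expect_error(morlet_transform(rep(1, 20)), "degenerate")
  expect_error(morlet_transform(c(1, 2, 3)), "too short")
  expect_error(morlet_transform(c(x[1:10], NA, x[12:32])), "missing")
})

test_that("bias correction rectifies power across periods", {
  expect_equal(bias_corrected_power(matrix(0i, 3, 4), scales = c(1, 2, 4)),
               matrix(0, 3, 4))
  # a single coefficient at scale 2 with |W|^2 = 8 has corrected power 4
  W <- matrix(0i, 2, 3)
  W[2, 2] <- complex(modulus = sqrt(8))
  expect_equal(bias_corrected_power(W, scales = c(1, 2))[2, 2], 4)

  # rectification: equal-amplitude oscillations at different periods get
  # equal corrected peak power, while raw peak power grows with period
  t <- 1:128
  peaks <- sapply(c(3, 5, 7), function(p) {
    cw <- morlet_transform(sin(2 * pi * t / p))
    in_coi <- outer(cw$periods, cw$coi, "<=")
    raw <- Mod(cw$W)^2
    cor_p <- bias_corrected_power(cw)
    raw[!in_coi] <- NA; cor_p[!in_coi] <- NA
    i <- which.min(abs(cw$periods - p))
    c(raw = max(raw[i, ], na.rm = TRUE), corr = max(cor_p[i, ], na.rm = TRUE))
  })
  expect_gt(peaks["raw", 3] / peaks["raw", 1], 2)         # raw biased to long periods
  expect_lt(max(peaks["corr", ]) / min(peaks["corr", ]), 1.1)  # corrected flat
})

test_that("the cone of influence widens toward the series edges", {
  cw <- morlet_transform(rnorm(40))
  n <- 40
  first_half <- cw$coi[1:(n / 2)]
  expect_true(all(diff(first_half) >= 0))
  second_half <- cw$coi[(n / 2 + 1):n]
  expect_true(all(diff(second_half) <= 0))
})

test_that("normalization z-scores the spectrum cells", {
  set.seed(5)
  sp <- site_spectrum(2000 + 1:40, rnorm(40, 0.3, 0.1))
  nm <- normalize_spectrum(sp)
  expect_lt(abs(mean(nm$power)), 1e-12)
  expect_equal(sd(nm$power), 1)
  # affine-transformed input power gives the identical normalized matrix
  sp2 <- sp
  sp2$power <- 3 * sp$power + 7
  expect_equal(normalize_spectrum(sp2)$power, nm$power, tolerance = 1e-10)
  # n-1 denominator: two cells {1, 3} map to -1/sqrt(2), +1/sqrt(2)
  spt <- sp
  spt$power <- matrix(c(1, 3), 1, 2)
  spt$in_coi <- matrix(TRUE, 1, 2)
  expect_equal(as.numeric(normalize_spectrum(spt)$power),
               c(-1, 1) / sqrt(2))
})

test_that("pooling averages aligned cells and counts contributors", {
  set.seed(6)
  mk <- function(site, years) {
    normalize_spectrum(site_spectrum(years, rnorm(length(years), 0.3, 0.1),
                                     site = site))
  }
  s1 <- mk("a", 1991:2010)
  pooled1 <- pool_spectra(list(s1), min_overlap = 5)
  expect_equal(pooled1$mean_power, s1$power)
  expect_true(all(pooled1$n_sites == 1))
  expect_false(any(significance_mask(pooled1)))  # all below min_overlap

  # identical spectra pool to themselves
  pooled3 <- pool_spectra(list(s1, s1, s1), min_overlap = 2)
  expect_equal(pooled3$mean_power, s1$power)
  expect_true(all(pooled3$n_sites == 3))

  # staggered years: counts reflect the overlap
  s2 <- mk("b", 2001:2020)
  pooled2 <- pool_spectra(list(s1, s2), min_overlap = 2)
  expect_equal(sort(unique(as.vector(pooled2$n_sites))), c(1, 2))
  cols2 <- pooled2$years %in% 2001:2010
  expect_true(all(pooled2$n_sites[, cols2] == 2))

  # variance of a 14-site mean of independent normalized spectra ~ 1/14
  mats <- replicate(14, matrix(rnorm(600), 20, 30), simplify = FALSE)
  specs <- lapply(seq_along(mats), function(i) {
    structure(list(site = i, periods = 1:20, years = 1:30,
                   power = mats[[i]], in_coi = matrix(TRUE, 20, 30),
                   normalized = TRUE), class = "site_spectrum")
  })
  pooled14 <- pool_spectra(specs, min_overlap = 5)
  expect_lt(abs(var(as.vector(pooled14$mean_power)) - 1 / 14), 0.01)
})

test_that("mismatched period grids are refused", {
  set.seed(7)
  s1 <- normalize_spectrum(site_spectrum(1:20, rnorm(20)))
  s2 <- normalize_spectrum(site_spectrum(1:20, rnorm(20),
                                         period_range = c(2, 6)))
  expect_error(pool_spectra(list(s1, s2)), "period grids differ")
})

test_that("the significance mask needs both overlap and elevated power", {
  pooled <- structure(list(
    periods = 1:3, years = 1:4,
    mean_power = matrix(0, 3, 4),
    n_sites = matrix(7L, 3, 4), min_overlap = 5
  ), class = "pooled_spectrum")
  expect_false(any(significance_mask(pooled)))
  # raise one well-supported cell above the Gaussian limit
  pooled$mean_power[2, 2] <- qnorm(0.975) / sqrt(7) + 0.01
  pooled$mean_power[3, 3] <- 5        # high power but weak support
  pooled$n_sites[3, 3] <- 2L
  m <- significance_mask(pooled)
  expect_true(m[2, 2])
  expect_false(m[3, 3])
  expect_equal(sum(m), 1)
})

test_that("gapped series are split and short segments skipped", {
  segs <- split_at_gaps(c(1:5, 8:20), rnorm(18))
  expect_length(segs, 2)
  expect_equal(segs[[1]]$years, 1:5)
  ser <- make_series(list(a = setNames(runif(18, 0.2, 0.6),
                                       c(1991:1995, 1998:2010))))
  expect_message(sp <- site_spectra(ser, min_length = 6), "too short")
  expect_length(sp, 1)
  expect_equal(sp[[1]]$years, 1998:2010)
})
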