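test_that("Fisher z-transform matches its closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.18), 0.5 * log(1.18 / 0.82))
  expect_equal(fisher_z(0.18), 0.18198, tolerance = 1e-4)
  r <- seq(-0.999, 0.999, by = 0.037)
  expect_lt(max(abs(inverse_fisher(fisher_z(r)) - r)), 1e-12)
  # clamping keeps z finite at |r| = 1
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
})

test_that("pairwise synchrony handles identical, opposite and short series", {
  yrs <- as.character(2000:2009)
  a <- setNames(sin(1:10) * 0.2 + 0.4, yrs)
  ser <- make_series(list(s1 = a, s2 = a, s3 = setNames(0.8 - a, yrs),
                          s4 = a[1:2]))
  ser$growth <- ser$rate   # synchrony on the rate column via variable choice
  p <- pairwise_synchrony(ser, variable = "abundance", min_overlap = 3)
  get <- function(i, j) p$r[p$site1 == i & p$site2 == j]
  expect_equal(get("s1", "s2"), 1)
  expect_equal(get("s1", "s3"), -1)
  # 2-year overlap with min_overlap 3: pair absent
  expect_false(any(p$site1 == "s4" | p$site2 == "s4"))
  # self-pairs excluded
  expect_false(any(p$site1 == p$site2))
  expect_equal(p$n_shared[p$site1 == "s1" & p$site2 == "s2"], 10)
})

test_that("zero-variance shared segments drop the pair with a warning", {
  yrs <- as.character(2000:2006)
  ser <- make_series(list(s1 = setNames(rep(0.3, 7), yrs),
                          s2 = setNames(runif(7, 0.2, 0.5), yrs),
                          s3 = setNames(runif(7, 0.2, 0.5), yrs)))
  expect_warning(p <- pairwise_synchrony(ser, variable = "abundance"),
                 "zero-variance")
  expect_false(any(p$site1 == "s1"))
})

test_that("average synchrony is the weighted z-scale mean, back-transformed", {
  p1 <- make_pairs(5, z = fisher_z(0.5), weights = 7, seed = 1)
  expect_equal(average_synchrony(p1), 0.5, tolerance = 1e-9)

  # antisymmetry: equal-weight +r and -r average to zero
  p2 <- make_pairs(5, z = 0, weights = 1, seed = 2)
  p2$z <- rep(c(fisher_z(0.5), fisher_z(-0.5)), length.out = nrow(p2))
  p2$r <- tanh(p2$z)
  expect_equal(average_synchrony(p2), 0, tolerance = 1e-12)

  # hand-computed weighted mean: {r=0.8, w=3}, {r=0, w=1}
  p3 <- make_pairs(2, z = c(fisher_z(0.8)), weights = 3, seed = 3)
  p3 <- rbind(p3, p3)
  p3$z <- c(fisher_z(0.8), 0); p3$r <- tanh(p3$z); p3$n_shared <- c(3, 1)
  expect_equal(average_synchrony(p3), tanh(0.75 * atanh(0.8)),
               tolerance = 1e-9)
  expect_equal(average_synchrony(p3), 0.677219, tolerance = 1e-6)
})

test_that("a distance-free pair set yields a flat correlogram", {
  p <- make_pairs(8, z = fisher_z(0.3), seed = 4)
  crg <- fit_correlogram(p, n_perm = 120, seed = 5)
  expect_lt(max(abs(crg$fit_r - 0.3)), 1e-6)
  # all r identical: bootstrap CI has zero width
  expect_lt(diff(crg$average_ci), 1e-9)

  # with noise but no distance structure, GCV shrinks towards a flat line
  set.seed(44)
  edfs <- replicate(10, {
    pp <- make_pairs(10, z = function(d) rnorm(length(d), fisher_z(0.2), 0.15))
    fit_correlogram(pp, envelopes = FALSE)$edf
  })
  expect_lt(median(edfs), 1.5)
})

test_that("back-transformed predictions stay inside (-1, 1)", {
  p <- make_pairs(10, z = function(d) 2.5 - 0.01 * d, weights = 10, seed = 6)
  crg <- fit_correlogram(p, envelopes = FALSE)
  expect_true(all(crg$fit_r > -1 & crg$fit_r < 1))
})

test_that("duplicating a pair is equivalent to doubling its weight", {
  p <- make_pairs(7, z = function(d) 0.4 * exp(-d / 150), seed = 7)
  p$z <- p$z + rnorm(nrow(p), 0, 0.05)
  p$r <- tanh(p$z)
  dup <- rbind(p, p[3, ])
  attr(dup, "dist_matrix") <- attr(p, "dist_matrix")
  class(dup) <- class(p)
  dbl <- p
  dbl$n_shared[3] <- 2 * dbl$n_shared[3]
  # at a fixed smoothing parameter the weighted-least-squares identity is
  # exact; under GCV the selected lambda differs slightly with row count
  f1 <- fit_correlogram(dup, envelopes = FALSE, sp = 1)
  f2 <- fit_correlogram(dbl, envelopes = FALSE, sp = 1)
  expect_equal(f1$fit_z, f2$fit_z, tolerance = 1e-8)
  g1 <- fit_correlogram(dup, envelopes = FALSE)
  g2 <- fit_correlogram(dbl, envelopes = FALSE)
  expect_equal(g1$fit_z, g2$fit_z, tolerance = 0.02)
})

test_that("a planted exponential decay gives a decreasing fit", {
  set.seed(8)
  p <- make_pairs(16, z = function(d) 0.4 * exp(-d / 100), weights = 15)
  p$z <- p$z + rnorm(nrow(p), 0, 0.05)
  p$r <- tanh(p$z)
  crg <- fit_correlogram(p, grid = seq(0, 300, 10), envelopes = FALSE)
  expect_true(all(diff(crg$fit_z) < 0.005))
  expect_gt(crg$fit_r[1], crg$fit_r[length(crg$fit_r)])
})

test_that("z-scale equivariance: shifting every z shifts the fit", {
  p <- make_pairs(9, z = function(d) 0.3 * exp(-d / 120), seed = 9)
  p$z <- p$z + rnorm(nrow(p), 0, 0.03)
  shift <- 0.25
  p2 <- p
  p2$z <- p$z + shift
  f1 <- fit_correlogram(p, envelopes = FALSE)
  f2 <- fit_correlogram(p2, envelopes = FALSE)
  expect_equal(f2$fit_z, f1$fit_z + shift, tolerance = 1e-7)
})

test_that("bootstrap null model is seeded and calibrated", {
  p <- make_pairs(10, z = function(d) rnorm(length(d), 0, 0.2), seed = 10)
  a1 <- null_envelope_no_correlation(p, n_perm = 300, seed = 77)
  a2 <- null_envelope_no_correlation(p, n_perm = 300, seed = 77)
  expect_identical(a1$average_ci, a2$average_ci)
  expect_warning(null_envelope_no_correlation(p, n_perm = 50, seed = 1),
                 "resolution")

  # coverage: CI covers the true mean z = 0 in about 95% of replicates
  set.seed(20)
  cover <- replicate(200, {
    pp <- make_pairs(10, z = function(d) rnorm(length(d), 0, 0.2))
    ci <- null_envelope_no_correlation(pp, n_perm = 300,
                                       seed = sample.int(1e6, 1))$average_ci
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gt(mean(cover), 0.88)
  expect_lte(mean(cover), 1)
})

test_that("distance-shuffle p-value hits zero when the empirical fit dominates", {
  set.seed(12)
  p <- make_pairs(16, z = function(d) 0.6 * exp(-d / 60), weights = 20)
  p$z <- p$z + rnorm(nrow(p), 0, 0.02)
  p$r <- tanh(p$z)
  crg <- fit_correlogram(p, n_perm = 500, seed = 13)
  expect_equal(crg$mantel_p, 0)
  expect_true(all(crg$band_distance_shuffle >= -1 &
                    crg$band_distance_shuffle <= 1))
})

test_that("fast and generic permutation paths agree", {
  p <- make_pairs(8, z = function(d) rnorm(length(d), 0, 0.2), seed = 14)
  fast <- null_envelope_distance_shuffle(p, n_perm = 120, seed = 5)
  # force the generic path by dropping one pair
  p2 <- p[-1, ]
  attr(p2, "dist_matrix") <- attr(p, "dist_matrix")
  class(p2) <- class(p)
  gen <- null_envelope_distance_shuffle(p2, n_perm = 120, seed = 5)
  expect_type(gen$p, "double")
  # same seed, same pairs: identical permutation stream between paths
  ref <- local({
    set.seed(5)
    D <- attr(p, "dist_matrix")
    i1 <- match(p$site1, rownames(D)); i2 <- match(p$site2, rownames(D))
    sapply(1:120, function(b) {
      perm <- sample.int(nrow(D))
      g <- suppressMessages(
        mgcv::gam(z ~ s(d, k = 5, bs = "cr"), weights = w,
                  data = data.frame(z = p$z, d = D[cbind(perm[i1], perm[i2])],
                                    w = p$n_shared)))
      n <- nrow(p)
      rss <- sum(p$n_shared * (p$z - fitted(g))^2)
      wm <- weighted.mean(p$z, p$n_shared)
      tss <- sum(p$n_shared * (p$z - wm)^2)
      1 - (rss / (n - sum(g$edf))) / (tss / (n - 1))
    })
  })
  expect_equal(fast$r2_perm, ref, tolerance = 1e-8)
})
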