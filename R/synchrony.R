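#' Fisher z-transformation
#'
#' z = 0.5 * ln((1 + r) / (1 - r)) = atanh(r). Correlations are clamped to
#' |r| <= 1 - 1e-6 before the transform so z stays finite; the inverse is
#' tanh.
#'
#' @param r correlation(s) in [-1, 1].
#' @return transformed value(s) on the real line.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-6
  atanh(pmin(pmax(r, -lim), lim))
}

#' @rdname fisher_z
#' @param z value(s) on the z scale.
#' @export
inverse_fisher <- function(z) tanh(z)

#' Pairwise between-site synchrony
#'
#' Pearson correlation of the chosen variable (log growth rate or
#' occupancy rate) over the years each unordered site pair has in common,
#' with the shared-year count kept as the pair's weight. Self-pairs are
#' excluded; pairs with fewer shared years than `min_overlap`, or with a
#' zero-variance shared segment, are dropped (the latter with a warning).
#'
#' @param series `site_series` data.frame (see [growth_rate()]), with
#'   `lat`/`lon` columns or an explicit distance matrix.
#' @param variable `"growth"` or `"abundance"` (occupancy rate).
#' @param min_overlap minimum number of shared years (default 3).
#' @param distances optional symmetric km matrix with site dimnames;
#'   computed from the series coordinates when absent.
#' @return data.frame of class `pair_correlation`: `site1`, `site2`,
#'   `dist_km`, `r`, `n_shared`, `z`; the site-level distance matrix is
#'   attached as attribute `dist_matrix`.
#' @export
pairwise_synchrony <- function(series, variable = c("growth", "abundance"),
                               min_overlap = 3, distances = NULL) {
  variable <- match.arg(variable)
  col <- if (variable == "growth") "growth" else "rate"
  stopifnot(col %in% names(series))
  sites <- unique(series$site)
  if (length(sites) < 2) stop("need at least two sites")
  if (is.null(distances)) {
    distances <- pairwise_distance(site_centres(series))
  }
  stopifnot(all(sites %in% rownames(distances)))

  by_site <- lapply(sites, function(s) {
    sub <- series[series$site == s & !is.na(series[[col]]), ]
    stats::setNames(sub[[col]], sub$year)
  })
  names(by_site) <- sites

  out <- list()
  n_degenerate <- 0L
  for (i in seq_along(sites)[-length(sites)]) {
    for (j in (i + 1L):length(sites)) {
      yrs <- intersect(names(by_site[[i]]), names(by_site[[j]]))
      if (length(yrs) < min_overlap) next
      a <- by_site[[i]][yrs]
      b <- by_site[[j]][yrs]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        site1 = sites[i], site2 = sites[j],
        dist_km = distances[sites[i], sites[j]],
        r = stats::cor(a, b), n_shared = length(yrs))
    }
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " pair(s) with zero-variance shared segment dropped")
  }
  if (!length(out)) stop("no site pair meets the overlap requirement")
  pairs <- do.call(rbind, out)
  pairs$z <- fisher_z(pairs$r)
  rownames(pairs) <- NULL
  attr(pairs, "dist_matrix") <- distances
  class(pairs) <- c("pair_correlation", "data.frame")
  pairs
}

#' Average synchrony
#'
#' Weighted mean of the Fisher-z-transformed pairwise correlations
#' (weights = shared-year counts), back-transformed to the r scale.
#'
#' @param pairs `pair_correlation` table from [pairwise_synchrony()].
#' @return scalar average synchrony on the Pearson-r scale.
#' @export
average_synchrony <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  inverse_fisher(stats::weighted.mean(pairs$z, pairs$n_shared))
}

# weighted adjusted r^2 used for both the empirical fit and every
# permutation refit, so the Mantel comparison is internally consistent
weighted_adj_r2 <- function(y, fitted, w, edf_total) {
  n <- length(y)
  rss <- sum(w * (y - fitted)^2)
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  1 - (rss / (n - edf_total)) / (tss / (n - 1))
}

# weighted penalized-spline fit of z on distance; k shrinks when there are
# too few unique distances (mgcv needs >= k unique covariate values).
# detail = TRUE adds the smooth-term summary (edf, F, p), which is too
# slow for the permutation loop.
correlogram_gam <- function(z, d, w, k, detail = FALSE, sp = NULL) {
  n_unique <- length(unique(d))
  k_eff <- min(k, n_unique)
  if (k_eff < 3) {
    fit <- stats::lm(z ~ d, weights = w)
    return(list(fit = fit, gam = FALSE,
                predict = function(newd) {
                  stats::predict(fit, data.frame(d = newd))
                },
                edf = 2, smooth_edf = 1, F = NA_real_,
                r2_adj = weighted_adj_r2(z, stats::fitted(fit), w, 2)))
  }
  if (k_eff < k) {
    message("basis dimension reduced from ", k, " to ", k_eff,
            " (only ", n_unique, " unique distances)")
  }
  fit <- mgcv::gam(z ~ s(d, k = k_eff, bs = "cr"), sp = sp,
                   weights = w, data = data.frame(z = z, d = d, w = w))
  out <- list(fit = fit, gam = TRUE,
              predict = function(newd) {
                as.numeric(mgcv::predict.gam(fit, data.frame(d = newd)))
              },
              edf = as.numeric(sum(fit$edf)),   # includes the intercept's 1
              r2_adj = weighted_adj_r2(z, stats::fitted(fit), w,
                                       sum(fit$edf)))
  if (detail) {
    sm <- summary(fit)
    out$smooth_edf <- as.numeric(sm$s.table[1, "edf"])
    out$F <- as.numeric(sm$s.table[1, "F"])
    out$p_smooth <- as.numeric(sm$s.table[1, "p-value"])
  } else {
    out$smooth_edf <- as.numeric(sum(fit$edf)) - 1
    out$F <- NA_real_
  }
  out
}

#' Distance correlogram of between-site synchrony
#'
#' Weighted penalized cubic regression spline of Fisher-z correlations on
#' inter-site distance (weights = shared-year counts, smoothness by GCV),
#' with predictions back-transformed to the r scale. Optionally attaches
#' the two permutation null models: a distance-free bootstrap of the pair
#' list (confidence interval of the average synchrony and a flat pointwise
#' band) and a Mantel-style distance-shuffling null (pointwise envelope
#' and a permutation p-value comparing adjusted r-squared values).
#'
#' @param pairs `pair_correlation` table from [pairwise_synchrony()].
#' @param grid distances (km) at which to report the fitted curve;
#'   defaults to 100 points from 0 to the maximum pair distance.
#' @param k spline basis dimension (default 5; shrinks automatically when
#'   unique distances are scarce).
#' @param n_perm permutations/bootstrap draws for the null models.
#' @param seed integer seed; the two null models use independent streams
#'   derived from it.
#' @param envelopes compute the null models (TRUE) or just the fit.
#' @param sp optional fixed smoothing parameter passed to the spline fit
#'   (and reused in every permutation refit); NULL selects smoothness by
#'   GCV.
#' @return object of class `correlogram`: grid, fitted values on the z and
#'   r scales, edf, adjusted r-squared, smooth-term F, and (with
#'   envelopes) `average_r`, `average_ci`, the two bands and the Mantel p.
#' @export
fit_correlogram <- function(pairs, grid = NULL, k = 5, n_perm = 5000,
                            seed = 1L, envelopes = TRUE, sp = NULL) {
  stopifnot(nrow(pairs) >= 10, all(pairs$dist_km > 0))
  if (is.null(grid)) grid <- seq(0, max(pairs$dist_km), length.out = 100)
  g <- correlogram_gam(pairs$z, pairs$dist_km, pairs$n_shared, k,
                       detail = TRUE, sp = sp)
  fit_z <- g$predict(grid)
  res <- structure(list(
    grid = grid, fit_z = fit_z, fit_r = inverse_fisher(fit_z),
    edf = if (g$gam) g$smooth_edf else 1,
    F = if (g$gam) g$F else NA_real_,
    r2_adj = g$r2_adj, k = k, n_pairs = nrow(pairs),
    n_perm = if (envelopes) n_perm else 0L, seed = seed
  ), class = "correlogram")
  if (envelopes) {
    set.seed(seed)
    s2 <- sample.int(.Machine$integer.max - 1L, 2L)
    nullA <- null_envelope_no_correlation(pairs, n_perm = n_perm,
                                          seed = s2[1], grid = grid)
    nullB <- null_envelope_distance_shuffle(pairs, n_perm = n_perm,
                                            seed = s2[2], grid = grid,
                                            k = k, r2_emp = res$r2_adj,
                                            sp = sp)
    res$average_r <- nullA$average_r
    res$average_ci <- nullA$average_ci
    res$band_no_correlation <- nullA$band
    res$band_distance_shuffle <- nullB$band
    res$mantel_p <- nullB$p
  }
  res
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Synchrony correlogram: %d pairs, edf %.2f, adj r^2 %.3f\n",
              x$n_pairs, x$edf, x$r2_adj))
  if (!is.null(x$average_r)) {
    cat(sprintf("  average synchrony r = %.3f (95%% CI %.3f-%.3f), Mantel p = %.4g (%d permutations)\n",
                x$average_r, x$average_ci[1], x$average_ci[2],
                x$mantel_p, x$n_perm))
  }
  invisible(x)
}

#' Distance-free bootstrap null model
#'
#' Resamples the pair list with replacement (weights carried), ignoring
#' distances, and recomputes the weighted average z each draw. Yields the
#' 95% confidence interval of the average synchrony (central 95% of the
#' back-transformed resampled means) and a flat pointwise band over the
#' distance grid from the refitted constant-only models.
#'
#' @param pairs `pair_correlation` table.
#' @param n_perm bootstrap draws (a warning is raised below 100).
#' @param seed integer seed.
#' @param grid distance grid for the pointwise band.
#' @return list with `average_r`, `average_ci` (r scale), and `band` (2 x
#'   length(grid) matrix of lower/upper r limits).
#' @export
null_envelope_no_correlation <- function(pairs, n_perm = 5000, seed = 1L,
                                         grid = seq(0, max(pairs$dist_km),
                                                    length.out = 100)) {
  if (n_perm < 100) warning("n_perm < 100 gives poor envelope resolution")
  set.seed(seed)
  n <- nrow(pairs)
  means <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    stats::weighted.mean(pairs$z[idx], pairs$n_shared[idx])
  }, numeric(1))
  ci_z <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  band <- rbind(lower = rep(inverse_fisher(ci_z[1]), length(grid)),
                upper = rep(inverse_fisher(ci_z[2]), length(grid)))
  list(average_r = average_synchrony(pairs),
       average_ci = inverse_fisher(ci_z),
       band = band, n_perm = n_perm, seed = seed)
}

#' Mantel-style distance-shuffling null model
#'
#' Permutes site labels of the distance matrix (rows and columns jointly),
#' re-pairs the empirical correlations with the permuted distances, and
#' refits the correlogram spline with the same base parameters each time.
#' The pointwise envelope is the central 95% of the permuted predictions
#' per grid distance, and the adjusted Mantel p-value is the proportion of
#' permuted fits whose adjusted r-squared exceeds the empirical one.
#'
#' @param pairs `pair_correlation` table (must carry the `dist_matrix`
#'   attribute from [pairwise_synchrony()], or pass `distances`).
#' @param n_perm number of site-label permutations.
#' @param seed integer seed.
#' @param grid distance grid for the envelope.
#' @param k spline basis dimension (same base parameters as the empirical
#'   fit).
#' @param r2_emp empirical adjusted r-squared; computed from `pairs` when
#'   missing.
#' @param distances optional site-level distance matrix.
#' @param band compute the pointwise envelope (slower); FALSE returns the
#'   p-value machinery only.
#' @param sp optional fixed smoothing parameter (same base parameters as
#'   the empirical fit).
#' @return list with `band` (2 x length(grid), r scale), `p` (Mantel
#'   p-value), and `r2_perm` (the permuted adjusted r-squared values).
#' @export
null_envelope_distance_shuffle <- function(pairs, n_perm = 5000, seed = 1L,
                                           grid = seq(0, max(pairs$dist_km),
                                                      length.out = 100),
                                           k = 5, r2_emp = NULL,
                                           distances = attr(pairs, "dist_matrix"),
                                           band = TRUE, sp = NULL) {
  if (is.null(distances)) {
    stop("need the site-level distance matrix (attribute dist_matrix)")
  }
  if (n_perm < 100) warning("n_perm < 100 gives poor envelope resolution")
  sites <- rownames(distances)
  i1 <- match(pairs$site1, sites)
  i2 <- match(pairs$site2, sites)
  if (is.null(r2_emp)) {
    r2_emp <- correlogram_gam(pairs$z, pairs$dist_km, pairs$n_shared, k,
                              sp = sp)$r2_adj
  }
  set.seed(seed)
  preds <- matrix(NA_real_, n_perm, length(grid))
  r2_perm <- numeric(n_perm)
  n_sites <- length(sites)
  n_pairs <- nrow(pairs)
  k_eff <- min(k, length(unique(pairs$dist_km)))
  complete <- n_pairs == choose(n_sites, 2) && k_eff >= 3

  if (complete) {
    # a site relabelling maps the complete pair set onto itself, so the
    # permuted distances are a reordering of the empirical ones: refit on
    # the fixed design with (z, w) carried to the relabelled pair, reusing
    # the precomputed model setup (exactly equal to a fresh gam fit)
    dat <- data.frame(z = pairs$z, d = pairs$dist_km, w = pairs$n_shared)
    G <- mgcv::gam(z ~ s(d, k = k_eff, bs = "cr"), weights = w,
                   data = dat, fit = FALSE, sp = sp)
    Xpred <- cbind(1, mgcv::PredictMat(G$smooth[[1]],
                                       data.frame(d = grid)))
    pair_row <- matrix(NA_integer_, n_sites, n_sites)
    pair_row[cbind(i1, i2)] <- seq_len(n_pairs)
    pair_row[cbind(i2, i1)] <- seq_len(n_pairs)
    y_new <- numeric(n_pairs)
    w_new <- numeric(n_pairs)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n_sites)
      q <- pair_row[cbind(perm[i1], perm[i2])]
      y_new[q] <- pairs$z
      w_new[q] <- pairs$n_shared
      G$y <- y_new
      G$w <- w_new
      f <- mgcv::gam(G = G)
      if (band) preds[b, ] <- as.numeric(Xpred %*% stats::coef(f))
      r2_perm[b] <- weighted_adj_r2(y_new, stats::fitted(f), w_new,
                                    sum(f$edf))
    }
  } else {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n_sites)
      d_perm <- distances[cbind(perm[i1], perm[i2])]
      g <- correlogram_gam(pairs$z, d_perm, pairs$n_shared, k, sp = sp)
      if (band) preds[b, ] <- g$predict(grid)
      r2_perm[b] <- g$r2_adj
    }
  }
  band_r <- NULL
  if (band) {
    band_z <- apply(preds, 2, stats::quantile, probs = c(0.025, 0.975))
    rownames(band_z) <- c("lower", "upper")
    band_r <- inverse_fisher(band_z)
  }
  list(band = band_r,
       p = mean(r2_perm > r2_emp),
       r2_perm = r2_perm, n_perm = n_perm, seed = seed)
}
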