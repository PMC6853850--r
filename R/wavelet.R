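#' Morlet continuous wavelet transform
#'
#' FFT-based continuous wavelet transform with the Morlet mother wavelet
#' psi0(eta) = pi^(-1/4) exp(i w0 eta) exp(-eta^2 / 2). The series is
#' centred and scaled to unit variance, zero-padded to the next power of
#' two, and analysed on log-spaced scales covering the requested period
#' range. Scale-to-period conversion and the cone of influence (e-folding
#' time sqrt(2) * scale) follow the standard continuous-wavelet
#' conventions.
#'
#' @param x numeric series, length >= 5, no internal missing values (split
#'   gapped series first, see [split_at_gaps()]).
#' @param dt sampling interval in years (default 1).
#' @param period_range periods (years) to cover, default c(2, 8.5).
#' @param dj scale resolution in octaves (default 1/12 = 12 voices per
#'   octave).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @return list of class `morlet_cwt`: complex coefficient matrix `W`
#'   (scales x time), `periods`, `scales`, `coi` (maximum reliable period
#'   per time point), `n`, and the transform parameters.
#' @export
morlet_transform <- function(x, dt = 1, period_range = c(2, 8.5),
                             dj = 1 / 12, omega0 = 6) {
  n <- length(x)
  if (n < 5) stop("series too short for the transform (need >= 5 points)")
  if (anyNA(x)) stop("series contains missing values; split at gaps first")
  if (stats::sd(x) == 0) stop("degenerate series: zero variance")
  x_std <- (x - mean(x)) / stats::sd(x)

  # Fourier period of the Morlet wavelet: period = ff * scale
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- period_range[1] / ff
  J <- ceiling(log2(period_range[2] / period_range[1]) / dj)
  scales <- s0 * 2^((0:J) * dj)
  periods <- scales * ff

  # zero-pad to the next power of two beyond the longest wavelet's
  # support, so the circular FFT convolution matches a linear one
  npad <- 2^ceiling(log2(n + ceiling(6 * max(scales) / dt)))
  xpad <- c(x_std, rep(0, npad - n))

  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)

  fx <- stats::fft(xpad)
  W <- matrix(0 + 0i, length(scales), npad)
  norm_const <- pi^(-1 / 4)
  for (s in seq_along(scales)) {
    sc <- scales[s]
    daughter <- sqrt(2 * pi * sc / dt) * norm_const *
      exp(-((sc * omega - omega0)^2) / 2) * (omega > 0)
    W[s, ] <- stats::fft(fx * daughter, inverse = TRUE) / npad
  }
  W <- W[, seq_len(n), drop = FALSE]

  t_idx <- seq_len(n)
  edge <- pmax(pmin(t_idx - 1, n - t_idx), 1e-8)
  coi <- ff * sqrt(2) * dt * edge

  structure(list(W = W, periods = periods, scales = scales, coi = coi,
                 n = n, dt = dt, dj = dj, omega0 = omega0,
                 fourier_factor = ff),
            class = "morlet_cwt")
}

#' Bias-corrected wavelet power
#'
#' Rectifies the raw power spectrum's bias toward long periods by
#' dividing the squared transform modulus by the scale: power =
#' |W(s, t)|^2 / s.
#'
#' @param W complex coefficient matrix (scales x time) or a `morlet_cwt`.
#' @param scales scale vector (taken from the transform when `W` is a
#'   `morlet_cwt`).
#' @return non-negative power matrix of the same dimension as `W`.
#' @export
bias_corrected_power <- function(W, scales = NULL) {
  if (inherits(W, "morlet_cwt")) {
    scales <- W$scales
    W <- W$W
  }
  stopifnot(!is.null(scales), length(scales) == nrow(W), all(scales > 0))
  Mod(W)^2 / scales
}

#' Split a year-indexed series at internal gaps
#'
#' Internal missing years split the series into contiguous segments that
#' are analysed separately (no interpolation).
#'
#' @param years integer calendar years (strictly increasing).
#' @param values series values, same length.
#' @return list of `list(years=, values=)` segments.
#' @export
split_at_gaps <- function(years, values) {
  stopifnot(length(years) == length(values), !is.unsorted(years))
  brk <- c(0, which(diff(years) > 1), length(years))
  lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    list(years = years[idx], values = values[idx])
  })
}

#' Per-site bias-corrected wavelet spectrum
#'
#' Runs the Morlet transform on one site's occupancy series and returns
#' the bias-corrected power on the (period x calendar-year) grid, with an
#' in-COI indicator per cell.
#'
#' @param years calendar years of the series (contiguous).
#' @param values occupancy rates (or any abundance proxy).
#' @param site site identifier carried in the result.
#' @param ... passed to [morlet_transform()].
#' @return list of class `site_spectrum`: `site`, `periods`, `years`,
#'   `power`, `in_coi` (logical matrix), `normalized` flag.
#' @export
site_spectrum <- function(years, values, site = "site", ...) {
  cw <- morlet_transform(values, ...)
  power <- bias_corrected_power(cw)
  in_coi <- outer(cw$periods, cw$coi, "<=")
  structure(list(site = site, periods = cw$periods, years = years,
                 power = power, in_coi = in_coi, normalized = FALSE),
            class = "site_spectrum")
}

#' Normalize a wavelet spectrum to mean 0, sd 1
#'
#' Z-scores all included cells of one site's power matrix (sd with the
#' n - 1 denominator). By default all cells are included; set
#' `coi_only = TRUE` to normalize over the in-COI cells only (cells
#' outside the COI are then set to NA).
#'
#' @param spec a `site_spectrum`.
#' @param coi_only restrict to cells inside the cone of influence.
#' @return the spectrum with `power` z-scored and `normalized = TRUE`.
#' @export
normalize_spectrum <- function(spec, coi_only = FALSE) {
  stopifnot(inherits(spec, "site_spectrum"))
  cells <- if (coi_only) spec$power[spec$in_coi] else as.vector(spec$power)
  if (length(cells) < 2) stop("need at least two cells to normalize")
  s <- stats::sd(cells)
  if (s == 0) stop("zero variance across spectrum cells")
  out <- (spec$power - mean(cells)) / s
  if (coi_only) out[!spec$in_coi] <- NA_real_
  spec$power <- out
  spec$normalized <- TRUE
  spec
}

#' Pool normalized spectra across sites
#'
#' Aligns site spectra on calendar years, averages the normalized power
#' per (period, year) cell over the sites contributing to that cell, and
#' records the contributing-site count used by the significance rule.
#'
#' @param spectra list of normalized `site_spectrum` objects sharing one
#'   period grid.
#' @param min_overlap minimum contributing sites for a cell to enter the
#'   significance mask (default 5).
#' @return list of class `pooled_spectrum`: `periods`, `years` (union
#'   grid), `mean_power`, `n_sites` count matrix, `min_overlap`.
#' @export
pool_spectra <- function(spectra, min_overlap = 5) {
  stopifnot(length(spectra) >= 1)
  if (!all(vapply(spectra, function(s) isTRUE(s$normalized), logical(1)))) {
    stop("all spectra must be normalized before pooling")
  }
  p0 <- spectra[[1]]$periods
  for (s in spectra) {
    if (length(s$periods) != length(p0) ||
        any(abs(s$periods - p0) > 1e-8 * p0)) {
      stop("period grids differ between spectra; use one transform setup")
    }
  }
  years <- sort(unique(unlist(lapply(spectra, `[[`, "years"))))
  acc <- matrix(0, length(p0), length(years))
  cnt <- matrix(0L, length(p0), length(years))
  for (s in spectra) {
    cols <- match(s$years, years)
    ok <- !is.na(s$power)
    acc[, cols] <- acc[, cols] + ifelse(ok, s$power, 0)
    cnt[, cols] <- cnt[, cols] + ok
  }
  mean_power <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(periods = p0, years = years, mean_power = mean_power,
                 n_sites = cnt, min_overlap = min_overlap),
            class = "pooled_spectrum")
}

#' Cell-wise Gaussian significance mask
#'
#' A cell of the pooled spectrum is flagged when enough sites contribute
#' (count >= min_overlap) and its mean normalized power exceeds the
#' upper Gaussian limit z_(1 - alpha/2) / sqrt(count) — i.e. power
#' significantly higher than the overall (zero-mean) average. Only the
#' upper tail is tested.
#'
#' @param pooled a `pooled_spectrum`.
#' @param alpha two-sided nominal level of the Gaussian interval whose
#'   upper limit is used (default 0.05).
#' @return logical matrix (periods x years), TRUE where significant.
#' @export
significance_mask <- function(pooled, alpha = 0.05) {
  stopifnot(inherits(pooled, "pooled_spectrum"))
  zcrit <- stats::qnorm(1 - alpha / 2)
  ok <- pooled$n_sites >= pooled$min_overlap
  mask <- ok & !is.na(pooled$mean_power) &
    pooled$mean_power > zcrit / sqrt(pmax(pooled$n_sites, 1L))
  mask[is.na(mask)] <- FALSE
  mask
}

#' Wavelet spectra for every site of a series table
#'
#' Builds the per-site normalized spectra from a `site_series` table:
#' series are split at internal gaps, segments shorter than `min_length`
#' or with zero variance are skipped (with a message), and each remaining
#' segment is transformed, bias-corrected and normalized.
#'
#' @param series `site_series` with `site`, `year`, `rate`.
#' @param min_length minimum segment length (default 5).
#' @param coi_only normalize over in-COI cells only.
#' @param ... passed to [morlet_transform()].
#' @return list of normalized `site_spectrum` objects.
#' @export
site_spectra <- function(series, min_length = 5, coi_only = FALSE, ...) {
  out <- list()
  for (s in unique(series$site)) {
    sub <- series[series$site == s, ]
    sub <- sub[order(sub$year), ]
    for (seg in split_at_gaps(sub$year, sub$rate)) {
      if (length(seg$values) < min_length) {
        message("site ", s, ": segment of ", length(seg$values),
                " year(s) too short for wavelet analysis, skipped")
        next
      }
      if (stats::sd(seg$values) == 0) {
        message("site ", s, ": constant segment skipped")
        next
      }
      sp <- site_spectrum(seg$years, seg$values, site = s, ...)
      out[[length(out) + 1L]] <- normalize_spectrum(sp, coi_only = coi_only)
    }
  }
  out
}

#' Long-format export of a pooled spectrum
#'
#' @param pooled a `pooled_spectrum`.
#' @param mask optional significance mask from [significance_mask()].
#' @return data.frame `period`, `year`, `power`, `n_sites`, `significant`.
#' @export
pooled_spectrum_table <- function(pooled, mask = significance_mask(pooled)) {
  data.frame(
    period = rep(pooled$periods, times = length(pooled$years)),
    year = rep(pooled$years, each = length(pooled$periods)),
    power = as.vector(pooled$mean_power),
    n_sites = as.vector(pooled$n_sites),
    significant = as.vector(mask)
  )
}
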