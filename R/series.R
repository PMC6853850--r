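#' Occupancy-rate series from a survey table
#'
#' Converts a long-format survey table into per-site occupancy-rate
#' series: rate = n_occupied / n_surveyed. Site-years with zero surveyed
#' units are dropped with a warning; records with more occupied than
#' surveyed units are rejected (dropped with a warning naming them).
#'
#' @param survey data.frame with columns `site`, `year`, `n_surveyed`,
#'   `n_occupied` and optionally `lat`, `lon`, `method`.
#' @return data.frame of class `site_series` with one row per surveyed
#'   site-year: `site`, `year`, `rate`, plus any coordinate/method columns
#'   carried through; ordered by site then year.
#' @export
occupancy_rate <- function(survey) {
  req <- c("site", "year", "n_surveyed", "n_occupied")
  missing_cols <- setdiff(req, names(survey))
  if (length(missing_cols)) {
    stop("survey table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- !is.na(survey$n_occupied) & survey$n_occupied > survey$n_surveyed
  if (any(bad)) {
    warning(sum(bad), " record(s) with n_occupied > n_surveyed rejected")
    survey <- survey[!bad, ]
  }
  zero <- survey$n_surveyed == 0 | is.na(survey$n_occupied)
  if (any(zero)) {
    warning(sum(zero), " site-year(s) with no surveyed units dropped")
    survey <- survey[!zero, ]
  }
  out <- survey
  out$rate <- out$n_occupied / out$n_surveyed
  out <- out[order(out$site, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("site_series", "data.frame")
  out
}

#' Log growth rates of occupancy series
#'
#' Adds the per-year log growth rate R_t = log(N_t / N_{t-1}) to a series
#' table, where N is the occupancy rate. R_t is defined only for
#' consecutive-year pairs with both rates positive; transitions touching a
#' zero rate are skipped with a warning (no pseudo-count is applied).
#'
#' @param series a `site_series` data.frame from [occupancy_rate()].
#' @return the same table with a `growth` column (NA where undefined).
#' @export
growth_rate <- function(series) {
  stopifnot(all(c("site", "year", "rate") %in% names(series)))
  series <- series[order(series$site, series$year), ]
  n_zero_skip <- 0L
  growth <- rep(NA_real_, nrow(series))
  for (s in unique(series$site)) {
    idx <- which(series$site == s)
    yr <- series$year[idx]
    rt <- series$rate[idx]
    prev <- match(yr - 1L, yr)        # consecutive-year predecessor, if any
    ok <- !is.na(prev)
    defined <- ok & rt > 0 & rt[prev] > 0
    defined[is.na(defined)] <- FALSE
    n_zero_skip <- n_zero_skip + sum(ok & !defined, na.rm = TRUE)
    growth[idx[defined]] <- log(rt[defined] / rt[prev[defined]])
  }
  if (n_zero_skip > 0) {
    warning(n_zero_skip,
            " transition(s) with zero occupancy skipped (log undefined)")
  }
  series$growth <- growth
  rownames(series) <- NULL
  class(series) <- c("site_series", "data.frame")
  series
}

#' Great-circle distance matrix between site centres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param centres data.frame with columns `lat`, `lon` in decimal degrees
#'   (one row per site); row order defines the matrix order. An optional
#'   `site` column provides dimnames.
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
pairwise_distance <- function(centres) {
  centres <- as.data.frame(centres)
  stopifnot(all(c("lat", "lon") %in% names(centres)))
  if (any(abs(centres$lat) > 90) || any(abs(centres$lon) > 180)) {
    stop("invalid coordinates: latitude must be in [-90, 90], ",
         "longitude in [-180, 180]")
  }
  R <- 6371.0088
  lat <- centres$lat * pi / 180
  lon <- centres$lon * pi / 180
  n <- nrow(centres)
  dlat <- outer(lat, lat, "-")
  dlon <- outer(lon, lon, "-")
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  d <- 2 * R * asin(sqrt(pmin(a, 1)))
  diag(d) <- 0
  if (!is.null(centres$site)) dimnames(d) <- list(centres$site, centres$site)
  d
}

#' Seasonal weather covariates from monthly records
#'
#' Aggregates monthly weather into the seasonal indices used by the
#' growth-rate model: winter = mean of December (previous calendar year),
#' January and February; spring = April-May; summer = June-August;
#' autumn = October-November. March and September are excluded. A seasonal
#' value is emitted only when every contributing month is present.
#'
#' @param monthly data.frame with columns `site`, `year`, `month` (1-12),
#'   `variable` (e.g. "temp", "rain", "snow") and `value`. December is
#'   assigned to the winter labelled by the following calendar year.
#' @return covariate data.frame `site`, `year`, `name`, `value` with
#'   names like `winter_temp`, `spring_rain`, `summer_temp`,
#'   `autumn_rain`.
#' @export
aggregate_weather <- function(monthly) {
  stopifnot(all(c("site", "year", "month", "variable", "value") %in%
                  names(monthly)))
  seasons <- list(
    winter = c(12L, 1L, 2L),
    spring = c(4L, 5L),
    summer = c(6L, 7L, 8L),
    autumn = c(10L, 11L)
  )
  # December contributes to the winter of the following calendar year
  m <- monthly
  m$season_year <- ifelse(m$month == 12L, m$year + 1L, m$year)
  out <- list()
  for (season in names(seasons)) {
    sub <- m[m$month %in% seasons[[season]], ]
    if (!nrow(sub)) next
    agg <- stats::aggregate(
      value ~ site + season_year + variable, data = sub,
      FUN = function(v) if (length(v) == length(v[!is.na(v)])) mean(v) else NA_real_)
    cnt <- stats::aggregate(value ~ site + season_year + variable, data = sub,
                            FUN = length)
    agg <- agg[cnt$value == length(seasons[[season]]) & !is.na(agg$value), ]
    if (!nrow(agg)) next
    out[[season]] <- data.frame(
      site = agg$site, year = agg$season_year,
      name = paste0(season, "_", agg$variable), value = agg$value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site, res$year, res$name), ]
}

#' Vole abundance index
#'
#' Index of vole abundance from snap-trapping: (pooled voles + 1) divided
#' by the number of trap-nights, times 100.
#'
#' @param n_voles pooled count of trapped voles.
#' @param n_traps total traps set (>= 1).
#' @return voles per 100 trap-nights (with the +1 offset).
#' @export
vole_index <- function(n_voles, n_traps) {
  if (any(n_traps < 1)) stop("vole index undefined for n_traps < 1")
  (n_voles + 1) / n_traps * 100
}

#' Site centres from a series or survey table
#'
#' One row per site with its centre coordinates (first value per site, or
#' the arithmetic mean when per-unit coordinates vary within a site).
#'
#' @param x data.frame with `site`, `lat`, `lon`.
#' @return data.frame `site`, `lat`, `lon`, one row per site, in order of
#'   first appearance.
#' @export
site_centres <- function(x) {
  stopifnot(all(c("site", "lat", "lon") %in% names(x)))
  agg <- stats::aggregate(cbind(lat, lon) ~ site, data = x, FUN = mean)
  agg[match(unique(x$site), agg$site), ]
}

#' Attach lagged covariates to growth-rate observations
#'
#' Builds the model dataset for one lag frame: for `lag = "year_t"` a
#' covariate measured in year t is attached to the growth rate R_t; for
#' `lag = "year_t-1"` the value from year t-1 is attached. The previous
#' year's occupancy rate N_{t-1} is always included. Rows with any missing
#' covariate are dropped (complete-case).
#'
#' @param series `site_series` with a `growth` column (see
#'   [growth_rate()]).
#' @param covariates covariate data.frame `site`, `year`, `name`, `value`.
#' @param lag `"year_t"` or `"year_t-1"`.
#' @param covariate_names covariates to include (default: all present).
#' @return data.frame with `site`, `year`, `growth`, `rate`, `rate_prev`
#'   and one column per covariate.
#' @export
build_model_data <- function(series, covariates = NULL,
                             lag = c("year_t-1", "year_t"),
                             covariate_names = NULL) {
  lag <- match.arg(lag)
  stopifnot("growth" %in% names(series))
  d <- series[!is.na(series$growth),
              c("site", "year", "rate", "growth")]
  prev <- series[, c("site", "year", "rate")]
  prev$year <- prev$year + 1L
  names(prev)[3] <- "rate_prev"
  d <- merge(d, prev, by = c("site", "year"))
  if (!is.null(covariates)) {
    if (is.null(covariate_names)) covariate_names <- unique(covariates$name)
    shift <- if (lag == "year_t-1") 1L else 0L
    for (nm in covariate_names) {
      cv <- covariates[covariates$name == nm, c("site", "year", "value")]
      cv$year <- cv$year + shift
      names(cv)[3] <- nm
      d <- merge(d, cv, by = c("site", "year"), all.x = TRUE)
    }
    d <- d[stats::complete.cases(d), ]
  }
  d <- d[order(d$site, d$year), ]
  rownames(d) <- NULL
  d
}
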