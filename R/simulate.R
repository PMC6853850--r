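#' Configuration for the Moran-effect survey simulator
#'
#' Builds and validates the configuration for a synthetic multi-site
#' occupancy survey. Local dynamics are Gompertz (log-scale AR(1)) with
#' density dependence `b`, forced by spatially correlated environmental
#' noise whose between-site correlation decays as exp(-d/rho) with
#' great-circle distance d. The latent log-abundance is observed through
#' binomial occupancy counts with a logistic link and method-specific
#' detection probability.
#'
#' @param n_sites number of sites (>= 2).
#' @param site_coords optional data.frame with columns `lat`, `lon`
#'   (decimal degrees). When `NULL`, sites are placed uniformly at random
#'   inside `bbox`.
#' @param bbox bounding box `c(lat_min, lat_max, lon_min, lon_max)` used
#'   when coordinates are drawn at random.
#' @param year_range inclusive calendar-year range covering all sites.
#' @param site_spans optional 2-column matrix (first, last year) giving a
#'   ragged observation window per site; defaults to spans drawn uniformly
#'   between `span_range` years, right-aligned at random within
#'   `year_range`.
#' @param span_range range (years) from which ragged site spans are drawn.
#' @param b density dependence on the log scale; must lie in (-2, 0] for
#'   stationary, stabilizing dynamics.
#' @param equilibrium_occupancy per-site equilibrium occupancy rates used
#'   to derive the intercepts `a_i`; recycled to `n_sites`.
#' @param env_decay_km e-folding range rho (km) of the environmental
#'   correlation; must be > 0.
#' @param env_sd standard deviation sigma_e of the environmental noise on
#'   the log-abundance scale; >= 0.
#' @param covariate_effects named numeric vector of regression
#'   coefficients beta_k applied to simulated covariates.
#' @param covariate_stats named list (one entry per covariate) of
#'   `list(mean=, sd=)` describing the covariate's marginal distribution;
#'   covariates are drawn i.i.d. Gaussian per site-year.
#' @param n_units units surveyed per site-year (nest-boxes or forest
#'   patches); recycled to `n_sites`.
#' @param method survey method per site, `"nestbox"` or `"pellet"`;
#'   recycled to `n_sites`.
#' @param p_det named detection probabilities per method, each in (0, 1].
#' @param oscillation optional list `list(years=, period=, amplitude=,
#'   sites=)` adding a sinusoid of the given period (years) and amplitude
#'   (log-abundance units) to the latent state of the chosen sites within
#'   the given calendar-year window, to plant transient cyclicity.
#' @param burn_in years simulated and discarded before the first
#'   observation (>= 50).
#' @param seed integer root seed; the same configuration (including the
#'   seed) reproduces the survey table exactly.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 16,
                       site_coords = NULL,
                       bbox = c(60, 64, 21, 27),
                       year_range = c(1988, 2015),
                       site_spans = NULL,
                       span_range = c(5, 25),
                       b = -0.5,
                       equilibrium_occupancy = NULL,
                       env_decay_km = 200,
                       env_sd = 0.3,
                       covariate_effects = NULL,
                       covariate_stats = NULL,
                       n_units = 150,
                       method = NULL,
                       p_det = c(nestbox = 0.3, pellet = 0.9),
                       oscillation = NULL,
                       burn_in = 50,
                       seed = 1L) {
  stopifnot(n_sites >= 2, env_decay_km > 0, env_sd >= 0, burn_in >= 50)
  if (b <= -2 || b > 0) {
    stop("density dependence b must lie in (-2, 0]: got ", b)
  }
  if (any(p_det <= 0) || any(p_det > 1)) {
    stop("detection probabilities must lie in (0, 1]")
  }
  seed <- as.integer(seed)

  # derive deterministic child seeds for the independent random stages
  set.seed(seed)
  streams <- sample.int(.Machine$integer.max - 1L, 5L)
  names(streams) <- c("coords", "spans", "environment", "covariates",
                      "observation")

  if (is.null(site_coords)) {
    set.seed(streams[["coords"]])
    site_coords <- data.frame(
      lat = stats::runif(n_sites, bbox[1], bbox[2]),
      lon = stats::runif(n_sites, bbox[3], bbox[4])
    )
  } else {
    site_coords <- as.data.frame(site_coords)
    stopifnot(nrow(site_coords) == n_sites,
              all(c("lat", "lon") %in% names(site_coords)))
  }

  years <- seq(year_range[1], year_range[2])
  if (is.null(site_spans)) {
    set.seed(streams[["spans"]])
    len <- sample(span_range[1]:min(span_range[2], length(years)),
                  n_sites, replace = TRUE)
    first <- vapply(len, function(l) {
      sample(seq_len(length(years) - l + 1L), 1L)
    }, integer(1))
    site_spans <- cbind(years[first], years[first + len - 1L])
  } else {
    site_spans <- as.matrix(site_spans)
    stopifnot(nrow(site_spans) == n_sites,
              all(site_spans[, 1] >= year_range[1]),
              all(site_spans[, 2] <= year_range[2]))
  }

  method <- if (is.null(method)) {
    # two pellet sites out of nine, scaled up: keep roughly that ratio
    rep(c("nestbox", "pellet"), c(ceiling(0.8 * n_sites),
                                  n_sites - ceiling(0.8 * n_sites)))
  } else rep_len(method, n_sites)
  stopifnot(all(method %in% names(p_det)))

  if (is.null(equilibrium_occupancy)) {
    # occupancy levels mimicking the field data: nest-box sites 0.05-0.18,
    # pellet sites around 0.55-0.60
    equilibrium_occupancy <- numeric(n_sites)
    nb <- method == "nestbox"
    equilibrium_occupancy[nb] <- seq(0.05, 0.18, length.out = sum(nb))
    equilibrium_occupancy[!nb] <- seq(0.55, 0.6, length.out = sum(!nb))
  }
  equilibrium_occupancy <- rep_len(equilibrium_occupancy, n_sites)
  # invert rate = p_det * logistic(x*) at the fixed point x* = a/(-b)
  p_site <- p_det[method]
  if (any(equilibrium_occupancy >= p_site)) {
    stop("equilibrium occupancy must be below the detection probability")
  }
  a <- stats::qlogis(equilibrium_occupancy / p_site) * (-b)

  if (!is.null(covariate_effects)) {
    stopifnot(!is.null(names(covariate_effects)))
    if (is.null(covariate_stats)) {
      covariate_stats <- stats::setNames(
        rep(list(list(mean = 0, sd = 1)), length(covariate_effects)),
        names(covariate_effects))
    }
    stopifnot(all(names(covariate_effects) %in% names(covariate_stats)))
  }

  structure(list(
    n_sites = n_sites, site_coords = site_coords, years = years,
    site_spans = site_spans, b = b, a = a,
    equilibrium_occupancy = equilibrium_occupancy,
    env_decay_km = env_decay_km, env_sd = env_sd,
    covariate_effects = covariate_effects,
    covariate_stats = covariate_stats,
    n_units = rep_len(n_units, n_sites), method = method, p_det = p_det,
    oscillation = oscillation, burn_in = burn_in, seed = seed,
    streams = streams
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Moran-effect survey simulator configuration\n")
  cat(sprintf("  %d sites, years %d-%d, b = %.2f, rho = %g km, sigma_e = %g\n",
              x$n_sites, min(x$years), max(x$years), x$b,
              x$env_decay_km, x$env_sd))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Spatially correlated environmental forcing
#'
#' Draws the environmental noise matrix: each year's cross-site vector is
#' multivariate Gaussian with zero mean and covariance
#' `sigma_e^2 * exp(-d_ij / rho)`; years are independent.
#'
#' @param cfg a [sim_config()].
#' @param n_years number of years to draw (defaults to the configured span
#'   plus burn-in).
#' @return matrix of dimension n_sites x n_years.
#' @export
simulate_environment <- function(cfg, n_years = length(cfg$years) + cfg$burn_in) {
  d <- pairwise_distance(cfg$site_coords)
  if (cfg$env_sd == 0) {
    return(matrix(0, cfg$n_sites, n_years))
  }
  sigma <- cfg$env_sd^2 * exp(-d / cfg$env_decay_km)
  L <- tryCatch(
    chol(sigma),
    error = function(e) {
      jit <- 1e-10 * cfg$env_sd^2
      tryCatch(chol(sigma + diag(jit, nrow(sigma))),
               error = function(e2) {
                 stop("environmental covariance is not positive definite ",
                      "even after jitter ", jit, ": ", conditionMessage(e2))
               })
    })
  set.seed(cfg$streams[["environment"]])
  z <- matrix(stats::rnorm(cfg$n_sites * n_years), cfg$n_sites, n_years)
  crossprod(L, z)
}

#' Simulate site-year covariate values
#'
#' Covariates named in `covariate_effects` are drawn i.i.d. Gaussian per
#' site-year with the configured mean and sd.
#'
#' @param cfg a [sim_config()].
#' @param n_years number of years (burn-in included).
#' @return named list of n_sites x n_years matrices (empty when no
#'   covariates are configured).
#' @export
simulate_covariates <- function(cfg, n_years = length(cfg$years) + cfg$burn_in) {
  if (is.null(cfg$covariate_effects)) return(list())
  set.seed(cfg$streams[["covariates"]])
  out <- lapply(names(cfg$covariate_effects), function(nm) {
    st <- cfg$covariate_stats[[nm]]
    matrix(stats::rnorm(cfg$n_sites * n_years, st$mean, st$sd),
           cfg$n_sites, n_years)
  })
  stats::setNames(out, names(cfg$covariate_effects))
}

#' Latent Gompertz log-abundance dynamics
#'
#' Iterates `x[i, t+1] = a_i + (1 + b) x[i, t] + sum_k beta_k cov[k, i, t]
#' + env[i, t]`, starting at the stationary mean and discarding the
#' burn-in years. An optional oscillation block adds a sinusoid to the
#' retained years of selected sites.
#'
#' @param cfg a [sim_config()].
#' @param env environment matrix from [simulate_environment()].
#' @param covariates list of covariate matrices from
#'   [simulate_covariates()].
#' @return matrix n_sites x length(cfg$years) of latent log-abundance,
#'   with `dimnames` carrying calendar years.
#' @export
simulate_latent <- function(cfg, env, covariates = simulate_covariates(cfg)) {
  n_years <- ncol(env)
  n_total <- length(cfg$years) + cfg$burn_in
  stopifnot(n_years == n_total)
  phi <- 1 + cfg$b
  # stationary mean of the AR(1): a + beta*mean_cov drift absorbed at start
  drift <- cfg$a
  if (length(covariates)) {
    for (nm in names(covariates)) {
      drift <- drift + cfg$covariate_effects[[nm]] * cfg$covariate_stats[[nm]]$mean
    }
  }
  x <- matrix(0, cfg$n_sites, n_total)
  x[, 1] <- drift / (1 - phi)
  for (t in seq_len(n_total - 1L)) {
    forcing <- cfg$a + env[, t]
    if (length(covariates)) {
      for (nm in names(covariates)) {
        forcing <- forcing + cfg$covariate_effects[[nm]] * covariates[[nm]][, t]
      }
    }
    x[, t + 1L] <- forcing + phi * x[, t]
  }
  x <- x[, -seq_len(cfg$burn_in), drop = FALSE]
  if (!is.null(cfg$oscillation)) {
    osc <- cfg$oscillation
    yrs <- intersect(cfg$years, osc$years)
    cols <- match(yrs, cfg$years)
    for (i in osc$sites) {
      x[i, cols] <- x[i, cols] +
        osc$amplitude * sin(2 * pi * (yrs - min(yrs)) / osc$period)
    }
  }
  dimnames(x) <- list(paste0("site", seq_len(cfg$n_sites)), cfg$years)
  x
}

#' Observe latent abundance through binomial occupancy counts
#'
#' Each surveyed site-year yields `occupied ~ Binomial(n_units,
#' p_det(method) * logistic(x))`. Years outside a site's configured span
#' are not surveyed and are omitted from the table.
#'
#' @param x latent matrix from [simulate_latent()].
#' @param cfg a [sim_config()].
#' @return long-format survey data.frame with columns `site`, `lat`,
#'   `lon`, `method`, `year`, `n_surveyed`, `n_occupied`.
#' @export
observe_occupancy <- function(x, cfg) {
  set.seed(cfg$streams[["observation"]])
  rows <- vector("list", cfg$n_sites)
  for (i in seq_len(cfg$n_sites)) {
    yrs <- seq(cfg$site_spans[i, 1], cfg$site_spans[i, 2])
    cols <- match(yrs, cfg$years)
    p_occ <- cfg$p_det[[cfg$method[i]]] * stats::plogis(x[i, cols])
    n <- cfg$n_units[i]
    occ <- if (n >= 1) stats::rbinom(length(yrs), n, p_occ) else
      rep(NA_integer_, length(yrs))
    rows[[i]] <- data.frame(
      site = paste0("site", i),
      lat = cfg$site_coords$lat[i], lon = cfg$site_coords$lon[i],
      method = cfg$method[i], year = yrs,
      n_surveyed = n, n_occupied = occ
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full simulator
#'
#' Environment, covariates, latent dynamics and binomial observation in
#' one call. Identical configurations (including the seed) give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with the survey table, a long-format covariate table (or
#'   NULL), the latent matrix, the environment matrix (burn-in removed)
#'   and the configuration.
#' @export
simulate_survey <- function(cfg) {
  env <- simulate_environment(cfg)
  covs <- simulate_covariates(cfg)
  x <- simulate_latent(cfg, env, covs)
  survey <- observe_occupancy(x, cfg)
  keep <- -seq_len(cfg$burn_in)
  cov_table <- NULL
  if (length(covs)) {
    cov_table <- do.call(rbind, lapply(names(covs), function(nm) {
      m <- covs[[nm]][, keep, drop = FALSE]
      data.frame(site = rep(paste0("site", seq_len(cfg$n_sites)),
                            times = ncol(m)),
                 year = rep(cfg$years, each = cfg$n_sites),
                 name = nm, value = as.vector(m))
    }))
    # keep only surveyed site-years (and the year before, for lagging)
    key <- with(survey, paste(site, year))
    key_prev <- with(survey, paste(site, year - 1L))
    cov_table <- cov_table[paste(cov_table$site, cov_table$year) %in%
                             c(key, key_prev), ]
    rownames(cov_table) <- NULL
  }
  list(survey = survey, covariates = cov_table, latent = x,
       environment = env[, keep, drop = FALSE], config = cfg)
}

#' Write simulator output as CSV
#'
#' Writes the survey table, the covariate table (when present) and a JSON
#' echo of the configuration into a directory.
#'
#' @param sim result of [simulate_survey()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_survey_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("survey.csv", "covariates.csv", "config.json"))
  utils::write.csv(sim$survey, paths[1], row.names = FALSE)
  if (!is.null(sim$covariates)) {
    utils::write.csv(sim$covariates, paths[2], row.names = FALSE)
  }
  cfg <- sim$config
  echo <- cfg[setdiff(names(cfg), "streams")]
  echo$site_coords <- as.data.frame(echo$site_coords)
  echo$site_spans <- as.data.frame(echo$site_spans)
  jsonlite::write_json(echo, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
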