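#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k) from regressing design column k on all other
#' columns (with intercept). Columns perfectly explained by the others get
#' `Inf`.
#'
#' @param X numeric matrix or data.frame of covariate columns (the
#'   site-indicator block is excluded by the caller).
#' @return named numeric vector of VIFs, each >= 1 (or Inf).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least two columns")
  if (nrow(X) < ncol(X) + 1) stop("VIF needs more rows than columns")
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Growth-rate regression with site fixed effects
#'
#' Ordinary least squares of the log growth rate (or, for the abundance
#' variant, the occupancy rate itself) on a site factor, the previous
#' year's occupancy rate and a set of environmental covariates. Each
#' covariate is reported with its estimate, standard error, marginal
#' (type-III) F statistic on 1 numerator df, denominator df and p-value,
#' plus its variance inflation factor against the other non-indicator
#' columns.
#'
#' @param data model dataset from [build_model_data()] (columns `site`,
#'   `growth`, `rate`, `rate_prev` and covariates).
#' @param covariates character vector of covariate column names (default:
#'   everything beyond site/year/growth/rate/rate_prev).
#' @param response `"growth"` (log growth rate R_t) or `"abundance"`
#'   (occupancy rate N_t).
#' @param include_year add a linear calendar-year term (trend test, used
#'   with the abundance response).
#' @return object of class `growth_fit`: the `lm` fit plus a coefficient
#'   table (`estimate`, `sd`, `F`, `df_den`, `p`), site effects, residual
#'   variance and VIFs.
#' @export
fit_growth_model <- function(data, covariates = NULL,
                             response = c("growth", "abundance"),
                             include_year = FALSE) {
  response <- match.arg(response)
  if (length(unique(data$site)) < 2) stop("need at least two sites")
  if (is.null(covariates)) {
    covariates <- setdiff(names(data),
                          c("site", "year", "growth", "rate", "rate_prev"))
  }
  yvar <- if (response == "growth") "growth" else "rate"
  terms <- c("factor(site)", "rate_prev", covariates,
             if (include_year) "year")
  fml <- stats::reformulate(terms, response = yvar)
  fit <- stats::lm(fml, data = data)

  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    al <- stats::alias(fit)$Complete
    partners <- if (!is.null(al)) {
      unique(unlist(lapply(rownames(al), function(r) {
        colnames(al)[abs(al[r, ]) > 1e-8]
      })))
    } else character(0)
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(unique(c(aliased, partners)), collapse = ", "))
  }

  sm <- summary(fit)
  tab <- sm$coefficients
  keep <- c("rate_prev", covariates, if (include_year) "year")
  rows <- tab[keep, , drop = FALSE]
  df_den <- fit$df.residual
  coef_table <- data.frame(
    term = keep,
    estimate = rows[, 1], sd = rows[, 2],
    F = rows[, 3]^2, df_den = df_den,
    p = 2 * stats::pt(abs(rows[, 3]), df_den, lower.tail = FALSE),
    row.names = NULL
  )

  vifs <- if (length(keep) >= 2) {
    vif(as.matrix(data[, keep, drop = FALSE]))
  } else stats::setNames(1, keep)

  structure(list(
    fit = fit,
    response = response,
    coef_table = coef_table,
    site_effects = tab[grep("^factor\\(site\\)", rownames(tab)), 1],
    sigma2 = sm$sigma^2,
    r_squared = sm$r.squared,
    vif = vifs,
    n_obs = nrow(data),
    df_den = df_den
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth-rate model (%s response), %d observations, %d df\n",
              x$response, x$n_obs, x$df_den))
  tab <- x$coef_table
  tab$vif <- x$vif[tab$term]
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}
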