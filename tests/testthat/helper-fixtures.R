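# shared fixtures built in code

# pair-correlation table with the structure pairwise_synchrony() emits,
# from explicit z values (or a z(d) function plus noise)
make_pairs <- function(n_sites, z, weights = NULL, seed = NULL,
                       coords = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(coords)) {
    coords <- data.frame(site = paste0("s", seq_len(n_sites)),
                         lat = runif(n_sites, 60, 64),
                         lon = runif(n_sites, 21, 27))
  }
  D <- pairwise_distance(coords)
  cmb <- t(utils::combn(n_sites, 2))
  d <- D[cmb]
  zv <- if (is.function(z)) z(d) else rep_len(z, nrow(cmb))
  if (is.null(weights)) weights <- sample(3:25, nrow(cmb), replace = TRUE)
  pairs <- data.frame(site1 = coords$site[cmb[, 1]],
                      site2 = coords$site[cmb[, 2]],
                      dist_km = d, r = tanh(zv),
                      n_shared = rep_len(weights, nrow(cmb)), z = zv)
  attr(pairs, "dist_matrix") <- D
  class(pairs) <- c("pair_correlation", "data.frame")
  pairs
}

# minimal site-series table from a named list of year-indexed rate vectors
make_series <- function(rates, coords = NULL) {
  sites <- names(rates)
  if (is.null(coords)) {
    coords <- data.frame(site = sites,
                         lat = seq(60, 64, length.out = length(sites)),
                         lon = seq(21, 27, length.out = length(sites)))
  }
  out <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site = s, lat = coords$lat[coords$site == s],
               lon = coords$lon[coords$site == s],
               year = as.integer(names(rates[[s]])), rate = unname(rates[[s]]))
  }))
  rownames(out) <- NULL
  class(out) <- c("site_series", "data.frame")
  out
}

# all permutations of 1..n (for exhaustive Mantel enumeration on tiny n)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
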