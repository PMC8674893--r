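#' Mantel and partial Mantel tests
#'
#' Pearson correlation of the off-diagonal upper triangles of two pairwise
#' matrices, with a one-tailed permutation p-value obtained by jointly
#' permuting the rows and columns of `A`. When a `conditioning` matrix is
#' supplied, the partial Mantel statistic is the partial correlation of A and
#' B given C, recomputed under the same row/column permutations of A.
#'
#' @param A,B [pairwise_matrix()] objects over the same populations.
#' @param conditioning optional third matrix for the partial test.
#' @param permutations number of permutations.
#' @param seed RNG seed.
#' @return tibble with r, p_value, permutations, seed.
#' @export
mantel_test <- function(A, B, conditioning = NULL, permutations = 9999, seed = 1) {
  check_that(identical(rownames(A), rownames(B)),
             "matrices must cover the same populations in the same order")
  if (!is.null(conditioning))
    check_that(identical(rownames(A), rownames(conditioning)),
               "conditioning matrix must cover the same populations")
  a <- pm_vec(A); b <- pm_vec(B)
  if (sd(a) == 0 || sd(b) == 0)
    abort("constant matrix: Mantel r is undefined")
  stat <- function(av) {
    if (is.null(conditioning)) return(cor(av, b))
    cv <- pm_vec(conditioning)
    r_ab <- cor(av, b); r_ac <- cor(av, cv); r_bc <- cor(b, cv)
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- stat(a)
  k <- nrow(A)
  hits <- with_seed(seed, {
    h <- 0L
    for (i in seq_len(permutations)) {
      perm <- sample.int(k)
      ap <- unclass(A)[perm, perm]
      if (stat(ap[upper.tri(ap)]) >= r_obs) h <- h + 1L
    }
    h
  })
  tibble(r = r_obs, p_value = (hits + 1) / (permutations + 1),
         permutations = permutations, seed = seed,
         partial = !is.null(conditioning))
}

#' Drift-based *di* distance from per-population carrying-capacity proxies
#'
#' Distance between populations built from the inverse of a positive
#' per-population value `v` (by default the log of lake surface area, a proxy
#' for carrying capacity). Two plausible forms are implemented:
#' `sum_inverse` (default), `d(i, j) = 1/v_i + 1/v_j`, the drift expectation
#' that differentiation accumulates inversely with both population sizes; and
#' `abs_diff_inverse`, `d(i, j) = |1/v_i - 1/v_j|`, an asymmetry-in-size
#' distance. Neither is claimed as the canonical published form; pick
#' explicitly.
#'
#' @param v named positive numeric vector (names are population ids). Note
#'   that log(area) is negative for lakes under 1 km^2 - shift or use raw
#'   areas in that case.
#' @param variant `"sum_inverse"` or `"abs_diff_inverse"`.
#' @return a [pairwise_matrix()].
#' @export
di_matrix <- function(v, variant = c("sum_inverse", "abs_diff_inverse")) {
  variant <- match.arg(variant)
  check_that(all(v > 0),
             "all values must be > 0 (log of surface area < 1 km^2 is negative; shift the values or use raw areas)")
  check_that(!is.null(names(v)), "`v` must be named by population")
  inv <- 1 / v
  pm_from_pairs(names(v), function(a, b) {
    if (variant == "sum_inverse") inv[a] + inv[b] else abs(inv[a] - inv[b])
  }, metric = paste0("di_", variant))
}

#' Planar geographic distances between lakes
#'
#' Equirectangular projection about the mean latitude; adequate at the
#' regional scale of a lake survey.
#'
#' @param lake_meta data frame with columns `population` (or `site`),
#'   `latitude`, `longitude` in decimal degrees.
#' @return a [pairwise_matrix()] of distances in km.
#' @export
geo_distances <- function(lake_meta) {
  lake_meta <- as_tibble(lake_meta)
  idc <- intersect(c("population", "site"), names(lake_meta))[1]
  check_that(!is.na(idc), "`lake_meta` needs a population/site column")
  R <- 6371
  phi <- lake_meta$latitude * pi / 180
  lam <- lake_meta$longitude * pi / 180
  phibar <- mean(phi)
  x <- R * cos(phibar) * lam
  y <- R * phi
  ids <- lake_meta[[idc]]
  m <- as.matrix(stats::dist(cbind(x, y)))
  dimnames(m) <- list(ids, ids)
  pairwise_matrix(m, metric = "geo_km")
}
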