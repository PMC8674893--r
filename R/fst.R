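# Weir-Cockerham theta and Nei's D_A genetic distance.

# Per-locus Weir-Cockerham variance components (a, b, c) for r populations.
# Inputs are per-population vectors at one locus: sample sizes n (genotyped
# diploids), alternate-allele frequencies p, heterozygote fractions h.
wc_components <- function(n, p, h) {
  use <- n > 0
  n <- n[use]; p <- p[use]; h <- h[use]
  r <- length(n)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(a = 0, b = 0, c = 0))
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

# Multi-locus Weir-Cockerham theta between the populations of `ds`
# (ratio of per-locus sums of components).
wc_theta <- function(ds) {
  pops <- unique(ds$samples$population)
  check_that(length(pops) >= 2, "need at least two populations")
  nmat <- pop_sizes(ds)
  pmat <- pop_freqs(ds)
  hmat <- t(vapply(pops, function(pn) {
    g <- ds$geno[ds$samples$population == pn, , drop = FALSE]
    nn <- colSums(!is.na(g))
    ifelse(nn > 0, colSums(g == 1L, na.rm = TRUE) / pmax(nn, 1), 0)
  }, numeric(ncol(ds$geno))))
  num <- den <- 0
  for (l in seq_len(ncol(ds$geno))) {
    cmp <- wc_components(nmat[, l], pmat[, l], hmat[, l])
    num <- num + cmp["a"]
    den <- den + sum(cmp)
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise Weir-Cockerham FST between populations
#'
#' Multi-locus theta for every population pair, computed as the ratio of
#' locus-summed Weir-Cockerham variance components. Raw (possibly negative)
#' values are reported; use [linearize_fst()] for the Slatkin linearization,
#' which floors negatives at zero first. An optional Hedrick standardization
#' divides each pairwise theta by its maximum attainable value given the
#' within-population diversity (`theta / theta_max` with
#' `theta_max = 1 - mean He`... computed as `F'ST = FST / FST_max` using the
#' recalculated components with all populations fixed).
#'
#' @param ds a [genotype_dataset()] with at least 2 populations.
#' @param standardize if `"none"` (default) plain theta; if `"hedrick"`,
#'   F'ST = theta / (1 - mean within-population He) as a simple
#'   heterozygosity-based standardization.
#' @return a [pairwise_matrix()].
#' @export
pairwise_fst <- function(ds, standardize = c("none", "hedrick")) {
  standardize <- match.arg(standardize)
  pops <- unique(ds$samples$population)
  div <- if (standardize == "hedrick") diversity_stats(ds) else NULL
  pm_from_pairs(pops, function(a, b) {
    sub <- subset_dataset(
      ds, individuals = ds$samples$individual[ds$samples$population %in% c(a, b)])
    th <- wc_theta(sub)
    if (standardize == "hedrick" && !is.na(th)) {
      hs <- mean(div$He[div$population %in% c(a, b)])
      th <- th / (1 - hs)
    }
    th
  }, metric = if (standardize == "none") "fst" else "fst_hedrick")
}

# Nei's D_A between two allele-frequency vectors at shared loci.
nei_da_pair <- function(pX, pY) {
  use <- !is.na(pX) & !is.na(pY)
  check_that(any(use), "no shared genotyped loci between populations")
  1 - mean(sqrt(pX[use] * pY[use]) + sqrt((1 - pX[use]) * (1 - pY[use])))
}

#' Nei's D_A genetic distance between populations
#'
#' `D_A = 1 - (1/L) * sum_l sum_alleles sqrt(p_l,X * p_l,Y)` over the loci
#' genotyped in both populations.
#'
#' @param ds a [genotype_dataset()] with at least 2 populations.
#' @return a [pairwise_matrix()].
#' @export
nei_da <- function(ds) {
  f <- pop_freqs(ds)
  f[!is.finite(f)] <- NA
  pm_from_pairs(rownames(f), function(a, b) nei_da_pair(f[a, ], f[b, ]),
                metric = "nei_da")
}
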