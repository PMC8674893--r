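#' Effective population size from linkage disequilibrium (LDNE)
#'
#' Per population: alleles with frequency below `p_crit` are screened out,
#' Burrows' composite disequilibrium r^2
#' (`r^2 = [S/(S-1) * (mean(XY)/2 - 2 p q)]^2 / (p(1-p) q(1-q))` on dosage
#' vectors X, Y) is computed for every retained pair of loci on different
#' linkage groups over the pair-complete observations, and the
#' sample-size-weighted mean r^2 is bias-corrected with the random-mating
#' expectation `1/S + 3.19/S^2` (samples of 30 or more). The point estimate is
#' `N_e = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')` where `r2'` is the
#' drift-attributable residual; a non-positive residual or a negative
#' discriminant yields an infinite estimate, the conventional signal that the
#' sample carries no resolvable drift LD.
#'
#' Confidence intervals are not computed; merged samples from two isolated
#' gene pools bias the estimate downward (Wahlund effect), which the caller
#' should keep in mind when pooling.
#'
#' @param ds a [genotype_dataset()]; needs a `linkage_group` locus column
#'   when `cross_group_only` is `TRUE`.
#' @param p_crit minimum allele frequency for a locus to enter (alleles rarer
#'   than this are excluded by dropping the locus within that population).
#' @param cross_group_only restrict to pairs of loci on different linkage
#'   groups (recommended; physical linkage inflates r^2).
#' @return tibble with one row per population: ne, mean_r2 (bias-corrected
#'   residual r2'), raw_r2, n_pairs, n_loci_used, S (weighted mean pair
#'   sample size), p_crit.
#' @export
ldne <- function(ds, p_crit = 0.05, cross_group_only = TRUE) {
  if (cross_group_only)
    check_that("linkage_group" %in% names(ds$loci) && !anyNA(ds$loci$linkage_group),
               "cross-group pairing needs a complete `linkage_group` column")
  pops <- unique(ds$samples$population)
  rows <- lapply(pops, function(pn) {
    X <- ds$geno[ds$samples$population == pn, , drop = FALSE]
    n <- colSums(!is.na(X))
    p <- colSums(X, na.rm = TRUE) / (2 * pmax(n, 1))
    maf <- pmin(p, 1 - p)
    use <- n >= 2 & maf >= p_crit
    if (sum(use) < 2) abort(paste0("population ", pn, ": fewer than 2 usable loci"))
    X <- X[, use, drop = FALSE]
    lg <- ds$loci$linkage_group[use]
    # Burrows composite r^2 over pair-complete observations, vectorised:
    # per ordered pair (a, b), sums of X_a restricted to rows where b is
    # also observed, then Delta = S/(S-1) * (mean(XY)/2 - 2 p_a p_b)
    M <- !is.na(X); Z <- X; Z[!M] <- 0
    Smat <- crossprod(M)
    SX <- crossprod(Z, M)          # SX[a, b] = sum of X_a over complete pairs
    SXY <- crossprod(Z)
    p_a <- SX / (2 * Smat)         # frequency of locus a within pair (a, b)
    p_b <- t(p_a)
    delta <- (Smat / (Smat - 1)) * (SXY / (2 * Smat) - 2 * p_a * p_b)
    r2 <- delta^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
    keep <- upper.tri(r2)
    if (cross_group_only) keep <- keep & outer(lg, lg, "!=")
    keep <- keep & is.finite(r2) & Smat >= 2
    check_that(any(keep), paste0("population ", pn, ": no usable locus pairs"))
    w <- Smat[keep]
    mean_r2 <- sum(w * r2[keep]) / sum(w)
    S <- sum(w * Smat[keep]) / sum(w)
    expected <- 1 / S + 3.19 / S^2
    r2p <- mean_r2 - expected
    disc <- 1 / 9 - 2.76 * r2p
    ne <- if (r2p <= 0 || disc < 0) Inf else (1 / 3 + sqrt(disc)) / (2 * r2p)
    tibble(population = pn, ne = ne, r2_drift = r2p, raw_r2 = mean_r2,
           n_pairs = sum(keep), n_loci_used = ncol(X), S = S, p_crit = p_crit)
  })
  bind_rows(rows)
}
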