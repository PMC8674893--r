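#' Per-population diversity statistics
#'
#' For every population: observed heterozygosity (`Ho`, fraction of
#' heterozygous calls), Nei's unbiased expected heterozygosity
#' (`He = (2n / (2n - 1)) * (1 - sum p^2)` per locus, averaged over loci),
#' the heterozygosity-based inbreeding coefficient
#' `G_IS = 1 - mean(Ho) / mean(He)`, and `prop_poly`, the fraction of the
#' dataset's loci at which both alleles are observed within the population.
#'
#' @param ds a [genotype_dataset()].
#' @return tibble with one row per population: n (mean genotyped
#'   individuals), Ho, He, G_IS, prop_poly. G_IS is `NA` for a population
#'   with zero mean expected heterozygosity.
#' @export
diversity_stats <- function(ds) {
  pops <- unique(ds$samples$population)
  rows <- lapply(pops, function(pn) {
    g <- ds$geno[ds$samples$population == pn, , drop = FALSE]
    n <- colSums(!is.na(g))
    use <- n >= 1
    check_that(any(use), paste0("population ", pn, " has no genotyped individuals"))
    g <- g[, use, drop = FALSE]; n <- n[use]
    p <- colSums(g, na.rm = TRUE) / (2 * n)
    ho_l <- colSums(g == 1L, na.rm = TRUE) / n
    he_l <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
    # a single genotyped diploid still has 2n - 1 = 1, so He is defined
    ho <- mean(ho_l); he <- mean(he_l)
    tibble(
      population = pn,
      n = mean(n),
      Ho = ho,
      He = he,
      G_IS = if (he > 0) 1 - ho / he else NA_real_,
      prop_poly = sum(p > 0 & p < 1) / n_loci(ds)
    )
  })
  bind_rows(rows)
}
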