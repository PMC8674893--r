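#' Filter a genotype dataset with the standard Rapture/RAD criteria
#'
#' Applies, in this fixed order: (1) drop loci genotyped in fewer than
#' `locus_call_rate` of individuals; (2) drop individuals missing more than
#' `indiv_max_missing` of the remaining loci; (3) drop loci whose minor allele
#' frequency - recomputed after the individual removal, since removing
#' individuals changes allele counts - is below `maf_min` (a MAF exactly at
#' the threshold is retained); (4) optionally drop loci without at least one
#' genotyped individual in every population.
#'
#' @param ds a [genotype_dataset()].
#' @param locus_call_rate minimum fraction of individuals genotyped per locus.
#' @param indiv_max_missing maximum fraction of missing loci per individual
#'   (strictly greater is removed).
#' @param maf_min minimum minor allele frequency (strictly lower is removed).
#' @param require_all_pops if `TRUE`, keep only loci genotyped in at least one
#'   individual of every population.
#' @return list with `dataset` (the filtered [genotype_dataset()]) and
#'   `report`, a tibble of per-stage removals in the order applied.
#' @export
filter_genotypes <- function(ds, locus_call_rate = 0.7, indiv_max_missing = 0.5,
                             maf_min = 0.01, require_all_pops = TRUE) {
  check_that(inherits(ds, "genotype_dataset"), "`ds` must be a genotype_dataset")
  check_that(n_loci(ds) > 0 && n_individuals(ds) > 0, "`ds` is empty")
  report <- list()
  log_stage <- function(stage, loci_rm, ind_rm, d) {
    report[[length(report) + 1]] <<- tibble(
      stage = stage, removed_loci = loci_rm, removed_individuals = ind_rm,
      loci_after = n_loci(d), individuals_after = n_individuals(d))
  }

  # 1: locus call rate
  cr <- colMeans(!is.na(ds$geno))
  keep_l <- colnames(ds$geno)[cr >= locus_call_rate]
  d1 <- subset_dataset(ds, loci = keep_l)
  log_stage("locus_call_rate", n_loci(ds) - n_loci(d1), 0L, d1)

  # 2: individual missingness
  miss <- rowMeans(is.na(d1$geno))
  keep_i <- rownames(d1$geno)[miss <= indiv_max_missing]
  d2 <- subset_dataset(d1, individuals = keep_i)
  log_stage("individual_missingness", 0L, n_individuals(d1) - n_individuals(d2), d2)

  # 3: MAF, recomputed on the reduced individual set
  maf <- locus_maf(d2)
  keep_l <- colnames(d2$geno)[!is.na(maf) & maf >= maf_min]
  d3 <- subset_dataset(d2, loci = keep_l)
  log_stage("minor_allele_frequency", n_loci(d2) - n_loci(d3), 0L, d3)

  d4 <- d3
  if (require_all_pops) {
    ns <- pop_sizes(d3)
    keep_l <- colnames(d3$geno)[colSums(ns == 0) == 0]
    d4 <- subset_dataset(d3, loci = keep_l)
    log_stage("genotyped_in_every_population", n_loci(d3) - n_loci(d4), 0L, d4)
  }
  if (n_loci(d4) == 0 || n_individuals(d4) == 0)
    abort("all data filtered: no loci or individuals remain")
  list(dataset = d4, report = bind_rows(report))
}

#' HDPlot-style paralog screen
#'
#' Flags putatively paralogous (duplicated) loci from heterozygote read-depth
#' patterns. Per locus, reads are pooled across heterozygous individuals
#' (total n = ref + alt): `allele_balance = ref / n`, the read-ratio deviation
#' is the pooled-binomial z-score `D = (ref - n/2) / sqrt(n/4)`, and `H` is
#' the fraction of genotyped individuals that are heterozygous. A locus is
#' flagged when `H > h_max`, `D` falls outside `d_limits`, or the allele
#' balance falls outside `ab_limits` (all comparisons strict, as conventional
#' for this screen). Loci with no heterozygotes have undefined `D` and
#' balance and are not flagged by those criteria.
#'
#' @param ds a [genotype_dataset()] with allele depths.
#' @param h_max maximum heterozygote fraction.
#' @param d_limits length-2 numeric; acceptable read-ratio deviation range.
#' @param ab_limits length-2 numeric; acceptable allele-balance range.
#' @return list with `stats` (per-locus tibble: H, D, allele_balance,
#'   flagged), `flagged` (locus ids) and `dataset` (the input with flagged
#'   loci removed).
#' @export
hdplot_screen <- function(ds, h_max = 0.5, d_limits = c(-15, 15),
                          ab_limits = c(0.3, 0.7)) {
  check_that(!is.null(ds$ref_depth) && !is.null(ds$alt_depth),
             "HDPlot screen needs allele depths")
  het <- ds$geno == 1L
  het[is.na(het)] <- FALSE
  H <- colSums(het) / colSums(!is.na(ds$geno))
  ref <- colSums(ds$ref_depth * het, na.rm = TRUE)
  alt <- colSums(ds$alt_depth * het, na.rm = TRUE)
  ntot <- ref + alt
  ab <- ifelse(ntot > 0, ref / ntot, NA_real_)
  D <- ifelse(ntot > 0, (ref - ntot / 2) / sqrt(ntot / 4), NA_real_)
  flagged <- (H > h_max) |
    (!is.na(D) & (D < d_limits[1] | D > d_limits[2])) |
    (!is.na(ab) & (ab < ab_limits[1] | ab > ab_limits[2]))
  stats <- tibble(locus = ds$loci$locus, H = unname(H), D = unname(D),
                  allele_balance = unname(ab), flagged = unname(flagged))
  keep <- ds$loci$locus[!flagged]
  list(stats = stats, flagged = ds$loci$locus[flagged],
       dataset = subset_dataset(ds, loci = keep))
}

#' Thin to one SNP per RAD tag
#'
#' Physically linked SNPs share a RAD tag; only the SNP with the highest
#' minor allele frequency on each tag is kept. Ties go to the
#' lexicographically lowest locus identifier, so the choice is deterministic.
#'
#' @param ds a [genotype_dataset()] whose locus table has a `tag` column.
#' @return a [genotype_dataset()] with exactly one locus per tag.
#' @export
select_snp_per_tag <- function(ds) {
  check_that("tag" %in% names(ds$loci) && !anyNA(ds$loci$tag),
             "locus table needs a complete `tag` column")
  maf <- locus_maf(ds)
  pick <- tibble(locus = ds$loci$locus, tag = ds$loci$tag, maf = unname(maf)) |>
    arrange(.data$tag, dplyr::desc(.data$maf), .data$locus) |>
    group_by(.data$tag) |>
    dplyr::slice(1) |>
    ungroup()
  keep <- ds$loci$locus[ds$loci$locus %in% pick$locus]
  subset_dataset(ds, loci = keep)
}
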