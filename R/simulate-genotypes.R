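#' Configuration for the hierarchical genotype simulator
#'
#' Bundles and validates the parameters of the Balding-Nichols genotype
#' generator. Defaults emulate the study system of long-isolated inland lake
#' populations: two divergent lineages (between-lineage F about 0.135, the
#' F_CT scale seen in hierarchical AMOVA of such systems) holding strongly
#' drifted lake populations (within-lineage F about 0.255, the F_SC scale),
#' which compounds to a mean pairwise FST near 0.36.
#'
#' @param n_lineages number of lineages (top hierarchy level).
#' @param n_pops_per_lineage populations (lakes) nested in each lineage.
#' @param n_individuals_per_pop diploid individuals sampled per population.
#' @param n_loci number of biallelic SNP loci.
#' @param fst_lineage Balding-Nichols F between lineages, in [0, 1).
#' @param fst_pop Balding-Nichols F of populations around their lineage
#'   frequency, in [0, 1).
#' @param maf_floor ancestral frequencies are drawn uniform on
#'   (maf_floor, 1 - maf_floor).
#' @param prop_deleterious fraction of loci labelled as carrying a scored
#'   deleterious alternate allele in the truth block.
#' @param mean_depth mean total read depth per genotype call (reads are
#'   Poisson(mean_depth / 2) per allele copy).
#' @param seed integer RNG seed; identical seeds give bit-identical datasets.
#' @param loci_per_tag number of SNPs sharing each RAD-tag label.
#' @param n_linkage_groups number of linkage-group labels cycled over loci.
#' @param missing_rate probability a genotype call is missing.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_lineages = 2, n_pops_per_lineage = 3,
                       n_individuals_per_pop = 25, n_loci = 1000,
                       fst_lineage = 0.135, fst_pop = 0.255,
                       maf_floor = 0.05, prop_deleterious = 0.1,
                       mean_depth = 20, seed = 1,
                       loci_per_tag = 1, n_linkage_groups = 8,
                       missing_rate = 0) {
  for (v in c("n_lineages", "n_pops_per_lineage", "n_individuals_per_pop",
              "n_loci", "loci_per_tag", "n_linkage_groups"))
    check_that(is_count(get(v)), paste0("`", v, "` must be a count >= 1"))
  for (v in c("fst_lineage", "fst_pop", "maf_floor", "prop_deleterious",
              "missing_rate"))
    check_that(is_fraction(get(v)), paste0("`", v, "` must be in [0, 1)"))
  check_that(maf_floor < 0.5, "`maf_floor` must be < 0.5")
  check_that(mean_depth > 0, "`mean_depth` must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# Balding-Nichols draw: daughter frequencies around `p` at divergence F.
# F = 0 degenerates to copying p (no Beta draw).
bn_draw <- function(p, f, n) {
  check_that(f >= 0 && f < 1, "Balding-Nichols F must be in [0, 1)")
  if (f == 0) return(matrix(rep(p, each = n), nrow = n))
  k <- (1 - f) / f
  matrix(rbeta(n * length(p), rep(p, each = n) * k, rep(1 - p, each = n) * k),
         nrow = n)
}

#' Simulate a hierarchically structured genotype dataset
#'
#' Draws allele frequencies down a lineage/population hierarchy under the
#' Balding-Nichols model, then diploid genotypes binomially and per-allele
#' read depths as Poisson(mean_depth / 2). The drift model is chosen because
#' only marginal FST levels are needed for testing the estimators; no
#' coalescent machinery is involved.
#'
#' The returned dataset carries a `truth` block with the ancestral, lineage
#' and population allele frequencies and the deleterious-allele labels, so
#' tests never have to re-derive the simulated state.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dataset()] with populations named `L<i>P<j>`.
#' @export
simulate_genotypes <- function(config) {
  check_that(inherits(config, "sim_config"), "`config` must come from sim_config()")
  c_ <- config
  with_seed(c_$seed, {
    L <- c_$n_loci
    p0 <- runif(L, c_$maf_floor, 1 - c_$maf_floor)
    p_lin <- bn_draw(p0, c_$fst_lineage, c_$n_lineages)        # lineages x loci
    pops <- lineage_of <- character(0)
    p_pop <- NULL
    for (i in seq_len(c_$n_lineages)) {
      pp <- bn_draw(p_lin[i, ], c_$fst_pop, c_$n_pops_per_lineage)
      p_pop <- rbind(p_pop, pp)
      pops <- c(pops, paste0("L", i, "P", seq_len(c_$n_pops_per_lineage)))
      lineage_of <- c(lineage_of, rep(paste0("L", i), c_$n_pops_per_lineage))
    }
    rownames(p_pop) <- pops
    n_ind <- c_$n_individuals_per_pop
    N <- n_ind * length(pops)
    geno <- matrix(NA_integer_, N, L)
    for (k in seq_along(pops)) {
      rows <- (k - 1) * n_ind + seq_len(n_ind)
      geno[rows, ] <- matrix(
        rbinom(n_ind * L, 2, rep(p_pop[k, ], each = n_ind)), n_ind, L)
    }
    if (c_$missing_rate > 0) {
      geno[runif(length(geno)) < c_$missing_rate] <- NA_integer_
    }
    half <- c_$mean_depth / 2
    ref_copies <- 2L - geno; ref_copies[is.na(ref_copies)] <- 0L
    alt_copies <- geno; alt_copies[is.na(alt_copies)] <- 0L
    ref_d <- matrix(rpois(length(geno), half * ref_copies), N, L)
    alt_d <- matrix(rpois(length(geno), half * alt_copies), N, L)
    ref_d[is.na(geno)] <- NA; alt_d[is.na(geno)] <- NA
    samples <- tibble(
      individual = paste0(rep(pops, each = n_ind), "_i",
                          rep(seq_len(n_ind), length(pops))),
      population = rep(pops, each = n_ind),
      lineage = rep(lineage_of, each = n_ind)
    )
    n_del <- round(c_$prop_deleterious * L)
    del <- logical(L); del[seq_len(n_del)] <- TRUE
    loci <- tibble(
      locus = sprintf("loc%05d", seq_len(L)),
      tag = sprintf("tag%05d", ceiling(seq_len(L) / c_$loci_per_tag)),
      linkage_group = sprintf("LG%02d", (seq_len(L) - 1L) %% c_$n_linkage_groups + 1L)
    )
    truth <- list(
      config = c_,
      ancestral_freq = p0,
      lineage_freq = p_lin,
      pop_freq = p_pop,
      deleterious = setNames(del, loci$locus)
    )
    genotype_dataset(geno, samples, loci, ref_depth = ref_d,
                     alt_depth = alt_d, truth = truth)
  })
}

#' Write the truth metadata of a simulated dataset as CSV sidecars
#'
#' @param ds a simulated [genotype_dataset()] carrying a `truth` block.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_truth_sidecar <- function(ds, dir) {
  check_that(!is.null(ds$truth), "dataset carries no truth block")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- ds$truth$pop_freq
  write.csv(
    data.frame(locus = ds$loci$locus,
               ancestral = ds$truth$ancestral_freq,
               deleterious = ds$truth$deleterious,
               t(pf) |> as.data.frame() |> setNames(paste0("freq_", rownames(pf)))),
    file.path(dir, "truth_frequencies.csv"), row.names = FALSE)
  invisible(dir)
}
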