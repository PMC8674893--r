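# Shared fixture builders. All randomness is seeded by the caller.

toy_dataset <- function(geno, pop, lineage = NULL, ref_depth = NULL,
                        alt_depth = NULL, tag = NULL, lg = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); L <- ncol(geno)
  samples <- tibble::tibble(
    individual = sprintf("i%03d", seq_len(n)), population = pop)
  if (!is.null(lineage)) samples$lineage <- lineage
  loci <- tibble::tibble(locus = sprintf("l%03d", seq_len(L)))
  if (!is.null(tag)) loci$tag <- tag
  if (!is.null(lg)) loci$linkage_group <- lg
  genotype_dataset(geno, samples, loci, ref_depth = ref_depth,
                   alt_depth = alt_depth)
}

# Two-population Balding-Nichols dataset for differentiation checks.
bn_two_pops <- function(n_per_pop, n_loci, fst, seed) {
  ds <- simulate_genotypes(sim_config(
    n_lineages = 1, n_pops_per_lineage = 2, n_individuals_per_pop = n_per_pop,
    n_loci = n_loci, fst_lineage = 0, fst_pop = fst, maf_floor = 0.1,
    seed = seed))
  ds
}

# Discrete-generation Wright-Fisher population of n_ind diploid parents;
# returns dosages for a final cohort of `final_n` offspring of the last
# parental generation. Loci are unlinked (free recombination), so LD among
# them is pure drift LD at scale 1/(3 Ne) with Ne = n_ind; a large final
# cohort keeps the sampled individuals a small fraction of the pool, as the
# LD estimator's sampling theory assumes.
simulate_wf_dosages <- function(n_ind, n_loci, n_gen, seed, final_n = 4 * n_ind) {
  withr::with_seed(seed, {
    p0 <- runif(n_loci, 0.2, 0.8)
    dos <- matrix(rbinom(n_ind * n_loci, 2, rep(p0, each = n_ind)), n_ind)
    breed <- function(parents, n_off) {
      mothers <- sample.int(nrow(parents), n_off, replace = TRUE)
      fathers <- sample.int(nrow(parents), n_off, replace = TRUE)
      a1 <- matrix(rbinom(n_off * ncol(parents), 1, parents[mothers, ] / 2), n_off)
      a2 <- matrix(rbinom(n_off * ncol(parents), 1, parents[fathers, ] / 2), n_off)
      a1 + a2
    }
    for (g in seq_len(n_gen)) dos <- breed(dos, n_ind)
    breed(dos, final_n)
  })
}

wf_dataset <- function(dos, sample_n, n_groups = 10, seed = 1) {
  idx <- withr::with_seed(seed, sample.int(nrow(dos), sample_n))
  toy_dataset(dos[idx, , drop = FALSE], pop = rep("P", sample_n),
              lg = sprintf("LG%02d", (seq_len(ncol(dos)) - 1) %% n_groups + 1))
}

# Simulated truth restricted to what a presence caller can recover: the
# singleton rule removes haplotypes carried by exactly one individual.
callable_truth <- function(truth) {
  carriers <- table(truth$haplotype)
  truth[truth$haplotype %in% names(carriers)[carriers > 1], ]
}
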