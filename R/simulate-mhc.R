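#' Simulate a multi-copy MHC amplicon read-count table
#'
#' Emulates amplicon sequencing of a duplicated MHC region: each individual
#' carries a small number of true haplotypes (uniform on `copies_range`),
#' reads are allocated to true haplotypes by a Dirichlet-multinomial, and a
#' configurable expected fraction of each individual's reads is diverted to
#' shared low-frequency noise haplotypes (sequencing artefacts). The truth
#' presence table is returned alongside so callers can be scored exactly.
#'
#' @param n_individuals number of genotyped individuals.
#' @param hap_pool number of distinct true haplotypes circulating.
#' @param copies_range length-2 integer vector; per-individual haplotype copy
#'   number is uniform on this range (must lie within `[1, hap_pool]`).
#' @param total_reads expected total reads per individual.
#' @param noise_rate expected fraction of an individual's reads assigned to
#'   noise haplotypes.
#' @param seed integer RNG seed.
#' @param dirichlet_alpha concentration of the read-allocation weights;
#'   smaller values give more uneven coverage across an individual's
#'   haplotypes.
#' @param min_call_frac read allocations are redrawn until every true
#'   haplotype strictly exceeds this fraction of the individual's total
#'   reads (default 0.10, the nominal within-individual calling threshold),
#'   so simulated truth is recoverable by a threshold caller by
#'   construction. Keep `noise_rate` well below this fraction.
#' @return list with `reads` (long tibble individual/haplotype/reads),
#'   `truth` (long tibble of true presences) and `haplotypes` (tibble of
#'   haplotype ids with a `noise` flag and a random 300 bp in-frame sequence).
#' @export
simulate_mhc_reads <- function(n_individuals, hap_pool, copies_range = c(1L, 4L),
                               total_reads = 1000, noise_rate = 0.02, seed = 1,
                               dirichlet_alpha = 20, min_call_frac = 0.10) {
  check_that(is_count(n_individuals) && is_count(hap_pool),
             "`n_individuals` and `hap_pool` must be counts")
  check_that(length(copies_range) == 2 && copies_range[1] >= 1 &&
               copies_range[2] <= hap_pool && copies_range[1] <= copies_range[2],
             "`copies_range` must lie within [1, hap_pool]")
  check_that(total_reads >= 1, "`total_reads` must be positive")
  check_that(is_fraction(noise_rate), "`noise_rate` must be in [0, 1)")
  with_seed(seed, {
    haps <- sprintf("hap%03d", seq_len(hap_pool))
    n_noise <- max(2L, ceiling(hap_pool / 3))
    noise_haps <- sprintf("noise%03d", seq_len(n_noise))
    inds <- sprintf("ind%03d", seq_len(n_individuals))
    recs <- truth <- vector("list", n_individuals)
    pick1 <- function(x) x[sample.int(length(x), 1)]
    for (i in seq_len(n_individuals)) {
      k <- pick1(seq(copies_range[1], copies_range[2]))
      mine <- sample(haps, k)
      n_noise_reads <- rbinom(1, total_reads, noise_rate)
      # condition the Dirichlet-multinomial on every true haplotype clearing
      # the calling threshold: truth must be recoverable by construction
      for (try in seq_len(1000)) {
        w <- rgamma(k, shape = dirichlet_alpha)
        true_reads <- as.vector(rmultinom(1, total_reads - n_noise_reads,
                                          w / sum(w)))
        if (min(true_reads) > min_call_frac * total_reads) break
      }
      check_that(min(true_reads) > min_call_frac * total_reads,
                 "could not allocate reads above min_call_frac; lower copies_range or min_call_frac")
      rec <- tibble(individual = inds[i], haplotype = mine, reads = true_reads)
      if (n_noise_reads > 0) {
        nh <- sample(noise_haps, min(2, n_noise), replace = FALSE)
        nr <- as.vector(rmultinom(1, n_noise_reads, rep(1, length(nh))))
        rec <- bind_rows(rec, tibble(individual = inds[i], haplotype = nh,
                                     reads = nr))
      }
      recs[[i]] <- filter(rec, .data$reads > 0)
      truth[[i]] <- tibble(individual = inds[i], haplotype = mine)
    }
    all_haps <- c(haps, noise_haps)
    seqs <- vapply(all_haps, function(h) random_cds(100), character(1))
    list(
      reads = bind_rows(recs),
      truth = bind_rows(truth),
      haplotypes = tibble(haplotype = all_haps,
                          noise = all_haps %in% noise_haps,
                          seq = unname(seqs))
    )
  })
}

# Random in-frame coding sequence of `n_codons` codons, no internal stops.
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# The 61 sense codons of the standard genetic code.
sense_codons <- function() {
  nt <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(nt, nt, nt), 1, paste, collapse = "")
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}
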