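#' Neighbour-joining population tree with locus bootstrap support
#'
#' Builds the canonical NJ tree (Saitou-Nei agglomeration, via [ape::nj()])
#' from a pairwise distance matrix. When a genotype dataset is supplied,
#' bootstrap support is computed by resampling loci with replacement,
#' recomputing Nei's D_A and counting recovered bipartitions.
#'
#' @param dist a [pairwise_matrix()] of genetic distances (>= 3 populations).
#' @param bootstrap number of locus-resampling replicates (0 to skip).
#' @param ds the [genotype_dataset()] the distances came from; required when
#'   `bootstrap > 0`.
#' @param seed RNG seed for the bootstrap.
#' @return an [ape::phylo] tree; when bootstrapped, `node.label` holds the
#'   bipartition support counts out of `bootstrap`.
#' @export
nj_tree <- function(dist, bootstrap = 1000, ds = NULL, seed = 1) {
  check_that(nrow(dist) >= 3, "NJ needs at least 3 populations")
  tr <- ape::nj(stats::as.dist(unclass(dist)))
  if (bootstrap > 0) {
    if (is.null(ds)) abort("bootstrap requested but no `ds` supplied")
    L <- n_loci(ds)
    f <- pop_freqs(ds)
    f[!is.finite(f)] <- NA
    reps <- with_seed(seed, lapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      fb <- f[, idx, drop = FALSE]
      m <- pm_from_pairs(rownames(fb),
                         function(a, d) nei_da_pair(fb[a, ], fb[d, ]),
                         metric = "nei_da")
      ape::nj(stats::as.dist(unclass(m)))
    }))
    support <- ape::prop.clades(tr, reps, rooted = FALSE)
    tr$node.label <- support
  }
  tr
}
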