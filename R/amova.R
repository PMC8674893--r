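# Hierarchical AMOVA on allele indicator variables, four levels:
# within individuals / among individuals within populations /
# among populations within lineages / among lineages.

# Variance components for one dataset + grouping. geno: N x L dosage matrix
# (NA allowed), pop/lin: length-N labels. Components are computed per locus
# with that locus's unequal-sample-size coefficients and summed over loci.
amova_components <- function(geno, pop, lin) {
  M <- !is.na(geno)
  G0 <- geno; G0[!M] <- 0L
  pop <- as.character(pop); lin <- as.character(lin)
  sum_p <- rowsum(G0, pop); n_p <- rowsum(M + 0L, pop)
  sum_l <- rowsum(G0, lin); n_l <- rowsum(M + 0L, lin)
  sum_t <- colSums(G0); n_t <- colSums(M)
  sq <- function(x) x^2
  ss_wi <- colSums(G0) - colSums(sq(G0)) / 2
  with0 <- function(x) ifelse(is.finite(x), x, 0)
  term_p <- colSums(with0(sq(sum_p) / (2 * n_p)))           # sum_p G_p^2 / 2n_p
  term_l <- colSums(with0(sq(sum_l) / (2 * n_l)))
  term_t <- with0(sq(sum_t) / (2 * n_t))
  ss_ai <- colSums(sq(G0)) / 2 - term_p
  ss_ap <- term_p - term_l
  ss_ag <- term_l - term_t

  P <- colSums(n_p > 0); Gl <- colSums(n_l > 0); N <- n_t
  d_wi <- N; d_ai <- N - P; d_ap <- P - Gl; d_ag <- Gl - 1

  # unequal-size coefficients, in gene copies c = 2n
  c_p <- 2 * n_p; c_l <- 2 * n_l; C <- 2 * N
  # map each population row to its lineage for the nested sums
  pop_lin <- lin[match(rownames(n_p), pop)]
  cp2_by_lin <- rowsum(sq(c_p), pop_lin)              # lineages x L
  cl_aligned <- c_l[rownames(cp2_by_lin), , drop = FALSE]
  sum_cp2_over_cl <- colSums(with0(cp2_by_lin / cl_aligned))
  n1 <- (C - sum_cp2_over_cl) / d_ap
  n2 <- (sum_cp2_over_cl - colSums(sq(c_p)) / C) / d_ag
  n3 <- (C - colSums(sq(c_l)) / C) / d_ag

  ok <- d_ai > 0 & d_ap > 0 & d_ag > 0 & is.finite(n1) & n1 > 0 & n3 > 0
  ms_wi <- ss_wi / d_wi
  ms_ai <- ss_ai / d_ai
  ms_ap <- ss_ap / d_ap
  ms_ag <- ss_ag / d_ag
  s1 <- ms_wi
  s2 <- (ms_ai - s1) / 2
  s3 <- (ms_ap - s1 - 2 * s2) / n1
  s4 <- (ms_ag - s1 - 2 * s2 - n2 * s3) / n3
  c(sigma_within_ind = sum(s1[ok]), sigma_among_ind = sum(s2[ok]),
    sigma_among_pop = sum(s3[ok]), sigma_among_lin = sum(s4[ok]))
}

amova_f_stats <- function(s) {
  # a zero denominator means no variance at or below that level: the
  # corresponding fixation index is 0 by convention
  ratio <- function(num, den) if (den == 0) 0 else num / den
  tot <- sum(s)
  c(F_IS = ratio(s[[2]], s[[1]] + s[[2]]),
    F_SC = ratio(s[[3]], s[[1]] + s[[2]] + s[[3]]),
    F_CT = ratio(s[[4]], tot),
    F_IT = ratio(s[[2]] + s[[3]] + s[[4]], tot))
}

# Permute gene copies among individuals within each population (per locus),
# the null for F_IS.
permute_alleles_within_pops <- function(geno, pop) {
  out <- geno
  for (pn in unique(pop)) {
    rows <- which(pop == pn)
    sub <- geno[rows, , drop = FALSE]
    out[rows, ] <- apply(sub, 2, function(g) {
      ok <- !is.na(g)
      if (sum(ok) > 1) {
        copies <- sample(rep(c(1L, 0L), c(sum(g[ok]), 2 * sum(ok) - sum(g[ok]))))
        g[ok] <- copies[c(TRUE, FALSE)] + copies[c(FALSE, TRUE)]
      }
      g
    })
  }
  out
}

#' Hierarchical analysis of molecular variance
#'
#' Partitions allele-indicator variance across four nested levels (within
#' individuals, among individuals within populations, among populations
#' within lineages, among lineages) with Excoffier-style sums of squares and
#' per-locus unequal-sample-size coefficients, summing components over loci.
#' F-statistics derive from the components; p-values come from permutation
#' nulls tailored to each statistic: gene copies among individuals within
#' populations (F_IS), individuals among populations within lineages (F_SC),
#' and whole populations among lineages (F_CT).
#'
#' @param ds a [genotype_dataset()] whose samples carry a `lineage` column
#'   with at least 2 lineages.
#' @param permutations permutation count for each test.
#' @param seed RNG seed for the permutations.
#' @return an object of class `amova_result` with `components` (tibble:
#'   level, sigma2, percent), `f_stats` (tibble: statistic, value, p_value),
#'   and the permutation settings. [tidy()] and [glance()] methods exist.
#' @export
amova <- function(ds, permutations = 999, seed = 1) {
  check_that("lineage" %in% names(ds$samples), "samples need a `lineage` column")
  lin <- ds$samples$lineage
  pop <- ds$samples$population
  check_that(length(unique(lin)) >= 2, "AMOVA needs at least 2 lineages")
  pops_per_lin <- table(unique(ds$samples[, c("population", "lineage")])$lineage)
  if (any(pops_per_lin < 2))
    warn("a lineage contains a single population; F_SC permutation resolution is low")

  s <- amova_components(ds$geno, pop, lin)
  fs <- amova_f_stats(s)

  pv <- c(F_IS = NA_real_, F_SC = NA_real_, F_CT = NA_real_)
  if (permutations > 0) {
    pop_tbl <- unique(ds$samples[, c("population", "lineage")])
    counts <- with_seed(seed, {
      hits <- c(F_IS = 0L, F_SC = 0L, F_CT = 0L)
      for (b in seq_len(permutations)) {
        g_is <- permute_alleles_within_pops(ds$geno, pop)
        f1 <- amova_f_stats(amova_components(g_is, pop, lin))
        if (f1["F_IS"] >= fs["F_IS"]) hits["F_IS"] <- hits["F_IS"] + 1L

        pop_sc <- pop
        for (ln in unique(lin)) {
          rows <- which(lin == ln)
          pop_sc[rows] <- sample(pop[rows])
        }
        f2 <- amova_f_stats(amova_components(ds$geno, pop_sc, lin))
        if (f2["F_SC"] >= fs["F_SC"]) hits["F_SC"] <- hits["F_SC"] + 1L

        perm_lin_of_pop <- setNames(sample(pop_tbl$lineage), pop_tbl$population)
        lin_ct <- unname(perm_lin_of_pop[pop])
        f3 <- amova_f_stats(amova_components(ds$geno, pop, lin_ct))
        if (f3["F_CT"] >= fs["F_CT"]) hits["F_CT"] <- hits["F_CT"] + 1L
      }
      hits
    })
    pv <- (counts + 1) / (permutations + 1)
  }

  tot <- sum(s)
  structure(list(
    components = tibble(
      level = c("within_individuals", "among_individuals_in_populations",
                "among_populations_in_lineages", "among_lineages"),
      sigma2 = unname(s),
      percent = unname(s) / tot
    ),
    f_stats = tibble(
      statistic = c("F_IS", "F_SC", "F_CT", "F_IT"),
      value = unname(fs),
      p_value = c(pv["F_IS"], pv["F_SC"], pv["F_CT"], NA_real_)
    ),
    permutations = permutations, seed = seed
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result> (", x$permutations, "permutations )\n")
  print(as.data.frame(x$components))
  print(as.data.frame(x$f_stats))
  invisible(x)
}

#' @rdname amova
#' @param x an `amova_result`.
#' @param ... unused.
#' @method tidy amova_result
#' @export
tidy.amova_result <- function(x, ...) x$components

#' @rdname amova
#' @method glance amova_result
#' @export
glance.amova_result <- function(x, ...) {
  tidyr::pivot_wider(x$f_stats[, c("statistic", "value")],
                     names_from = "statistic", values_from = "value") |>
    mutate(permutations = x$permutations)
}
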