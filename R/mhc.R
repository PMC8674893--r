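#' Call MHC haplotype presence from amplicon read counts
#'
#' Because the amplified region sits in a duplicated gene family, dosage
#' cannot be assigned; calls are strictly presence/absence. Thresholds apply
#' in a fixed order: (1) haplotypes whose dataset-wide read total is at or
#' below `min_total_reads` are discarded; (2) within each individual, a
#' haplotype is present iff its reads strictly exceed `within_indiv_frac` of
#' that individual's total reads (totals taken over the raw input table);
#' (3) haplotypes then present in exactly one individual are dropped as
#' likely sequencing errors.
#'
#' @param reads long tibble with columns individual, haplotype, reads.
#' @param min_total_reads dataset-wide read-count floor (strictly greater
#'   survives).
#' @param within_indiv_frac within-individual presence threshold (strictly
#'   greater calls presence).
#' @param drop_singletons drop haplotypes seen in exactly one individual.
#' @return object of class `haplotype_matrix`: list with `presence` (binary
#'   individuals x haplotypes matrix), `no_reads` (individuals with zero
#'   total reads, flagged and uncalled). [tidy()] gives the long form.
#' @export
call_haplotypes <- function(reads, min_total_reads = 50,
                            within_indiv_frac = 0.10, drop_singletons = TRUE) {
  reads <- as_tibble(reads)
  check_that(nrow(reads) > 0, "empty read table")
  check_that(all(reads$reads >= 0), "read counts must be non-negative")
  totals_ind <- reads |> group_by(.data$individual) |>
    summarise(total = sum(.data$reads))
  no_reads <- totals_ind$individual[totals_ind$total == 0]
  totals_hap <- reads |> group_by(.data$haplotype) |>
    summarise(total = sum(.data$reads))
  keep_h <- totals_hap$haplotype[totals_hap$total > min_total_reads]
  calls <- reads |>
    filter(.data$haplotype %in% keep_h) |>
    left_join(totals_ind, by = "individual") |>
    filter(.data$total > 0, .data$reads > within_indiv_frac * .data$total)
  if (drop_singletons) {
    seen <- calls |> group_by(.data$haplotype) |>
      summarise(n_ind = dplyr::n_distinct(.data$individual))
    calls <- filter(calls, .data$haplotype %in% seen$haplotype[seen$n_ind > 1])
  }
  inds <- sort(unique(reads$individual))
  haps <- sort(unique(calls$haplotype))
  pres <- matrix(0L, length(inds), length(haps), dimnames = list(inds, haps))
  if (nrow(calls) > 0) pres[cbind(calls$individual, calls$haplotype)] <- 1L
  structure(list(presence = pres, no_reads = no_reads),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("<haplotype_matrix>", nrow(x$presence), "individuals x",
      ncol(x$presence), "haplotypes\n")
  invisible(x)
}

#' @rdname call_haplotypes
#' @param x a `haplotype_matrix`.
#' @param ... unused.
#' @method tidy haplotype_matrix
#' @export
tidy.haplotype_matrix <- function(x, ...) {
  idx <- which(x$presence == 1L, arr.ind = TRUE)
  tibble(individual = rownames(x$presence)[idx[, 1]],
         haplotype = colnames(x$presence)[idx[, 2]]) |>
    arrange(.data$individual, .data$haplotype)
}

#' Per-population MHC diversity with resampling rarefaction
#'
#' Sample sizes differ between lakes, so haplotype richness is rarefied:
#' `n_hap` is the mean number of distinct haplotypes present in
#' `rarefaction_n` individuals drawn without replacement, over `resamples`
#' draws. Populations smaller than `rarefaction_n` are computed at their own
#' size and flagged. Also reported: the fraction of individuals carrying more
#' than one (`prop_poly`) and more than two (`prop_gt2`) haplotypes, and
#' per-haplotype carrier frequencies renormalized to sum to one (individuals
#' can carry several haplotypes, so raw carrier frequencies sum above one).
#'
#' @param hm a `haplotype_matrix` from [call_haplotypes()].
#' @param popmap data frame with columns individual, population.
#' @param rarefaction_n individuals per rarefaction draw.
#' @param resamples number of draws.
#' @param seed RNG seed.
#' @return list of class `mhc_diversity`: `populations` tibble (population,
#'   n, n_hap, prop_poly, prop_gt2, rarefied_at, flagged) and `frequencies`
#'   tibble (population, haplotype, carrier_freq, std_freq).
#' @export
mhc_diversity <- function(hm, popmap, rarefaction_n = 5, resamples = 1000,
                          seed = 1) {
  popmap <- as_tibble(popmap)
  pres <- hm$presence
  check_that(all(rownames(pres) %in% popmap$individual),
             "popmap is missing called individuals")
  pop_of <- setNames(popmap$population, popmap$individual)[rownames(pres)]
  pops <- unique(pop_of)
  with_seed(seed, {
    prows <- lapply(pops, function(pn) {
      P <- pres[pop_of == pn, , drop = FALSE]
      N <- nrow(P)
      check_that(N >= 1, paste0("population ", pn, " is empty"))
      nn <- min(rarefaction_n, N)
      if (N == nn) {
        n_hap <- sum(colSums(P) > 0)      # resampling the full set is exact
      } else {
        n_hap <- mean(vapply(seq_len(resamples), function(b) {
          sum(colSums(P[sample.int(N, nn), , drop = FALSE]) > 0)
        }, numeric(1)))
      }
      k <- rowSums(P)
      tibble(population = pn, n = N, n_hap = n_hap,
             prop_poly = mean(k > 1), prop_gt2 = mean(k > 2),
             rarefied_at = nn, flagged = N < rarefaction_n)
    })
    frows <- lapply(pops, function(pn) {
      P <- pres[pop_of == pn, , drop = FALSE]
      cf <- colSums(P) / nrow(P)
      cf <- cf[cf > 0]
      if (length(cf) == 0) return(NULL)
      tibble(population = pn, haplotype = names(cf),
             carrier_freq = unname(cf), std_freq = unname(cf / sum(cf)))
    })
    structure(list(populations = bind_rows(prows),
                   frequencies = bind_rows(frows),
                   rarefaction_n = rarefaction_n, resamples = resamples,
                   seed = seed),
              class = "mhc_diversity")
  })
}

#' @export
print.mhc_diversity <- function(x, ...) {
  cat("<mhc_diversity> rarefied at n =", x$rarefaction_n, "with",
      x$resamples, "resamples\n")
  print(as.data.frame(x$populations))
  invisible(x)
}

#' @rdname mhc_diversity
#' @param x an `mhc_diversity` object.
#' @param ... unused.
#' @method tidy mhc_diversity
#' @export
tidy.mhc_diversity <- function(x, ...) x$populations
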