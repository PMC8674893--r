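reads_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(individual = r[[1]], haplotype = r[[2]],
                   reads = as.numeric(r[[3]]))))
}

test_that("within-individual threshold is strict and uses raw totals", {
  # i1: {h1: 900, h2: 95, h3: 5}; h2 sits at 9.5% -> only h1 called
  rt <- reads_tbl(list("i1", "h1", 900), list("i1", "h2", 95),
                  list("i1", "h3", 5),
                  list("i2", "h1", 500), list("i2", "h2", 400),
                  list("i2", "h3", 100))
  hm <- call_haplotypes(rt, drop_singletons = FALSE)
  expect_equal(colnames(hm$presence)[hm$presence["i1", ] == 1], "h1")
  # i2: h3 at exactly 10% is excluded (strict >)
  expect_setequal(colnames(hm$presence)[hm$presence["i2", ] == 1],
                  c("h1", "h2"))
})

test_that("dataset-wide read floor and singleton removal apply in order", {
  rt <- reads_tbl(list("i1", "h1", 30), list("i1", "h2", 100),
                  list("i2", "h1", 25), list("i2", "h2", 90),
                  list("i3", "h2", 80), list("i3", "h4", 60))
  # h1 dataset total 55 > 50 -> kept at stage 1; h4 called only in i3 -> dropped
  hm <- call_haplotypes(rt)
  expect_false("h4" %in% colnames(hm$presence))
  expect_true("h1" %in% colnames(hm$presence))
  # a haplotype with total exactly 50 is discarded (rule is > 50)
  rt2 <- reads_tbl(list("i1", "h1", 25), list("i2", "h1", 25),
                   list("i1", "h2", 500), list("i2", "h2", 500))
  hm2 <- call_haplotypes(rt2)
  expect_false("h1" %in% colnames(hm2$presence))
})

test_that("individuals with zero reads are flagged and uncalled", {
  rt <- reads_tbl(list("i1", "h1", 0), list("i2", "h1", 600),
                  list("i3", "h1", 700))
  hm <- call_haplotypes(rt)
  expect_equal(hm$no_reads, "i1")
  expect_equal(sum(hm$presence["i1", ]), 0)
})

test_that("calling is invariant to row order of the read table", {
  sim <- simulate_mhc_reads(25, 10, seed = 71)
  hm1 <- call_haplotypes(sim$reads)
  shuffled <- sim$reads[withr::with_seed(1, sample(nrow(sim$reads))), ]
  hm2 <- call_haplotypes(shuffled)
  expect_identical(hm1$presence, hm2$presence)
})

test_that("sub-threshold noise haplotypes are never called: truth recovered", {
  for (seed in c(72, 73)) {
    sim <- simulate_mhc_reads(40, 12, noise_rate = 0.02, seed = seed)
    hm <- call_haplotypes(sim$reads)
    called <- tidy(hm)
    # truth up to the documented singleton exclusion: a true haplotype
    # carried by exactly one individual is removed by the caller by design
    truth <- dplyr::arrange(callable_truth(sim$truth), individual, haplotype)
    expect_identical(as.data.frame(called), as.data.frame(truth))
    expect_false(any(grepl("noise", called$haplotype)))
  }
})

test_that("rarefied richness matches enumeration and hypergeometric oracles", {
  withr::with_seed(74, {
    pres <- matrix(rbinom(10 * 8, 1, 0.35), 10, 8,
                   dimnames = list(paste0("i", 1:10), paste0("h", 1:8)))
    hm <- structure(list(presence = pres, no_reads = character(0)),
                    class = "haplotype_matrix")
    pm <- tibble::tibble(individual = paste0("i", 1:10), population = "A")
    div <- mhc_diversity(hm, pm, rarefaction_n = 5, resamples = 2000, seed = 7)
    exact_enum <- rarefaction_enumeration(pres, 5)
    exact_hyper <- rarefaction_hypergeometric(pres, 5)
    expect_equal(exact_enum, exact_hyper, tolerance = 1e-12)
    expect_lt(abs(div$populations$n_hap - exact_hyper), 0.1)
  })
})

test_that("rarefaction degenerates exactly for small or uniform populations", {
  # population of exactly n individuals: the resample is the full set
  pres <- matrix(1L, 5, 3, dimnames = list(paste0("i", 1:5), paste0("h", 1:3)))
  hm <- structure(list(presence = pres, no_reads = character(0)),
                  class = "haplotype_matrix")
  pm <- tibble::tibble(individual = paste0("i", 1:5), population = "A")
  div <- mhc_diversity(hm, pm, resamples = 10, seed = 1)
  expect_equal(div$populations$n_hap, 3)
  expect_equal(div$populations$prop_poly, 1)
  expect_equal(div$populations$prop_gt2, 1)
  # identical haplotype sets: zero resampling variance at any n
  pres2 <- rbind(pres, pres)
  rownames(pres2) <- paste0("i", 1:10)
  hm2 <- structure(list(presence = pres2, no_reads = character(0)),
                   class = "haplotype_matrix")
  pm2 <- tibble::tibble(individual = paste0("i", 1:10), population = "A")
  div2 <- mhc_diversity(hm2, pm2, resamples = 50, seed = 2)
  expect_equal(div2$populations$n_hap, 3)
})

test_that("rarefied richness is monotone in rarefaction_n", {
  withr::with_seed(75, {
    pres <- matrix(rbinom(12 * 9, 1, 0.3), 12, 9,
                   dimnames = list(paste0("i", 1:12), paste0("h", 1:9)))
    hm <- structure(list(presence = pres, no_reads = character(0)),
                    class = "haplotype_matrix")
    pm <- tibble::tibble(individual = paste0("i", 1:12), population = "A")
    vals <- vapply(c(3, 5, 8, 12), function(n)
      mhc_diversity(hm, pm, rarefaction_n = n, resamples = 500,
                    seed = 3)$populations$n_hap, numeric(1))
    expect_true(all(diff(vals) >= -1e-9))
  })
})

test_that("standardized haplotype frequencies sum to one per population", {
  sim <- simulate_mhc_reads(30, 10, seed = 76)
  hm <- call_haplotypes(sim$reads)
  pm <- tibble::tibble(individual = rownames(hm$presence),
                       population = rep(c("A", "B"), length.out = 30))
  div <- mhc_diversity(hm, pm, seed = 4)
  sums <- tapply(div$frequencies$std_freq, div$frequencies$population, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("Nei-Gojobori counts equal the pathway-enumeration oracle", {
  codons <- ciscogen:::sense_codons()
  withr::with_seed(77, {
    for (rep in 1:40) {
      c1 <- sample(codons, 1); c2 <- sample(codons, 1)
      expect_equal(unname(ciscogen:::ng_diffs(c1, c2)),
                   ng_oracle_diffs(c1, c2), tolerance = 1e-12)
      expect_equal(ciscogen:::ng_syn_sites(c1), ng_oracle_sites(c1),
                   tolerance = 1e-12)
    }
  })
  # 5-codon toy pair with mixed changes, full-sequence check
  s1 <- "TTTGCAGGAACCAAA"
  s2 <- "TTCGCGGGTACCAGA"
  res <- nei_gojobori_ztest(c(s1, s2), bootstrap = 50, seed = 1)
  cods1 <- ciscogen:::split_codons(s1); cods2 <- ciscogen:::split_codons(s2)
  sd_tot <- nd_tot <- 0
  for (i in seq_along(cods1)) {
    d <- ng_oracle_diffs(cods1[i], cods2[i])
    sd_tot <- sd_tot + d[1]; nd_tot <- nd_tot + d[2]
  }
  s_sites <- (sum(vapply(cods1, ng_oracle_sites, numeric(1))) +
                sum(vapply(cods2, ng_oracle_sites, numeric(1)))) / 2
  expect_equal(res$ds, sd_tot / s_sites, tolerance = 1e-12)
  expect_equal(res$dn, nd_tot / (15 - s_sites), tolerance = 1e-12)
})

test_that("degenerate alignments give the expected Z-test behaviour", {
  s <- strrep("GCTAAAGAT", 5)
  res <- nei_gojobori_ztest(c(s, s, s), bootstrap = 50, seed = 2)
  expect_equal(res$dn, 0)
  expect_equal(res$ds, 0)
  expect_gte(res$p_value, 0.5)
  # synonymous-only divergence: dN = 0, Z <= 0
  s2 <- strrep("GCCAAGGAT", 5)   # third-position changes only
  res2 <- nei_gojobori_ztest(c(s, s2), bootstrap = 100, seed = 3)
  expect_equal(res2$dn, 0)
  expect_lte(res2$z, 0)
  expect_gte(res2$p_value, 0.5)
})

test_that("strong nonsynonymous divergence is detected as positive selection", {
  withr::with_seed(78, {
    # derive haplotypes by single-nucleotide amino-acid-changing
    # substitutions so divergence is purely nonsynonymous
    nt <- c("A", "C", "G", "T")
    base <- ciscogen:::random_cds(60)
    mutate_nonsyn <- function(cods, n_sub) {
      for (j in sample(length(cods), n_sub)) {
        repeat {
          pos <- sample(3, 1)
          cand <- cods[j]
          substr(cand, pos, pos) <- sample(setdiff(nt, substr(cand, pos, pos)), 1)
          if (!ciscogen:::is_stop_codon(cand) &&
              ciscogen:::codon_aa(cand) != ciscogen:::codon_aa(cods[j])) break
        }
        cods[j] <- cand
      }
      cods
    }
    seqs <- c(base, vapply(1:5, function(i) {
      paste(mutate_nonsyn(ciscogen:::split_codons(base), 20), collapse = "")
    }, character(1)))
    res <- nei_gojobori_ztest(seqs, bootstrap = 300, seed = 4)
    expect_gt(res$z, 1.64)
    expect_lt(res$p_value, 0.05)
  })
})
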