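# Fixture: 10 individuals in 3 pops, loci engineered per filtering stage.
make_filter_fixture <- function() {
  pop <- c(rep("A", 4), rep("B", 3), rep("C", 3))
  g <- matrix(1L, 10, 5)
  # locus 1: genotyped in 6/10 = 60% -> removed at call-rate stage
  g[1:4, 1] <- NA
  # locus 2: fine, MAF high
  g[, 2] <- c(0L, 1L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L)
  # locus 3: rare variant, MAF = 1/20 = 0.05 kept at default, removed at 0.06
  g[, 3] <- c(1L, rep(0L, 9))
  # locus 4: entirely missing in pop C, MAF otherwise ~0.3
  g[, 4] <- c(1L, 1L, 0L, 1L, 0L, 1L, 0L, NA, NA, NA)
  # locus 5: monomorphic (MAF 0) -> removed at MAF stage
  g[, 5] <- 0L
  toy_dataset(g, pop)
}

test_that("filters apply in the documented order with strict thresholds", {
  ds <- make_filter_fixture()
  out <- filter_genotypes(ds)
  expect_equal(colnames(out$dataset$geno), c("l002", "l003"))
  rep <- out$report
  expect_equal(rep$removed_loci[rep$stage == "locus_call_rate"], 1)
  expect_equal(rep$removed_loci[rep$stage == "minor_allele_frequency"], 1)
  expect_equal(rep$removed_loci[rep$stage == "genotyped_in_every_population"], 1)
  # report stage counts sum to input - output
  expect_equal(sum(rep$removed_loci), n_loci(ds) - n_loci(out$dataset))
  expect_equal(sum(rep$removed_individuals),
               n_individuals(ds) - n_individuals(out$dataset))
})

test_that("MAF exactly at the threshold is retained (rule is strictly below)", {
  ds <- make_filter_fixture()
  out <- filter_genotypes(ds, maf_min = 0.05)
  expect_true("l003" %in% colnames(out$dataset$geno))
  out2 <- filter_genotypes(ds, maf_min = 0.051)
  expect_false("l003" %in% colnames(out2$dataset$geno))
})

test_that("individual missingness removes above 50% only, and recomputes MAF after", {
  g <- matrix(1L, 6, 4)
  g[1, 1:3] <- NA                  # individual 1 missing 75% -> dropped
  g[2, 1:2] <- NA                  # exactly 50% -> kept
  # locus 4 is common only through individual 1; after its removal MAF drops to 0.1
  g[, 4] <- c(2L, 0L, 0L, 0L, 1L, 0L)
  ds <- toy_dataset(g, rep("A", 6))
  out <- filter_genotypes(ds, locus_call_rate = 0.5, maf_min = 0.15,
                          require_all_pops = FALSE)
  expect_false("i001" %in% out$dataset$samples$individual)
  expect_true("i002" %in% out$dataset$samples$individual)
  expect_false("l004" %in% colnames(out$dataset$geno))
})

test_that("filtering is idempotent and an all-filtered dataset errors", {
  ds <- simulate_genotypes(sim_config(n_loci = 200, n_individuals_per_pop = 12,
                                      missing_rate = 0.1, seed = 8))
  once <- filter_genotypes(ds)$dataset
  twice <- filter_genotypes(once)$dataset
  expect_identical(once$geno, twice$geno)
  expect_error(filter_genotypes(ds, maf_min = 0.6), "all data filtered")
})

test_that("HDPlot flags by allele balance, deviation and heterozygosity", {
  # 20 heterozygotes, 100 reads each at 80% ref: n = 2000, AB = 0.8,
  # D = (1600 - 1000) / sqrt(500) ~ 26.8 -> flagged twice over
  n <- 20
  g <- matrix(1L, n, 2)
  rd <- matrix(80, n, 2); ad <- matrix(20, n, 2)
  rd[, 2] <- 50; ad[, 2] <- 50          # locus 2 perfectly balanced
  g2 <- rbind(g, matrix(c(0L, 0L), 2, 2))  # two homozygotes dilute H below 1
  rd <- rbind(rd, matrix(100, 2, 2)); ad <- rbind(ad, matrix(0, 2, 2))
  ds <- toy_dataset(g2, rep("A", n + 2), ref_depth = rd, alt_depth = ad)
  out <- hdplot_screen(ds, h_max = 0.95)
  expect_equal(out$stats$allele_balance[1], 0.8)
  expect_equal(out$stats$D[1], (1600 - 1000) / sqrt(2000 / 4), tolerance = 1e-12)
  expect_true(out$stats$flagged[1])
  expect_equal(out$stats$D[2], 0)
  expect_equal(out$stats$allele_balance[2], 0.5)
  expect_false(out$stats$flagged[2])
  expect_equal(colnames(out$dataset$geno), "l002")
})

test_that("all-heterozygous loci are flagged and zero-het loci are not", {
  g <- cbind(rep(1L, 10), rep(0L, 10))
  rd <- matrix(10, 10, 2); ad <- matrix(10, 10, 2)
  ds <- toy_dataset(g, rep("A", 10), ref_depth = rd, alt_depth = ad)
  out <- hdplot_screen(ds)
  expect_true(out$stats$flagged[1])     # H = 1 > 0.5
  expect_false(out$stats$flagged[2])    # no heterozygotes: D, AB undefined
  expect_true(is.na(out$stats$D[2]))
})

test_that("simulated single-copy loci rarely trip the paralog screen", {
  # sample sizes comparable to a real Rapture panel keep the heterozygote
  # fraction estimate stable
  ds <- simulate_genotypes(sim_config(n_loci = 1500, n_individuals_per_pop = 40,
                                      mean_depth = 30, seed = 21))
  out <- hdplot_screen(ds)
  expect_lt(mean(out$stats$flagged), 0.01)
})

test_that("one SNP per tag keeps the top-MAF SNP with deterministic ties", {
  g <- cbind(
    c(rep(1L, 2), rep(0L, 23)),   # MAF 0.04
    c(rep(1L, 13), rep(0L, 12)),  # MAF 0.26... engineered below
    c(rep(1L, 13), rep(0L, 12)),
    c(rep(2L, 5), rep(0L, 20)))   # separate tag, single SNP
  ds <- toy_dataset(g, rep("A", 25), tag = c("t1", "t1", "t1", "t2"))
  out <- select_snp_per_tag(ds)
  expect_equal(colnames(out$geno), c("l002", "l004"))  # tie l002/l003 -> lower id
  expect_equal(n_loci(out), length(unique(ds$loci$tag)))
})
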