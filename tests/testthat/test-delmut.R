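make_hit <- function(locus = "x", identity = 95, overlap = 50, frame = 0L,
                     strand = "+") {
  tibble::tibble(locus = locus, protein = "p", identity = identity,
                 overlap_aa = overlap, frame = frame, strand = strand)
}

test_that("alignment retention thresholds are strict", {
  seqs <- tibble::tibble(locus = "x", allele = c("ref", "alt"),
                         seq = c(strrep("GCA", 50),
                                 paste0("GCC", strrep("GCA", 49))))
  # identity exactly 90 removed, 90.1 kept; overlap exactly 40 removed, 41 kept
  expect_equal(nrow(annotate_coding(seqs, make_hit(identity = 90))), 0)
  expect_equal(nrow(annotate_coding(seqs, make_hit(identity = 90.1))), 1)
  expect_equal(nrow(annotate_coding(seqs, make_hit(overlap = 40))), 0)
  expect_equal(nrow(annotate_coding(seqs, make_hit(overlap = 41))), 1)
})

test_that("best-identity hit wins and frames/strands are honoured", {
  seqs <- tibble::tibble(locus = "x", allele = c("ref", "alt"),
                         seq = c(strrep("GCA", 50),
                                 paste0("TCA", strrep("GCA", 49))))
  hits <- dplyr::bind_rows(make_hit(identity = 92), make_hit(identity = 97))
  ann <- annotate_coding(seqs, hits)
  expect_equal(nrow(ann), 1)              # single best-identity row retained
  # reverse strand: reverse-complement first, then translate
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  seqs_rc <- tibble::tibble(locus = "x", allele = c("ref", "alt"),
                            seq = c(rc(strrep("GCA", 50)),
                                    rc(paste0("TCA", strrep("GCA", 49)))))
  ann_f <- annotate_coding(seqs, make_hit())
  ann_r <- annotate_coding(seqs_rc, make_hit(strand = "-"))
  expect_equal(ann_r$ref_protein, ann_f$ref_protein)
  expect_equal(ann_r$alt_protein, ann_f$alt_protein)
  expect_equal(ann_r$synonymous, ann_f$synonymous)
})

test_that("premature stop codons are flagged and excluded from the catalog", {
  seqs <- tibble::tibble(locus = "x", allele = c("ref", "alt"),
                         seq = c(paste0("TGC", strrep("GCA", 49)),
                                 paste0("TGA", strrep("GCA", 49))))  # alt gains stop
  ann <- annotate_coding(seqs, make_hit())
  expect_true(ann$premature_stop)
  cat0 <- classify_deleterious(ann, tibble::tibble(locus = "x", allele = "alt",
                                                   score = -9))
  expect_equal(nrow(cat0), 0)
})

test_that("classification boundary is score <= -2.5, both-deleterious flagged", {
  seqs <- tibble::tibble(locus = rep(c("a", "b", "c"), each = 2),
                         allele = rep(c("ref", "alt"), 3),
                         seq = rep(c(strrep("GCA", 50),
                                     paste0("TCA", strrep("GCA", 49))), 3))
  hits <- dplyr::bind_rows(make_hit("a"), make_hit("b"), make_hit("c"))
  ann <- annotate_coding(seqs, hits)
  scores <- tibble::tibble(
    locus = c("a", "b", "c", "c"),
    allele = c("alt", "alt", "alt", "ref"),
    score = c(-2.5, -2.49, -4, -3))
  cat0 <- classify_deleterious(ann, scores)
  expect_true("a" %in% cat0$locus)                 # exactly at threshold
  expect_false("b" %in% cat0$locus)                # just above threshold
  crow <- cat0[cat0$locus == "c", ]
  expect_equal(crow$deleterious_allele, "alt")     # lower of the two scores
  expect_equal(crow$flag, "both_deleterious")
})

test_that("load metrics reproduce hand arithmetic and handle no-data loci", {
  # 3 catalog loci; population frequencies of the deleterious allele
  # engineered to (0.5, 0.0, 1.0) -> af_del = 0.5, prop_del = 2/3
  g <- cbind(c(1L, 1L, 0L, 0L),      # alt freq 0.25 -> del is ref? no: alt
             c(0L, 0L, 0L, 0L),
             c(2L, 2L, 2L, 2L))
  g[, 1] <- c(1L, 1L, 1L, 1L)        # alt freq 0.5
  ds <- toy_dataset(g, rep("A", 4))
  catalog <- tibble::tibble(locus = c("l001", "l002", "l003"),
                            deleterious_allele = "alt",
                            score = -3, flag = NA_character_)
  lm_ <- load_metrics(ds, catalog)
  expect_equal(lm_$af_del, 0.5)
  expect_equal(lm_$prop_del, 2 / 3)
  # a locus with zero genotyped individuals leaves the af mean but stays in
  # the prop_del denominator
  g2 <- g; g2[, 3] <- NA
  ds2 <- toy_dataset(g2, rep("A", 4))
  lm2 <- load_metrics(ds2, catalog)
  expect_equal(lm2$af_del, mean(c(0.5, 0)))
  expect_equal(lm2$n_loci, 2)
  expect_equal(lm2$prop_del, 1 / 3)
})

test_that("fixed and absent deleterious alleles hit the metric extremes", {
  g <- matrix(2L, 5, 4)
  ds <- toy_dataset(g, rep("A", 5))
  catalog <- tibble::tibble(locus = paste0("l00", 1:4),
                            deleterious_allele = "alt", score = -3,
                            flag = NA_character_)
  lm_ <- load_metrics(ds, catalog)
  expect_equal(lm_$af_del, 1)
  expect_equal(lm_$prop_del, 1)
  catalog$deleterious_allele <- "ref"
  lm0 <- load_metrics(ds, catalog)
  expect_equal(lm0$af_del, 0)
  expect_equal(lm0$prop_del, 0)
})

test_that("prop_del is monotone under pooling populations", {
  ds <- simulate_genotypes(sim_config(n_loci = 200, prop_deleterious = 0.3,
                                      n_individuals_per_pop = 10, seed = 61))
  del_loci <- names(ds$truth$deleterious)[ds$truth$deleterious]
  catalog <- tibble::tibble(locus = del_loci, deleterious_allele = "alt",
                            score = -3, flag = NA_character_)
  sep <- load_metrics(ds, catalog)
  pooled <- ds
  pooled$samples$population <- ifelse(
    pooled$samples$population %in% c("L1P1", "L1P2"), "POOL",
    pooled$samples$population)
  pl <- load_metrics(pooled, catalog)
  expect_gte(pl$prop_del[pl$population == "POOL"],
             max(sep$prop_del[sep$population %in% c("L1P1", "L1P2")]))
})

test_that("synthetic scores give perfect classification recall and precision", {
  cds <- simulate_cds_alleles(60, 50, prop_nonsyn = 0.6, seed = 62)
  ann <- annotate_coding(cds$sequences, cds$hits)
  cat0 <- classify_deleterious(ann, cds$scores)
  truth <- cds$truth$locus[cds$truth$deleterious]
  expect_setequal(cat0$locus, truth)
})

test_that("minor-allele mode swaps the designated allele where alt is major", {
  g <- cbind(c(2L, 2L, 2L, 0L),   # alt is major (0.75)
             c(0L, 0L, 0L, 1L))   # alt is minor (0.125)
  ds <- toy_dataset(g, rep("A", 4))
  catalog <- tibble::tibble(locus = c("l001", "l002"),
                            deleterious_allele = "alt", score = -3,
                            flag = NA_character_)
  by_catalog <- load_metrics(ds, catalog)
  by_minor <- load_metrics(ds, catalog, allele = "minor")
  expect_equal(by_catalog$af_del, mean(c(0.75, 0.125)))
  expect_equal(by_minor$af_del, mean(c(0.25, 0.125)))
})
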