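#' Diploid SNP genotype dataset
#'
#' Container for a diploid biallelic SNP matrix with per-individual allele
#' read depths and the sample/locus annotations the downstream analyses need
#' (population and lineage membership, RAD-tag ids, linkage groups).
#'
#' Genotypes are stored as an individuals-by-loci integer matrix of
#' alternate-allele dosages (0, 1, 2) with `NA` for missing calls. Allele
#' depths, when present, are matrices of the same shape counting reference and
#' alternate reads.
#'
#' @param geno integer matrix, individuals x loci, values in {0, 1, 2, NA};
#'   rownames are individual ids, colnames locus ids.
#' @param samples tibble with columns `individual`, `population` and
#'   optionally `lineage`; one row per row of `geno`.
#' @param loci tibble with column `locus` and optionally `tag`,
#'   `linkage_group`; one row per column of `geno`.
#' @param ref_depth,alt_depth optional matrices of per-call read counts with
#'   the same dimensions as `geno`.
#' @param truth optional list of generator truth metadata (kept verbatim).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, samples, loci, ref_depth = NULL,
                             alt_depth = NULL, truth = NULL) {
  check_that(is.matrix(geno), "`geno` must be a matrix")
  storage.mode(geno) <- "integer"
  check_that(all(geno %in% c(0L, 1L, 2L) | is.na(geno)),
             "genotype dosages must be 0, 1, 2 or NA")
  samples <- as_tibble(samples)
  loci <- as_tibble(loci)
  check_that(all(c("individual", "population") %in% names(samples)),
             "`samples` needs columns individual, population")
  check_that("locus" %in% names(loci), "`loci` needs a `locus` column")
  check_that(nrow(samples) == nrow(geno), "samples/genotype row mismatch")
  check_that(nrow(loci) == ncol(geno), "loci/genotype column mismatch")
  rownames(geno) <- samples$individual
  colnames(geno) <- loci$locus
  for (d in list(ref_depth, alt_depth)) {
    if (!is.null(d)) {
      check_that(identical(dim(d), dim(geno)), "depth matrix dimension mismatch")
      check_that(all(d >= 0, na.rm = TRUE), "read depths must be non-negative")
    }
  }
  structure(
    list(geno = geno, samples = samples, loci = loci,
         ref_depth = ref_depth, alt_depth = alt_depth, truth = truth),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " loci; ", length(unique(x$samples$population)), " populations",
      if (!is.null(x$samples$lineage))
        paste0(", ", length(unique(x$samples$lineage)), " lineages"),
      "\n", sep = "")
  cat("  missing calls: ",
      sprintf("%.1f%%", 100 * mean(is.na(x$geno))),
      if (!is.null(x$ref_depth)) "; allele depths present", "\n", sep = "")
  invisible(x)
}

#' Number of individuals / loci in a dataset
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(ds) nrow(ds$geno)

#' @rdname n_individuals
#' @export
n_loci <- function(ds) ncol(ds$geno)

# Subset by individual ids (rows) and/or locus ids (columns), keeping
# annotations and depth matrices aligned.
subset_dataset <- function(ds, individuals = NULL, loci = NULL) {
  ri <- if (is.null(individuals)) seq_len(nrow(ds$geno)) else
    match(individuals, rownames(ds$geno))
  ci <- if (is.null(loci)) seq_len(ncol(ds$geno)) else
    match(loci, colnames(ds$geno))
  check_that(!anyNA(ri) && !anyNA(ci), "unknown individual or locus id")
  genotype_dataset(
    ds$geno[ri, ci, drop = FALSE],
    ds$samples[ri, , drop = FALSE],
    ds$loci[ci, , drop = FALSE],
    ref_depth = if (!is.null(ds$ref_depth)) ds$ref_depth[ri, ci, drop = FALSE],
    alt_depth = if (!is.null(ds$alt_depth)) ds$alt_depth[ri, ci, drop = FALSE],
    truth = ds$truth
  )
}

# Per-locus alternate-allele frequency over a set of rows (default: all).
alt_freq <- function(geno) {
  colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
}

# Per-locus minor allele frequency across all individuals.
locus_maf <- function(ds) {
  p <- alt_freq(ds$geno)
  pmin(p, 1 - p)
}

# population x loci matrix of alternate-allele frequencies (NaN where a
# population has no genotyped individual at a locus).
pop_freqs <- function(ds) {
  pops <- unique(ds$samples$population)
  t(vapply(pops, function(p) {
    alt_freq(ds$geno[ds$samples$population == p, , drop = FALSE])
  }, numeric(ncol(ds$geno)))) |>
    (\(m) {rownames(m) <- pops; m})()
}

# population x loci matrix of genotyped sample sizes.
pop_sizes <- function(ds) {
  pops <- unique(ds$samples$population)
  t(vapply(pops, function(p) {
    colSums(!is.na(ds$geno[ds$samples$population == p, , drop = FALSE]))
  }, numeric(ncol(ds$geno)))) |>
    (\(m) {rownames(m) <- pops; m})()
}

#' Read a genotype dataset from VCF
#'
#' Reads GT and (when present) AD fields from a VCF file and joins a
#' population map. Missing calls (`./.`) become `NA` dosages.
#'
#' @param vcf path to a VCF file (plain or bgzipped).
#' @param popmap data frame with columns `individual`, `population` and
#'   optionally `lineage`, or path to such a CSV.
#' @param locus_map optional data frame (or CSV path) with columns `locus`,
#'   `tag`, `linkage_group`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes_vcf <- function(vcf, popmap, locus_map = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  gt_clean <- gsub("\\|", "/", gt)
  dos_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(matrix(dos_map[gt_clean], nrow = nrow(gt)))
  ref_d <- alt_d <- NULL
  if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(v, element = "AD")
    split2 <- function(k) {
      x <- suppressWarnings(vapply(strsplit(ad, ","), function(z)
        as.numeric(z[k]), numeric(1)))
      t(matrix(x, nrow = nrow(ad)))
    }
    ref_d <- split2(1); alt_d <- split2(2)
    dimnames(ref_d) <- dimnames(alt_d) <- dimnames(dos)
  }
  if (is.character(popmap)) popmap <- read.csv(popmap)
  popmap <- as_tibble(popmap)
  check_that(all(rownames(dos) %in% popmap$individual),
             "popmap is missing individuals present in the VCF")
  samples <- popmap[match(rownames(dos), popmap$individual), ]
  loci <- tibble(locus = colnames(dos))
  if (!is.null(locus_map)) {
    if (is.character(locus_map)) locus_map <- read.csv(locus_map)
    loci <- left_join(loci, as_tibble(locus_map), by = "locus")
  }
  genotype_dataset(dos, samples, loci, ref_depth = ref_d, alt_depth = alt_d)
}

#' Write a genotype dataset to a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with GT (and AD when depths are present) so
#' filtered datasets can be handed to external tools. Output is uncompressed
#' text.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(ds, path) {
  n <- n_individuals(ds); L <- n_loci(ds)
  has_ad <- !is.null(ds$ref_depth) && !is.null(ds$alt_depth)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ciscogen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele read depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(ds$geno)), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[ds$geno + 1L], nrow = n)
  gt_str[is.na(ds$geno)] <- "./."
  if (has_ad) {
    ad <- matrix(paste0(ifelse(is.na(ds$ref_depth), ".", ds$ref_depth), ",",
                        ifelse(is.na(ds$alt_depth), ".", ds$alt_depth)),
                 nrow = n)
    gt_str <- matrix(paste0(gt_str, ":", ad), nrow = n)
  }
  rows <- vapply(seq_len(L), function(j) {
    paste(c("1", j, ds$loci$locus[j], "A", "T", ".", "PASS", ".",
            if (has_ad) "GT:AD" else "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write the sample population map / locus map as CSV
#'
#' @param ds a [genotype_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_popmap_csv <- function(ds, path) {
  write.csv(ds$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_popmap_csv
#' @export
write_locus_map_csv <- function(ds, path) {
  write.csv(ds$loci, path, row.names = FALSE)
  invisible(path)
}
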