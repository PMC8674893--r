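#' Annotate locus alleles against protein alignments
#'
#' Consumes a tabular protein-alignment report (from an external aligner or
#' the synthetic generator; the aligner itself is out of scope) and the
#' per-allele nucleotide sequences, keeps hits with an amino-acid overlap
#' strictly above `min_overlap` and identity strictly above `min_identity`
#' (best identity per locus on ties of eligibility), translates each allele
#' in the aligned frame, and marks substitutions as synonymous or
#' nonsynonymous. Alleles that gain a premature stop codon are flagged and
#' excluded from downstream scoring.
#'
#' @param sequences tibble with columns locus, allele (`"ref"`/`"alt"`), seq
#'   (nucleotide strings), e.g. from [read_alleles_fasta()].
#' @param hits tibble with columns locus, protein, identity (percent),
#'   overlap_aa, frame (0/1/2), strand (`"+"`/`"-"`).
#' @param min_overlap minimum amino-acid overlap (strict).
#' @param min_identity minimum percent identity (strict).
#' @return tibble: locus, protein, frame, strand, ref_protein, alt_protein,
#'   synonymous, premature_stop.
#' @export
annotate_coding <- function(sequences, hits, min_overlap = 40, min_identity = 90) {
  hits <- as_tibble(hits) |>
    filter(.data$overlap_aa > min_overlap, .data$identity > min_identity) |>
    arrange(.data$locus, dplyr::desc(.data$identity)) |>
    group_by(.data$locus) |>
    dplyr::slice(1) |>
    ungroup()
  sequences <- as_tibble(sequences)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  translate_in_frame <- function(s, frame, strand) {
    s <- toupper(s)
    if (strand == "-") s <- revcomp(s)
    s <- substr(s, frame + 1, nchar(s))
    s <- substr(s, 1, 3 * (nchar(s) %/% 3))
    if (nchar(s) < 3) return(NA_character_)
    translate_cds(s)
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    sq <- sequences[sequences$locus == h$locus, ]
    ref <- sq$seq[sq$allele == "ref"]; alt <- sq$seq[sq$allele == "alt"]
    if (length(ref) != 1 || length(alt) != 1) return(NULL)
    pr <- translate_in_frame(ref, h$frame, h$strand)
    pa <- translate_in_frame(alt, h$frame, h$strand)
    # a stop introduced before the final codon disqualifies the locus
    mid_stop <- function(p) grepl("\\*", substr(p, 1, nchar(p) - 1))
    tibble(locus = h$locus, protein = h$protein, frame = h$frame,
           strand = h$strand, ref_protein = pr, alt_protein = pa,
           synonymous = identical(pr, pa),
           premature_stop = mid_stop(pr) || mid_stop(pa))
  })
  bind_rows(rows)
}

#' Classify nonsynonymous alleles as deleterious by effect score
#'
#' The allele whose effect score is at or below `threshold` is designated the
#' deleterious allele; its alternative is designated neutral. Loci where no
#' allele reaches the threshold are excluded from the catalog. If both
#' alleles score at or below the threshold the lower-scoring allele is taken
#' as deleterious and the entry is flagged `both_deleterious`.
#'
#' @param annotations output of [annotate_coding()]; only nonsynonymous,
#'   non-premature-stop loci are considered.
#' @param scores tibble with columns locus, allele (`"ref"`/`"alt"`), score.
#'   Typically only the derived (alt) allele carries a score; a missing ref
#'   score is treated as neutral (score above threshold).
#' @param threshold deleterious cut-off (scores <= threshold, default -2.5).
#' @return tibble catalog: locus, deleterious_allele, score, flag.
#' @export
classify_deleterious <- function(annotations, scores, threshold = -2.5) {
  cand <- annotations |>
    filter(!.data$synonymous, !.data$premature_stop)
  scores <- as_tibble(scores)
  rows <- lapply(cand$locus, function(lc) {
    sc <- scores[scores$locus == lc, ]
    if (nrow(sc) == 0) return(NULL)
    del <- sc[sc$score <= threshold, ]
    if (nrow(del) == 0) return(NULL)
    del <- del[which.min(del$score), ]
    tibble(locus = lc, deleterious_allele = del$allele, score = del$score,
           flag = if (sum(sc$score <= threshold) > 1) "both_deleterious" else NA_character_)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    tibble(locus = character(), deleterious_allele = character(),
           score = numeric(), flag = character())
  else out
}

#' Population mutational-load metrics
#'
#' Two complementary summaries over a deleterious-allele catalog:
#' `af_del`, the unweighted mean sample frequency of the deleterious allele
#' across catalog loci (loci with no genotyped individual in a population are
#' excluded from that population's mean), and `prop_del`, the fraction of all
#' catalog loci at which the deleterious allele segregates (frequency > 0) in
#' the population - the denominator is always the full catalog.
#'
#' For cross-study comparison with work that assumes strongly deleterious
#' variants are purged to low frequency, `allele = "minor"` replaces the
#' catalog designation by the dataset-wide minor allele at each catalog
#' locus.
#'
#' @param ds a [genotype_dataset()] containing the catalog loci.
#' @param catalog output of [classify_deleterious()].
#' @param allele `"catalog"` (default, score-designated allele) or `"minor"`.
#' @return tibble: population, af_del, prop_del, n_loci (loci contributing to
#'   the mean).
#' @export
load_metrics <- function(ds, catalog, allele = c("catalog", "minor")) {
  allele <- match.arg(allele)
  check_that(all(catalog$locus %in% ds$loci$locus),
             "catalog loci missing from the dataset")
  sub <- subset_dataset(ds, loci = catalog$locus)
  f_alt <- pop_freqs(sub)                       # pops x catalog loci
  del_is_alt <- catalog$deleterious_allele[match(colnames(f_alt), catalog$locus)] == "alt"
  if (allele == "minor") {
    overall <- alt_freq(sub$geno)
    del_is_alt <- overall <= 0.5
  }
  f_del <- f_alt
  f_del[, !del_is_alt] <- 1 - f_alt[, !del_is_alt, drop = FALSE]
  total <- nrow(catalog)
  rows <- lapply(rownames(f_del), function(pn) {
    fr <- f_del[pn, ]
    tibble(population = pn,
           af_del = mean(fr[is.finite(fr)]),
           prop_del = sum(fr > 0, na.rm = TRUE) / total,
           n_loci = sum(is.finite(fr)))
  })
  bind_rows(rows)
}
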