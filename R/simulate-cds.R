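# Codon helpers shared by the CDS simulator, coding annotation and the
# Nei-Gojobori test.

codon_aa <- function(codon) {
  seqinr::translate(strsplit(toupper(codon), "")[[1]])
}

translate_cds <- function(seq) {
  paste(seqinr::translate(strsplit(toupper(seq), "")[[1]]), collapse = "")
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Simulate coding-sequence alleles with known effect scores
#'
#' Generates a reference coding sequence per locus and a single-nucleotide
#' alternate allele whose synonymous/nonsynonymous status is controlled by
#' `prop_nonsyn`. Nonsynonymous alleles carry a synthetic effect score drawn
#' uniformly on `score_spread`; the truth set of deleterious loci (score at or
#' below -2.5) is returned so the classification stage can be checked exactly.
#' A synthetic protein-alignment table (high identity, full overlap) is
#' emitted in the shape an external aligner report would take.
#'
#' @param n_loci number of loci.
#' @param codons_per_locus coding length of each locus, in codons (>= 2).
#' @param prop_nonsyn fraction of alternate alleles that are nonsynonymous.
#' @param score_spread length-2 numeric range for the synthetic effect scores.
#' @param seed integer RNG seed.
#' @param threshold truth deleterious cut-off applied to the scores.
#' @return list with `sequences` (locus/allele/seq tibble), `hits` (synthetic
#'   alignment table), `scores` (locus/allele/score for nonsynonymous
#'   alleles), and `truth` (locus/deleterious).
#' @export
simulate_cds_alleles <- function(n_loci, codons_per_locus, prop_nonsyn = 0.5,
                                 score_spread = c(-8, 4), seed = 1,
                                 threshold = -2.5) {
  check_that(is_count(n_loci), "`n_loci` must be a count")
  check_that(is_count(codons_per_locus) && codons_per_locus >= 2,
             "`codons_per_locus` must be >= 2")
  check_that(is_fraction(prop_nonsyn, open_top = FALSE),
             "`prop_nonsyn` must be in [0, 1]")
  with_seed(seed, {
    loci <- sprintf("cds%04d", seq_len(n_loci))
    want_nonsyn <- runif(n_loci) < prop_nonsyn
    nt <- c("A", "C", "G", "T")
    seq_rows <- vector("list", n_loci)
    allele_rows <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      repeat {
        codons <- sample(sense_codons(), codons_per_locus, replace = TRUE)
        hit <- NULL
        # search random single-nt substitutions for the requested class
        for (try in seq_len(200)) {
          ci <- sample(codons_per_locus, 1)
          pos <- sample(3, 1)
          old <- codons[ci]
          new_nt <- sample(setdiff(nt, substr(old, pos, pos)), 1)
          new <- old
          substr(new, pos, pos) <- new_nt
          if (is_stop_codon(new)) next
          syn <- identical(codon_aa(old), codon_aa(new))
          if (syn != want_nonsyn[i]) { hit <- list(ci = ci, pos = pos, new = new); break }
        }
        if (!is.null(hit)) break
      }
      alt_codons <- codons
      alt_codons[hit$ci] <- hit$new
      seq_rows[[i]] <- tibble(
        locus = loci[i],
        allele = c("ref", "alt"),
        seq = c(paste(codons, collapse = ""), paste(alt_codons, collapse = ""))
      )
      allele_rows[[i]] <- tibble(
        locus = loci[i],
        codon = hit$ci, position = (hit$ci - 1L) * 3L + hit$pos,
        ref_codon = codons[hit$ci], alt_codon = hit$new,
        synonymous = !want_nonsyn[i]
      )
    }
    scores <- tibble(
      locus = loci[want_nonsyn], allele = "alt",
      score = runif(sum(want_nonsyn), score_spread[1], score_spread[2])
    )
    hits <- tibble(
      locus = loci, protein = paste0("prot_", loci),
      identity = 99, overlap_aa = codons_per_locus,
      frame = 0L, strand = "+"
    )
    truth <- tibble(locus = loci) |>
      left_join(scores[, c("locus", "score")], by = "locus") |>
      mutate(nonsynonymous = want_nonsyn,
             deleterious = !is.na(.data$score) & .data$score <= threshold)
    list(sequences = bind_rows(seq_rows), alleles = bind_rows(allele_rows),
         hits = hits, scores = scores, truth = truth)
  })
}

#' Write locus allele sequences as FASTA
#'
#' Headers take the form `<locus>|<allele>`.
#'
#' @param sequences tibble with columns locus, allele, seq.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alleles_fasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", sequences$locus, "|", sequences$allele),
                           sequences$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read locus allele sequences from FASTA written by [write_alleles_fasta()]
#'
#' @param path FASTA path.
#' @return tibble with columns locus, allele, seq.
#' @export
read_alleles_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  nm <- names(fa)
  parts <- strsplit(nm, "|", fixed = TRUE)
  tibble(
    locus = vapply(parts, `[`, character(1), 1),
    allele = vapply(parts, `[`, character(1), 2),
    seq = toupper(unname(vapply(fa, as.character, character(1))))
  )
}
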