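# Nei-Gojobori (1986) codon-based synonymous/nonsynonymous analysis and the
# one-tailed Z-test of positive selection (dN > dS).

# Fractional synonymous site count of one codon: at each position, the
# fraction of the three possible nucleotide changes that preserve the amino
# acid. Changes that create a stop codon count as nonsynonymous.
ng_syn_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nt, substr(codon, pos, pos))) {
      new <- codon
      substr(new, pos, pos) <- alt
      if (!is_stop_codon(new) && identical(codon_aa(new), aa0)) s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous differences between two codons.
# All orderings of the differing positions are enumerated; pathways passing
# through a stop codon are excluded (falling back to all pathways when every
# ordering is blocked).
ng_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(pos) else {
    pp <- gtools_permutations(d)
    lapply(seq_len(nrow(pp)), function(i) pos[pp[i, ]])
  }
  walk <- function(order) {
    cur <- c1; sd <- nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop_codon(nxt)) blocked <- TRUE
      if (identical(codon_aa(cur), codon_aa(nxt))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  open <- res["blocked", ] == 0
  if (any(open)) res <- res[, open, drop = FALSE]
  c(sd = mean(res["sd", ]), nd = mean(res["nd", ]))
}

# All permutations of 1..n as a matrix (n is at most 3 here).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori codon Z-test for positive selection
#'
#' Tests whether nonsynonymous divergence exceeds synonymous divergence
#' across a set of aligned in-frame coding haplotypes - historical balancing
#' selection at MHC loci leaves exactly this signature. Per sequence pair,
#' fractional synonymous/nonsynonymous sites and pathway-averaged differences
#' are counted per codon; `dN` and `dS` are the pairwise proportions averaged
#' over all pairs, their variances come from bootstrapping codon columns, and
#' `Z = (dN - dS) / sqrt(Var(dN) + Var(dS))` with a one-tailed p-value for
#' `dN > dS`. Codons containing non-ACGT characters are skipped (and
#' reported).
#'
#' @param seqs character vector of aligned coding sequences (equal length,
#'   multiple of 3, no internal stops).
#' @param bootstrap codon bootstrap replicates for the variances.
#' @param seed RNG seed.
#' @return tibble: dn, ds, z, p_value, n_pairs, n_codons, skipped_codons.
#' @export
nei_gojobori_ztest <- function(seqs, bootstrap = 1000, seed = 1) {
  check_that(length(seqs) >= 2, "need at least 2 sequences")
  check_that(length(unique(nchar(seqs))) == 1, "sequences must be aligned (equal length)")
  check_that(nchar(seqs[1]) %% 3 == 0, "alignment length must be a multiple of 3")
  cod <- t(vapply(seqs, split_codons, character(nchar(seqs[1]) / 3)))
  ncod <- ncol(cod)
  valid <- matrix(grepl("^[ACGT]{3}$", cod), nrow(cod))
  check_that(!any(valid & matrix(cod %in% c("TAA", "TAG", "TGA"), nrow(cod))),
             "internal stop codon in input")
  skipped <- sum(colSums(!valid) > 0)

  syn_cache <- new.env(parent = emptyenv())
  s_of <- function(c3) {
    v <- get0(c3, envir = syn_cache)
    if (is.null(v)) { v <- ng_syn_sites(c3); assign(c3, v, envir = syn_cache) }
    v
  }
  S <- matrix(NA_real_, nrow(cod), ncod)
  S[valid] <- vapply(cod[valid], s_of, numeric(1))

  pairs <- combn(nrow(cod), 2)
  np <- ncol(pairs)
  sd_arr <- nd_arr <- matrix(0, np, ncod)
  use_arr <- matrix(FALSE, np, ncod)
  diff_cache <- new.env(parent = emptyenv())
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- valid[i, ] & valid[j, ]
    use_arr[k, ] <- ok
    for (m in which(ok & cod[i, ] != cod[j, ])) {
      key <- paste0(cod[i, m], cod[j, m])
      v <- get0(key, envir = diff_cache)
      if (is.null(v)) { v <- ng_diffs(cod[i, m], cod[j, m]); assign(key, v, envir = diff_cache) }
      sd_arr[k, m] <- v["sd"]; nd_arr[k, m] <- v["nd"]
    }
  }

  pair_stats <- function(codon_idx) {
    dn <- ds <- numeric(np)
    for (k in seq_len(np)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      ok <- codon_idx[use_arr[k, codon_idx]]
      if (length(ok) == 0) { dn[k] <- ds[k] <- NA; next }
      s_sites <- (sum(S[i, ok]) + sum(S[j, ok])) / 2
      n_sites <- 3 * length(ok) - s_sites
      ds[k] <- sum(sd_arr[k, ok]) / s_sites
      dn[k] <- sum(nd_arr[k, ok]) / n_sites
    }
    c(dn = mean(dn, na.rm = TRUE), ds = mean(ds, na.rm = TRUE))
  }
  obs <- pair_stats(seq_len(ncod))
  boot <- with_seed(seed, {
    vapply(seq_len(bootstrap), function(b) {
      pair_stats(sample.int(ncod, ncod, replace = TRUE))
    }, numeric(2))
  })
  v_dn <- var(boot["dn", ]); v_ds <- var(boot["ds", ])
  z <- (obs["dn"] - obs["ds"]) / sqrt(v_dn + v_ds)
  if (!is.finite(z)) z <- 0   # identical sequences: no divergence, no signal
  tibble(dn = unname(obs["dn"]), ds = unname(obs["ds"]), z = unname(z),
         p_value = unname(1 - pnorm(z)), n_pairs = np, n_codons = ncod,
         skipped_codons = skipped)
}
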