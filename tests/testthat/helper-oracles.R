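# Independent oracle implementations used to verify the package estimators.
# These are deliberately written as literal, loop-based transcriptions of the
# textbook formulas, sharing no code with the implementations they check.

# Weir-Cockerham (1984) multi-locus theta: per-locus a, b, c transcribed
# term by term, summed over loci.
wc_theta_oracle <- function(ds) {
  pops <- unique(ds$samples$population)
  num <- den <- 0
  for (l in seq_len(ncol(ds$geno))) {
    n <- p <- h <- numeric(0)
    for (pp in pops) {
      g <- ds$geno[ds$samples$population == pp, l]
      g <- g[!is.na(g)]
      if (length(g) == 0) next
      n <- c(n, length(g))
      p <- c(p, sum(g) / (2 * length(g)))
      h <- c(h, mean(g == 1))
    }
    r <- length(n)
    if (r < 2) next
    nbar <- sum(n) / r
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force four-level AMOVA: explicit sums of squares from group means and
# a linear solve of the expected-mean-square system, per locus.
amova_oracle <- function(geno, pop, lin) {
  tot <- c(0, 0, 0, 0)
  for (l in seq_len(ncol(geno))) {
    g <- geno[, l]
    ok <- !is.na(g)
    if (sum(ok) < 2) next
    g <- g[ok]; pp <- pop[ok]; ll <- lin[ok]
    ybar_ind <- g / 2
    ybar_pop <- tapply(g, pp, sum) / (2 * tapply(ok[ok], pp, length))
    ybar_lin <- tapply(g, ll, sum) / (2 * tapply(ok[ok], ll, length))
    ybar <- sum(g) / (2 * length(g))
    n_p <- table(pp); n_l <- table(ll); N <- length(g)
    P <- length(n_p); G <- length(n_l)
    if (N - P <= 0 || P - G <= 0 || G - 1 <= 0) next
    # within individuals: each het contributes (1-.5)^2+(0-.5)^2 = .5
    ss_wi <- sum(g == 1) * 0.5
    ss_ai <- 0
    for (i in seq_along(g))
      ss_ai <- ss_ai + 2 * (ybar_ind[i] - ybar_pop[[pp[i]]])^2
    ss_ap <- 0
    for (pn in names(n_p)) {
      lk <- unique(ll[pp == pn])
      ss_ap <- ss_ap + 2 * n_p[[pn]] * (ybar_pop[[pn]] - ybar_lin[[lk]])^2
    }
    ss_ag <- 0
    for (ln in names(n_l))
      ss_ag <- ss_ag + 2 * n_l[[ln]] * (ybar_lin[[ln]] - ybar)^2
    c_p <- 2 * n_p; c_l <- 2 * n_l; C <- 2 * N
    sum_cp2_cl <- 0
    for (ln in names(n_l)) {
      inl <- names(n_p)[vapply(names(n_p), function(pn)
        unique(ll[pp == pn]) == ln, logical(1))]
      sum_cp2_cl <- sum_cp2_cl + sum(c_p[inl]^2) / c_l[[ln]]
    }
    n1 <- (C - sum_cp2_cl) / (P - G)
    n2 <- (sum_cp2_cl - sum(c_p^2) / C) / (G - 1)
    n3 <- (C - sum(c_l^2) / C) / (G - 1)
    ms <- c(ss_wi / N, ss_ai / (N - P), ss_ap / (P - G), ss_ag / (G - 1))
    A <- rbind(c(1, 0, 0, 0),
               c(1, 2, 0, 0),
               c(1, 2, n1, 0),
               c(1, 2, n2, n3))
    tot <- tot + solve(A, ms)
  }
  tot
}

# Nei-Gojobori pathway enumeration for a pair of codons, written as direct
# recursion over orderings of the differing sites.
GEN_CODE <- setNames(
  as.character(seqinr::translate(t(sapply(
    apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                      c("T","C","A","G")), 1, paste, collapse = ""),
    function(x) strsplit(x, "")[[1]]))[, 1])), NA)
aa_of <- function(codon) seqinr::translate(strsplit(codon, "")[[1]])

ng_oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (i in 1:3) for (b in bases) {
    if (b == substr(codon, i, i)) next
    mut <- codon
    substr(mut, i, i) <- b
    if (mut %in% c("TAA", "TAG", "TGA")) next
    if (aa_of(mut) == aa_of(codon)) syn <- syn + 1 / 3
  }
  syn
}

ng_oracle_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  if (length(dpos) == 0) return(c(0, 0))
  orders <- if (length(dpos) == 1) list(dpos) else {
    perm <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perm(v[-i])) out <- c(out, list(c(v[i], rest)))
      out
    }
    perm(dpos)
  }
  paths <- lapply(orders, function(ord) {
    cur <- c1; s <- ns <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% c("TAA", "TAG", "TGA")) blocked <- TRUE
      if (aa_of(cur) == aa_of(nxt)) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    c(s, ns, blocked)
  })
  m <- do.call(rbind, paths)
  open <- m[, 3] == 0
  if (any(open)) m <- m[open, , drop = FALSE]
  c(mean(m[, 1]), mean(m[, 2]))
}

# Worst-case error of 1 - Ho/He when Ho, He and the printed G_IS are all
# rounded to 3 decimals: |d(1 - Ho/He)| <= (dHo + dHe * Ho/He) / He with
# dHo = dHe = 5e-4, plus 5e-4 for the rounding of G_IS itself.
gis_rounding_bound <- function(Ho, He) {
  (5e-4 + 5e-4 * Ho / He) / He + 5e-4
}

# Exact rarefaction expectation by full subset enumeration.
rarefaction_enumeration <- function(presence, n) {
  subsets <- combn(nrow(presence), n)
  mean(apply(subsets, 2, function(idx)
    sum(colSums(presence[idx, , drop = FALSE]) > 0)))
}

# Closed-form hypergeometric rarefaction expectation.
rarefaction_hypergeometric <- function(presence, n) {
  N <- nrow(presence)
  m <- colSums(presence)
  sum(1 - choose(N - m, n) / choose(N, n))
}
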