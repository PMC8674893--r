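# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so a given
# seed yields bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, open_top = TRUE) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 &&
    (if (open_top) x < 1 else x <= 1)
}

check_that <- function(ok, msg) {
  if (!ok) abort(msg)
  invisible(TRUE)
}

#' Construct a symmetric population-by-population matrix
#'
#' Thin S3 wrapper around a base symmetric matrix with zero diagonal, used for
#' all pairwise quantities (Weir-Cockerham theta, Nei's D_A, geographic km,
#' *di*). [tidy()] turns it into a long tibble of unique pairs.
#'
#' @param m square numeric matrix with identical row/column names.
#' @param metric short label stored as an attribute (e.g. "fst").
#' @return an object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(m, metric = "value") {
  check_that(is.matrix(m) && nrow(m) == ncol(m), "`m` must be square")
  check_that(!is.null(rownames(m)) && identical(rownames(m), colnames(m)),
             "`m` needs identical row and column names")
  diag(m) <- 0
  check_that(isTRUE(all.equal(m, t(m), tolerance = 1e-12, check.attributes = FALSE)),
             "`m` must be symmetric")
  structure(m, metric = metric, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("<pairwise_matrix:", attr(x, "metric"), "-", nrow(x), "populations>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname pairwise_matrix
#' @param x a `pairwise_matrix`.
#' @param ... unused.
#' @method tidy pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  ut <- upper.tri(x)
  idx <- which(ut, arr.ind = TRUE)
  tibble(
    pop1 = rownames(x)[idx[, 1]],
    pop2 = colnames(x)[idx[, 2]],
    metric = attr(x, "metric"),
    value = x[ut]
  )
}

# Off-diagonal upper-triangle vector in a fixed order.
pm_vec <- function(x) unclass(x)[upper.tri(x)]

# Build a pairwise_matrix by applying f(pop_i, pop_j) over all pairs.
pm_from_pairs <- function(pops, f, metric) {
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- f(pops[i], pops[j])
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  pairwise_matrix(m, metric = metric)
}

#' Slatkin-linearize an FST matrix
#'
#' Computes FST / (1 - FST) elementwise. Negative multi-locus estimates are
#' floored at zero before linearization (raw values should be inspected on the
#' unlinearized matrix).
#'
#' @param fst a `pairwise_matrix` of FST values.
#' @return a `pairwise_matrix` of linearized values.
#' @export
linearize_fst <- function(fst) {
  m <- pmax(unclass(fst), 0)
  pairwise_matrix(m / (1 - m), metric = "linearized_fst")
}
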