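# Correlation stage: collinearity pruning, redundancy analysis, lmg relative
# importance, univariate regressions, and summary statistics over the joined
# metrics table.

vif_values <- function(X) {
  X <- as.data.frame(X)
  vapply(names(X), function(j) {
    r2 <- summary(lm(stats::reformulate(setdiff(names(X), j), response = j),
                     data = X))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Iterative collinearity pruning of a predictor table
#'
#' First removes, one at a time, the predictor with the largest variance
#' inflation factor until all VIF fall below `vif_max`. Then inspects the
#' remaining pairwise Pearson correlations: for every pair with
#' `|r| > r_max`, the member named in `manual_drops` is removed - the choice
#' between two merely-correlated predictors is a scientific judgement the
#' tool refuses to make silently, so an unresolved pair is an error listing
#' the offenders.
#'
#' @param X data frame of numeric predictors (more rows than columns).
#' @param vif_max VIF threshold (keep while VIF < vif_max).
#' @param r_max absolute pairwise correlation threshold.
#' @param manual_drops character vector naming which member of each
#'   high-correlation pair to drop.
#' @return list with `predictors` (pruned data frame) and `log` (tibble of
#'   removals with stage and criterion value).
#' @export
collinearity_prune <- function(X, vif_max = 5, r_max = 0.7,
                               manual_drops = character()) {
  X <- as.data.frame(X)
  check_that(ncol(X) >= 2, "need at least 2 predictors")
  check_that(nrow(X) > ncol(X), "need more rows than predictors")
  log <- list()
  repeat {
    if (ncol(X) < 2) break
    v <- vif_values(X)
    if (all(v < vif_max)) break
    worst <- names(which.max(v))
    log[[length(log) + 1]] <- tibble(stage = "vif", dropped = worst,
                                     value = unname(v[worst]))
    X <- X[, setdiff(names(X), worst), drop = FALSE]
  }
  cm <- cor(X)
  ut <- which(abs(cm) > r_max & upper.tri(cm), arr.ind = TRUE)
  if (nrow(ut) > 0) {
    pairs <- apply(ut, 1, function(ij)
      c(rownames(cm)[ij[1]], colnames(cm)[ij[2]]))
    for (k in seq_len(ncol(pairs))) {
      pr <- pairs[, k]
      if (!any(pr %in% names(X))) next      # already resolved by earlier drop
      hit <- intersect(manual_drops, pr)
      if (length(hit) == 0)
        abort(paste0("correlated pair above |r| = ", r_max, ": ",
                     paste(pr, collapse = " ~ "),
                     "; name one of them in `manual_drops`"))
      log[[length(log) + 1]] <- tibble(stage = "pairwise_r", dropped = hit[1],
                                       value = unname(cm[pr[1], pr[2]]))
      X <- X[, setdiff(names(X), hit[1]), drop = FALSE]
    }
  }
  list(predictors = X,
       log = if (length(log)) bind_rows(log)
             else tibble(stage = character(), dropped = character(),
                         value = numeric()))
}

#' Redundancy analysis of genetic metrics on spatial/environmental predictors
#'
#' Responses and predictors are centred and unit-scaled, then the response
#' block is regressed on the predictors (RDA via [vegan::rda()]). Reported:
#' the constrained variance fraction, the Ezekiel-adjusted R^2, a global
#' permutation test, and per-predictor permutation tests - marginal
#' (leave-one-out) by default since no fitting order is privileged, or
#' sequential on request.
#'
#' @param Y data frame of responses (one row per population).
#' @param X data frame of predictors (same rows).
#' @param permutations permutation count for the ANOVA tests.
#' @param seed RNG seed.
#' @param by per-predictor test type: `"margin"` (default) or `"terms"`
#'   (sequential).
#' @return object of class `rda_result` wrapping the vegan ordination with
#'   `constrained` (fraction), `r2_adj`, `global` and `terms` tibbles.
#'   [tidy()]/[glance()] methods exist.
#' @export
rda_genetics <- function(Y, X, permutations = 999, seed = 1,
                         by = c("margin", "terms")) {
  by <- match.arg(by)
  Y <- as.data.frame(Y); X <- as.data.frame(X)
  check_that(nrow(Y) == nrow(X), "Y and X need matching rows")
  check_that(nrow(X) > ncol(X), "need more rows than predictors")
  check_that(all(complete.cases(Y)) && all(complete.cases(X)),
             "Y and X must be complete")
  qr_x <- qr(scale(as.matrix(X)))
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qr_x$rank)]
    abort(paste0("rank-deficient predictors: ", paste(bad, collapse = ", ")))
  }
  Ys <- as.data.frame(scale(Y))
  Xs <- as.data.frame(scale(X))
  ord <- vegan::rda(Ys ~ ., data = Xs)
  constrained <- ord$CCA$tot.chi / ord$tot.chi
  r2 <- vegan::RsquareAdj(ord)
  glob <- with_seed(seed, as.data.frame(
    vegan::anova.cca(ord, permutations = permutations)))
  trm <- with_seed(seed, as.data.frame(
    vegan::anova.cca(ord, by = by, permutations = permutations)))
  structure(list(
    ordination = ord,
    constrained = constrained,
    r2_adj = r2$adj.r.squared,
    global = tibble(variance = glob$Variance[1], F = glob$F[1],
                    p_value = glob$`Pr(>F)`[1]),
    terms = tibble(predictor = rownames(trm)[seq_len(nrow(trm) - 1)],
                   variance = trm$Variance[seq_len(nrow(trm) - 1)],
                   F = trm$F[seq_len(nrow(trm) - 1)],
                   p_value = trm$`Pr(>F)`[seq_len(nrow(trm) - 1)]),
    permutations = permutations, seed = seed, by = by
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("<rda_result> constrained fraction ", round(x$constrained, 3),
      ", adjusted R2 ", round(x$r2_adj, 3), ", global p ",
      format(x$global$p_value), "\n", sep = "")
  print(as.data.frame(x$terms))
  invisible(x)
}

#' @rdname rda_genetics
#' @param x an `rda_result`.
#' @param ... unused.
#' @method tidy rda_result
#' @export
tidy.rda_result <- function(x, ...) x$terms

#' @rdname rda_genetics
#' @method glance rda_result
#' @export
glance.rda_result <- function(x, ...) {
  tibble(constrained = x$constrained, r2_adj = x$r2_adj,
         global_p = x$global$p_value, permutations = x$permutations)
}

# R^2 of y on a subset of predictor columns (empty subset -> 0).
subset_r2 <- function(y, Xm, cols) {
  if (length(cols) == 0) return(0)
  f <- lm.fit(cbind(1, Xm[, cols, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' Multiple regression with lmg relative-importance decomposition
#'
#' Ordinary least squares of `y` on all predictors, plus the lmg share of
#' each predictor: its increment to R^2 when entering the model, averaged
#' over all orderings of the predictors (computed by exact enumeration over
#' subsets; practical for up to ~8 predictors). Raw shares sum to the model
#' R^2; normalized shares sum to 1.
#'
#' @param y numeric response.
#' @param X data frame of predictors (n > p + 1, full rank).
#' @return object of class `lmg_result`: `model` (glance-style tibble with
#'   r2, p) and `importance` (tibble: predictor, lmg, lmg_normalized,
#'   univariate_r2, univariate_p).
#' @export
mlr_lmg <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X); n <- length(y)
  check_that(n == nrow(X), "length mismatch")
  check_that(n > p + 1, "need n > predictors + 1")
  check_that(p <= 12, "exact lmg enumeration limited to 12 predictors")
  Xm <- as.matrix(X)
  check_that(qr(cbind(1, Xm))$rank == p + 1, "collinear predictors rejected")
  fit <- lm(y ~ ., data = cbind.data.frame(y = y, X))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  model_p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  r2_full <- sm$r.squared

  # cache R^2 over all subsets, keyed by bitmask
  r2_cache <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    r2_cache[mask + 1] <- subset_r2(y, Xm, cols)
  }
  lmg <- vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    total <- 0
    for (k in 0:(p - 1)) {
      wt <- factorial(k) * factorial(p - k - 1) / factorial(p)
      # index into `others` (combn treats a scalar x as seq_len(x))
      subs <- if (k == 0) list(integer(0)) else
        lapply(asplit(combn(seq_along(others), k), 2), function(ii) others[ii])
      for (s in subs) {
        m0 <- sum(2^(s - 1))
        m1 <- m0 + 2^(j - 1)
        total <- total + wt * (r2_cache[m1 + 1] - r2_cache[m0 + 1])
      }
    }
    total
  }, numeric(1))
  uni <- lapply(seq_len(p), function(j) {
    sf <- summary(lm(y ~ Xm[, j]))
    fs <- sf$fstatistic
    tibble(univariate_r2 = sf$r.squared,
           univariate_p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
  })
  structure(list(
    model = tibble(r2 = r2_full, p_value = model_p, n = n, df = p),
    importance = bind_rows(uni) |>
      mutate(predictor = names(X), lmg = lmg,
             lmg_normalized = lmg / r2_full, .before = 1),
    fit = fit
  ), class = "lmg_result")
}

#' @export
print.lmg_result <- function(x, ...) {
  cat("<lmg_result> R2 =", round(x$model$r2, 3),
      "p =", format(x$model$p_value), "\n")
  print(as.data.frame(x$importance))
  invisible(x)
}

#' @rdname mlr_lmg
#' @param x an `lmg_result`.
#' @param ... unused.
#' @method tidy lmg_result
#' @export
tidy.lmg_result <- function(x, ...) x$importance

#' @rdname mlr_lmg
#' @method glance lmg_result
#' @export
glance.lmg_result <- function(x, ...) x$model

#' Univariate regressions between metric/predictor pairs
#'
#' Simple linear regressions for chosen (response, predictor) pairs;
#' predictors named in `log_transform` (typically lake surface area) are
#' log-transformed first.
#'
#' @param table data frame with the named columns.
#' @param pairs data frame with columns `response`, `predictor`.
#' @param log_transform character vector of predictors to log-transform.
#' @return tibble: response, predictor, slope, r2, p_value, log_transformed.
#' @export
univariate_regressions <- function(table, pairs, log_transform = character()) {
  table <- as.data.frame(table)
  pairs <- as.data.frame(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    rs <- pairs$response[i]; pd <- pairs$predictor[i]
    check_that(all(c(rs, pd) %in% names(table)),
               paste0("unknown column in pair ", rs, " ~ ", pd))
    x <- table[[pd]]
    logged <- pd %in% log_transform
    if (logged) x <- log(x)
    check_that(sd(x) > 0, paste0("zero-variance predictor ", pd))
    sf <- summary(lm(table[[rs]] ~ x))
    fs <- sf$fstatistic
    tibble(response = rs, predictor = pd,
           slope = unname(coef(sf)[2, 1]), r2 = sf$r.squared,
           p_value = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
           log_transformed = logged)
  })
  bind_rows(rows)
}

#' Summary statistics over a joined metrics table
#'
#' Column means (plus medians over finite values, which matters for N_e where
#' infinite estimates are legitimate output), and lineage-stratified means
#' when a lineage column is present.
#'
#' @param table data frame, one row per population.
#' @param lineage_col name of the lineage label column (ignored if absent).
#' @return list with `overall` (tibble: metric, mean, median_finite, n) and
#'   `by_lineage` (tibble: lineage, metric, mean), the latter `NULL` without
#'   lineage labels.
#' @export
summarize_metrics <- function(table, lineage_col = "lineage") {
  table <- as_tibble(table)
  check_that(nrow(table) > 0, "empty table")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  overall <- bind_rows(lapply(num, function(cn) {
    x <- table[[cn]]
    tibble(metric = cn,
           mean = mean(x[is.finite(x)], na.rm = TRUE),
           median_finite = median(x[is.finite(x)], na.rm = TRUE),
           n = sum(!is.na(x)))
  }))
  by_lineage <- NULL
  if (lineage_col %in% names(table)) {
    by_lineage <- table |>
      group_by(lineage = .data[[lineage_col]]) |>
      summarise(across(all_of(num), ~ mean(.x[is.finite(.x)], na.rm = TRUE)),
                .groups = "drop") |>
      tidyr::pivot_longer(-"lineage", names_to = "metric", values_to = "mean")
  }
  list(overall = overall, by_lineage = by_lineage)
}
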