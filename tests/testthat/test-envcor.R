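test_that("VIF values equal the per-column regression oracle", {
  withr::with_seed(81, {
    n <- 40
    x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n, sd = 0.8); x3 <- rnorm(n)
    X <- data.frame(x1 = x1, x2 = x2, x3 = x3)
    v <- ciscogen:::vif_values(X)
    for (j in names(X)) {
      r2 <- summary(lm(X[[j]] ~ ., data = X[setdiff(names(X), j)]))$r.squared
      expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-9)
    }
  })
})

test_that("orthogonal predictors survive pruning; duplicates are removed", {
  X <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4),
                  c = rep(c(-1, 1, 1, -1), 4))
  out <- collinearity_prune(X)
  expect_equal(names(out$predictors), names(X))
  expect_equal(nrow(out$log), 0)
  X2 <- cbind(X, d = X$a + rnorm(16, sd = 1e-8))
  out2 <- collinearity_prune(X2)
  expect_equal(ncol(out2$predictors), 3)
  expect_true(any(out2$log$stage == "vif"))
})

test_that("high-correlation pairs demand an explicit manual choice", {
  withr::with_seed(82, {
    n <- 30
    a <- rnorm(n)
    # r ~ 0.8 with a, but VIF ~ 1/(1-0.64) = 2.8 < 5: passes the VIF stage
    b <- 0.8 * a + rnorm(n, sd = sqrt(1 - 0.64))
    X <- data.frame(a = a, b = b, c = rnorm(n))
    expect_error(collinearity_prune(X, r_max = 0.55), "manual_drops")
    out <- collinearity_prune(X, r_max = 0.55, manual_drops = "b")
    expect_false("b" %in% names(out$predictors))
    expect_true("pairwise_r" %in% out$log$stage)
  })
})

test_that("RDA constrained fraction matches a direct least-squares oracle", {
  withr::with_seed(83, {
    n <- 25
    X <- data.frame(x = rnorm(n))
    Y <- data.frame(y1 = 0.8 * X$x + rnorm(n), y2 = rnorm(n))
    fit <- rda_genetics(Y, X, permutations = 49, seed = 1)
    Ys <- scale(as.matrix(Y)); xs <- scale(X$x)
    H <- xs %*% solve(crossprod(xs)) %*% t(xs)
    frac <- sum((H %*% Ys)^2) / sum(Ys^2)
    expect_equal(fit$constrained, frac, tolerance = 1e-9)
  })
})

test_that("responses equal to predictors are fully constrained", {
  withr::with_seed(84, {
    X <- data.frame(a = rnorm(12), b = rnorm(12))
    fit <- rda_genetics(X, X, permutations = 49, seed = 1)
    expect_equal(fit$constrained, 1, tolerance = 1e-9)
  })
})

test_that("rank-deficient predictor blocks are rejected by name", {
  withr::with_seed(85, {
    X <- data.frame(a = rnorm(10))
    X$b <- 2 * X$a
    Y <- data.frame(y = rnorm(10))
    expect_error(rda_genetics(Y, X, permutations = 9), "rank-deficient.*b")
  })
})

test_that("lmg shares sum to R2, and match the closed form when orthogonal", {
  withr::with_seed(86, {
    # random instance: raw shares sum to model R2
    n <- 30
    X <- data.frame(matrix(rnorm(n * 4), n))
    y <- X[[1]] + 0.5 * X[[2]] + rnorm(n)
    res <- mlr_lmg(y, X)
    expect_equal(sum(res$importance$lmg), res$model$r2, tolerance = 1e-9)
    expect_equal(sum(res$importance$lmg_normalized), 1, tolerance = 1e-9)
    # orthogonal design: lmg_j = r^2(y, x_j) exactly
    Xo <- data.frame(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
    yo <- 2 * Xo$a - Xo$b + rnorm(20)
    ro <- mlr_lmg(yo, Xo)
    expect_equal(ro$importance$lmg,
                 c(cor(yo, Xo$a)^2, cor(yo, Xo$b)^2), tolerance = 1e-9)
  })
})

test_that("lmg is invariant to predictor order and rescaling", {
  withr::with_seed(87, {
    n <- 25
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- X$a + 2 * X$b + rnorm(n)
    r1 <- mlr_lmg(y, X)
    r2 <- mlr_lmg(y, X[, c("c", "a", "b")])
    m1 <- setNames(r1$importance$lmg, r1$importance$predictor)
    m2 <- setNames(r2$importance$lmg, r2$importance$predictor)
    expect_equal(m1[names(m2)], m2, tolerance = 1e-9)
    X3 <- X; X3$a <- 100 * X3$a + 7
    r3 <- mlr_lmg(y, X3)
    m3 <- setNames(r3$importance$lmg, r3$importance$predictor)
    expect_equal(m1[names(m3)], m3, tolerance = 1e-9)
  })
})

test_that("single predictor degenerates to the univariate regression", {
  withr::with_seed(88, {
    x <- rnorm(15); y <- 2 * x + rnorm(15)
    res <- mlr_lmg(y, data.frame(x = x))
    expect_equal(res$importance$lmg_normalized, 1)
    expect_equal(res$importance$lmg, cor(x, y)^2, tolerance = 1e-9)
  })
})

test_that("univariate regressions honour exact fits and log flags", {
  tab <- data.frame(y = 2 * (1:10), x = 1:10, area = exp(1:10))
  # exact fits trip summary.lm's perfect-fit warning; that is the point here
  out <- suppressWarnings(
    univariate_regressions(tab, data.frame(response = "y", predictor = "x")))
  expect_equal(out$r2, 1, tolerance = 1e-12)
  expect_equal(out$slope, 2, tolerance = 1e-9)
  lo <- suppressWarnings(univariate_regressions(
    tab, data.frame(response = "y", predictor = "area"),
    log_transform = "area"))
  expect_true(lo$log_transformed)
  expect_equal(lo$r2, 1, tolerance = 1e-9)   # y is linear in log(area)
  expect_error(univariate_regressions(
    data.frame(y = 1:5, x = rep(1, 5)),
    data.frame(response = "y", predictor = "x")), "zero-variance")
})

test_that("survey-table aggregates reproduce the published summaries", {
  tab <- cisco_population_metrics()
  s <- summarize_metrics(tab)
  get <- function(m, col) s$overall[[col]][s$overall$metric == m]
  expect_equal(round(get("af_del", "mean"), 2), 0.71)
  expect_equal(round(get("prop_del", "mean"), 2), 0.95)
  expect_equal(round(get("n_hap", "mean"), 2), 5.93)
  expect_equal(get("ne", "median_finite"), 296)
  lin <- function(l, m) s$by_lineage$mean[s$by_lineage$lineage == l &
                                            s$by_lineage$metric == m]
  expect_equal(round(lin("MS", "af_del"), 2), 0.72)
  expect_equal(round(lin("GL", "af_del"), 2), 0.69)
  # constant column mean is that constant
  s2 <- summarize_metrics(data.frame(k = rep(3.5, 4)))
  expect_equal(s2$overall$mean, 3.5)
})
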