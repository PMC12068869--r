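test_that("unpaired t-test matches the hand-computed oracle", {
  res <- ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$cohens_d, -1, tolerance = 1e-9)
  expect_equal(res$df, 4)
  # swapping the samples flips the signs
  res2 <- ttest_unpaired(c(2, 3, 4), c(1, 2, 3))
  expect_equal(res2$t, -res$t)
  expect_equal(res2$cohens_d, -res$cohens_d)
  expect_error(ttest_unpaired(c(1, 1), c(1, 1)), "degenerate")
})

test_that("JZS Bayes factor reproduces frozen reference values", {
  # references computed with an independent numerical implementation
  # (pingouin.bayesfactor_ttest, two-sample, r = 0.707)
  expect_equal(bayes_factor_t(0, 25, 25), 0.2826971, tolerance = 1e-4)
  expect_equal(bayes_factor_t(2, 25, 25), 1.4131931, tolerance = 1e-4)
  expect_equal(bayes_factor_t(2.5, 20, 22), 3.3512934, tolerance = 1e-4)
  expect_equal(bayes_factor_t(-1.948, 24, 25), 1.3079252, tolerance = 1e-4)
  # a decisive group difference gives an astronomically large BF10
  expect_gt(bayes_factor_t(8.49, 24, 25), 1e6)
  # monotone increasing in |t| at fixed n
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5), bayes_factor_t, numeric(1),
                n1 = 25, n2 = 25)
  expect_true(all(diff(bfs) > 0))
})

test_that("Spearman matrix is symmetric with unit diagonal and honors monotone transforms", {
  set.seed(1)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  X$c <- exp(X$a)  # monotone transform of a
  res <- spearman_fdr(X)
  expect_equal(res$rho["a", "c"], 1)
  expect_equal(res$rho, t(res$rho))
  expect_equal(unname(diag(res$rho)), rep(1, 3))
  # BH never rejects more than uncorrected testing
  expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
})

test_that("FDR correction suppresses false positives among independent features", {
  set.seed(2)
  n_sig_raw <- 0; n_sig_adj <- 0
  for (i in 1:50) {
    X <- matrix(rnorm(49 * 10), 49, 10)
    res <- spearman_fdr(X)
    up <- upper.tri(res$p)
    n_sig_raw <- n_sig_raw + sum(res$p[up] < 0.05)
    n_sig_adj <- n_sig_adj + sum(res$p_adj[up] < 0.05)
  }
  expect_lt(abs(n_sig_raw / (50 * 45) - 0.05), 0.02)
  expect_lt(n_sig_adj / (50 * 45), 0.005)
})

test_that("AUC equals brute-force pairwise concordance", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    s <- sample(seq_len(n %/% 2), n, replace = TRUE) + rnorm(n, 0, 1e-9)
    brute <- mean(outer(s[y], s[!y], function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(s, y), brute, tolerance = 1e-12)
  }
})

test_that("logistic omnibus handles perfect, null, and intercept-only cases", {
  set.seed(4)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  # a perfectly predictive feature: AUC = 1 (with separation fallback)
  X <- data.frame(f = y + rnorm(n, 0, 0.01), g = rnorm(n))
  fit <- logistic_omnibus(X, y)
  expect_equal(fit$auc, 1)
  # pure noise: AUC above chance in-sample but chi-square not extreme
  Xn <- data.frame(a = rnorm(n), b = rnorm(n))
  fitn <- logistic_omnibus(Xn, y)
  expect_gte(fitn$auc, 0.5)
  expect_gt(fitn$p, 0.001)
})

test_that("linear omnibus gives exact fits and standardized betas", {
  set.seed(5)
  n <- 30
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 * X$a - X$b
  fit <- suppressWarnings(linear_omnibus(X, y))  # "essentially perfect fit"
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # betas are invariant to affine rescaling of raw predictors
  X2 <- data.frame(a = 100 * X$a + 7, b = 0.01 * X$b - 3)
  y2 <- y + rnorm(n)
  f1 <- linear_omnibus(X, y2); f2 <- linear_omnibus(X2, y2)
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-9)
})

test_that("dominance ranks an outcome-identical feature first and noise near zero", {
  set.seed(6)
  n <- 49
  X <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  y <- X$signal + rnorm(n, 0, 0.2)
  dom <- dominance(X, y, family = "linear")
  expect_equal(dom$table$measure[1], "signal")
  noise_rows <- dom$table[dom$table$measure != "signal", ]
  expect_lt(max(abs(noise_rows$delta_index)), 0.15)
  # logistic family: duplicate-noise feature contributes ~ nothing on average
  deltas <- replicate(20, {
    Xl <- data.frame(matrix(rnorm(n * 5), n), dup = 0)
    Xl$dup <- Xl$X1 + rnorm(n, 0, 1e-6)
    yl <- rbinom(n, 1, 0.5)
    d <- dominance(Xl, yl, family = "logistic")
    d$table$delta_index[d$table$measure == "dup"]
  })
  expect_lt(abs(mean(deltas)), 0.02)
})

test_that("noise-only linear omnibus R-squared matches its k/(n-1) expectation", {
  set.seed(7)
  r2 <- replicate(200, {
    X <- matrix(rnorm(49 * 10), 49, 10)
    linear_omnibus(X, rnorm(49))$r_squared
  })
  expect_equal(mean(r2), 10 / 48, tolerance = 0.05)
})
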