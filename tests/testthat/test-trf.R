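test_that("lag matrix follows the shift and layout contracts", {
  S <- matrix(rnorm(40), ncol = 1)
  # k = 1, lag 0 -> identity
  X <- build_lag_matrix(S, 0, 100)
  expect_equal(X[, 1], S[, 1], ignore_attr = TRUE)
  # impulse at sample 10, +30 ms lag at 100 Hz = 3 samples
  imp <- matrix(0, 40, 1); imp[10] <- 1
  Xi <- build_lag_matrix(imp, 30, 100)
  expect_equal(which(Xi[, 1] != 0), 13)
  # negative lag shifts the other way
  Xn <- build_lag_matrix(imp, -30, 100)
  expect_equal(which(Xn[, 1] != 0), 7)
  # k = 2, L = 5 -> 10 columns, regressor-major
  S2 <- cbind(rnorm(40), rnorm(40))
  lags <- lag_grid(c(0, 40), 100)
  X2 <- build_lag_matrix(S2, lags, 100)
  expect_equal(ncol(X2), 10)
  expect_equal(X2[, 1], S2[, 1], ignore_attr = TRUE)  # regressor 1, lag 0
  expect_equal(X2[, 6], S2[, 2], ignore_attr = TRUE)  # regressor 2, lag 0
  expect_error(build_lag_matrix(S, numeric(0), 100), "empty lag")
})

test_that("ridge solution matches the direct normal-equation oracle", {
  set.seed(42)
  # small instances solved two ways: package path vs direct dense solve
  for (p in c(5, 20)) {
    X <- matrix(rnorm(200 * p), 200, p)
    Y <- matrix(rnorm(200 * 2), 200, 2)
    XtX <- crossprod(X); XtY <- crossprod(X, Y)
    for (lam in c(0, 0.1, 10)) {
      W_pkg <- vrattn:::.ridge_solve(XtX, XtY, lam)
      A <- XtX + diag(lam * mean(diag(XtX)), p)
      W_direct <- qr.solve(A, XtY)
      expect_lt(max(abs(W_pkg - W_direct)), 1e-8)
    }
  }
})

test_that("ridge shrinkage is monotone in lambda", {
  set.seed(5)
  sim <- simulate_trf_trials(4, 10, 50, c(0, 0.5, 1, 0.5), 3, noise_sd = 1)
  norms <- vapply(c(0.01, 1, 100, 1e4), function(lam) {
    f <- fit_encoder(sim$S, sim$R, 50, lags_ms = c(0, 100), lambda = lam)
    sqrt(sum(f$model$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("encoder recovers a known kernel from noiseless data", {
  set.seed(1)
  fs <- 50
  kt <- seq(0, 0.3, by = 1 / fs)
  kernel <- -exp(-(kt - 0.1)^2 / (2 * 0.03^2)) + 0.7 * exp(-(kt - 0.2)^2 / (2 * 0.04^2))
  sim <- simulate_trf_trials(5, 12, fs, kernel, 4, noise_sd = 0)
  fit <- fit_encoder(sim$S, sim$R, fs, lags_ms = c(-100, 400), lambda = 1e-4)
  expect_gt(mean(fit$predictive_power), 0.99)
  lag_sel <- fit$model$lags_ms >= 0 & fit$model$lags_ms <= 300
  k_est <- fit$model$weights[1, lag_sel, 1]
  expect_gt(cor(k_est, kernel[seq_len(sum(lag_sel))]), 0.99)
})

test_that("encoder predictive power is near zero for unrelated noise", {
  set.seed(2)
  fs <- 50
  S <- lapply(1:8, function(i) matrix(rnorm(400), ncol = 1))
  R <- lapply(1:8, function(i) scale(matrix(rnorm(400 * 3), ncol = 3)))
  fit <- fit_encoder(S, R, fs, lags_ms = c(-100, 400), lambda = 1)
  expect_lt(abs(mean(fit$predictive_power)), 0.05)
  # LOO contract: one fold per trial
  expect_equal(fit$n_trials, 8)
})

test_that("decoder reconstructs a stimulus copied into one channel", {
  set.seed(3)
  fs <- 50
  S <- lapply(1:4, function(i) {
    s <- generate_envelope_regressor(10, fs)$data[, 1]
    matrix(as.numeric(scale(s)), ncol = 1)
  })
  R <- lapply(S, function(s) cbind(s[, 1], rnorm(nrow(s))))
  fit <- fit_decoder(R, S, fs, lambda = 1e-4)
  expect_gt(fit$reconstruction_r, 0.99)
})

test_that("decoder reconstruction is near zero for unrelated EEG", {
  set.seed(4)
  fs <- 50
  S <- lapply(1:8, function(i) matrix(rnorm(500), ncol = 1))
  R <- lapply(1:8, function(i) scale(matrix(rnorm(500 * 4), ncol = 4)))
  fit <- fit_decoder(R, S, fs, lambda = 10)
  expect_lt(abs(fit$reconstruction_r), 0.1)
})

test_that("multivariate encoding separates regressors: a zero-kernel regressor stays near zero", {
  set.seed(6)
  fs <- 50
  kernel <- c(0, 0.6, 1, 0.6, 0.2)
  n_tr <- 5
  S <- list(); R <- list()
  for (i in seq_len(n_tr)) {
    s1 <- as.numeric(scale(generate_envelope_regressor(12, fs)$data[, 1]))
    s2 <- as.numeric(scale(generate_envelope_regressor(12, fs)$data[, 1]))
    drive <- stats::convolve(s1, rev(kernel), type = "open")[seq_along(s1)]
    S[[i]] <- cbind(s1, s2)
    R[[i]] <- scale(matrix(drive, ncol = 1))
  }
  fit <- fit_encoder(S, R, fs, lags_ms = c(0, 200), lambda = 1e-4)
  w1 <- sqrt(sum(fit$model$weights[1, , ]^2))
  w2 <- sqrt(sum(fit$model$weights[2, , ]^2))
  expect_gt(w1 / w2, 20)
})

test_that("permutation arithmetic and derangements behave as specified", {
  set.seed(8)
  for (i in 1:20) {
    p <- vrattn:::.derangement(7)
    expect_false(any(p == 1:7))
  }
  fs <- 50
  kernel <- c(0.2, 1, 0.4)
  sim <- simulate_trf_trials(6, 8, fs, kernel, 3, noise_sd = 0.5)
  pt <- permutation_test(sim$S, sim$R, fs, lambda = 1, type = "encoding",
                         n_perm = 50)
  # coupled data: observed beats the null
  expect_lt(pt$p_value, 0.05)
  # empirical p can never be smaller than 1/(n_perm + 1)
  expect_gte(pt$p_value, 1 / 51)
  expect_length(pt$null_values, 50)
  expect_warning(
    permutation_test(sim$S, sim$R, fs, lambda = 1, type = "encoding",
                     n_perm = 10),
    "unstable")
  # decoding direction: coupled data beat the shuffled-pairing null too
  set.seed(12)
  S <- lapply(1:5, function(i) {
    matrix(as.numeric(scale(generate_envelope_regressor(8, fs)$data[, 1])),
           ncol = 1)
  })
  R <- lapply(S, function(s) {
    drive <- stats::convolve(s[, 1], rev(c(0.2, 1, 0.4)),
                             type = "open")[seq_len(nrow(s))]
    scale(cbind(drive, drive + rnorm(nrow(s))))
  })
  ptd <- permutation_test(S, R, fs, lambda = 1, type = "decoding",
                          n_perm = 50)
  expect_lt(ptd$p_value, 0.05)
  expect_true(ptd$significant)
})

test_that("group-level lambda selection reduces to the subject optimum", {
  set.seed(9)
  sim <- simulate_trf_trials(4, 8, 50, c(0.2, 1, 0.4), 3, noise_sd = 1)
  fit <- fit_encoder(sim$S, sim$R, 50, lags_ms = c(0, 100),
                     lambda_grid = 10^seq(-2, 4))
  expect_equal(select_lambda_group(list(fit)), fit$lambda)
  # identical subjects -> same choice as any single one
  expect_equal(select_lambda_group(list(fit, fit, fit)), fit$lambda)
})

test_that("TRF component extraction takes signed extrema in their windows", {
  fs <- 100
  lags <- lag_grid(c(-150, 450), fs)
  k <- -2 * exp(-(lags - 100)^2 / (2 * 15^2)) +
    1.5 * exp(-(lags - 220)^2 / (2 * 15^2))
  W <- array(0, dim = c(1, length(lags), 2),
             dimnames = list("teacher", NULL, c("FCz", "Cz")))
  W[1, , 1] <- k; W[1, , 2] <- k
  model <- structure(list(weights = W, lags_ms = lags, lambda = 1, fs = fs),
                     class = "vr_trf")
  comp <- extract_trf_components(model, c("FCz", "Cz"))
  expect_equal(unname(comp["TRF_N1"]), -2, tolerance = 0.01)
  expect_equal(unname(comp["TRF_P2"]), 1.5, tolerance = 0.01)
  # equivariance under global scaling
  model$weights <- 3 * W
  comp3 <- extract_trf_components(model, c("FCz", "Cz"))
  expect_equal(unname(comp3), unname(3 * comp), tolerance = 1e-10)
})
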