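test_that("ERP of identical epochs equals one epoch and averaging cuts noise", {
  set.seed(1)
  fs <- 100
  kernel <- -1.5 * exp(-((0:60) / fs - 0.35)^2 / (2 * 0.05^2))
  mk_epochs <- function(n_ep, noise_sd) {
    ep <- array(0, dim = c(n_ep, 61, 2))
    for (i in seq_len(n_ep)) {
      for (j in 1:2) ep[i, , j] <- kernel + rnorm(61, 0, noise_sd)
    }
    list(epochs = ep, times = seq(-0.1, 0.5, by = 1 / fs),
         kept = rep(TRUE, n_ep), n_dropped = 0,
         channel_names = c("Cz", "Pz"), fs = fs)
  }
  ep1 <- mk_epochs(5, 0)
  erp <- compute_erp(ep1, lowpass = NULL, baseline_window = NULL)
  expect_equal(erp$data[, 1], kernel, ignore_attr = TRUE, tolerance = 1e-12)
  # RMSE shrinks roughly as 1/sqrt(n): 52 vs 13 epochs -> factor ~2
  rmse <- function(n_ep) {
    errs <- replicate(30, {
      e <- compute_erp(mk_epochs(n_ep, 1), lowpass = NULL,
                       baseline_window = NULL)
      sqrt(mean((e$data[, 1] - kernel)^2))
    })
    mean(errs)
  }
  expect_equal(rmse(13) / rmse(52), 2, tolerance = 0.35)
  expect_error(compute_erp(list(epochs = array(0, c(0, 61, 2)), fs = fs)),
               "no epochs")
})

test_that("component amplitudes take windowed extrema and scale with the data", {
  fs <- 200
  times <- seq(-0.1, 0.5, by = 1 / fs)
  wave <- 2.2 * exp(-(times - 0.35)^2 / (2 * 0.02^2))
  erp <- structure(list(data = cbind(wave, wave), times = times,
                        n_epochs = 10, fs = fs,
                        channel_names = c("Cz", "Pz")), class = "vr_erp")
  expect_equal(component_amplitude(erp, "P3"), 2.2, tolerance = 1e-6)
  expect_lt(abs(component_amplitude(erp, "N1")), 0.05)
  erp$data <- erp$data * 4
  expect_equal(component_amplitude(erp, "P3"), 8.8, tolerance = 1e-6)
})

test_that("adjacency graph respects the distance threshold", {
  mont <- montage(c("a", "b", "c"),
                  rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)))
  A <- build_adjacency(mont, neighbor_distance = 0.1)
  expect_true(A["a", "b"])   # coincident channels are adjacent
  expect_false(A["a", "c"])
  A0 <- build_adjacency(mont, neighbor_distance = 0)
  expect_false(any(A0))
  # the full 64-channel template yields a connected graph at the default
  # median-degree-6 threshold
  m64 <- default_montage(64)
  A64 <- build_adjacency(m64)
  reach <- rep(FALSE, 64); reach[1] <- TRUE
  for (i in 1:64) reach <- reach | (A64 %*% reach > 0)[, 1]
  expect_true(all(reach))
  expect_equal(median(rowSums(A64)), 6, tolerance = 2)
})

test_that("cluster permutation finds a planted spatio-temporal difference", {
  set.seed(2)
  mont <- default_montage(16)
  adj <- build_adjacency(mont)
  n_sub <- 10; n_t <- 61
  times <- seq(-0.1, 0.5, length.out = n_t)
  planted_t <- times >= 0.1 & times <= 0.2
  planted_c <- 1:10
  mk <- function(n, effect) {
    arr <- array(rnorm(n * n_t * 16, 0, 1), dim = c(n, n_t, 16))
    if (effect != 0) {
      for (ch in planted_c) arr[, planted_t, ch] <- arr[, planted_t, ch] + effect
    }
    arr
  }
  A <- mk(n_sub, 1.8); B <- mk(n_sub, 0)
  res <- cluster_permutation(A, B, adj, "unpaired", cluster_alpha = 0.05,
                             n_perm = 300, times = times)
  expect_gt(nrow(res$clusters), 0)
  top <- res$clusters[1, ]
  expect_lt(top$p_value, 0.05)
  expect_gt(top$sign, 0)
  # the winning cluster overlaps the planted window
  expect_lt(top$t_start, 0.2)
  expect_gt(top$t_end, 0.1)
})

test_that("cluster test is invariant to channel reordering", {
  set.seed(3)
  mont <- default_montage(8)
  adj <- build_adjacency(mont)
  A <- array(rnorm(6 * 20 * 8), dim = c(6, 20, 8))
  B <- array(rnorm(6 * 20 * 8), dim = c(6, 20, 8))
  A[, 8:12, 1:4] <- A[, 8:12, 1:4] + 2
  perm <- sample(8)
  res1 <- cluster_permutation(A, B, adj, "unpaired", n_perm = 150)
  set.seed(99)
  res2 <- cluster_permutation(A[, , perm], B[, , perm], adj[perm, perm],
                              "unpaired", n_perm = 150)
  expect_equal(sort(abs(res1$clusters$mass)), sort(abs(res2$clusters$mass)),
               tolerance = 1e-10)
})

test_that("mixed 2x2 ANOVA matches the closed-form sums-of-squares oracle", {
  # balanced oracle: hand-computed decomposition on a constructed table
  set.seed(4)
  n_per <- 6
  subj <- factor(rep(1:(2 * n_per), each = 2))
  grp <- rep(c("ADHD", "CONTROL"), each = 2 * n_per)
  evt <- rep(c("ARTIFICIAL", "HUMAN"), times = 2 * n_per)
  val <- rnorm(4 * n_per) + ifelse(grp == "ADHD", 1, 0) +
    ifelse(evt == "HUMAN", 0.5, 0)
  df <- data.frame(subject = subj, group = grp, event_type = evt, value = val)
  res <- mixed_anova_2x2(df)

  # oracle: direct SS decomposition for the balanced mixed design
  Y <- matrix(val, ncol = 2, byrow = TRUE)  # subjects x event types
  g <- rep(c("ADHD", "CONTROL"), each = n_per)
  gm <- mean(Y)
  subj_m <- rowMeans(Y)
  grp_m <- tapply(subj_m, g, mean)
  ss_group <- 2 * sum(n_per * (grp_m - gm)^2)
  ss_subj <- 2 * sum((subj_m - grp_m[g])^2)
  evt_m <- colMeans(Y)
  ss_evt <- 2 * n_per * sum((evt_m - gm)^2)
  cell_m <- rbind(tapply(Y[, 1], g, mean), tapply(Y[, 2], g, mean))
  ss_int <- n_per * sum((t(cell_m) - outer(grp_m, evt_m, `+`) + gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err_w <- ss_tot - ss_group - ss_subj - ss_evt - ss_int
  F_group <- (ss_group / 1) / (ss_subj / (2 * n_per - 2))
  F_evt <- (ss_evt / 1) / (ss_err_w / (2 * n_per - 2))
  F_int <- (ss_int / 1) / (ss_err_w / (2 * n_per - 2))
  expect_equal(res["Group", "F"], F_group, tolerance = 1e-8)
  expect_equal(res["EventType", "F"], F_evt, tolerance = 1e-8)
  expect_equal(res["Interaction", "F"], F_int, tolerance = 1e-8)
  expect_equal(res["Group", "eta_sq_partial"],
               ss_group / (ss_group + ss_subj), tolerance = 1e-8)

  # all-equal data: zero F everywhere
  df0 <- df; df0$value <- 1
  res0 <- suppressWarnings(mixed_anova_2x2(df0))
  expect_equal(res0$F, c(0, 0, 0), ignore_attr = TRUE)
})

test_that("group-label permutation gives a uniform Group F null", {
  set.seed(5)
  n_per <- 8
  ps <- replicate(150, {
    df <- data.frame(
      subject = factor(rep(1:(2 * n_per), each = 2)),
      group = rep(sample(rep(c("A", "B"), n_per)), each = 2),
      event_type = rep(c("x", "y"), times = 2 * n_per),
      value = rnorm(4 * n_per))
    levels(df$group) <- c("ADHD", "CONTROL")
    mixed_anova_2x2(df)["Group", "p"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
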