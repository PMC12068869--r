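#' Build a time-lagged design matrix
#'
#' Expands a stimulus matrix into lagged copies for TRF estimation. Column
#' (j, l) holds regressor j delayed by lag l: `X[t, (j,l)] = S[t - l, j]`,
#' zero-filled outside the segment. Positive lags mean the stimulus precedes
#' the response (encoding); negative lags let future response samples inform
#' the reconstruction (decoding). Columns are ordered regressor-major.
#'
#' @param S samples x k numeric matrix.
#' @param lags_ms numeric vector of lags in milliseconds.
#' @param fs sampling rate in Hz.
#' @return samples x (k * L) matrix; attribute `lags_ms` records the lag of
#'   each column block.
#' @export
build_lag_matrix <- function(S, lags_ms, fs) {
  S <- as.matrix(S)
  if (length(lags_ms) == 0) stop("empty lag list")
  lag_samp <- round(lags_ms * fs / 1000)
  n <- nrow(S)
  k <- ncol(S)
  L <- length(lag_samp)
  X <- matrix(0, n, k * L)
  for (j in seq_len(k)) {
    for (l in seq_len(L)) {
      d <- lag_samp[l]
      col <- (j - 1) * L + l
      if (d >= 0) {
        if (d < n) X[(d + 1):n, col] <- S[1:(n - d), j]
      } else {
        if (-d < n) X[1:(n + d), col] <- S[(1 - d):n, j]
      }
    }
  }
  attr(X, "lags_ms") <- lags_ms
  attr(X, "n_regressors") <- k
  X
}

#' Lag grid in milliseconds for a window
#' @param lag_range_ms c(min, max) in ms.
#' @param fs sampling rate in Hz.
#' @return vector of lags in ms aligned to the sample grid.
#' @export
lag_grid <- function(lag_range_ms, fs) {
  seq(round(lag_range_ms[1] * fs / 1000), round(lag_range_ms[2] * fs / 1000)) *
    1000 / fs
}

# Ridge solve of (XtX + lambda * mean(diag(XtX)) * I) W = XtY.
# lambda scales the mean diagonal of the design autocovariance, making the
# printed grid 1e-2..1e4 scale-free. Falls back to a pseudo-inverse when the
# system is singular at lambda = 0.
.ridge_solve <- function(XtX, XtY, lambda) {
  p <- nrow(XtX)
  A <- XtX + diag(lambda * mean(diag(XtX)), p)
  W <- tryCatch({
    R <- chol(A)
    backsolve(R, forwardsolve(t(R), XtY))
  }, error = function(e) NULL)
  if (is.null(W)) {
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-12
    W <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% XtY) / sv$d[keep])
  }
  W
}

.cor_cols <- function(A, B) {
  # column-wise Pearson correlation of two matrices with matching dims
  A <- sweep(A, 2, colMeans(A), "-")
  B <- sweep(B, 2, colMeans(B), "-")
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  r <- num / den
  r[!is.finite(r)] <- 0
  r
}

# Shared leave-one-trial-out ridge CV on precomputed designs.
# X_list: per-trial lagged designs; Y_list: per-trial targets (matrices).
# pairing: index vector pi, trial i's design is paired with Y_list[[pi[i]]].
# Returns folds x channels matrix of prediction correlations.
.ridge_cv_r <- function(X_list, Y_list, lambda, XtX_list, XtY_pair) {
  n <- length(X_list)
  XtX_tot <- Reduce(`+`, XtX_list)
  XtY_tot <- Reduce(`+`, XtY_pair)
  C <- ncol(Y_list[[1]])
  r <- matrix(0, n, C)
  for (i in seq_len(n)) {
    W <- .ridge_solve(XtX_tot - XtX_list[[i]], XtY_tot - XtY_pair[[i]], lambda)
    pred <- X_list[[i]] %*% W
    r[i, ] <- .cor_cols(pred, Y_list[[i]])
  }
  r
}

# Grid variant: one eigendecomposition of the training covariance per fold,
# reused across the whole lambda grid. Returns lambdas x channels CV-averaged
# correlations.
.ridge_cv_grid <- function(X_list, Y_list, lambdas, XtX_list, XtY_list) {
  n <- length(X_list)
  if (length(lambdas) == 1) {
    return(matrix(colMeans(.ridge_cv_r(X_list, Y_list, lambdas, XtX_list,
                                       XtY_list)), 1))
  }
  XtX_tot <- Reduce(`+`, XtX_list)
  XtY_tot <- Reduce(`+`, XtY_list)
  C <- ncol(Y_list[[1]])
  acc <- matrix(0, length(lambdas), C)
  for (i in seq_len(n)) {
    XtX_tr <- XtX_tot - XtX_list[[i]]
    XtY_tr <- XtY_tot - XtY_list[[i]]
    eg <- eigen(XtX_tr, symmetric = TRUE)
    proj <- crossprod(eg$vectors, XtY_tr)
    md <- mean(diag(XtX_tr))
    for (gi in seq_along(lambdas)) {
      W <- eg$vectors %*% (proj / (pmax(eg$values, 0) + lambdas[gi] * md))
      pred <- X_list[[i]] %*% W
      acc[gi, ] <- acc[gi, ] + .cor_cols(pred, Y_list[[i]])
    }
  }
  acc / n
}

#' Fit a TRF encoding model (stimulus to EEG)
#'
#' Estimates per-channel temporal response functions by ridge regression with
#' leave-one-trial-out cross-validation. Covariances are accumulated across
#' training trials (sum of per-trial S'S and S'R) so no spurious cross-trial
#' lags enter the model. The ridge parameter multiplies the mean diagonal of
#' the design autocovariance. Predictive power is the Pearson correlation
#' between predicted and recorded EEG on the left-out trial, per channel,
#' averaged across folds.
#'
#' @param S_trials list of per-trial stimulus matrices (samples x k, z-scored).
#' @param R_trials list of per-trial EEG matrices (samples x channels,
#'   z-scored), same lengths as `S_trials`.
#' @param fs sampling rate in Hz.
#' @param lags_ms lag window in ms (default c(-150, 450)).
#' @param lambda_grid ridge parameters to evaluate (default 10^(-2..4)).
#' @param lambda if non-NULL, skip grid search and use this value (used after
#'   group-level selection).
#' @param channel_names optional channel labels.
#' @return A `vr_encoding` list: `predictive_power` (per channel, at the
#'   chosen lambda), `lambda`, `r_grid` (lambda x channel matrix of
#'   CV-averaged correlations), `model` (a `vr_trf` with `weights`
#'   regressors x lags x channels, `lags_ms`, `lambda`, `fs`), `n_trials`.
#' @export
fit_encoder <- function(S_trials, R_trials, fs, lags_ms = c(-150, 450),
                        lambda_grid = 10^seq(-2, 4), lambda = NULL,
                        channel_names = NULL) {
  stopifnot(length(S_trials) == length(R_trials))
  if (length(S_trials) < 3) stop("need at least 3 trials for LOO estimation")
  lags <- lag_grid(lags_ms, fs)
  X_list <- lapply(S_trials, build_lag_matrix, lags_ms = lags, fs = fs)
  R_trials <- lapply(R_trials, as.matrix)
  XtX_list <- lapply(X_list, crossprod)
  XtY_list <- Map(crossprod, X_list, R_trials)
  grid <- if (is.null(lambda)) lambda_grid else lambda
  r_grid <- .ridge_cv_grid(X_list, R_trials, grid, XtX_list, XtY_list)
  best <- which.max(rowMeans(r_grid))
  lam <- grid[best]
  W <- .ridge_solve(Reduce(`+`, XtX_list), Reduce(`+`, XtY_list), lam)
  k <- ncol(S_trials[[1]])
  C <- ncol(R_trials[[1]])
  if (is.null(channel_names)) channel_names <- colnames(R_trials[[1]])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  weights <- array(0, dim = c(k, length(lags), C),
                   dimnames = list(colnames(S_trials[[1]]), NULL, channel_names))
  for (j in seq_len(k)) {
    weights[j, , ] <- W[((j - 1) * length(lags) + 1):(j * length(lags)), ]
  }
  pp <- r_grid[best, ]
  names(pp) <- channel_names
  structure(list(
    predictive_power = pp,
    lambda = lam,
    lambda_grid = grid,
    r_grid = r_grid,
    model = structure(list(weights = weights, lags_ms = lags, lambda = lam,
                           fs = fs, intercept = rep(0, C)), class = "vr_trf"),
    n_trials = length(S_trials)
  ), class = "vr_encoding")
}

#' Fit a TRF decoding model (EEG to stimulus)
#'
#' Reconstructs the teacher-speech envelope from all EEG channels jointly,
#' with lags from -400 to 0 ms (the response follows the stimulus; no
#' post-zero baseline lags are used since they cannot carry stimulus
#' information). Reconstruction quality is the CV-averaged Pearson
#' correlation between the reconstructed and actual envelope of the left-out
#' trial.
#'
#' @param R_trials list of per-trial EEG matrices (samples x channels).
#' @param s_trials list of per-trial target envelopes (vectors or 1-column
#'   matrices).
#' @param fs sampling rate in Hz.
#' @param lags_ms lag window in ms (default c(-400, 0)).
#' @param lambda_grid ridge parameters (default 10^(-2..4)).
#' @param lambda fixed ridge parameter (skips the grid search).
#' @return A `vr_decoding` list: `reconstruction_r`, `lambda`, `r_grid`
#'   (per-lambda CV-averaged r), `weights` (channels x lags matrix), `fs`.
#' @export
fit_decoder <- function(R_trials, s_trials, fs, lags_ms = c(-400, 0),
                        lambda_grid = 10^seq(-2, 4), lambda = NULL) {
  stopifnot(length(R_trials) == length(s_trials))
  if (length(R_trials) < 3) stop("need at least 3 trials for LOO estimation")
  lags <- lag_grid(lags_ms, fs)
  X_list <- lapply(R_trials, build_lag_matrix, lags_ms = lags, fs = fs)
  s_list <- lapply(s_trials, function(s) as.matrix(s)[, 1, drop = FALSE])
  XtX_list <- lapply(X_list, crossprod)
  Xts_list <- Map(crossprod, X_list, s_list)
  grid <- if (is.null(lambda)) lambda_grid else lambda
  r_grid <- as.numeric(.ridge_cv_grid(X_list, s_list, grid, XtX_list,
                                      Xts_list))
  best <- which.max(r_grid)
  lam <- grid[best]
  W <- .ridge_solve(Reduce(`+`, XtX_list), Reduce(`+`, Xts_list), lam)
  Cn <- ncol(R_trials[[1]])
  weights <- matrix(W[, 1], nrow = Cn, byrow = TRUE)
  structure(list(
    reconstruction_r = r_grid[best],
    lambda = lam,
    lambda_grid = grid,
    r_grid = r_grid,
    weights = weights,
    lags_ms = lags,
    fs = fs,
    n_trials = length(R_trials)
  ), class = "vr_decoding")
}

.derangement <- function(n, rng_ok = TRUE) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Shuffled-pairing permutation test for TRF models
#'
#' Builds a null distribution by re-estimating the model `n_perm` times with
#' the stimulus of each trial paired with the response of a different trial
#' (a derangement, so no trial keeps its own stimulus). For encoding models
#' the statistic is the maximum CV-averaged predictive power across channels
#' (which also corrects across electrodes); for decoding it is the
#' CV-averaged reconstruction correlation. The observed model is significant
#' when its statistic falls in the top 5% of the null.
#'
#' @param S_trials list of per-trial stimulus matrices (encoding) or target
#'   envelopes (decoding).
#' @param R_trials list of per-trial EEG matrices.
#' @param fs sampling rate in Hz.
#' @param lambda ridge parameter (use the group-selected value).
#' @param type "encoding" or "decoding".
#' @param lags_ms lag window (defaults per type).
#' @param n_perm number of permutations (default 100).
#' @param alpha significance level on the null distribution (default 0.05).
#' @return A `vr_permnull` list: `observed` (per-channel predictive power or
#'   scalar reconstruction r), `statistic` (observed max / scalar),
#'   `null_values`, `threshold` (100(1-alpha) percentile), `p_value`
#'   (empirical, min 1/(n_perm+1)), `significant` (per-channel mask for
#'   encoding, scalar for decoding).
#' @export
permutation_test <- function(S_trials, R_trials, fs, lambda,
                             type = c("encoding", "decoding"),
                             lags_ms = NULL, n_perm = 100, alpha = 0.05) {
  type <- match.arg(type)
  n <- length(R_trials)
  if (n < 3) stop("need at least 3 trials")
  if (n_perm < 20) warning("fewer than 20 permutations: unstable percentile")
  if (is.null(lags_ms)) {
    lags_ms <- if (type == "encoding") c(-150, 450) else c(-400, 0)
  }
  lags <- lag_grid(lags_ms, fs)
  if (type == "encoding") {
    X_list <- lapply(S_trials, build_lag_matrix, lags_ms = lags, fs = fs)
    Y_list <- lapply(R_trials, as.matrix)
  } else {
    X_list <- lapply(R_trials, build_lag_matrix, lags_ms = lags, fs = fs)
    Y_list <- lapply(S_trials, function(s) as.matrix(s)[, 1, drop = FALSE])
  }
  XtX_list <- lapply(X_list, crossprod)
  # all pairwise cross-products X_i' Y_j, so each permutation is a cheap sum
  cross <- vector("list", n)
  for (i in seq_len(n)) {
    cross[[i]] <- lapply(Y_list, function(Y) crossprod(X_list[[i]], Y))
  }
  stat_of <- function(pairing) {
    XtY <- lapply(seq_len(n), function(i) cross[[i]][[pairing[i]]])
    Yp <- Y_list[pairing]
    rf <- .ridge_cv_r(X_list, Yp, lambda, XtX_list, XtY)
    if (type == "encoding") max(colMeans(rf)) else mean(rf)
  }
  identity_pair <- seq_len(n)
  XtY0 <- lapply(seq_len(n), function(i) cross[[i]][[i]])
  rf0 <- .ridge_cv_r(X_list, Y_list, lambda, XtX_list, XtY0)
  observed <- if (type == "encoding") colMeans(rf0) else mean(rf0)
  stat <- if (type == "encoding") max(observed) else observed
  null_values <- vapply(seq_len(n_perm), function(p) stat_of(.derangement(n)),
                        numeric(1))
  threshold <- stats::quantile(null_values, 1 - alpha, names = FALSE)
  p_value <- (1 + sum(null_values >= stat)) / (n_perm + 1)
  significant <- if (type == "encoding") observed > threshold else stat > threshold
  structure(list(observed = observed, statistic = stat,
                 null_values = null_values, threshold = threshold,
                 p_value = p_value, significant = significant,
                 n_perm = n_perm, type = type),
            class = "vr_permnull")
}

#' Group-level ridge parameter selection
#'
#' Chooses the single ridge parameter maximizing the grand-mean predictive
#' power over subjects and channels, so the same lambda (and hence comparable
#' TRF models) is applied to every subject.
#'
#' @param encoding_results list of `vr_encoding` (or `vr_decoding`) objects
#'   fitted on a shared `lambda_grid`.
#' @return the selected lambda.
#' @export
select_lambda_group <- function(encoding_results) {
  grids <- lapply(encoding_results, function(e) {
    if (is.matrix(e$r_grid)) rowMeans(e$r_grid) else e$r_grid
  })
  lam_grid <- encoding_results[[1]]$lambda_grid
  stopifnot(all(vapply(grids, length, 1L) == length(lam_grid)))
  grand <- Reduce(`+`, grids) / length(grids)
  lam_grid[which.max(grand)]
}

#' Extract TRF component amplitudes
#'
#' Averages the teacher-envelope kernel over an electrode cluster and takes
#' the signed extremum within each component window: the minimum for the
#' negative N1-like deflection (default 75-155 ms) and the maximum for the
#' positive P2-like deflection (default 190-260 ms).
#'
#' @param model a `vr_trf` from [fit_encoder()].
#' @param channels electrode names (or indices) of the extraction cluster.
#' @param windows named list of component windows in ms; names ending in a
#'   digit are treated as N-components (minimum) when they start with "N",
#'   otherwise the maximum is taken.
#' @param regressor which regressor's kernel to use (default 1, the teacher).
#' @return named numeric vector of component amplitudes (e.g. TRF_N1, TRF_P2).
#' @export
extract_trf_components <- function(model, channels,
                                   windows = list(N1 = c(75, 155),
                                                  P2 = c(190, 260)),
                                   regressor = 1) {
  W <- model$weights[regressor, , , drop = TRUE]
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  chan_names <- dimnames(model$weights)[[3]]
  idx <- if (is.character(channels)) match(channels, chan_names) else channels
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("no cluster channel present in the model")
  kern <- rowMeans(W[, idx, drop = FALSE])
  out <- vapply(names(windows), function(nm) {
    sel <- model$lags_ms >= windows[[nm]][1] & model$lags_ms <= windows[[nm]][2]
    if (!any(sel)) return(NA_real_)
    if (startsWith(nm, "N")) min(kern[sel]) else max(kern[sel])
  }, numeric(1))
  names(out) <- paste0("TRF_", names(windows))
  out
}
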