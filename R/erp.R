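#' Compute an event-related potential
#'
#' Low-pass filters each epoch (default 12 Hz, as is common for ERP display
#' and peak extraction), re-applies the pre-stimulus baseline correction
#' after filtering, and averages across epochs.
#'
#' @param ep epoch list from [epoch_ts()].
#' @param lowpass low-pass cutoff in Hz, or NULL to skip filtering.
#' @param baseline_window baseline window in seconds relative to onset
#'   (default c(-0.1, 0)).
#' @return A `vr_erp`: list with `data` (samples x channels average),
#'   `times`, `n_epochs`, `fs`, `channel_names`.
#' @export
compute_erp <- function(ep, lowpass = 12, baseline_window = c(-0.1, 0)) {
  n_ep <- dim(ep$epochs)[1]
  if (is.null(n_ep) || n_ep == 0) stop("no epochs to average")
  n_t <- dim(ep$epochs)[2]
  n_c <- dim(ep$epochs)[3]
  eps <- ep$epochs
  if (!is.null(lowpass)) {
    bf <- signal::butter(4, lowpass / (ep$fs / 2), type = "low")
    for (i in seq_len(n_ep)) {
      for (j in seq_len(n_c)) {
        eps[i, , j] <- signal::filtfilt(bf, eps[i, , j])
      }
    }
  }
  if (!is.null(baseline_window)) {
    bsel <- ep$times >= baseline_window[1] & ep$times <= baseline_window[2]
    for (i in seq_len(n_ep)) {
      bmean <- colMeans(matrix(eps[i, bsel, ], nrow = sum(bsel)))
      eps[i, , ] <- sweep(matrix(eps[i, , ], nrow = n_t), 2, bmean, "-")
    }
  }
  avg <- matrix(0, n_t, n_c)
  for (j in seq_len(n_c)) avg[, j] <- colMeans(matrix(eps[, , j], nrow = n_ep))
  colnames(avg) <- ep$channel_names
  structure(list(data = avg, times = ep$times, n_epochs = n_ep, fs = ep$fs,
                 channel_names = ep$channel_names),
            class = "vr_erp")
}

# Default component extraction windows (ms): N1 and P2 bounds follow the
# visually dominant deflections of the auditory response; the P3 window is a
# configurable default around the late positive peak.
.erp_windows <- list(N1 = c(75, 200), P2 = c(210, 260), P3 = c(300, 400))

#' Extract an ERP component amplitude
#'
#' Averages the ERP over an electrode cluster and takes the signed extremum
#' of the cluster-mean waveform within the component window: minimum for
#' N-components, maximum for P-components.
#'
#' @param erp a `vr_erp`.
#' @param component "N1", "P2" or "P3" (or any name present in `windows`).
#' @param cluster electrode names of the extraction cluster (default: all).
#' @param windows named list of windows in ms (defaults: N1 75-200, P2
#'   210-260, P3 300-400).
#' @return signed amplitude (same units as the data).
#' @export
component_amplitude <- function(erp, component, cluster = NULL,
                                windows = .erp_windows) {
  if (!component %in% names(windows)) stop("unknown component")
  idx <- if (is.null(cluster)) seq_len(ncol(erp$data)) else {
    i <- match(cluster, erp$channel_names)
    i[!is.na(i)]
  }
  if (length(idx) == 0) stop("no cluster channel present in the ERP")
  wave <- rowMeans(erp$data[, idx, drop = FALSE])
  w <- windows[[component]]
  sel <- erp$times * 1000 >= w[1] & erp$times * 1000 <= w[2]
  if (!any(sel)) stop("component window outside the epoch")
  if (startsWith(component, "N")) min(wave[sel]) else max(wave[sel])
}

#' Channel adjacency graph for cluster statistics
#'
#' Two channels are neighbors when their montage distance is below
#' `neighbor_distance`. When no distance is given, the threshold is set from
#' the data so the median channel has about six neighbors (the typical
#' neighborhood size of an EEG cap).
#'
#' @param montage a `vr_montage`.
#' @param neighbor_distance distance threshold, or NULL for the automatic
#'   median-degree-6 choice.
#' @param channels optional subset/order of channels to use.
#' @return symmetric logical adjacency matrix (FALSE diagonal).
#' @export
build_adjacency <- function(montage, neighbor_distance = NULL, channels = NULL) {
  pos <- montage$positions
  if (!is.null(channels)) pos <- pos[channels, , drop = FALSE]
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  if (is.null(neighbor_distance)) {
    if (n <= 7) {
      neighbor_distance <- max(d) + 1  # tiny montages: fully connected
    } else {
      kth <- apply(d, 1, function(r) sort(r)[7])  # 6 neighbors + self
      neighbor_distance <- stats::median(kth) * 1.0001
    }
  }
  A <- d <= neighbor_distance
  if (neighbor_distance <= 0) A[] <- FALSE
  diag(A) <- FALSE
  A
}

# Connected components of suprathreshold (time, channel) points. Points are
# connected along time within a channel and across neighboring channels at
# the same time point. mask/tmap: samples x channels. Returns a list of
# clusters with linear indices and mass.
.find_clusters <- function(mask, tmap, adjacency) {
  n_t <- nrow(mask)
  n_c <- ncol(mask)
  lab <- matrix(0L, n_t, n_c)
  clusters <- list()
  nb_chan <- lapply(seq_len(n_c), function(j) which(adjacency[j, ]))
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    members <- integer(0)
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, p)
      tt <- ((p - 1L) %% n_t) + 1L
      cc <- ((p - 1L) %/% n_t) + 1L
      cand <- integer(0)
      if (tt > 1) cand <- c(cand, p - 1L)
      if (tt < n_t) cand <- c(cand, p + 1L)
      if (length(nb_chan[[cc]]) > 0) {
        cand <- c(cand, (nb_chan[[cc]] - 1L) * n_t + tt)
      }
      for (q in cand) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
    clusters[[cur]] <- list(indices = members, mass = sum(tmap[members]))
  }
  list(labels = lab, clusters = clusters)
}

.tmap_unpaired <- function(A, B) {
  # A: nA x P, B: nB x P matrices of flattened subject data
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- colSums(sweep(A, 2, mA, "-")^2) / (nA - 1)
  vB <- colSums(sweep(B, 2, mB, "-")^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

.tmap_paired <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m, "-")^2) / (n - 1))
  m / (s / sqrt(n))
}

#' Spatio-temporal cluster permutation test
#'
#' Monte-Carlo cluster-based permutation test over all channels and time
#' points. Pointwise t statistics exceeding the two-tailed
#' `cluster_alpha` threshold are joined into clusters by temporal adjacency
#' (within channel) and spatial adjacency (between neighboring channels at
#' the same time point), separately for positive and negative deflections.
#' The cluster mass (sum of t) is compared with the permutation null of the
#' maximum absolute cluster mass, obtained by relabeling groups (unpaired
#' design) or swapping conditions within subject (paired design).
#'
#' @param dataA subjects x samples x channels array (group A, or condition A).
#' @param dataB subjects x samples x channels array (group B / condition B;
#'   paired designs need matching subject order).
#' @param adjacency channel adjacency matrix from [build_adjacency()].
#' @param design "unpaired" (between groups) or "paired" (within subject).
#' @param cluster_alpha pointwise two-tailed p threshold for cluster
#'   formation (0.05 for robust effects; very small values such as 1e-5
#'   split temporally adjacent components into separate clusters).
#' @param n_perm number of permutations (default 1000).
#' @param times optional vector of sample times (seconds) for reporting.
#' @return A `vr_clustertest`: `clusters` data frame (mass, sign, p_value,
#'   time span, n_channels, n_points), `labels` matrix (samples x channels,
#'   0 = background), `tmap`, `null_max`, `threshold_t`, `n_perm`.
#' @export
cluster_permutation <- function(dataA, dataB, adjacency,
                                design = c("unpaired", "paired"),
                                cluster_alpha = 0.05, n_perm = 1000,
                                times = NULL) {
  design <- match.arg(design)
  if (n_perm < 100) warning("fewer than 100 permutations: unstable p-values")
  nA <- dim(dataA)[1]; nB <- dim(dataB)[1]
  if (min(nA, nB) < 2) stop("need at least 2 units per cell")
  n_t <- dim(dataA)[2]; n_c <- dim(dataA)[3]
  P <- n_t * n_c
  A <- matrix(dataA, nA, P)
  B <- matrix(dataB, nB, P)
  if (design == "unpaired") {
    df <- nA + nB - 2
    tvec <- .tmap_unpaired(A, B)
  } else {
    if (nA != nB) stop("paired design needs matching subjects")
    df <- nA - 1
    tvec <- .tmap_paired(A - B)
  }
  tcrit <- stats::qt(1 - cluster_alpha / 2, df)
  tmap <- matrix(tvec, n_t, n_c)
  cl_pos <- .find_clusters(tmap > tcrit, tmap, adjacency)
  cl_neg <- .find_clusters(tmap < -tcrit, -tmap, adjacency)
  obs <- c(lapply(cl_pos$clusters, function(cl) c(cl, sign = 1)),
           lapply(cl_neg$clusters, function(cl) c(cl, sign = -1)))
  perm_stat <- function() {
    if (design == "unpaired") {
      all <- rbind(A, B)
      pick <- sample.int(nA + nB, nA)
      tv <- .tmap_unpaired(all[pick, , drop = FALSE], all[-pick, , drop = FALSE])
    } else {
      flip <- sample(c(1, -1), nA, replace = TRUE)
      tv <- .tmap_paired((A - B) * flip)
    }
    tm <- matrix(tv, n_t, n_c)
    mx <- 0
    cp <- .find_clusters(tm > tcrit, tm, adjacency)
    if (length(cp$clusters) > 0) {
      mx <- max(mx, max(vapply(cp$clusters, `[[`, numeric(1), "mass")))
    }
    cn <- .find_clusters(tm < -tcrit, -tm, adjacency)
    if (length(cn$clusters) > 0) {
      mx <- max(mx, max(vapply(cn$clusters, `[[`, numeric(1), "mass")))
    }
    mx
  }
  null_max <- vapply(seq_len(n_perm), function(i) perm_stat(), numeric(1))
  if (is.null(times)) times <- seq_len(n_t)
  rows <- lapply(obs, function(cl) {
    tt <- ((cl$indices - 1L) %% n_t) + 1L
    cc <- ((cl$indices - 1L) %/% n_t) + 1L
    data.frame(mass = cl$sign * cl$mass, sign = cl$sign,
               p_value = (1 + sum(null_max >= cl$mass)) / (n_perm + 1),
               t_start = min(times[tt]), t_end = max(times[tt]),
               n_channels = length(unique(cc)), n_points = length(cl$indices))
  })
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mass = numeric(0), sign = numeric(0), p_value = numeric(0),
               t_start = numeric(0), t_end = numeric(0),
               n_channels = integer(0), n_points = integer(0))
  if (nrow(clusters) > 0) clusters <- clusters[order(clusters$p_value), ]
  labels <- cl_pos$labels
  labels[cl_neg$labels > 0] <- -cl_neg$labels[cl_neg$labels > 0]
  structure(list(clusters = clusters, labels = labels, tmap = tmap,
                 null_max = null_max, threshold_t = tcrit, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, design = design),
            class = "vr_clustertest")
}

#' 2x2 mixed-design ANOVA
#'
#' Mixed ANOVA with one between-subject factor (Group) and one
#' within-subject factor (EventType), as used for component amplitudes and
#' event-related skin-conductance summaries. Effects are decomposed with
#' `stats::aov` using an Error(subject) stratum; effect sizes are partial
#' eta squared.
#'
#' @param df data frame with columns `subject`, `group` (2 levels, between),
#'   `event_type` (2 levels, within), `value`.
#' @return A `vr_anova`: data frame with rows Group, EventType, Interaction
#'   and columns F, df1, df2, p, eta_sq_partial.
#' @export
mixed_anova_2x2 <- function(df) {
  need <- c("subject", "group", "event_type", "value")
  if (!all(need %in% names(df))) stop("missing columns")
  df$subject <- factor(df$subject)
  df$group <- factor(df$group)
  df$event_type <- factor(df$event_type)
  if (nlevels(df$group) != 2 || nlevels(df$event_type) != 2) {
    stop("both factors need exactly 2 levels")
  }
  counts <- table(df$subject, df$event_type)
  if (any(counts != 1)) stop("each subject needs one value per event type")
  if (stats::var(df$value) < 1e-24) {
    out <- data.frame(F = c(0, 0, 0), df1 = 1,
                      df2 = c(nlevels(df$subject) - 2, nlevels(df$subject) - 2,
                              nlevels(df$subject) - 2),
                      p = 1, eta_sq_partial = 0,
                      row.names = c("Group", "EventType", "Interaction"))
    class(out) <- c("vr_anova", class(out))
    return(out)
  }
  fit <- stats::aov(value ~ group * event_type + Error(subject), data = df)
  sm <- summary(fit)
  # between stratum: group vs subject residuals; within: event_type and
  # interaction vs within residuals
  betw <- sm[["Error: subject"]][[1]]
  with_ <- sm[["Error: Within"]][[1]]
  row_of <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    as.numeric(tab[i, c("Df", "Sum Sq", "F value", "Pr(>F)")])
  }
  g <- row_of(betw, "group")
  g_err <- as.numeric(betw[which(trimws(rownames(betw)) == "Residuals"),
                           c("Df", "Sum Sq")])
  e <- row_of(with_, "event_type")
  i_ <- row_of(with_, "group:event_type")
  w_err <- as.numeric(with_[which(trimws(rownames(with_)) == "Residuals"),
                            c("Df", "Sum Sq")])
  mk <- function(eff, err) {
    data.frame(F = eff[3], df1 = eff[1], df2 = err[1], p = eff[4],
               eta_sq_partial = eff[2] / (eff[2] + err[2]))
  }
  out <- rbind(Group = mk(g, g_err), EventType = mk(e, w_err),
               Interaction = mk(i_, w_err))
  class(out) <- c("vr_anova", class(out))
  out
}
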