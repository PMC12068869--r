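#' Unpaired two-sample t-test with effect size
#'
#' Student's pooled-variance t-test plus Cohen's d computed with the pooled
#' standard deviation (positive when `x` exceeds `y`).
#'
#' @param x,y numeric samples.
#' @return one-row data frame: `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
ttest_unpaired <- function(x, y) {
  if (stats::sd(c(x, y)) == 0) stop("degenerate samples: zero variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohens_d = (mean(x) - mean(y)) / sp,
             mean_diff = mean(x) - mean(y))
}

#' JZS Bayes factor for a two-sample t-test
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor BF10 computed by
#' numerical integration: the marginal likelihood under H1 places a
#' Cauchy(0, `prior_scale`) prior on the standardized effect size, giving a
#' noncentral-t marginal, which is divided by the central-t likelihood under
#' H0. BF10 > 1 favors the alternative.
#'
#' @param t observed t statistic.
#' @param n1,n2 group sizes.
#' @param prior_scale Cauchy prior scale (default 0.707 = sqrt(2)/2).
#' @return BF10 (positive scalar).
#' @export
bayes_factor_t <- function(t, n1, n2, prior_scale = 0.707) {
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  lik0 <- stats::dt(t, nu)
  f <- function(delta) {
    stats::dt(t, nu, ncp = delta * sqrt(neff)) *
      stats::dcauchy(delta, 0, prior_scale)
  }
  # dt(ncp = ...) warns about reduced precision deep in the tails; harmless
  lik1 <- suppressWarnings(stats::integrate(f, -Inf, Inf, rel.tol = 1e-8,
                                            stop.on.error = FALSE)$value)
  if (lik1 <= 0 || lik0 <= 0) {
    # far-tail t: integrate on a grid around the MLE where dt() underflows
    grid <- seq(-10, 10, length.out = 4001)
    lw <- suppressWarnings(stats::dt(t, nu, ncp = grid * sqrt(neff),
                                     log = TRUE)) +
      stats::dcauchy(grid, 0, prior_scale, log = TRUE)
    m <- max(lw)
    lik1 <- exp(m) * sum(exp(lw - m)) * (grid[2] - grid[1])
    l0 <- stats::dt(t, nu, log = TRUE)
    return(exp(log(lik1) - l0))
  }
  lik1 / lik0
}

#' Spearman correlation matrix with FDR correction
#'
#' Pairwise Spearman rank correlations between all measure columns, with
#' Benjamini-Hochberg adjustment of the p-values over the unique pairs.
#'
#' @param features data frame or matrix of measures (columns) per subject.
#' @return list with `rho` (symmetric, unit diagonal), `p` (uncorrected),
#'   `p_adj` (BH-adjusted; diagonal NA).
#' @export
spearman_fdr <- function(features) {
  X <- as.matrix(features)
  k <- ncol(X)
  rho <- stats::cor(X, method = "spearman")
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p[i, j] <- p[j, i] <- stats::cor.test(X[, i], X[, j],
                                            method = "spearman",
                                            exact = FALSE)$p.value
    }
  }
  up <- upper.tri(p)
  padj <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  padj[up] <- stats::p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(rho = rho, p = p, p_adj = padj)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC of scores against binary labels, with
#' midranks for ties: the probability that a random positive outranks a
#' random negative.
#'
#' @param scores numeric predictions.
#' @param labels binary outcome (logical, 0/1, or 2-level factor; the second
#'   level / TRUE / 1 is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- if (is.factor(labels)) labels == levels(labels)[2] else as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("need both classes")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.standardize_cols <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) stop("constant feature cannot be standardized")
  scale(X)
}

#' Logistic omnibus model
#'
#' Maximum-likelihood logistic regression of the binary group label on all
#' standardized measures. Reports the in-sample AUC of the fitted
#' probabilities (optimistic by construction; no cross-validation, matching
#' how the omnibus fit index is used downstream), the likelihood-ratio
#' chi-squared against the intercept-only model, and the AIC. Complete
#' separation triggers a small ridge penalty (flagged).
#'
#' @param features subject x measure data frame or matrix.
#' @param labels binary outcome.
#' @return list with `model` (glm, or coefficient vector under the penalized
#'   fallback), `auc`, `chi_sq`, `df`, `p`, `aic`, `log_lik`, `penalized`.
#' @export
logistic_omnibus <- function(features, labels) {
  X <- .standardize_cols(features)
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2]) else
    as.integer(as.logical(labels))
  dat <- data.frame(y = y, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (separated) {
    fit <- .ridge_logistic(X, y, lambda = 1e-2)
    prob <- fit$prob
    ll <- fit$log_lik
    k <- ncol(X) + 1
  } else {
    prob <- stats::fitted(fit)
    ll <- as.numeric(stats::logLik(fit))
    k <- length(stats::coef(fit))
  }
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  chi <- 2 * (ll - ll0)
  dfree <- k - 1
  list(model = fit, auc = auc_score(prob, y), chi_sq = chi, df = dfree,
       p = stats::pchisq(chi, dfree, lower.tail = FALSE),
       aic = 2 * k - 2 * ll, log_lik = ll, penalized = separated)
}

# Ridge-penalized logistic fit by IRLS; fallback for separated data.
.ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(Xd, Xd * w) + pen, crossprod(Xd, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- as.numeric(Xd %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  list(coefficients = as.numeric(beta), prob = mu,
       log_lik = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Linear omnibus model
#'
#' Ordinary least squares of a continuous outcome (e.g. symptom severity
#' score) on all standardized measures; coefficients are standardized betas.
#'
#' @param features subject x measure data frame or matrix.
#' @param outcome numeric outcome.
#' @return list with `model` (lm), `r_squared`, `F`, `df1`, `df2`, `p`,
#'   `aic`, `beta` (standardized coefficients, no intercept).
#' @export
linear_omnibus <- function(features, outcome) {
  X <- .standardize_cols(features)
  yz <- as.numeric(scale(outcome))
  dat <- data.frame(y = yz, X)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(model = fit, r_squared = sm$r.squared,
       F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
       p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
       aic = stats::AIC(fit),
       beta = stats::coef(fit)[-1])
}

#' Hold-one-out dominance analysis
#'
#' Quantifies each measure's unique contribution to the omnibus model:
#' the drop in the fit index (AUC for the logistic family, R-squared for the
#' linear family) when that measure is held out, plus the change in AIC.
#' Sign convention: `delta_index = index(omnibus) - index(held-out)`, so
#' positive values mean the measure helps; `delta_aic = AIC(held-out) -
#' AIC(omnibus)`, so negative values mean the measure's inclusion was not
#' worth its parameter. Measures are returned sorted by dominance.
#'
#' @param features subject x measure data frame.
#' @param outcome group labels (logistic) or numeric scores (linear).
#' @param family "logistic" or "linear".
#' @param top_k optionally refit a reduced model with the `top_k` most
#'   dominant measures.
#' @return A `vr_dominance`: list with `table` (measure, delta_index,
#'   delta_aic, sorted), `omnibus` (full-model fit), `family`, and `reduced`
#'   (reduced-model fit, when `top_k` given).
#' @export
dominance <- function(features, outcome, family = c("logistic", "linear"),
                      top_k = NULL) {
  family <- match.arg(family)
  features <- as.data.frame(features)
  fit_fn <- if (family == "logistic") {
    function(X) {
      f <- logistic_omnibus(X, outcome)
      list(index = f$auc, aic = f$aic, fit = f)
    }
  } else {
    function(X) {
      f <- linear_omnibus(X, outcome)
      list(index = f$r_squared, aic = f$aic, fit = f)
    }
  }
  full <- fit_fn(features)
  rows <- lapply(names(features), function(m) {
    red <- fit_fn(features[, setdiff(names(features), m), drop = FALSE])
    data.frame(measure = m,
               delta_index = full$index - red$index,
               delta_aic = red$aic - full$aic)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$delta_index), ]
  rownames(tab) <- NULL
  reduced <- NULL
  if (!is.null(top_k)) {
    keep <- tab$measure[seq_len(top_k)]
    reduced <- fit_fn(features[, keep, drop = FALSE])$fit
    reduced$measures <- keep
  }
  structure(list(table = tab, omnibus = full$fit, family = family,
                 reduced = reduced),
            class = "vr_dominance")
}
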