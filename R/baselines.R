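# Information-based directed-connectivity baselines: univariate, multivariate,
# extended (locally linear) and RBF (nonlinear) Granger causality, and
# transfer entropy. All scores follow the log error-ratio convention
# score = ln(RSS_restricted / RSS_full), >= 0 up to estimator noise, and all
# matrices use the shared row = target / column = source orientation.

lag_design <- function(x, order) {
  T_len <- length(x)
  idx <- seq(order + 1L, T_len)
  m <- vapply(seq_len(order), function(l) x[idx - l], numeric(length(idx)))
  matrix(m, ncol = order)
}

# OLS residual sum of squares with a ridge fallback for rank-deficient designs.
ols_rss <- function(X, y) {
  X1 <- cbind(1, X)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    warning("rank-deficient design; using ridge fallback")
    lambda <- 1e-8 * sum(diag(crossprod(X1))) / ncol(X1)
    beta <- solve(crossprod(X1) + lambda * diag(ncol(X1)), crossprod(X1, y))
    return(sum((y - X1 %*% beta)^2))
  }
  sum(qr.resid(qr_x, y)^2)
}

bic_order <- function(target, predictors_fun, max_order = 10L) {
  T_len <- length(target)
  scores <- vapply(seq_len(max_order), function(p) {
    X <- predictors_fun(p)
    y <- target[seq(p + 1L, T_len)]
    n <- length(y)
    rss <- ols_rss(X, y)
    n * log(rss / n) + (ncol(X) + 1L) * log(n)
  }, numeric(1))
  which.min(scores)
}

#' Univariate Granger causality
#'
#' Tests whether the source's past improves least-squares prediction of the
#' target beyond the target's own past. The score is
#' `ln(RSS_restricted / RSS_full)`; significance is the F-test on the added
#' source lags. The autoregressive order is selected by BIC over
#' `1..max_order` on the target's own-past model when not given.
#'
#' @param x_target,x_source numeric series of equal length.
#' @param order autoregressive order; `NULL` for BIC selection.
#' @param max_order BIC search bound.
#' @return A list: `score`, `order`, `f`, `p`.
#' @export
gc_univariate <- function(x_target, x_source, order = NULL, max_order = 10L) {
  stopifnot(length(x_target) == length(x_source))
  T_len <- length(x_target)
  if (is.null(order)) {
    order <- bic_order(x_target, function(p) lag_design(x_target, p), max_order)
  }
  order <- as.integer(order)
  if (T_len < 4L * order + 4L) stop("series too short for the requested order")
  y <- x_target[seq(order + 1L, T_len)]
  Xr <- lag_design(x_target, order)
  Xf <- cbind(Xr, lag_design(x_source, order))
  rss_r <- ols_rss(Xr, y)
  rss_f <- ols_rss(Xf, y)
  n <- length(y)
  df2 <- n - ncol(Xf) - 1L
  f <- ((rss_r - rss_f) / order) / (rss_f / df2)
  list(score = log(rss_r / rss_f), order = order, f = f,
       p = pf(f, order, df2, lower.tail = FALSE))
}

#' Multivariate (conditional) Granger causality matrix
#'
#' For each target, the full model regresses the target on the past of all
#' units; the restricted model drops the source's lags. The score is the log
#' RSS ratio, conditioning out all other recorded units (a mediated chain
#' x -> y -> z therefore yields MGC(x -> z | y) near zero).
#'
#' @param ensemble an [ensemble_ts()].
#' @param order autoregressive order; `NULL` selects by BIC on the full model
#'   (shared across targets, the median of per-target selections).
#' @param max_order BIC search bound.
#' @return A `baseline_matrix` with method `"mgc"`.
#' @export
gc_multivariate <- function(ensemble, order = NULL, max_order = 10L) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  v <- ensemble$values
  n_units <- nrow(v); T_len <- ncol(v)
  full_design <- function(p) {
    do.call(cbind, lapply(seq_len(n_units), function(u) lag_design(v[u, ], p)))
  }
  if (is.null(order)) {
    sel <- vapply(seq_len(n_units), function(i) {
      bic_order(v[i, ], full_design,
                max_order = min(max_order, (T_len - 2L) %/% (n_units + 1L)))
    }, integer(1))
    order <- as.integer(round(median(sel)))
  }
  order <- as.integer(order)
  if (n_units * order >= T_len - order) {
    stop("insufficient samples for conditional model")
  }
  Xf <- full_design(order)
  S <- matrix(NA_real_, n_units, n_units)
  for (i in seq_len(n_units)) {
    y <- v[i, seq(order + 1L, T_len)]
    rss_f <- ols_rss(Xf, y)
    for (j in seq_len(n_units)) {
      if (i == j) next
      drop_cols <- (j - 1L) * order + seq_len(order)
      rss_r <- ols_rss(Xf[, -drop_cols, drop = FALSE], y)
      S[i, j] <- log(rss_r / rss_f)
    }
  }
  new_conn_matrix(S, method = "mgc", unit_ids = ensemble$unit_ids,
                  labels = ensemble$labels,
                  meta = list(order = order))
}

#' Extended (locally linear) Granger causality
#'
#' Granger causality evaluated in local phase-space neighborhoods: around
#' each of `n_refs` reference delay states, the nearest `neighborhood`
#' fraction of joint states is fit with restricted (own past) and full
#' (own + source past) linear models, and the score is the mean local
#' `ln(RSS_restricted / RSS_full)`.
#'
#' @param x_target,x_source numeric series of equal length.
#' @param order lags per series in the joint embedding.
#' @param neighborhood fraction of states forming each local neighborhood.
#' @param n_refs number of reference states (sampled deterministically).
#' @param seed seed for reference sampling.
#' @return A list: `score`, `order`, `neighborhood`.
#' @export
gc_extended <- function(x_target, x_source, order = 2L, neighborhood = 0.1,
                        n_refs = 50L, seed = 1) {
  stopifnot(length(x_target) == length(x_source))
  order <- as.integer(order)
  T_len <- length(x_target)
  y <- x_target[seq(order + 1L, T_len)]
  Xr <- lag_design(x_target, order)
  Xs <- lag_design(x_source, order)
  m <- length(y)
  k <- max(as.integer(ceiling(neighborhood * m)), 4L * order + 4L)
  refs <- withr::with_seed(seed, sample.int(m, min(n_refs, m)))
  joint <- cbind(Xr, Xs)
  ratios <- vapply(refs, function(r) {
    d2 <- colSums((t(joint) - joint[r, ])^2)
    nb <- order(d2)[seq_len(k)]
    rss_r <- ols_rss(Xr[nb, , drop = FALSE], y[nb])
    rss_f <- ols_rss(joint[nb, , drop = FALSE], y[nb])
    log(rss_r / max(rss_f, 1e-300))
  }, numeric(1))
  list(score = mean(ratios), order = order, neighborhood = neighborhood)
}

rbf_features <- function(U, n_centers, seed) {
  n_centers <- min(n_centers, max(2L, nrow(unique(U)) - 1L))
  km <- withr::with_seed(seed, kmeans(U, centers = n_centers, nstart = 3))
  cen <- km$centers
  w <- median(stats::dist(cen))
  if (!is.finite(w) || w <= 0) w <- 1
  d2 <- outer(rowSums(U^2), rowSums(cen^2), "+") - 2 * U %*% t(cen)
  exp(-pmax(d2, 0) / (2 * w^2))
}

#' Nonlinear Granger causality with radial-basis-function autoregression
#'
#' Replaces the linear autoregression with RBF features of the lag vectors:
#' centers are placed by k-means on the lag vectors, widths equal the median
#' inter-center distance, and the restricted model uses the target's own RBF
#' features while the full model adds the source's. The score is
#' `ln(RSS_restricted / RSS_full)`.
#'
#' @param x_target,x_source numeric series of equal length.
#' @param order lags per series.
#' @param n_centers RBF centers per series (default 20).
#' @param seed seed for k-means initialization.
#' @return A list: `score`, `order`, `n_centers`.
#' @export
gc_nonlinear_rbf <- function(x_target, x_source, order = 2L, n_centers = 20L,
                             seed = 1) {
  stopifnot(length(x_target) == length(x_source))
  order <- as.integer(order)
  T_len <- length(x_target)
  y <- x_target[seq(order + 1L, T_len)]
  Phi_y <- rbf_features(lag_design(x_target, order), n_centers, seed)
  Phi_x <- rbf_features(lag_design(x_source, order), n_centers, seed + 1L)
  rss_r <- ols_rss(Phi_y, y)
  rss_f <- ols_rss(cbind(Phi_y, Phi_x), y)
  list(score = log(rss_r / max(rss_f, 1e-300)), order = order,
       n_centers = n_centers)
}

discretize_equal_occupancy <- function(x, n_bins) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) stop("cannot bin a constant series")
  # discrete data with few levels keep their own symbols (quantile breaks
  # collapse on heavy ties)
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1L)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Transfer entropy (plug-in, equal-occupancy bins)
#'
#' `TE(source -> target) = H(y+ | y_hist) - H(y+ | y_hist, x_hist)` in bits,
#' estimated by plug-in entropies over equal-occupancy-binned symbols with
#' history length `k_history`. The bias-corrected value subtracts the mean
#' TE over circularly time-shifted source surrogates, which preserve the
#' source's marginal statistics while destroying its alignment with the
#' target.
#'
#' @param x_target,x_source numeric series of equal length.
#' @param k_history history length (symbols of past per series).
#' @param n_bins equal-occupancy bins per series (default 4). Errors if
#'   `n_bins^(2 k_history + 1) > T / 5` (undersampled joint histogram).
#' @param n_shuffles shift surrogates for bias correction (default 20);
#'   `0` returns the raw plug-in estimate.
#' @param seed seed for the shift draws.
#' @return A list: `te` (bias-corrected, bits), `te_raw`, `null_mean`,
#'   `null_sd`.
#' @export
transfer_entropy <- function(x_target, x_source, k_history = 1L, n_bins = 4L,
                             n_shuffles = 20L, seed = 1) {
  stopifnot(length(x_target) == length(x_source))
  T_len <- length(x_target)
  if (n_bins^(2L * k_history + 1L) > T_len / 5) {
    stop("undersampled joint histogram: reduce n_bins or k_history")
  }
  ys <- discretize_equal_occupancy(x_target, n_bins)
  xs <- discretize_equal_occupancy(x_source, n_bins)
  k <- as.integer(k_history)
  idx <- seq(k + 1L, T_len)
  hist_sym <- function(s) {
    # collapse the k most recent symbols into one base-n_bins code
    out <- integer(length(idx))
    for (l in seq_len(k)) out <- out * n_bins + (s[idx - l] - 1L)
    out + 1L
  }
  te_of <- function(xsym) {
    yn <- ys[idx]; yh <- hist_sym(ys); xh <- hist_sym(xsym)
    h_yh <- entropy_bits(table(yh))
    h_yn_yh <- entropy_bits(table(paste(yn, yh)))
    h_yh_xh <- entropy_bits(table(paste(yh, xh)))
    h_all <- entropy_bits(table(paste(yn, yh, xh)))
    (h_yn_yh - h_yh) - (h_all - h_yh_xh)
  }
  te_raw <- te_of(xs)
  if (n_shuffles > 0L) {
    nulls <- withr::with_seed(seed, {
      shifts <- sample(seq(k + 5L, T_len - k - 5L), n_shuffles, replace = TRUE)
      vapply(shifts, function(s) {
        te_of(c(xs[(s + 1L):T_len], xs[1:s]))
      }, numeric(1))
    })
    list(te = te_raw - mean(nulls), te_raw = te_raw,
         null_mean = mean(nulls), null_sd = sd(nulls))
  } else {
    list(te = te_raw, te_raw = te_raw, null_mean = NA_real_,
         null_sd = NA_real_)
  }
}

#' Baseline directed-connectivity matrix
#'
#' Fills the N x N matrix of a chosen information-based estimator in the
#' shared row = target / column = source convention. Optional significance
#' uses a circular time-shift surrogate null of the source (99 shifts,
#' add-one p-value), mirroring the surrogate-testing burden of the
#' causal-flow pipeline.
#'
#' @param ensemble an [ensemble_ts()].
#' @param method one of `"gc"`, `"mgc"`, `"egc"`, `"ngc"`, `"te"`.
#' @param ... passed to the per-pair estimator.
#' @param significance add a time-shift surrogate significance mask.
#' @param n_null surrogates for the significance pass.
#' @param alpha significance level.
#' @param seed seed for surrogate shifts.
#' @return A `baseline_matrix`.
#' @export
compute_baseline_matrix <- function(ensemble,
                                    method = c("gc", "mgc", "egc", "ngc", "te"),
                                    ..., significance = FALSE, n_null = 99L,
                                    alpha = 0.05, seed = 1) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  method <- match.arg(method)
  if (method == "mgc") {
    out <- gc_multivariate(ensemble, ...)
    return(out)
  }
  v <- ensemble$values
  n <- nrow(v); T_len <- ncol(v)
  score_fun <- switch(method,
    gc = function(y, x, ...) gc_univariate(y, x, ...)$score,
    egc = function(y, x, ...) gc_extended(y, x, ...)$score,
    ngc = function(y, x, ...) gc_nonlinear_rbf(y, x, ...)$score,
    te = function(y, x, ...) transfer_entropy(y, x, ...)$te)
  S <- matrix(NA_real_, n, n)
  p_mat <- if (significance) matrix(NA_real_, n, n) else NULL
  sig <- if (significance) matrix(NA, n, n) else NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      S[i, j] <- score_fun(v[i, ], v[j, ], ...)
      if (significance) {
        nulls <- withr::with_seed(seed + 31L * i + j, {
          shifts <- sample(seq(10L, T_len - 10L), n_null, replace = TRUE)
          vapply(shifts, function(s) {
            score_fun(v[i, ], c(v[j, (s + 1L):T_len], v[j, 1:s]), ...)
          }, numeric(1))
        })
        p_mat[i, j] <- (1 + sum(nulls >= S[i, j])) / (1 + n_null)
        sig[i, j] <- p_mat[i, j] < alpha
      }
    }
  }
  new_conn_matrix(S, method = method, unit_ids = ensemble$unit_ids,
                  p = p_mat, sig_mask = sig, labels = ensemble$labels,
                  meta = list(...))
}
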