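#' Takens delay-coordinate embedding
#'
#' Builds the delay matrix whose row for time `t` is
#' \deqn{X(t) = (x(t), x(t-\tau), \ldots, x(t - d\tau + \tau)),}
#' for `t = (d-1) tau + 1, ..., T` (rows in time order). Under mild
#' conditions these vectors reconstruct the attractor of the system that
#' generated `x`, which is what cross-map prediction exploits.
#'
#' @param series numeric vector (one unit's activity).
#' @param d embedding dimension (>= 1).
#' @param tau delay step in samples (>= 1).
#' @return A `delay_matrix`: a numeric matrix with `T - (d-1) tau` rows and
#'   `d` columns, with attributes `d`, `tau` and `t_index` (the original
#'   sample index of each row's first coordinate).
#' @examples
#' delay_embed(1:5, d = 2, tau = 2) # rows (3,1), (4,2), (5,3)
#' @export
delay_embed <- function(series, d, tau) {
  series <- as.numeric(series)
  d <- as.integer(d); tau <- as.integer(tau)
  if (d < 1L || tau < 1L) stop("need d >= 1 and tau >= 1")
  T_len <- length(series)
  min_len <- (d - 1L) * tau + 2L
  if (T_len < min_len) {
    stop(sprintf("series too short: need at least %d samples for d = %d, tau = %d",
                 min_len, d, tau))
  }
  t_index <- seq((d - 1L) * tau + 1L, T_len)
  lags <- (seq_len(d) - 1L) * tau
  emb <- vapply(lags, function(l) series[t_index - l], numeric(length(t_index)))
  emb <- matrix(emb, ncol = d)
  structure(emb, d = d, tau = tau, t_index = t_index,
            class = c("delay_matrix", "matrix"))
}

# Clipped Fisher z transform of a correlation; strictly increasing and odd.
fisher_z <- function(rho) {
  atanh(pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12))
}

block_folds <- function(m, folds) {
  if (folds <= 1L) return(rep(1L, m))
  as.integer(cut(seq_len(m), breaks = folds, labels = FALSE))
}

#' Cross-map prediction (simplex projection) with block cross-validation
#'
#' Predicts the source series from the delay embedding of a (putative)
#' target: for each held-out time, the prediction is the distance-weighted
#' average (weights `exp(-dist / dist_min)`) of the source values at the
#' times of the `k` nearest in-library neighbors of the target's delay
#' state. Cross-validation uses contiguous blocks, and library points within
#' a Theiler window of the predicted time are excluded to prevent leakage
#' through temporal autocorrelation. Accuracy is the Pearson correlation
#' between pooled held-out predictions and the truth, reported with its
#' Fisher z transform (clipped at `|rho| = 1 - 1e-12`).
#'
#' @param reconstructor a [delay_embed()] matrix of the target unit.
#' @param source_series full-length numeric series of the source unit (the
#'   rows of `reconstructor` are aligned to it via their time index).
#' @param k_neighbors number of neighbors; default `d + 1` (minimal simplex).
#' @param folds number of contiguous cross-validation blocks (default 5);
#'   `folds = 1` disables fold exclusion (Theiler exclusion still applies).
#' @param theiler exclusion half-width in samples; default `(d - 1) * tau`.
#' @return A list of class `cross_map`: `rho`, `z`, and a tibble
#'   `predictions` with `time`, `observed`, `predicted`.
#' @export
cross_map <- function(reconstructor, source_series, k_neighbors = NULL,
                      folds = 5L, theiler = NULL) {
  if (!inherits(reconstructor, "delay_matrix")) {
    stop("`reconstructor` must come from delay_embed()")
  }
  d <- attr(reconstructor, "d"); tau <- attr(reconstructor, "tau")
  t_index <- attr(reconstructor, "t_index")
  if (max(t_index) > length(source_series)) {
    stop("source series shorter than the reconstructor's time range")
  }
  if (is.null(k_neighbors)) k_neighbors <- d + 1L
  if (k_neighbors < d + 1L) stop("k_neighbors must be at least d + 1")
  if (is.null(theiler)) theiler <- (d - 1L) * tau
  emb <- unclass(reconstructor); attributes(emb)[c("d", "tau", "t_index")] <- NULL
  m <- nrow(emb)
  rng <- apply(emb, 2, function(col) diff(range(col)))
  if (all(rng == 0)) stop("degenerate embedding: all delay states identical")
  src <- as.numeric(source_series)[t_index]
  fold <- block_folds(m, folds)
  pred <- simplex_cv_cpp(emb, src, fold, as.integer(k_neighbors),
                         as.integer(theiler), use_folds = folds > 1L)
  rho <- suppressWarnings(cor(pred, src))
  if (is.na(rho)) rho <- 0 # constant predictions or constant truth
  structure(list(rho = rho, z = fisher_z(rho),
                 predictions = tibble::tibble(time = t_index, observed = src,
                                              predicted = pred),
                 d = d, tau = tau, k = k_neighbors, folds = folds,
                 theiler = theiler),
            class = "cross_map")
}

#' @export
print.cross_map <- function(x, ...) {
  cat(sprintf("<cross_map> rho = %.4f, z = %.4f (d = %d, tau = %d, k = %d, %d folds)\n",
              x$rho, x$z, x$d, x$tau, x$k, x$folds))
  invisible(x)
}

#' Causal-flow matrix from convergent cross-mapping
#'
#' Fills the N x N matrix `F` with `F[i, j] = z(rho(X_j | X_i))`: the
#' cross-validated Fisher-z accuracy of reconstructing source unit `j`'s
#' series from target unit `i`'s delay embedding. Columns index the source
#' (the unit being reconstructed); column `j` is the causal-flow vector
#' `f^(j)`. High `F[i, j]` indicates that `j` is causally upstream of `i`.
#' Constant-series units are flagged missing (row and column `NA`) with a
#' warning rather than an error.
#'
#' @param ensemble an [ensemble_ts()] with at least two units.
#' @param d,tau embedding dimension and delay (samples); see
#'   [select_hyperparameters()] for data-driven selection. The default
#'   `tau = 4` corresponds to the 4 ms delay at 1 ms bins used for spike
#'   counts; `d = 5` sits at or above the accuracy plateau for the default
#'   simulated network.
#' @param k_neighbors,folds,theiler passed to [cross_map()].
#' @return A `cf_matrix` (see [new_conn_matrix()]) with an empty
#'   significance mask; fill it with [cf_significance()].
#' @export
compute_cf_matrix <- function(ensemble, d = 5L, tau = 4L, k_neighbors = NULL,
                              folds = 5L, theiler = NULL) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  v <- ensemble$values
  n <- nrow(v)
  if (n < 2L) stop("need at least two units")
  ok <- apply(v, 1, function(r) sd(r) > 0)
  if (any(!ok)) {
    warning("constant unit series flagged missing: ",
            paste(ensemble$unit_ids[!ok], collapse = ", "))
  }
  embeds <- vector("list", n)
  for (i in which(ok)) embeds[[i]] <- delay_embed(v[i, ], d, tau)
  F_mat <- matrix(NA_real_, n, n)
  for (i in which(ok)) {
    for (j in which(ok)) {
      if (i == j) next
      F_mat[i, j] <- cross_map(embeds[[i]], v[j, ], k_neighbors = k_neighbors,
                               folds = folds, theiler = theiler)$z
    }
  }
  new_conn_matrix(F_mat, method = "ccm", unit_ids = ensemble$unit_ids,
                  subclass = "cf_matrix", labels = ensemble$labels,
                  meta = list(d = as.integer(d), tau = as.integer(tau),
                              k = if (is.null(k_neighbors)) d + 1L
                                  else as.integer(k_neighbors),
                              folds = as.integer(folds),
                              theiler = if (is.null(theiler)) (d - 1L) * tau
                                        else as.integer(theiler)))
}

#' Select embedding hyperparameters by the accuracy plateau
#'
#' Cross-map accuracy grows with the embedding dimension until the attractor
#' is unfolded, then plateaus. This scans a `(d, tau)` grid, scores each
#' setting by the median cross-validated Fisher-z accuracy over a probe set
#' of ordered unit pairs, and returns the smallest `d` (ties broken toward
#' the smallest `tau`) whose score is within `plateau_tol` of the grid
#' maximum. If the accuracy is still rising at the grid edge a warning is
#' issued and the grid maximum is returned with `plateau = FALSE`.
#'
#' @param ensemble an [ensemble_ts()].
#' @param d_grid,tau_grid candidate dimensions and delays (samples).
#' @param n_probe number of probe pairs (sampled deterministically under
#'   `seed`; all ordered pairs if fewer).
#' @param plateau_tol plateau tolerance in Fisher-z units (default 0.02).
#' @param folds cross-validation blocks for the probe cross-maps.
#' @param seed seed for probe-pair sampling.
#' @return A list: `d`, `tau`, `plateau` (logical), and `scores`, a tibble
#'   of median accuracy per grid point.
#' @export
select_hyperparameters <- function(ensemble, d_grid = 2:10, tau_grid = 1:8,
                                   n_probe = 6L, plateau_tol = 0.02,
                                   folds = 5L, seed = 1) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  if (length(d_grid) < 1L || length(tau_grid) < 1L) stop("empty grid")
  n <- nrow(ensemble$values)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  if (nrow(pairs) > n_probe) {
    keep <- withr::with_seed(seed, sample(nrow(pairs), n_probe))
    pairs <- pairs[keep, , drop = FALSE]
  }
  grid <- expand.grid(d = sort(unique(as.integer(d_grid))),
                      tau = sort(unique(as.integer(tau_grid))))
  grid$score <- purrr::pmap_dbl(grid[c("d", "tau")], function(d, tau) {
    zs <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
      emb <- delay_embed(ensemble$values[i, ], d, tau)
      cross_map(emb, ensemble$values[j, ], folds = folds)$z
    })
    median(zs)
  })
  best <- max(grid$score)
  cand <- grid[grid$score >= best - plateau_tol, , drop = FALSE]
  cand <- cand[order(cand$d, cand$tau), , drop = FALSE]
  d_sel <- cand$d[1]; tau_sel <- cand$tau[1]
  plateau <- TRUE
  if (d_sel == max(grid$d) && length(unique(grid$d)) > 1L) {
    per_d <- tapply(grid$score, grid$d, max)
    if (diff(tail(per_d, 2)) > plateau_tol) {
      plateau <- FALSE
      warning("no accuracy plateau within the grid; returning the grid maximum")
    }
  }
  list(d = d_sel, tau = tau_sel, plateau = plateau,
       scores = tibble::as_tibble(grid))
}
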