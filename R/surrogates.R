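#' Find twin states in a delay embedding
#'
#' Twins are embedded states sharing exactly the same set of neighbors,
#' where neighbors are states closer than a radius taken as a quantile of
#' the off-diagonal pairwise distance distribution (max-norm, the standard
#' metric of the recurrence-plot literature). Twins are dynamically
#' interchangeable: swapping them preserves the attractor geometry, which is
#' what makes the surrogate construction below break causal coupling without
#' destroying the marginal dynamics.
#'
#' @param embedding a [delay_embed()] matrix with at least 10 states.
#' @param radius_quantile quantile of the off-diagonal distance distribution
#'   used as the neighborhood radius (default 0.1).
#' @return A `twin_set`: list with `radius`, `classes` (integer class id per
#'   state), `members` (list of state indices per class), `n_per_state`
#'   (class size of each state's class), `t_index`.
#' @export
find_twins <- function(embedding, radius_quantile = 0.1) {
  if (!inherits(embedding, "delay_matrix")) {
    stop("`embedding` must come from delay_embed()")
  }
  m <- nrow(embedding)
  if (m < 10L) stop("need at least 10 embedded states")
  D <- as.matrix(stats::dist(unclass(embedding), method = "maximum"))
  radius <- as.numeric(quantile(D[upper.tri(D)], radius_quantile))
  R <- D < radius # neighbors are states strictly closer than the radius
  diag(R) <- TRUE # every state belongs to its own neighborhood
  key <- apply(R, 1, function(r) paste(which(r), collapse = ","))
  classes <- match(key, unique(key))
  members <- split(seq_len(m), classes)
  if (max(lengths(members)) > m / 2) {
    stop("degenerate twin partition: a single twin class holds most states; decrease radius_quantile")
  }
  structure(list(radius = radius, radius_quantile = radius_quantile,
                 classes = classes, members = members,
                 n_per_state = lengths(members)[classes],
                 t_index = attr(embedding, "t_index")),
            class = "twin_set")
}

#' @export
print.twin_set <- function(x, ...) {
  m <- length(x$classes)
  cat(sprintf("<twin_set> %d states, %d classes, radius = %.4g (%d states with a twin)\n",
              m, length(x$members), x$radius, sum(x$n_per_state > 1)))
  invisible(x)
}

#' Generate twin surrogates
#'
#' Re-threads the observed trajectory through phase space: a surrogate
#' starts at a uniformly random embedded state and at each step either
#' follows the recorded successor of its current state (retention
#' probability `(n - 1) / n`, where `n` is the size of the state's twin
#' class) or jumps to a uniformly chosen twin and continues from that twin's
#' successor. A walk reaching the final recorded state continues from the
#' successor of a random twin of it, or restarts at a random state if it has
#' none. Surrogates preserve the value multiset and attractor geometry of
#' the original series while destroying its causal relation to other series.
#'
#' @param series the original scalar series (defines surrogate values and
#'   length).
#' @param embedding the [delay_embed()] of `series` used for `twinset`.
#' @param twinset a [find_twins()] result built from `embedding`.
#' @param n_surrogates number of surrogate series (>= 1).
#' @param seed integer seed; the same seed gives the identical surrogate set.
#' @return A `surrogate_ensemble`: list with `series` (matrix, one surrogate
#'   per row, `length(series)` columns), `paths` (the visited state indices,
#'   same shape) and the generation parameters.
#' @export
generate_surrogates <- function(series, embedding, twinset, n_surrogates,
                                seed = 1) {
  stopifnot(inherits(twinset, "twin_set"))
  if (!identical(attr(embedding, "t_index"), twinset$t_index)) {
    stop("`twinset` was not built from this embedding")
  }
  if (n_surrogates < 1L) stop("n_surrogates must be >= 1")
  m <- length(twinset$classes)
  T_len <- length(series)
  vals <- as.numeric(series)[twinset$t_index]
  classes <- twinset$classes
  members <- twinset$members
  n_of <- twinset$n_per_state
  out <- withr::with_seed(seed, {
    one_walk <- function() {
      path <- integer(T_len)
      cur <- sample.int(m, 1L)
      for (s in seq_len(T_len)) {
        path[s] <- cur
        n <- n_of[cur]
        from <- cur
        if (runif(1) >= (n - 1) / n && n > 1L) {
          others <- members[[classes[cur]]]
          others <- others[others != cur]
          from <- if (length(others) == 1L) others else sample(others, 1L)
        }
        if (from >= m) { # final state has no recorded successor
          tw <- members[[classes[m]]]
          tw <- tw[tw != m]
          if (length(tw) > 0L) {
            from <- if (length(tw) == 1L) tw else sample(tw, 1L)
            cur <- from + 1L
          } else {
            cur <- sample.int(m, 1L) # restart
          }
        } else {
          cur <- from + 1L
        }
      }
      path
    }
    t(vapply(seq_len(n_surrogates), function(i) one_walk(), integer(T_len)))
  })
  structure(list(series = matrix(vals[out], nrow(out), ncol(out)),
                 paths = out, n_surrogates = as.integer(n_surrogates),
                 radius = twinset$radius, seed = as.integer(seed)),
            class = "surrogate_ensemble")
}

#' Twin-surrogate significance of causal-flow entries
#'
#' For each tested ordered pair (target `i`, source `j`), the empirical
#' cross-map accuracy `F[i, j]` is compared with the accuracies obtained
#' when the reconstructor series (target `i`) is replaced by each of its
#' twin surrogates; surrogating the reconstructor breaks its causal read-out
#' of the source while preserving its own dynamics. The one-sided empirical
#' p-value uses the add-one rule
#' `p = (1 + #\{F_surr >= F_emp\}) / (1 + n_surrogates)`, so the smallest
#' attainable p is `1 / (1 + n_surrogates)`.
#'
#' @param ensemble the [ensemble_ts()] the causal-flow matrix was computed on.
#' @param cf the [compute_cf_matrix()] result (carries `d`, `tau`, `folds`).
#' @param n_surrogates surrogates per target unit (default 99).
#' @param alpha significance level (default 0.05); must satisfy
#'   `1 / (1 + n_surrogates) <= alpha`.
#' @param radius_quantile passed to [find_twins()].
#' @param adjust `"none"` (per-pair significance, the default) or `"BH"` for
#'   Benjamini-Hochberg correction across the tested pairs.
#' @param pairs optional two-column matrix or data frame of (target, source)
#'   unit ids restricting the test to those ordered pairs.
#' @param seed integer seed (per-target surrogate seeds derive from it).
#' @return The `cf_matrix` with `p` and `sig_mask` filled for tested pairs.
#' @export
cf_significance <- function(ensemble, cf, n_surrogates = 99L, alpha = 0.05,
                            radius_quantile = 0.1, adjust = c("none", "BH"),
                            pairs = NULL, seed = 1) {
  stopifnot(inherits(ensemble, "ensemble_ts"), inherits(cf, "cf_matrix"))
  adjust <- match.arg(adjust)
  if (1 / (1 + n_surrogates) > alpha) {
    stop(sprintf("n_surrogates = %d cannot reach alpha = %g; need at least %d",
                 n_surrogates, alpha, ceiling(1 / alpha) - 1))
  }
  ids <- cf$unit_ids
  n <- length(ids)
  d <- cf$meta$d; tau <- cf$meta$tau; folds <- cf$meta$folds
  if (is.null(pairs)) {
    pairs <- expand.grid(target = ids, source = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$target != pairs$source, ]
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("target", "source")
  }
  p_mat <- if (is.null(cf$p)) matrix(NA_real_, n, n) else cf$p
  sig <- if (is.null(cf$sig_mask)) matrix(NA, n, n) else cf$sig_mask
  for (tid in unique(pairs$target)) {
    i <- match(tid, ids)
    srcs <- pairs$source[pairs$target == tid]
    js <- match(srcs, ids)
    x_i <- ensemble$values[i, ]
    emb <- delay_embed(x_i, d, tau)
    twins <- find_twins(emb, radius_quantile)
    surr <- generate_surrogates(x_i, emb, twins, n_surrogates,
                                seed = seed + 7919L * i)
    z_surr <- matrix(NA_real_, n_surrogates, length(js))
    for (s in seq_len(n_surrogates)) {
      semb <- delay_embed(surr$series[s, ], d, tau)
      for (q in seq_along(js)) {
        z_surr[s, q] <- cross_map(semb, ensemble$values[js[q], ],
                                  folds = folds)$z
      }
    }
    for (q in seq_along(js)) {
      j <- js[q]
      p_mat[i, j] <- (1 + sum(z_surr[, q] >= cf$values[i, j])) /
        (1 + n_surrogates)
    }
  }
  tested <- !is.na(p_mat)
  p_use <- p_mat
  if (adjust == "BH") p_use[tested] <- stats::p.adjust(p_mat[tested], "BH")
  sig[tested] <- p_use[tested] < alpha
  new_conn_matrix(cf$values, method = cf$method, unit_ids = ids,
                  subclass = "cf_matrix", p = p_mat, sig_mask = sig,
                  labels = cf$labels,
                  meta = c(cf$meta, list(n_surrogates = as.integer(n_surrogates),
                                         alpha = alpha, adjust = adjust,
                                         radius_quantile = radius_quantile,
                                         seed = as.integer(seed))))
}
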