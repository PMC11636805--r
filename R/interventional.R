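#' Extract pre/post stimulation window summaries
#'
#' For each trial, sums the target unit's activity over the half-open window
#' `[onset - w, onset)` before the pulse and `[offset, offset + w)` after it
#' (the pulse interval itself is excluded to keep stimulation artifacts out
#' of the comparison), giving one scalar per trial per side.
#'
#' @param session a [run_perturbation_session()] result (or any list with
#'   `ensemble`, `onsets`, `pulse_samples`, `window_samples`).
#' @param target unit id or index of the recorded target.
#' @param window_samples window width in samples; defaults to the session's.
#' @return A tibble with columns `trial`, `pre`, `post`.
#' @export
extract_windows <- function(session, target, window_samples = NULL) {
  stopifnot(inherits(session, "perturbation_session"))
  w <- if (is.null(window_samples)) session$window_samples
       else as.integer(window_samples)
  if (w < 1L) stop("window must contain at least one sample")
  ens <- session$ensemble
  ti <- if (is.character(target)) match(target, ens$unit_ids)
        else as.integer(target)
  if (is.na(ti)) stop("target unit not found")
  x <- ens$values[ti, ]
  onsets <- session$onsets
  offsets <- onsets + session$pulse_samples
  if (any(onsets - w < 1L) || any(offsets + w - 1L > length(x))) {
    stop("pre/post windows fall outside the recording")
  }
  span <- offsets + w - 1L # end of each trial's footprint
  bad <- which(head(span, -1) >= tail(onsets, -1) - w)
  if (length(bad) > 0L) {
    stop("overlapping trial windows for trials: ",
         paste(bad, collapse = ", "))
  }
  tibble::tibble(
    trial = seq_along(onsets),
    pre = vapply(onsets, function(o) sum(x[(o - w):(o - 1L)]), numeric(1)),
    post = vapply(offsets, function(o) sum(x[o:(o + w - 1L)]), numeric(1))
  )
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The exact supremum over the pooled sample points of the absolute
#' difference between the two empirical cumulative distribution functions.
#' Rank-based: invariant under any strictly monotone transform applied to
#' both samples.
#'
#' @param a,b numeric samples (non-empty).
#' @return `D` in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3), c(2, 3, 4)) # 1/3
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, sort(a)) / length(a)
  Fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(Fa - Fb))
}

#' Interventional-connectivity matrix
#'
#' Quantifies the effect of stimulating source `j` on target `i` as
#' `S[i, j]`, the Kolmogorov-Smirnov statistic between the distributions of
#' pre-onset and post-offset window-summed activity across trials. Column
#' `j` is the perturbation vector `s^(j)`. Significance is assessed by
#' within-trial label permutation: pre/post values are swapped independently
#' per trial, the statistic recomputed `n_perms` times, and the add-one
#' empirical p-value compared with `alpha`. Unstimulated sources are flagged
#' missing.
#'
#' @param sessions list of [run_perturbation_session()] results, one per
#'   stimulated source; all must share the same unit set.
#' @param alpha significance level.
#' @param n_perms permutations per pair (default 999); `0` skips the
#'   significance pass and leaves `p`/`sig_mask` empty.
#' @param window_samples optional override of each session's window.
#' @param seed integer seed for the permutations.
#' @return An `ic_matrix` (see [new_conn_matrix()]); rows are targets,
#'   columns are (stimulated) sources.
#' @export
compute_ic_matrix <- function(sessions, alpha = 0.05, n_perms = 999L,
                              window_samples = NULL, seed = 1) {
  if (inherits(sessions, "perturbation_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L)
  ens0 <- sessions[[1]]$ensemble
  ids <- ens0$unit_ids
  n <- length(ids)
  S <- matrix(NA_real_, n, n)
  p_mat <- matrix(NA_real_, n, n)
  for (sess in sessions) {
    if (!identical(sess$ensemble$unit_ids, ids)) {
      stop("sessions have inconsistent unit sets")
    }
    j <- match(sess$stimulated_unit, ids)
    if (length(sess$onsets) < 5L) {
      warning(sprintf("source %s has only %d trials; KS estimates will be noisy",
                      sess$stimulated_unit, length(sess$onsets)))
    }
    for (i in seq_len(n)) {
      if (i == j) next
      wins <- extract_windows(sess, i, window_samples)
      S[i, j] <- ks_statistic(wins$pre, wins$post)
      if (n_perms > 0L) {
        n_tr <- nrow(wins)
        d_perm <- withr::with_seed(seed + 104729L * j + i, {
          vapply(seq_len(n_perms), function(r) {
            flip <- runif(n_tr) < 0.5
            ks_statistic(ifelse(flip, wins$post, wins$pre),
                         ifelse(flip, wins$pre, wins$post))
          }, numeric(1))
        })
        p_mat[i, j] <- (1 + sum(d_perm >= S[i, j])) / (1 + n_perms)
      }
    }
  }
  sig <- if (n_perms > 0L) {
    m <- matrix(NA, n, n); m[!is.na(p_mat)] <- p_mat[!is.na(p_mat)] < alpha; m
  } else NULL
  new_conn_matrix(S, method = "ks", unit_ids = ids, subclass = "ic_matrix",
                  p = if (n_perms > 0L) p_mat else NULL, sig_mask = sig,
                  labels = ens0$labels,
                  meta = list(alpha = alpha, n_perms = as.integer(n_perms),
                              n_trials = vapply(sessions,
                                function(s) length(s$onsets), integer(1)),
                              sources = vapply(sessions,
                                function(s) s$stimulated_unit, character(1)),
                              seed = as.integer(seed)))
}
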