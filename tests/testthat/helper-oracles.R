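# Independent brute-force oracles used to pin the fast implementations.

# Quadratic-time KS: evaluate both ECDFs at every pooled point explicitly.
oracle_ks <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# O(m^2) pairwise-difference Gini (population formula).
oracle_gini <- function(v) {
  m <- length(v)
  sum(abs(outer(v, v, "-"))) / (2 * m^2 * mean(v))
}

# Exhaustive-search simplex projection with explicit weights, mirroring the
# documented prediction rule (block CV folds + Theiler exclusion).
oracle_simplex <- function(emb, source_full, k, folds = 5,
                           theiler = (attr(emb, "d") - 1) * attr(emb, "tau")) {
  m <- nrow(emb)
  ti <- attr(emb, "t_index")
  src <- source_full[ti]
  fold <- as.integer(cut(seq_len(m), folds, labels = FALSE))
  pred <- numeric(m)
  for (r in seq_len(m)) {
    cand <- which(fold != fold[r] & abs(seq_len(m) - r) > theiler)
    dd <- sqrt(colSums((t(emb[cand, , drop = FALSE]) - emb[r, ])^2))
    ord <- order(dd, cand)[seq_len(k)]
    nb <- cand[ord]
    dn <- dd[ord]
    w <- if (dn[1] <= 0) as.numeric(dn <= 0) else exp(-dn / dn[1])
    pred[r] <- sum(w * src[nb]) / sum(w)
  }
  pred
}

# Small deterministic unidirectionally coupled pair (a drives b).
coupled_pair <- function(T_len = 1000, seed = 1, beta = 0.8, noise = 0.3) {
  withr::with_seed(seed, {
    a <- as.numeric(stats::arima.sim(list(ar = 0.7), T_len))
    b <- numeric(T_len)
    e <- rnorm(T_len, sd = noise)
    for (t in 2:T_len) b[t] <- 0.4 * b[t - 1] + beta * a[t - 1] + e[t]
    list(a = a, b = b)
  })
}

# Small simulated network shared across tests (cheap: 20 driven units).
# g_r is scaled so the effective recurrent gain 10 * g_r * sqrt(n_y) matches
# the full-size default (= 2), keeping the dynamical regime comparable.
small_network <- function(seed = 1, duration = 8000, n_y = 20,
                          g_r = 0.2 / sqrt(n_y), ...) {
  simulate_network(sim_params(seed = seed, n_y = n_y, duration = duration,
                              transient = 1000, g_r = g_r, ...))
}
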