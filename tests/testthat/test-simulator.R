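test_that("network has 103 nodes by default and runs are bit-reproducible", {
  p <- sim_params(duration = 300, transient = 50)
  sim <- simulate_network(p)
  expect_equal(nrow(sim$values), 103)
  expect_equal(sim$labels, rep(c("X", "Y"), c(3, 100)))
  sim2 <- simulate_network(sim_params(duration = 300, transient = 50))
  expect_identical(sim$values, sim2$values)
  # a different seed gives a different recurrent realization
  sim3 <- simulate_network(sim_params(duration = 300, transient = 50, seed = 2))
  expect_false(identical(sim$values, sim3$values))
})

test_that("uncoupled driven units decay to zero under pure leak", {
  p <- sim_params(g = 0, g_r = 0, I = 0, n_y = 5,
                  duration = 2000, transient = 0)
  sim <- simulate_network(p)
  y_tail <- sim$values[4:8, 1801:2000]
  expect_lt(max(abs(y_tail)), 1e-6)
})

test_that("the driver is bounded and chaotic (positive Lyapunov sign)", {
  p <- sim_params(g = 0, n_y = 2, duration = 20000, transient = 3000)
  sim <- simulate_network(p)
  x <- sim$values[1:3, ]
  expect_true(all(abs(x) < 50)) # bounded, far from the overflow guard
  expect_gt(sd(x[1, ]), 1)      # not collapsed to a fixed point
  # not periodic: no lag (beyond a short window) recurs to near-zero distance
  x1 <- x[1, seq(1, 20000, by = 10)]
  acf_vals <- stats::acf(x1, lag.max = 1500, plot = FALSE)$acf[-(1:50)]
  expect_lt(max(acf_vals), 0.995)
  # positive largest-Lyapunov sign, measured against a fine-step reference
  # integration (dt/10) of a nearby trajectory
  fine <- function(x0, n_time) {
    pp <- sim_params(g = 0, n_y = 2, dt = 0.001,
                     duration = n_time * 1000, transient = 0)
    init <- causalflow:::sim_init(pp)
    init$state0[1:3] <- x0
    vals <- causalflow:::rk4_network_cpp(init$state0, init$Jyy,
      g = 0, alpha = pp$alpha, beta = pp$beta, gamma = pp$gamma,
      tau0 = 1, lambda = 1, Iext = 0, dt = 0.001,
      n_steps = n_time * 1000, keep_from = 0, stim_unit = -1L,
      stim_active = logical(0), stim_S = 0, guard = 1e6, noise_sd = 0)
    vals[1:3, ]
  }
  x0 <- x[, 1]
  ref <- fine(x0, 20)
  per <- fine(x0 + c(1e-6, 0, 0), 20)
  d0 <- 1e-6
  d_end <- sqrt(sum((ref[, 20000] - per[, 20000])^2))
  lyap <- log(d_end / d0) / 20
  expect_gt(lyap, 0.01)
})

test_that("halving dt changes a short post-transient window by a tiny RMS", {
  run_dt <- function(dt) {
    p <- sim_params(dt = dt, n_y = 10, duration = round(10 / dt),
                    transient = round(5 / dt))
    v <- simulate_network(p)$values
    by <- round(0.1 / dt)
    v[, seq(by, ncol(v), by = by)] # samples at matching absolute times
  }
  a <- run_dt(0.01)
  b <- run_dt(0.005)
  expect_lt(sqrt(mean((a - b)^2)), 1e-4)
})

test_that("divergence raises an explicit error", {
  # an integration step far above the stability limit for the leak term
  p <- sim_params(tau0 = 1e-4, duration = 2000, transient = 0, n_y = 5)
  expect_error(simulate_network(p), "diverged")
})

test_that("injected noise hits the requested SNR exactly, per unit", {
  sim <- small_network(duration = 2000)
  for (snr in c(-10, 0, 7.5)) {
    noisy <- inject_noise(sim, snr, mode = "private", seed = 3)
    comp <- noisy$values - sim$values
    snr_meas <- 10 * log10(apply(sim$values, 1, sd) / apply(comp, 1, sd))
    expect_lt(max(abs(snr_meas - snr)), 1e-9)
  }
})

test_that("shared noise is one common realization; private noise is independent", {
  sim <- small_network(duration = 4000)
  sh <- inject_noise(sim, 0, mode = "shared", seed = 5)
  comp <- sh$values - sim$values
  cors <- cor(t(comp))
  expect_equal(min(cors), 1, tolerance = 1e-12)
  pr <- inject_noise(sim, 0, mode = "private", seed = 5)
  comp_p <- pr$values - sim$values
  cors_p <- cor(t(comp_p))
  off <- abs(cors_p[upper.tri(cors_p)])
  expect_lt(mean(off), 3 / sqrt(ncol(comp_p)))
})

test_that("constant rows are rejected by inject_noise", {
  ens <- ensemble_ts(rbind(a = rnorm(100), b = rep(1, 100)), dt = 1)
  expect_error(inject_noise(ens, 0), "zero-variance")
})

test_that("a zero-strength perturbation session reproduces the resting run", {
  p <- sim_params(n_y = 10, duration = 30000, transient = 500)
  sess <- run_perturbation_session(p, "y5", pulse_strength = 0, n_trials = 3)
  sim <- simulate_network(p)
  expect_identical(sess$ensemble$values, sim$values)
})

test_that("stimulating a driven unit leaves the driver untouched", {
  p <- sim_params(n_y = 10, duration = 30000, transient = 500)
  sess <- run_perturbation_session(p, "y5", pulse_strength = 5, n_trials = 3)
  sim <- simulate_network(p)
  expect_equal(sess$ensemble$values[1:3, ], sim$values[1:3, ],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sess$ensemble$values[8, ], sim$values[8, ])))
})

test_that("stimulating a driver coordinate shifts the driven activity (KS)", {
  p <- sim_params(n_y = 10, g_r = 0.2 / sqrt(10), duration = 130000,
                  transient = 500)
  mean_D <- function(S) {
    sess <- run_perturbation_session(p, "x1", pulse_strength = S,
                                     n_trials = 40)
    mean(vapply(paste0("y", 4:13), function(u) {
      w <- extract_windows(sess, u)
      ks_statistic(w$pre, w$post)
    }, numeric(1)))
  }
  expect_gt(mean_D(5), mean_D(0))
})

test_that("onsets outside the recording are rejected", {
  p <- sim_params(n_y = 5, duration = 5000, transient = 100)
  expect_error(run_perturbation_session(p, "y4", onsets = c(4950)),
               "outside")
  expect_error(run_perturbation_session(p, "zz", n_trials = 2), "not found")
})

test_that("with no coupling, driver-driven lagged cross-correlation sits in the shuffled null", {
  sim <- simulate_network(sim_params(g = 0, n_y = 6, duration = 6000,
                                     transient = 1000, seed = 4))
  v <- decimate_ensemble(sim, 10)$values
  max_lag_cor <- function(a, b) {
    cc <- stats::ccf(a, b, lag.max = 50, plot = FALSE)$acf
    max(abs(cc))
  }
  obs <- max_lag_cor(v[1, ], v[5, ])
  # shuffled-pair null: circularly shift the driven unit far from alignment
  null <- withr::with_seed(9, vapply(1:40, function(i) {
    s <- sample(100:(ncol(v) - 100), 1)
    max_lag_cor(v[1, ], v[5, c((s + 1):ncol(v), 1:s)])
  }, numeric(1)))
  expect_lte(obs, quantile(null, 0.95) + 0.05)
})

test_that("poisson observation layer has the right moments and reproducibility", {
  ens <- ensemble_ts(matrix(2, 2, 5000), dt = 0.01) # constant latent
  counts <- poissonify(ens, gain = 3, bin = 0.05, seed = 2)
  rate <- 3 * log1p(exp(2)) * 0.05 # per-bin intensity
  n_bins <- ncol(counts$values)
  expect_lt(abs(mean(counts$values[1, ]) - rate), 4 * sqrt(rate / n_bins))
  vmr <- var(counts$values[1, ]) / mean(counts$values[1, ])
  expect_lt(abs(vmr - 1), 0.1)
  expect_identical(counts$values,
                   poissonify(ens, gain = 3, bin = 0.05, seed = 2)$values)
  expect_true(all(poissonify(ens, gain = 0, bin = 0.05)$values == 0))
  expect_error(poissonify(ens, gain = 1, bin = 0.001), "bin")
})
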