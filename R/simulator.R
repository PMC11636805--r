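#' Ground-truth network simulator parameters
#'
#' Parameters of the driver/driven rate network used as ground truth: three
#' units `X = (x1, x2, x3)` follow chaotic Rossler dynamics,
#' \deqn{\tau_0 \dot x_1 = -x_2 - x_3,\quad
#'       \tau_0 \dot x_2 = x_1 + \alpha x_2,\quad
#'       \tau_0 \dot x_3 = \beta + x_3 (x_1 - \gamma),}
#' and feed forward onto `n_y` rate units
#' \deqn{\tau_0 \dot y = -\lambda y + 10\,\tanh(J_{YX} x + J_{YY} y + I),}
#' with `J_YX = g * ones` (every driven unit receives the summed driver) and
#' recurrent weights `J_YY` drawn i.i.d. from `N(0, g_r^2)`. There is no
#' feedback from Y to X, so X is causally upstream by construction.
#'
#' Defaults are the canonical chaotic Rossler constants
#' (`alpha = beta = 0.2`, `gamma = 5.7`) with a weakly recurrent Y
#' subnetwork (`g = 0.1`, `g_r = 0.02`). The effective recurrent gain is
#' `10 * g_r * sqrt(n_y)` (the tanh has slope 10 at the origin): the default
#' puts it at 2, just past the transition to autonomous recurrent dynamics,
#' so driven units carry the driver's imprint while retaining private
#' fluctuations the driver cannot predict. Much larger `g_r` buries the
#' feed-forward drive under recurrent chaos; much smaller `g_r` enslaves Y
#' to X completely and makes cross-mapping symmetric.
#'
#' @param alpha,beta,gamma Rossler coefficients (dimensionless).
#' @param tau0 intrinsic time constant (time units).
#' @param lam leak rate of the driven units (1/time).
#' @param g feed-forward coupling strength X to Y (>= 0).
#' @param g_r standard deviation of the recurrent weights `J_YY` (>= 0).
#' @param I constant external drive per driven unit.
#' @param n_x number of driver units; must be 3 (the Rossler system has
#'   exactly three coordinates).
#' @param n_y number of driven rate units.
#' @param dt integration step (time units).
#' @param duration number of post-transient samples returned.
#' @param transient number of initial samples discarded.
#' @param noise_sd standard deviation of dynamical noise injected into the
#'   driven units at each step (Euler-Maruyama increment,
#'   `noise_sd * sqrt(dt) * N(0,1)`); 0 (the default) gives the
#'   deterministic system. Observational noise is a separate stage, see
#'   [inject_noise()].
#' @param seed integer RNG seed controlling `J_YY`, initial conditions and
#'   the dynamical noise path.
#'
#' @return A list of class `sim_params`.
#' @seealso [simulate_network()], [run_perturbation_session()]
#' @export
sim_params <- function(alpha = 0.2, beta = 0.2, gamma = 5.7, tau0 = 1,
                       lam = 1, g = 0.1, g_r = 0.02, I = 0,
                       n_x = 3, n_y = 100, dt = 0.01,
                       duration = 20000, transient = 2000, noise_sd = 0,
                       seed = 1) {
  if (n_x != 3) stop("n_x must be 3: the Rossler driver has exactly three coordinates")
  if (dt <= 0) stop("dt must be positive")
  if (transient < 0 || duration < 1) stop("need transient >= 0 and duration >= 1")
  if (transient >= duration) stop("transient must be shorter than duration")
  if (g < 0 || g_r < 0) stop("g and g_r must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau0 = tau0,
                 lam = lam, g = g, g_r = g_r, I = I, n_x = n_x, n_y = n_y,
                 dt = dt, duration = as.integer(duration),
                 transient = as.integer(transient), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Seeded draws shared by resting and perturbed runs: recurrent weights and
# initial conditions. Same seed => same network realization, bit for bit.
sim_init <- function(params) {
  withr::with_seed(params$seed, {
    Jyy <- matrix(rnorm(params$n_y^2, mean = 0, sd = params$g_r),
                  params$n_y, params$n_y)
    x0 <- runif(3, -1, 1)
    y0 <- runif(params$n_y, -0.1, 0.1)
    list(Jyy = Jyy, state0 = c(x0, y0))
  })
}

sim_unit_ids <- function(params) {
  c(paste0("x", 1:3), paste0("y", 3 + seq_len(params$n_y)))
}

run_network <- function(params, stim_unit = -1L, stim_active = logical(0),
                        stim_S = 0) {
  init <- sim_init(params)
  n_steps <- params$duration + params$transient
  vals <- withr::with_seed(params$seed + 500009L, {
    rk4_network_cpp(init$state0, init$Jyy,
                    g = params$g, alpha = params$alpha,
                    beta = params$beta, gamma = params$gamma,
                    tau0 = params$tau0, lambda = params$lam,
                    Iext = params$I, dt = params$dt,
                    n_steps = n_steps, keep_from = params$transient,
                    stim_unit = stim_unit, stim_active = stim_active,
                    stim_S = stim_S, guard = 1e6,
                    noise_sd = params$noise_sd)
  })
  ensemble_ts(vals, params$dt, sim_unit_ids(params),
              labels = rep(c("X", "Y"), c(3, params$n_y)))
}

#' Simulate the ground-truth driver/driven network
#'
#' Integrates the system described in [sim_params()] with fixed-step
#' fourth-order Runge-Kutta and discards the transient. Identical parameters
#' (including `seed`) give bit-identical output. Trajectories exceeding an
#' overflow guard of `1e6` in absolute value raise a "trajectory diverged"
#' error (strong `g_r` regimes can be unstable).
#'
#' @param params a [sim_params()] object.
#' @return An [ensemble_ts()] with `n_x + n_y` units labelled `"X"`/`"Y"`.
#' @examples
#' p <- sim_params(n_y = 10, duration = 500, transient = 100)
#' sim <- simulate_network(p)
#' dim(sim)
#' @export
simulate_network <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  run_network(params)
}

#' Add observational noise at a controlled signal-to-noise ratio
#'
#' Adds Gaussian noise scaled per unit so that the realized
#' `10 * log10(sd(signal) / sd(noise))` equals `snr_db` exactly (standard
#' deviations taken over time, per unit). With `mode = "private"` each unit
#' receives an independent realization; with `mode = "shared"` a single
#' scalar realization (a common input) is scaled per unit and added to all
#' units, so the injected components are perfectly correlated across units.
#'
#' @param ensemble an [ensemble_ts()]; every unit must have positive variance.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param mode `"private"` or `"shared"`.
#' @param seed integer seed for the noise draw.
#' @return An [ensemble_ts()] with noisy values.
#' @export
inject_noise <- function(ensemble, snr_db, mode = c("private", "shared"),
                         seed = 1) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  mode <- match.arg(mode)
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  v <- ensemble$values
  sig_sd <- apply(v, 1, sd)
  if (any(sig_sd <= 0)) {
    stop("zero-variance signal in unit(s): ",
         paste(ensemble$unit_ids[sig_sd <= 0], collapse = ", "))
  }
  target_sd <- sig_sd / 10^(snr_db / 10)
  noise <- withr::with_seed(seed, {
    if (mode == "private") {
      raw <- matrix(rnorm(length(v)), nrow(v), ncol(v))
      raw * (target_sd / apply(raw, 1, sd))
    } else {
      z <- rnorm(ncol(v))
      outer(target_sd / sd(z), z)
    }
  })
  ensemble_ts(v + noise, ensemble$dt, ensemble$unit_ids, ensemble$labels)
}

#' Draw jittered non-overlapping stimulation trial onsets
#'
#' Onsets are placed in post-transient sample coordinates so that each trial,
#' padded by the pulse plus pre/post comparison windows plus an inter-trial
#' gap of `gap_factor * pulse_samples`, fits inside the recording without
#' overlap; within each slot the onset is jittered uniformly.
#'
#' @param duration recording length in samples.
#' @param n_trials number of trials.
#' @param pulse_samples pulse duration in samples.
#' @param window_samples pre/post comparison window in samples.
#' @param gap_factor inter-trial gap as a multiple of the pulse duration.
#' @param seed integer seed for the jitter.
#' @return Integer vector of trial onset samples (1-based, post-transient).
#' @export
make_trial_onsets <- function(duration, n_trials = 40, pulse_samples = 10,
                              window_samples = 20, gap_factor = 10, seed = 1) {
  slot <- pulse_samples + 2L * window_samples +
    as.integer(ceiling(gap_factor * pulse_samples))
  lead <- window_samples + 1L
  avail <- duration - window_samples - lead
  if (n_trials * slot > avail) {
    stop(sprintf("cannot place %d non-overlapping trials of slot %d in %d samples",
                 n_trials, slot, duration))
  }
  jitter_room <- (avail - n_trials * slot) / n_trials
  withr::with_seed(seed, {
    base <- lead + (seq_len(n_trials) - 1L) * (slot + floor(jitter_room))
    base + as.integer(floor(runif(n_trials, 0, max(1, jitter_room))))
  })
}

#' Run a pulse-perturbation session
#'
#' Re-integrates the network of [sim_params()] (same seed, hence the same
#' `J_YY` and initial conditions as the resting run) while injecting an
#' external current of strength `pulse_strength` into one unit during each
#' pulse interval `[onset, onset + pulse_samples)`. The current enters a
#' driven (Y) unit inside the tanh transfer function — the input port where
#' the constant drive `I` enters — and a driver (X) coordinate additively in
#' its rate equation (the Rossler system has no input port). With
#' `pulse_strength = 0` the output is bit-identical to [simulate_network()].
#'
#' Defaults map 1 model time unit (= the leak time constant `tau0`) to
#' 50 ms of experimental time, so a 100 ms stimulation pulse is 2 time
#' units = 200 samples at `dt = 0.01`, and the 200 ms comparison windows
#' are 400 samples. Forty padded, jittered, non-overlapping trials then
#' need a recording of at least ~125,000 samples; pass a `params` with a
#' suitably long `duration`.
#'
#' @param params a [sim_params()].
#' @param stimulated_unit unit id (e.g. `"x1"`, `"y8"`) or index to stimulate.
#' @param pulse_strength pulse current `S` (input units; default 5, strong
#'   enough to saturate a driven unit's transfer function without
#'   destabilizing the driver).
#' @param pulse_samples pulse duration in samples (default 200 = 100 ms).
#' @param window_samples pre/post comparison window in samples (default
#'   400 = 200 ms); stored for the interventional stage.
#' @param n_trials number of stimulation trials.
#' @param onsets optional explicit onset samples (post-transient, 1-based);
#'   defaults to [make_trial_onsets()] seeded by `params$seed`.
#' @return A `perturbation_session`: list with the perturbed `ensemble`,
#'   `stimulated_unit`, `onsets`, `pulse_samples`, `pulse_strength`,
#'   `window_samples`.
#' @export
run_perturbation_session <- function(params, stimulated_unit,
                                     pulse_strength = 5,
                                     pulse_samples = 200L,
                                     window_samples = 400L,
                                     n_trials = 40L, onsets = NULL) {
  stopifnot(inherits(params, "sim_params"))
  ids <- sim_unit_ids(params)
  su <- if (is.character(stimulated_unit)) match(stimulated_unit, ids)
        else as.integer(stimulated_unit)
  if (is.na(su) || su < 1L || su > length(ids)) {
    stop("stimulated_unit not found in the network")
  }
  if (is.null(onsets)) {
    onsets <- make_trial_onsets(params$duration, n_trials = n_trials,
                                pulse_samples = pulse_samples,
                                window_samples = window_samples,
                                seed = params$seed + 10000L * su)
  }
  onsets <- as.integer(onsets)
  if (any(onsets < 1L) || any(onsets + pulse_samples - 1L > params$duration)) {
    stop("trial onsets fall outside the post-transient recording")
  }
  n_steps <- params$duration + params$transient
  stim_active <- logical(n_steps)
  for (o in onsets) {
    stim_active[params$transient + o + seq_len(pulse_samples) - 1L] <- TRUE
  }
  ens <- run_network(params, stim_unit = su - 1L, stim_active = stim_active,
                     stim_S = pulse_strength)
  structure(list(ensemble = ens, stimulated_unit = ids[su],
                 onsets = sort(onsets), pulse_samples = as.integer(pulse_samples),
                 pulse_strength = pulse_strength,
                 window_samples = as.integer(window_samples)),
            class = "perturbation_session")
}

#' @export
print.perturbation_session <- function(x, ...) {
  cat(sprintf("<perturbation_session> stim %s, %d trials, S = %g, pulse %d samples\n",
              x$stimulated_unit, length(x$onsets), x$pulse_strength,
              x$pulse_samples))
  invisible(x)
}

#' Poisson spike-count observation layer
#'
#' Emulates electrode spike-count observations: latent activity is mapped to
#' a non-negative rate through a softplus link scaled by `gain`, integrated
#' over time bins, and observed as Poisson counts.
#'
#' @param ensemble an [ensemble_ts()] of latent activity.
#' @param gain rate scale (spikes per time unit per softplus activity unit).
#' @param bin bin width in time units; must be at least `dt`.
#' @param seed integer seed for the Poisson draws.
#' @return An [ensemble_ts()] of integer counts with `dt = bin`.
#' @export
poissonify <- function(ensemble, gain, bin, seed = 1) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  if (bin < ensemble$dt) stop("bin must be >= dt")
  if (gain < 0) stop("gain must be non-negative")
  per <- max(1L, as.integer(round(bin / ensemble$dt)))
  n_bins <- ncol(ensemble$values) %/% per
  if (n_bins < 1L) stop("recording shorter than one bin")
  rate <- gain * log1p(exp(ensemble$values)) # softplus link
  idx <- rep(seq_len(n_bins), each = per)
  lam <- t(apply(rate[, seq_len(n_bins * per), drop = FALSE], 1,
                 function(r) tapply(r * ensemble$dt, idx, sum)))
  counts <- withr::with_seed(seed,
    matrix(rpois(length(lam), as.vector(lam)), nrow(lam), ncol(lam)))
  ensemble_ts(counts, dt = per * ensemble$dt, ensemble$unit_ids,
              ensemble$labels)
}
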