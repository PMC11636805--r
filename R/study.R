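#' Ground-truth simulation study: does resting connectivity predict
#' perturbation effects?
#'
#' Runs the full validation experiment on the simulated driver/driven
#' network: (1) simulate resting activity of the `3 + n_y`-node network and
#' subsample 10 units (the 3 driver coordinates plus 7 evenly spaced driven
#' units); (2) estimate the causal-flow matrix by cross-validated
#' convergent cross-mapping on the decimated resting series, with embedding
#' hyperparameters chosen by the accuracy-plateau rule; (3) stimulate each
#' subsampled unit with repeated 100 ms pulses in its own session and
#' compute the interventional-connectivity matrix from pre/post 200 ms
#' windows; (4) estimate the univariate Granger-causality matrix on the
#' same resting series; (5) correlate each connectivity estimate with IC
#' over the ordered unit pairs.
#'
#' @param seed integer seed; controls the network realization, trial
#'   jitter, fold-probe sampling and permutations.
#' @param params resting-run [sim_params()]; defaults to `sim_params(seed =
#'   seed)`.
#' @param n_sub_y number of driven units subsampled (default 7).
#' @param decimate thinning factor applied before embedding (default 10),
#'   setting the effective bin width of the analyzed series; see
#'   [bin_ensemble()] for the averaging alternative suited to noisy data.
#' @param d_grid,tau_grid hyperparameter grids for
#'   [select_hyperparameters()]; pass scalars to fix them.
#' @param n_trials,pulse_strength perturbation protocol, see
#'   [run_perturbation_session()].
#' @param ic_perms permutations for IC significance (0 to skip).
#' @param cf_surrogates twin surrogates for CF significance (0 to skip the
#'   significance pass, which the correlation analysis does not need).
#' @param baselines additional baseline methods to correlate with IC
#'   (subset of `"gc"`, `"mgc"`, `"egc"`, `"ngc"`, `"te"`).
#' @param baseline_args named list of per-method argument lists, e.g.
#'   `list(egc = list(n_refs = 20))`.
#' @return A list of class `simulation_study`: `cf`, `ic`, `baseline`
#'   (named list of matrices), `reports` (named list of
#'   [prediction_tests()] results, `"ccm"` first), `correlations` (tibble
#'   method/pearson_r/n_pairs), `hyper` (selected d, tau), `units`.
#' @export
simulation_study <- function(seed = 1, params = NULL, n_sub_y = 7L,
                             decimate = 10L, d_grid = 2:10, tau_grid = 4L,
                             n_trials = 40L, pulse_strength = 5,
                             ic_perms = 199L, cf_surrogates = 0L,
                             baselines = "gc", baseline_args = list()) {
  if (is.null(params)) params <- sim_params(seed = seed)
  stopifnot(inherits(params, "sim_params"))
  sim <- simulate_network(params)
  rest <- decimate_ensemble(sim, decimate)
  y_pick <- round(seq(4, 3 + params$n_y, length.out = n_sub_y))
  units <- c(paste0("x", 1:3), paste0("y", y_pick))
  sub <- subset_units(rest, units)

  hyper <- select_hyperparameters(sub, d_grid = d_grid, tau_grid = tau_grid,
                                  seed = seed)
  cf <- compute_cf_matrix(sub, d = hyper$d, tau = hyper$tau)
  if (cf_surrogates > 0L) {
    cf <- cf_significance(sub, cf, n_surrogates = cf_surrogates, seed = seed)
  }

  # one session per stimulated unit; longer run to hold the padded trials
  slot <- 200L + 2L * 400L + 10L * 200L
  sess_params <- params
  sess_params$duration <- max(params$duration,
                              as.integer(n_trials * slot * 1.05) + 2000L)
  sessions <- lapply(units, function(u) {
    s <- run_perturbation_session(sess_params, u, n_trials = n_trials,
                                  pulse_strength = pulse_strength)
    s$ensemble <- subset_units(s$ensemble, units)
    s
  })
  ic <- compute_ic_matrix(sessions, n_perms = ic_perms, seed = seed)

  base <- list()
  for (b in baselines) {
    base[[b]] <- do.call(compute_baseline_matrix,
                         c(list(sub, method = b),
                           if (!is.null(baseline_args[[b]]))
                             baseline_args[[b]]))
  }
  reports <- c(list(ccm = prediction_tests(cf, ic)),
               lapply(base, function(m) prediction_tests(m, ic)))
  correlations <- purrr::imap_dfr(reports, function(r, m) {
    tibble::tibble(method = m, pearson_r = r$stats$pearson_r,
                   pearson_p = r$stats$pearson_p, n_pairs = r$stats$n_pairs)
  })
  structure(list(cf = cf, ic = ic, baseline = base, reports = reports,
                 correlations = correlations,
                 hyper = hyper[c("d", "tau", "plateau")], units = units,
                 seed = as.integer(seed)),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("<simulation_study> seed %d, units: %s (d = %d, tau = %d)\n",
              x$seed, paste(x$units, collapse = " "), x$hyper$d, x$hyper$tau))
  print(x$correlations)
  invisible(x)
}

#' @describeIn simulation_study per-method connectivity-IC correlations.
#' @param x a `simulation_study`.
#' @param ... unused.
#' @export
tidy.simulation_study <- function(x, ...) x$correlations
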