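#' Ensemble time series
#'
#' The universal container for multivariate activity: one row per unit, one
#' column per time sample, with a fixed sampling interval `dt`. Optional
#' per-unit subnetwork labels (e.g. `"X"` for driver units, `"Y"` for driven
#' units) are carried along by the simulator and used by evaluation helpers.
#'
#' @param values numeric matrix, units x time samples. No missing values.
#' @param dt sampling interval (time units per sample), positive scalar.
#' @param unit_ids character vector of unique unit labels; defaults to
#'   rownames of `values` or `u1..uN`.
#' @param labels optional character vector of per-unit subnetwork tags.
#'
#' @return An object of class `ensemble_ts`: a list with elements `values`,
#'   `dt`, `unit_ids`, `labels`.
#' @examples
#' ts <- ensemble_ts(matrix(rnorm(40), 2), dt = 0.01)
#' dplyr::glimpse(tibble::as_tibble(ts))
#' @export
ensemble_ts <- function(values, dt, unit_ids = NULL, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` contains missing or non-finite entries")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive scalar")
  }
  if (is.null(unit_ids)) {
    unit_ids <- rownames(values)
    if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(nrow(values)))
  }
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) != nrow(values)) {
    stop("`unit_ids` must have one entry per row of `values`")
  }
  if (anyDuplicated(unit_ids)) stop("duplicate unit ids: ",
    paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      stop("`labels` must have one entry per unit")
    }
  }
  rownames(values) <- unit_ids
  structure(
    list(values = values, dt = dt, unit_ids = unit_ids, labels = labels),
    class = "ensemble_ts"
  )
}

#' @export
print.ensemble_ts <- function(x, ...) {
  cat(sprintf("<ensemble_ts> %d units x %d samples, dt = %g\n",
              nrow(x$values), ncol(x$values), x$dt))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ensemble_ts <- function(x) dim(x$values)

#' Tidy view of an ensemble
#'
#' @param x an [ensemble_ts()].
#' @param ... unused.
#' @return A tibble with columns `unit`, `label` (if present), `time`,
#'   `activity`; time is `(sample - 1) * dt` (0-based sample convention).
#' @export
as_tibble.ensemble_ts <- function(x, ...) {
  n_t <- ncol(x$values)
  out <- tibble::tibble(
    unit = rep(x$unit_ids, each = n_t),
    time = rep((seq_len(n_t) - 1) * x$dt, times = nrow(x$values)),
    activity = as.vector(t(x$values))
  )
  if (!is.null(x$labels)) {
    out <- dplyr::mutate(out,
      label = rep(x$labels, each = n_t), .after = "unit")
  }
  out
}

#' Subset an ensemble to selected units
#'
#' @param ensemble an [ensemble_ts()].
#' @param units character ids or integer indices of units to keep (in order).
#' @return An `ensemble_ts` with the selected units.
#' @export
subset_units <- function(ensemble, units) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  if (is.character(units)) {
    idx <- match(units, ensemble$unit_ids)
    if (anyNA(idx)) stop("unknown unit ids: ",
      paste(units[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(units)
  }
  ensemble_ts(ensemble$values[idx, , drop = FALSE], ensemble$dt,
              ensemble$unit_ids[idx],
              if (!is.null(ensemble$labels)) ensemble$labels[idx])
}

#' Bin or decimate an ensemble in time
#'
#' `bin_ensemble` averages non-overlapping windows of `by` samples — the
#' analog of counting spikes in time bins, which also suppresses
#' per-sample observation noise by `sqrt(by)`. `decimate_ensemble` keeps
#' every `by`-th raw sample. Both multiply the sampling interval by `by`
#' and set the effective bin width of the series fed to the
#' delay-embedding stage.
#'
#' @param ensemble an [ensemble_ts()].
#' @param by positive integer window / decimation factor.
#' @return An `ensemble_ts` with `dt * by` sampling interval.
#' @export
bin_ensemble <- function(ensemble, by) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  by <- as.integer(by)
  if (by < 1L) stop("`by` must be a positive integer")
  n_bins <- ncol(ensemble$values) %/% by
  if (n_bins < 1L) stop("recording shorter than one bin")
  idx <- rep(seq_len(n_bins), each = by)
  v <- ensemble$values[, seq_len(n_bins * by), drop = FALSE]
  binned <- t(apply(v, 1, function(r) tapply(r, idx, mean)))
  ensemble_ts(binned, ensemble$dt * by, ensemble$unit_ids, ensemble$labels)
}

#' @rdname bin_ensemble
#' @export
decimate_ensemble <- function(ensemble, by) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  by <- as.integer(by)
  if (by < 1L) stop("`by` must be a positive integer")
  keep <- seq(1L, ncol(ensemble$values), by = by)
  ensemble_ts(ensemble$values[, keep, drop = FALSE], ensemble$dt * by,
              ensemble$unit_ids, ensemble$labels)
}
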