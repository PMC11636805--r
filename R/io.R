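# Delimited-text readers and writers. Every artifact is a plain TSV plus a
# JSON sidecar (same path + ".json") carrying the metadata needed for a
# lossless round trip; matrices inline their p-values and significance masks
# in the sidecar.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an ensemble as delimited text
#'
#' The TSV has one column per unit (header = unit ids) and one row per time
#' sample; `dt` and the optional subnetwork labels live in the JSON sidecar
#' `<path>.json`.
#'
#' @param ensemble an [ensemble_ts()].
#' @param path output TSV path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns the [ensemble_ts()].
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_ts"))
  df <- as.data.frame(t(ensemble$values))
  names(df) <- ensemble$unit_ids
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(dt = ensemble$dt, unit_ids = ensemble$unit_ids,
         labels = ensemble$labels, n_samples = ncol(ensemble$values)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        name_repair = "minimal")
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty ensemble file: ", path)
  ids <- names(df)
  if (anyDuplicated(ids)) {
    stop("duplicate unit ids in header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- t(as.matrix(df))
  if (anyNA(vals)) stop("ensemble file contains missing values")
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar (dt unknown): ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  labels <- meta$labels
  if (length(labels) == 0L) labels <- NULL
  ensemble_ts(vals, dt = meta$dt, unit_ids = ids, labels = labels)
}

#' Write / read a connectivity matrix as delimited text
#'
#' The TSV holds the values with a `target` id column and source ids as the
#' remaining headers (missing entries are empty cells); method, metadata,
#' labels, p-values and the significance mask go to the JSON sidecar.
#'
#' @param matrix a `conn_matrix`.
#' @param path output TSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` the
#'   reconstructed `conn_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "conn_matrix"))
  df <- tibble::as_tibble(as.data.frame(matrix$values))
  names(df) <- matrix$unit_ids
  df <- dplyr::bind_cols(tibble::tibble(target = matrix$unit_ids), df)
  readr::write_tsv(df, path, na = "")
  jsonlite::write_json(
    list(subclass = class(matrix)[1], method = matrix$method,
         unit_ids = matrix$unit_ids, labels = matrix$labels,
         meta = matrix$meta,
         p = if (is.null(matrix$p)) NULL else unname(matrix$p),
         sig_mask = if (is.null(matrix$sig_mask)) NULL
                    else unname(matrix$sig_mask)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ids <- side$unit_ids
  vals <- as.matrix(df[, -1, drop = FALSE])
  to_mat <- function(x, mode = "double") {
    if (is.null(x) || length(x) == 0L) return(NULL)
    m <- as.matrix(x)
    storage.mode(m) <- mode
    unname(m)
  }
  labels <- side$labels
  if (length(labels) == 0L) labels <- NULL
  meta <- side$meta
  new_conn_matrix(vals, method = side$method, unit_ids = ids,
                  subclass = side$subclass,
                  p = to_mat(side$p), sig_mask = to_mat(side$sig_mask, "logical"),
                  labels = labels, meta = if (is.null(meta)) list() else meta)
}

#' Write / read a perturbation-session record
#'
#' The session's trial structure goes to JSON; the perturbed recording is
#' written with [write_ensemble()] next to it (`<path>.ensemble.tsv`).
#'
#' @param session a [run_perturbation_session()] result.
#' @param path output JSON path.
#' @return `write_session` returns `path` invisibly; `read_session` the
#'   reconstructed session.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "perturbation_session"))
  ens_path <- paste0(path, ".ensemble.tsv")
  write_ensemble(session$ensemble, ens_path)
  jsonlite::write_json(
    list(stimulated_unit = session$stimulated_unit,
         onsets = session$onsets, pulse_samples = session$pulse_samples,
         pulse_strength = session$pulse_strength,
         window_samples = session$window_samples,
         ensemble = basename(ens_path)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  ens <- read_ensemble(file.path(dirname(path), rec$ensemble))
  structure(list(ensemble = ens, stimulated_unit = rec$stimulated_unit,
                 onsets = as.integer(rec$onsets),
                 pulse_samples = as.integer(rec$pulse_samples),
                 pulse_strength = rec$pulse_strength,
                 window_samples = as.integer(rec$window_samples)),
            class = "perturbation_session")
}

#' Deterministic test fixtures
#'
#' Writes small, fully deterministic datasets used by examples and the test
#' suite: `"toy-series"` (a single unit holding the worked 1..5 embedding
#' example plus a smooth sine unit), `"coupled-pair"` (two noisy
#' autoregressive units with known one-way coupling `a -> b`, the shared
#' convention fixture), and `"grid-session"` (a small simulated network with
#' a geometry table and one perturbation-session record).
#'
#' @param kind fixture name.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Character vector of written file paths (invisibly their md5 sums
#'   as names are stable for a fixed seed).
#' @export
make_fixture <- function(kind = c("toy-series", "coupled-pair", "grid-session"),
                         dir = tempdir(), seed = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(kind,
    "toy-series" = {
      ens <- ensemble_ts(rbind(ramp = 1:5,
                               sine = sin(2 * pi * (0:4) / 5)), dt = 1)
      p <- file.path(dir, "toy-series.tsv")
      write_ensemble(ens, p)
      c(p, sidecar_path(p))
    },
    "coupled-pair" = {
      T_len <- 1000L
      vals <- withr::with_seed(seed, {
        a <- as.numeric(stats::arima.sim(list(ar = 0.7), T_len))
        b <- numeric(T_len)
        e <- rnorm(T_len, sd = 0.3)
        for (t in 2:T_len) b[t] <- 0.4 * b[t - 1] + 0.8 * a[t - 1] + e[t]
        rbind(a = a, b = b)
      })
      p <- file.path(dir, "coupled-pair.tsv")
      write_ensemble(ensemble_ts(vals, dt = 1), p)
      c(p, sidecar_path(p))
    },
    "grid-session" = {
      params <- sim_params(n_y = 2, duration = 2000, transient = 300,
                           seed = seed)
      sess <- run_perturbation_session(params, "x1", n_trials = 3L,
                                       pulse_samples = 40L,
                                       window_samples = 80L)
      geom <- make_grid_geometry(sim_unit_ids(params), n_side = 3L,
                                 seed = seed)
      ps <- file.path(dir, "grid-session.json")
      write_session(sess, ps)
      pg <- file.path(dir, "grid-geometry.tsv")
      readr::write_tsv(geom, pg)
      c(ps, paste0(ps, ".ensemble.tsv"), paste0(ps, ".ensemble.tsv.json"), pg)
    })
  invisible(setNames(paths, unname(tools::md5sum(paths))))
}
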