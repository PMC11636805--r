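#' Directed connectivity matrices
#'
#' Causal-flow, interventional-connectivity and baseline matrices share one
#' container and one orientation convention, enforced everywhere: **rows are
#' targets** (the reconstructing / recorded unit `i`), **columns are sources**
#' (the reconstructed / stimulated unit `j`). Column `j` is therefore the
#' causal-flow vector `f^(j)` or the perturbation vector `s^(j)`. The
#' diagonal is undefined and stored as `NA`.
#'
#' @param values N x N numeric matrix in the row = target, column = source
#'   convention.
#' @param method short method tag (e.g. `"ccm"`, `"ks"`, `"gc"`).
#' @param unit_ids unit labels (row and column names).
#' @param subclass S3 subclass, one of `"cf_matrix"`, `"ic_matrix"`,
#'   `"baseline_matrix"`.
#' @param p optional matrix of per-pair p-values.
#' @param sig_mask optional logical matrix of per-pair significance.
#' @param labels optional per-unit subnetwork tags.
#' @param meta list of estimation metadata (d, tau, folds, n_surrogates, ...).
#' @return A `conn_matrix` object (list with the above fields).
#' @keywords internal
#' @export
new_conn_matrix <- function(values, method, unit_ids,
                            subclass = "baseline_matrix",
                            p = NULL, sig_mask = NULL, labels = NULL,
                            meta = list()) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("connectivity matrix must be square")
  if (length(unit_ids) != n) stop("unit_ids must match matrix dimension")
  dimnames(values) <- list(target = unit_ids, source = unit_ids)
  diag(values) <- NA_real_
  check_mask <- function(m, what) {
    if (!is.null(m) && !identical(dim(m), dim(values))) {
      stop(what, " shape does not match values")
    }
    if (!is.null(m)) dimnames(m) <- dimnames(values)
    m
  }
  p <- check_mask(p, "p")
  sig_mask <- check_mask(sig_mask, "sig_mask")
  if (!is.null(sig_mask)) sig_mask[is.na(values)] <- FALSE
  structure(list(values = values, p = p, sig_mask = sig_mask,
                 method = method, unit_ids = as.character(unit_ids),
                 labels = labels, meta = meta),
            class = c(subclass, "conn_matrix"))
}

#' @export
print.conn_matrix <- function(x, ...) {
  n_sig <- if (is.null(x$sig_mask)) NA_integer_ else sum(x$sig_mask, na.rm = TRUE)
  cat(sprintf("<%s> %d x %d (rows = targets, cols = sources), method = %s\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$method))
  if (!is.na(n_sig)) cat(sprintf("  significant pairs: %d / %d\n",
                                 n_sig, sum(!is.na(x$values))))
  invisible(x)
}

#' Tidy a connectivity matrix into one row per ordered pair
#'
#' @param x a `conn_matrix` (causal flow, interventional connectivity or
#'   baseline).
#' @param ... unused.
#' @return A tibble with columns `target`, `source`, `value`, and where
#'   available `p` and `significant`; diagonal and undefined entries are
#'   dropped.
#' @export
tidy.conn_matrix <- function(x, ...) {
  ids <- x$unit_ids
  out <- tibble::tibble(
    target = rep(ids, times = length(ids)),
    source = rep(ids, each = length(ids)),
    value = as.vector(x$values)
  )
  if (!is.null(x$p)) out$p <- as.vector(x$p)
  if (!is.null(x$sig_mask)) out$significant <- as.vector(x$sig_mask)
  if (!is.null(x$labels)) {
    lab <- setNames(x$labels, ids)
    out <- dplyr::mutate(out,
      target_label = unname(lab[.data$target]),
      source_label = unname(lab[.data$source]))
  }
  dplyr::filter(out, !is.na(.data$value))
}

#' One-row summary of a connectivity matrix
#'
#' @param x a `conn_matrix`.
#' @param ... unused.
#' @return A one-row tibble: method, number of units, defined pairs, mean
#'   value, significant-pair count and fraction (when a mask is present).
#' @export
glance.conn_matrix <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  tibble::tibble(
    method = x$method,
    n_units = length(x$unit_ids),
    n_pairs = length(v),
    mean_value = mean(v),
    n_significant = if (is.null(x$sig_mask)) NA_integer_
                    else sum(x$sig_mask, na.rm = TRUE),
    prop_significant = if (is.null(x$sig_mask)) NA_real_
                       else sum(x$sig_mask, na.rm = TRUE) / length(v)
  )
}

#' Heatmap of a connectivity matrix
#'
#' @param object a `conn_matrix`.
#' @param ... unused.
#' @return A ggplot: sources on the x axis, targets on the y axis, fill =
#'   value; significant pairs (if a mask is present) are dotted.
#' @export
autoplot.conn_matrix <- function(object, ...) {
  df <- tidy(object)
  df$target <- factor(df$target, levels = rev(object$unit_ids))
  df$source <- factor(df$source, levels = object$unit_ids)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "source", y = "target", fill = object$method) +
    ggplot2::theme_minimal()
  if (!is.null(object$sig_mask)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$significant),
      shape = 16, size = 0.8, colour = "black")
  }
  p
}
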