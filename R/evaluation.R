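#' Gini coefficient of a non-negative vector
#'
#' Population (no small-sample correction) inequality measure
#' \deqn{G = \sum_{a,b} |v_a - v_b| \; / \; (2 m^2 \bar v),}
#' used to quantify hierarchical structure in causal-flow and perturbation
#' vectors: a constant vector gives 0 (no hierarchy), samples from an
#' exponential distribution give 0.5, and concentration of the mass on few
#' targets pushes G toward 1.
#'
#' @param v numeric vector; negative entries are floored at 0 with a
#'   warning, `NA`s are dropped, and an all-zero vector is an error.
#' @return G in `[0, 1)`.
#' @examples
#' gini(c(0, 1)) # 0.5
#' @export
gini <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no non-missing values")
  if (any(v < 0)) {
    warning("negative values floored at 0 for the Gini coefficient")
    v[v < 0] <- 0
  }
  if (mean(v) <= 0) stop("undefined Gini: all values are zero")
  m <- length(v)
  vs <- sort(v)
  (2 * sum(seq_len(m) * vs)) / (m * sum(vs)) - (m + 1) / m
}

#' Synthetic electrode-array geometry
#'
#' Places units on a square grid with the four corners removed, mimicking a
#' 96-channel (10 x 10 minus corners) array layout; used to attach
#' coordinates to simulated units when a spatial analysis is requested.
#'
#' @param unit_ids unit labels (at most `n_side^2 - 4`).
#' @param n_side grid side length (default 10).
#' @param pitch electrode spacing (default 1; the 96-channel array has
#'   0.4 mm pitch over a 4 x 4 mm footprint).
#' @param seed seed for the (deterministic) assignment of units to sites.
#' @return A geometry tibble: `unit`, `x`, `y`.
#' @export
make_grid_geometry <- function(unit_ids, n_side = 10L, pitch = 1, seed = 1) {
  sites <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
  corners <- with(sites, (x %in% c(1L, n_side)) & (y %in% c(1L, n_side)))
  sites <- sites[!corners, ]
  if (length(unit_ids) > nrow(sites)) {
    stop(sprintf("too many units (%d) for a %d x %d grid minus corners",
                 length(unit_ids), n_side, n_side))
  }
  pick <- withr::with_seed(seed, sample(nrow(sites), length(unit_ids)))
  tibble::tibble(unit = as.character(unit_ids),
                 x = sites$x[pick] * pitch, y = sites$y[pick] * pitch)
}

check_geometry <- function(geom, ids) {
  if (!all(c("unit", "x", "y") %in% names(geom))) {
    stop("geometry must have columns unit, x, y")
  }
  if (!all(ids %in% geom$unit)) {
    stop("geometry does not cover units: ",
         paste(setdiff(ids, geom$unit), collapse = ", "))
  }
  if (anyDuplicated(geom[c("x", "y")])) stop("duplicate coordinates in geometry")
  geom
}

pair_distance_tbl <- function(geom, pairs) {
  gx <- setNames(geom$x, geom$unit); gy <- setNames(geom$y, geom$unit)
  dplyr::mutate(pairs, distance = sqrt(
    (gx[.data$target] - gx[.data$source])^2 +
    (gy[.data$target] - gy[.data$source])^2))
}

#' Spatial footprint of a connectivity matrix
#'
#' Mean connectivity (with s.e.m.) as a function of source-target Euclidean
#' distance, grouped into equal-width distance bins. Empty bins are kept as
#' missing rows, never interpolated.
#'
#' @param matrix a `conn_matrix` (causal flow, interventional connectivity
#'   or baseline).
#' @param geom geometry tibble (`unit`, `x`, `y`) covering all units.
#' @param bins number of equal-width distance bins, or a numeric vector of
#'   break points.
#' @return A tibble of class `footprint`: `bin`, `d_lo`, `d_hi`, `d_mid`,
#'   `mean`, `sem`, `n`.
#' @export
spatial_footprint <- function(matrix, geom, bins = 6L) {
  stopifnot(inherits(matrix, "conn_matrix"))
  geom <- check_geometry(geom, matrix$unit_ids)
  df <- pair_distance_tbl(geom, tidy(matrix))
  breaks <- if (length(bins) > 1L) bins else
    seq(0, max(df$distance) * (1 + 1e-9), length.out = bins + 1L)
  df$bin <- cut(df$distance, breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble::tibble(
    bin = seq_len(length(breaks) - 1L),
    d_lo = head(breaks, -1), d_hi = tail(breaks, -1)
  )
  smry <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(out, smry, by = "bin")
  out$n[is.na(out$n)] <- 0L
  out$d_mid <- (out$d_lo + out$d_hi) / 2
  class(out) <- c("footprint", class(out))
  out
}

#' Remove the distance trend from a connectivity matrix
#'
#' Subtracts the binned-mean spatial footprint at each pair's distance
#' (assumption-free bin-mean detrending), leaving residuals with zero mean
#' within every distance bin. With a single usable bin a warning is issued
#' and the global mean is subtracted.
#'
#' @inheritParams spatial_footprint
#' @return A `conn_matrix` of the same subclass with residual values
#'   (method tag suffixed `"_resid"`); p-values and significance masks are
#'   carried over unchanged.
#' @export
residualize_distance <- function(matrix, geom, bins = 6L) {
  stopifnot(inherits(matrix, "conn_matrix"))
  geom <- check_geometry(geom, matrix$unit_ids)
  ids <- matrix$unit_ids
  idx <- expand.grid(i = seq_along(ids), j = seq_along(ids))
  df <- tibble::tibble(target = ids[idx$i], source = ids[idx$j],
                       i = idx$i, j = idx$j,
                       value = matrix$values[cbind(idx$i, idx$j)])
  df <- pair_distance_tbl(geom, df)
  ok <- !is.na(df$value)
  breaks <- if (length(bins) > 1L) bins else
    seq(0, max(df$distance[ok]) * (1 + 1e-9), length.out = bins + 1L)
  bin <- cut(df$distance, breaks, include.lowest = TRUE, labels = FALSE)
  bm <- tapply(df$value[ok], bin[ok], mean)
  if (length(bm) <= 1L) {
    warning("single usable distance bin; subtracting the global mean")
    resid <- df$value - mean(df$value[ok])
  } else {
    resid <- df$value - unname(bm[as.character(bin)])
  }
  vals <- matrix$values
  vals[cbind(df$i, df$j)] <- resid
  new_conn_matrix(vals, method = paste0(matrix$method, "_resid"),
                  unit_ids = ids, subclass = class(matrix)[1],
                  p = matrix$p, sig_mask = matrix$sig_mask,
                  labels = matrix$labels,
                  meta = c(matrix$meta, list(resid_bins = breaks)))
}

welch_or_na <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L || (sd(a) == 0 && sd(b) == 0)) {
    return(list(mean_a = mean(a), mean_b = mean(b), t = NA_real_,
                p = NA_real_))
  }
  tt <- t.test(a, b)
  list(mean_a = mean(a), mean_b = mean(b),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Does resting connectivity predict perturbation effects?
#'
#' Joins a causal-flow (or baseline) matrix with an
#' interventional-connectivity matrix over the ordered pairs defined in
#' both and computes: the Pearson correlation and linear regression of IC
#' on the connectivity values; Welch two-group comparisons (mean IC for
#' connectivity-significant vs nonsignificant pairs, and mean connectivity
#' for IC-significant vs nonsignificant pairs); per-source Gini
#' coefficients of both column vectors; and, when a geometry is supplied,
#' the same statistics after bin-mean distance residualization of both
#' matrices (computed on the identical pair set).
#'
#' @param cf a `cf_matrix` or `baseline_matrix`.
#' @param ic an `ic_matrix` on the same unit set.
#' @param geom optional geometry tibble for the residualized variants.
#' @param bins distance bins for residualization.
#' @return A `cf_ic_report`: list with `pairs` (the joined tibble), `stats`
#'   (named list of test results), `gini_per_source`, and `method`.
#'   Group tests with an empty group are flagged not-computable (`NA`).
#' @seealso [tidy.cf_ic_report()], [glance.cf_ic_report()]
#' @export
prediction_tests <- function(cf, ic, geom = NULL, bins = 6L) {
  stopifnot(inherits(cf, "conn_matrix"), inherits(ic, "ic_matrix"))
  if (!identical(cf$unit_ids, ic$unit_ids)) {
    common <- intersect(cf$unit_ids, ic$unit_ids)
    if (length(common) < 2L) stop("cf and ic share fewer than 2 units")
    warning("cf and ic unit sets differ; using their ", length(common),
            "-unit intersection")
  }
  cf_t <- dplyr::rename(tidy(cf), cf = "value")
  ic_t <- dplyr::rename(tidy(ic), ic = "value")
  keep <- intersect(names(cf_t), c("target", "source", "cf", "significant"))
  cf_t <- cf_t[keep]
  if ("significant" %in% names(cf_t)) {
    cf_t <- dplyr::rename(cf_t, cf_sig = "significant")
  }
  keep <- intersect(names(ic_t), c("target", "source", "ic", "significant"))
  ic_t <- ic_t[keep]
  if ("significant" %in% names(ic_t)) {
    ic_t <- dplyr::rename(ic_t, ic_sig = "significant")
  }
  pairs <- dplyr::inner_join(cf_t, ic_t, by = c("target", "source"))
  if (nrow(pairs) < 3L) stop("fewer than 3 pairs defined in both matrices")

  core_stats <- function(df) {
    ct <- stats::cor.test(df$cf, df$ic)
    fit <- lm(ic ~ cf, data = df)
    sm <- summary(fit)
    out <- list(
      n_pairs = nrow(df),
      pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
      regression_slope = unname(coef(fit)[2]),
      slope_p = sm$coefficients[2, 4],
      r_squared = sm$r.squared
    )
    if ("cf_sig" %in% names(df) && !all(is.na(df$cf_sig))) {
      g <- welch_or_na(df$ic[df$cf_sig %in% TRUE], df$ic[df$cf_sig %in% FALSE])
      out$ic_by_cf_sig <- g
    }
    if ("ic_sig" %in% names(df) && !all(is.na(df$ic_sig))) {
      g <- welch_or_na(df$cf[df$ic_sig %in% TRUE], df$cf[df$ic_sig %in% FALSE])
      out$cf_by_ic_sig <- g
    }
    out
  }
  stats_raw <- core_stats(pairs)
  stats_resid <- NULL
  if (!is.null(geom)) {
    cf_r <- dplyr::rename(tidy(residualize_distance(cf, geom, bins)),
                          cf = "value")
    ic_r <- dplyr::rename(tidy(residualize_distance(ic, geom, bins)),
                          ic = "value")
    pr <- dplyr::inner_join(cf_r[c("target", "source", "cf")],
                            ic_r[c("target", "source", "ic")],
                            by = c("target", "source"))
    pr <- dplyr::inner_join(pr, pairs[c("target", "source",
                                        intersect(names(pairs),
                                                  c("cf_sig", "ic_sig")))],
                            by = c("target", "source"))
    stats_resid <- core_stats(pr)
  }
  gini_src <- pairs |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(
      gini_cf = suppressWarnings(gini(.data$cf)),
      gini_ic = suppressWarnings(gini(.data$ic)), .groups = "drop")
  structure(list(pairs = pairs, stats = stats_raw,
                 stats_residual = stats_resid,
                 gini_per_source = gini_src, method = cf$method),
            class = "cf_ic_report")
}

#' @export
print.cf_ic_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<cf_ic_report> %s vs IC over %d pairs\n", x$method, s$n_pairs))
  cat(sprintf("  Pearson r = %.3f (p = %.3g); slope = %.3f (p = %.3g)\n",
              s$pearson_r, s$pearson_p, s$regression_slope, s$slope_p))
  if (!is.null(s$ic_by_cf_sig)) {
    g <- s$ic_by_cf_sig
    cat(sprintf("  mean IC | CF sig = %.4f vs nonsig = %.4f (t = %.2f, p = %.3g)\n",
                g$mean_a, g$mean_b, g$t, g$p))
  }
  if (!is.null(x$stats_residual)) {
    cat(sprintf("  residualized: r = %.3f (p = %.3g)\n",
                x$stats_residual$pearson_r, x$stats_residual$pearson_p))
  }
  invisible(x)
}

report_stats_tbl <- function(s, variant) {
  rows <- list(
    c("pearson_r", s$pearson_r, s$pearson_p),
    c("regression_slope", s$regression_slope, s$slope_p)
  )
  if (!is.null(s$ic_by_cf_sig)) {
    rows <- c(rows, list(c("mean_ic_diff_by_cf_sig",
                           s$ic_by_cf_sig$mean_a - s$ic_by_cf_sig$mean_b,
                           s$ic_by_cf_sig$p)))
  }
  if (!is.null(s$cf_by_ic_sig)) {
    rows <- c(rows, list(c("mean_cf_diff_by_ic_sig",
                           s$cf_by_ic_sig$mean_a - s$cf_by_ic_sig$mean_b,
                           s$cf_by_ic_sig$p)))
  }
  tibble::tibble(
    variant = variant,
    statistic = vapply(rows, `[`, character(1), 1),
    estimate = as.numeric(vapply(rows, `[`, character(1), 2)),
    p.value = as.numeric(vapply(rows, `[`, character(1), 3))
  )
}

#' @describeIn prediction_tests tidy the report into one row per statistic
#'   (columns `variant`, `statistic`, `estimate`, `p.value`).
#' @param x a `cf_ic_report`.
#' @param ... unused.
#' @export
tidy.cf_ic_report <- function(x, ...) {
  out <- report_stats_tbl(x$stats, "raw")
  if (!is.null(x$stats_residual)) {
    out <- dplyr::bind_rows(out, report_stats_tbl(x$stats_residual, "residual"))
  }
  out
}

#' @describeIn prediction_tests one-row summary (r, slope, group-test p's).
#' @export
glance.cf_ic_report <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    method = x$method, n_pairs = s$n_pairs,
    pearson_r = s$pearson_r, pearson_p = s$pearson_p,
    regression_slope = s$regression_slope, slope_p = s$slope_p,
    ic_by_cf_sig_p = if (is.null(s$ic_by_cf_sig)) NA_real_ else s$ic_by_cf_sig$p,
    cf_by_ic_sig_p = if (is.null(s$cf_by_ic_sig)) NA_real_ else s$cf_by_ic_sig$p,
    residual_r = if (is.null(x$stats_residual)) NA_real_
                 else x$stats_residual$pearson_r
  )
}

#' Hierarchy of causal-flow vectors by principal components
#'
#' Projects the causal-flow column vectors `f^(j)` (one observation per
#' source unit; the undefined diagonal entry is replaced by the column mean)
#' onto their first two principal components and clusters the scores with
#' 2-means. On the simulated driver/driven network this separates the
#' upstream and downstream subnetworks.
#'
#' @param cf a `cf_matrix` (or any `conn_matrix`) with at least 3 units.
#' @param seed seed for the k-means initialization.
#' @return A tibble: `unit`, `label` (if known), `PC1`, `PC2`, `cluster`,
#'   with attributes `silhouette` (mean silhouette width on the 2-D scores;
#'   ~0 flags no real cluster structure) and `var_explained`.
#' @export
cf_hierarchy_pca <- function(cf, seed = 1) {
  stopifnot(inherits(cf, "conn_matrix"))
  n <- length(cf$unit_ids)
  if (n < 3L) stop("need at least 3 units")
  X <- t(cf$values) # rows = source vectors f^(j)
  for (r in seq_len(n)) {
    miss <- is.na(X[r, ])
    X[r, miss] <- mean(X[r, !miss])
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  spread <- sum(apply(sc, 2, sd))
  if (spread < 1e-10) {
    out <- tibble::tibble(unit = cf$unit_ids, PC1 = sc[, 1], PC2 = sc[, 2],
                          cluster = 1L)
    attr(out, "silhouette") <- 0
    attr(out, "var_explained") <- NA_real_
    return(out)
  }
  km <- withr::with_seed(seed, kmeans(sc, centers = 2L, nstart = 10))
  sil <- {
    D <- as.matrix(stats::dist(sc))
    s_i <- vapply(seq_len(n), function(i) {
      own <- which(km$cluster == km$cluster[i]); own <- own[own != i]
      oth <- which(km$cluster != km$cluster[i])
      if (length(own) == 0L || length(oth) == 0L) return(0)
      a <- mean(D[i, own]); b <- mean(D[i, oth])
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s_i)
  }
  out <- tibble::tibble(unit = cf$unit_ids, PC1 = sc[, 1], PC2 = sc[, 2],
                        cluster = unname(km$cluster))
  if (!is.null(cf$labels)) out <- dplyr::mutate(out, label = cf$labels,
                                                .after = "unit")
  attr(out, "silhouette") <- sil
  attr(out, "var_explained") <-
    sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  out
}
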