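# Two-sided Mann-Whitney p-value: exact enumeration for small tie-free
# samples, normal approximation with tie correction otherwise.
mw_p <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  exact <- max(length(x), length(y)) <= 20 && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Glass's delta effect size
#'
#' Absolute standardized mean difference using only the control group's
#' (sample, n-1) standard deviation:
#' \deqn{\Delta = |M_1 - M_2| / \sigma_{control}.}
#' Values above 0.8 are flagged as a significant effect. Note the documented
#' asymmetry: swapping the groups changes the standardizer.
#'
#' @param experimental,control numeric vectors; the control group needs
#'   `n >= 2` and positive SD.
#' @return the effect size, with attribute `significant` (`Delta > 0.8`).
#' @export
glass_delta <- function(experimental, control) {
  experimental <- experimental[is.finite(experimental)]
  control <- control[is.finite(control)]
  of_check(length(control) >= 2, "control group needs at least 2 values")
  s <- stats::sd(control)
  if (!is.finite(s) || s == 0) {
    of_stop("control group has zero standard deviation", "omiflim_degenerate_control")
  }
  d <- abs(mean(experimental) - mean(control)) / s
  attr(d, "significant") <- d > 0.8
  d
}

#' Group comparisons over the twelve OMI parameters
#'
#' For each parameter, a two-sided Mann-Whitney test between the two groups
#' and Glass's delta standardized by the designated control group
#' (e.g. spleen when comparing tissues, immune cells when comparing cell
#' types within a tumor). No multiple-testing correction is applied;
#' significance is instead gated on `Delta > 0.8`.
#'
#' @param table a feature table (see [extract_cell_features]).
#' @param split_key column that defines the two groups (e.g. `"tissue"`).
#' @param control_label value of `split_key` designating the control group.
#' @param parameters parameter columns to compare (default [omi_parameters]).
#' @return data frame with one row per parameter: `parameter`,
#'   `mean_experimental`, `mean_control`, `sd_control`, `glass_delta`,
#'   `significant`, `mw_p`, `n_experimental`, `n_control`, `control_label`.
#' @export
compare_groups <- function(table, split_key = "tissue", control_label = "spleen",
                           parameters = omi_parameters()) {
  of_check(split_key %in% names(table), sprintf("no column '%s'", split_key),
           "omiflim_config_error")
  groups <- unique(table[[split_key]])
  of_check(control_label %in% groups,
           sprintf("control label '%s' absent from '%s'", control_label, split_key),
           "omiflim_config_error")
  exp_labels <- setdiff(groups, control_label)
  of_check(length(exp_labels) == 1,
           "split key must define exactly two groups", "omiflim_config_error")
  ctrl <- table[table[[split_key]] == control_label, , drop = FALSE]
  expg <- table[table[[split_key]] == exp_labels, , drop = FALSE]
  rows <- lapply(parameters, function(p) {
    x <- expg[[p]]; y <- ctrl[[p]]
    d <- glass_delta(x, y)
    data.frame(parameter = p,
               mean_experimental = mean(x, na.rm = TRUE),
               mean_control = mean(y, na.rm = TRUE),
               sd_control = stats::sd(y[is.finite(y)]),
               glass_delta = as.numeric(d),
               significant = attr(d, "significant"),
               mw_p = mw_p(x, y),
               n_experimental = sum(is.finite(x)), n_control = sum(is.finite(y)),
               control_label = control_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clipped z-score matrix of per-cell OMI parameters
#'
#' Standardizes every parameter over all cells jointly (sample SD) and clips
#' the result to `[-clip, clip]` standard deviations (default 4). Constant
#' columns standardize to zero with a warning.
#'
#' @param table a feature table with at least 2 rows.
#' @param parameters columns to standardize (default [omi_parameters]).
#' @param clip clipping bound in SD units.
#' @return object of class `omi_zscore`: list with `z` (cells x parameters
#'   matrix) and `meta` (data frame with `cell_type`, `tissue`, `mouse_id`,
#'   `fov_id`, `cell_id`).
#' @export
zscore_matrix <- function(table, parameters = omi_parameters(), clip = 4) {
  if (nrow(table) < 2) {
    of_stop("z-scores need at least 2 cells", "omiflim_insufficient_data")
  }
  m <- as.matrix(table[, parameters, drop = FALSE])
  z <- apply(m, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) {
      warning("constant parameter column standardized to zeros")
      return(rep(0, length(col)))
    }
    (col - mean(col)) / s
  })
  z <- pmin(pmax(z, -clip), clip)
  meta_cols <- intersect(c("cell_type", "tissue", "mouse_id", "fov_id", "cell_id"),
                         names(table))
  structure(list(z = z, meta = table[, meta_cols, drop = FALSE], clip = clip),
            class = "omi_zscore")
}

#' Ward hierarchical clustering of cells
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between the z-scored parameter rows. Metadata (cell
#' type, tissue, mouse) never enters the distances.
#'
#' @param z an `omi_zscore` or a numeric matrix (rows = cells).
#' @param k optional number of flat clusters to cut.
#' @return object of class `omi_clustering`: list with `hclust`, `order`
#'   (leaf order) and, when `k` is given, `labels` (flat assignments).
#' @export
ward_cluster <- function(z, k = NULL) {
  m <- if (inherits(z, "omi_zscore")) z$z else as.matrix(z)
  of_check(nrow(m) >= 2, "clustering needs at least 2 rows")
  if (anyNA(m)) of_stop("NaN/NA in the z-score matrix", "omiflim_data_error")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  res <- list(hclust = hc, order = hc$order,
              labels = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
  structure(res, class = "omi_clustering")
}

#' Export statistics artifacts as CSV
#'
#' `write_comparison_csv` writes a [compare_groups] report;
#' `write_zscore_csv` writes the z-score matrix with metadata columns
#' prefixed `meta_`; `write_linkage_csv` writes the merge table and leaf
#' order of an [ward_cluster] result.
#'
#' @param x the object to write.
#' @param path output path.
#' @export
write_comparison_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
write_zscore_csv <- function(x, path) {
  of_check(inherits(x, "omi_zscore"), "x must be an omi_zscore")
  meta <- x$meta
  names(meta) <- paste0("meta_", names(meta))
  utils::write.csv(cbind(meta, as.data.frame(x$z)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
write_linkage_csv <- function(x, path) {
  of_check(inherits(x, "omi_clustering"), "x must be an omi_clustering")
  hc <- x$hclust
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  utils::write.csv(merges, path, row.names = FALSE)
  writeLines(paste(hc$order, collapse = ","), paste0(path, ".leaforder"))
  invisible(path)
}
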