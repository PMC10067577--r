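#' The twelve OMI parameters
#'
#' Column names of the per-cell optical metabolic imaging parameter set:
#' five NAD(P)H lifetime endpoints, five FAD lifetime endpoints, cell size
#' and the optical redox ratio.
#'
#' @return character vector of length 12.
#' @export
omi_parameters <- function() {
  c("nadph_tau1", "nadph_tau2", "nadph_alpha1", "nadph_alpha2", "nadph_tau_m",
    "fad_tau1", "fad_tau2", "fad_alpha1", "fad_alpha2", "fad_tau_m",
    "cell_size", "redox_ratio")
}

feature_schema <- function() {
  c("cell_id", "fov_id", "mouse_id", "tissue", "cell_type", omi_parameters())
}

empty_feature_table <- function() {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(feature_schema())),
                               feature_schema()), stringsAsFactors = FALSE)
  for (col in c("fov_id", "mouse_id", "tissue", "cell_type")) df[[col]] <- character(0)
  df$cell_id <- integer(0)
  df
}

weighted_or_plain_mean <- function(x, w, weighted) {
  ok <- is.finite(x)
  if (!any(ok)) return(NA_real_)
  if (weighted) {
    w <- w[ok]
    if (sum(w) <= 0) w <- rep(1, sum(ok))
    sum(x[ok] * w) / sum(w)
  } else mean(x[ok])
}

#' Per-cell OMI feature extraction
#'
#' Aggregates per-pixel fit maps into one record per labelled cell:
#' photon-weighted means of every fitted parameter over non-`NaN` pixels
#' (weights are the pixel photon counts of that channel), a redox ratio from
#' the summed per-cell NAD(P)H and FAD intensities, and the cell size in
#' pixels. Cells with no fittable pixel in either channel are excluded with a
#' message.
#'
#' @param labels integer label mask.
#' @param nadph_maps,fad_maps fit-map lists from [fit_pixels] (fields `tau1`,
#'   `tau2`, `alpha1`, `alpha2`, `tau_m`), or per-cell fit tables from
#'   [fit_cells] (data frames keyed by `label`).
#' @param nadph_intensity,fad_intensity photon-count matrices.
#' @param fov_id,mouse_id,tissue,cell_type provenance labels attached to every
#'   record.
#' @param weighted photon-weighted (default) or unweighted parameter means.
#' @return a feature table: one row per cell, columns
#'   `cell_id, fov_id, mouse_id, tissue, cell_type` plus [omi_parameters].
#' @export
extract_cell_features <- function(labels, nadph_maps, fad_maps,
                                  nadph_intensity, fad_intensity,
                                  fov_id = "FOV1", mouse_id = "M1",
                                  tissue = NA_character_, cell_type = "immune",
                                  weighted = TRUE) {
  of_check(all(dim(labels) == dim(nadph_intensity)) &&
             all(dim(labels) == dim(fad_intensity)),
           "mask and intensity shapes differ", "omiflim_dimension_error")
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) return(empty_feature_table())
  param_fields <- c("tau1", "tau2", "alpha1", "alpha2", "tau_m")
  per_cell_tables <- is.data.frame(nadph_maps)

  rows <- lapply(labs, function(l) {
    idx <- which(labels == l)
    n_sum <- sum(nadph_intensity[idx])
    f_sum <- sum(fad_intensity[idx])
    if (per_cell_tables) {
      nr <- nadph_maps[nadph_maps$label == l, , drop = FALSE]
      fr <- fad_maps[fad_maps$label == l, , drop = FALSE]
      if (!nrow(nr) || !nrow(fr) || anyNA(nr$tau_m) || anyNA(fr$tau_m)) {
        message(sprintf("cell %d: no usable fit; excluded", l))
        return(NULL)
      }
      nvals <- unlist(nr[1, param_fields])
      fvals <- unlist(fr[1, param_fields])
    } else {
      nvals <- vapply(param_fields, function(p)
        weighted_or_plain_mean(nadph_maps[[p]][idx], nadph_intensity[idx], weighted),
        numeric(1))
      fvals <- vapply(param_fields, function(p)
        weighted_or_plain_mean(fad_maps[[p]][idx], fad_intensity[idx], weighted),
        numeric(1))
      if (anyNA(nvals) || anyNA(fvals)) {
        message(sprintf("cell %d: no fittable pixels; excluded", l))
        return(NULL)
      }
    }
    if (n_sum + f_sum == 0) {
      message(sprintf("cell %d: zero intensity in both channels; excluded", l))
      return(NULL)
    }
    data.frame(cell_id = as.integer(l), fov_id = fov_id, mouse_id = mouse_id,
               tissue = tissue, cell_type = cell_type,
               nadph_tau1 = nvals[1], nadph_tau2 = nvals[2],
               nadph_alpha1 = nvals[3], nadph_alpha2 = nvals[4],
               nadph_tau_m = nvals[5],
               fad_tau1 = fvals[1], fad_tau2 = fvals[2],
               fad_alpha1 = fvals[3], fad_alpha2 = fvals[4], fad_tau_m = fvals[5],
               cell_size = length(idx),
               redox_ratio = redox_ratio(n_sum, f_sum),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_feature_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine per-FOV feature tables
#'
#' Concatenates feature tables from multiple fields of view / mice, enforcing
#' a consistent schema and uniqueness of `(fov_id, cell_id)`.
#'
#' @param tables list of feature tables (possibly empty).
#' @return one feature table.
#' @export
build_feature_table <- function(tables) {
  if (!length(tables)) return(empty_feature_table())
  for (tb in tables) {
    of_check(all(feature_schema() %in% names(tb)),
             "feature table is missing schema columns", "omiflim_integrity_error")
  }
  out <- do.call(rbind, lapply(tables, function(tb) tb[, feature_schema()]))
  rownames(out) <- NULL
  key <- paste(out$fov_id, out$cell_id, sep = "::")
  if (anyDuplicated(key)) {
    of_stop("duplicate (fov_id, cell_id) keys in feature tables",
            "omiflim_integrity_error")
  }
  out
}

#' Write / read a feature table as annotated CSV
#'
#' The CSV carries a `#`-prefixed header documenting units (lifetimes in
#' picoseconds, weights and redox ratio as fractions, cell size in pixels)
#' and round-trips losslessly.
#'
#' @param table a feature table.
#' @param path output path.
#' @export
write_feature_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# omiflim single-cell OMI feature table",
    "# units: *_tau1/*_tau2/*_tau_m picoseconds; *_alpha1/*_alpha2 fractions (sum 1);",
    "#        redox_ratio fraction N/(N+F); cell_size pixels"), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
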