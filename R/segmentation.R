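#' Segmentation pipeline configuration
#'
#' Every tunable of the lifetime-gated ensemble segmentation pipeline.
#'
#' @param gate_low,gate_high inclusive lifetime gate bounds in picoseconds
#'   (default 800-1500 ps, the band that separates the fluorescent-protein
#'   label from non-specific red autofluorescence).
#' @param threshold_methods character vector of threshold specs
#'   (see [threshold_intensity]); defaults to the 25-spec ensemble of
#'   [default_threshold_specs].
#' @param local_block,local_offset adaptive ("local") threshold parameters.
#' @param canny_sigma Gaussian smoothing (px) of the edge detector.
#' @param canny_low,canny_high hysteresis thresholds as quantiles of the
#'   gradient magnitude.
#' @param expansion_modes region-expansion modes to include in the ensemble
#'   (`"dilate"`, `"close"`).
#' @param struct_radius_1,struct_radius_2 disc radii (px) of the two
#'   expansion rounds.
#' @param min_area small-item filter: minimum region area in pixels.
#' @param connectivity pixel connectivity for labelling (4 or 8).
#' @param voting_mode `"per_image_argmax"` (pick the best variant per image
#'   by Dice against ground truth) or `"global_calibration"` (pick one
#'   variant by mean Dice over a calibration set, then apply it everywhere).
#' @param gate_bin,gate_min_photons spatial binning and photon floor used
#'   when deriving the gating lifetime map from a decay cube
#'   (see [lifetime_map_com]).
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(gate_low = 800, gate_high = 1500,
                                threshold_methods = default_threshold_specs(),
                                local_block = 33, local_offset = 1,
                                canny_sigma = 1, canny_low = 0.1, canny_high = 0.9,
                                expansion_modes = c("dilate", "close"),
                                struct_radius_1 = 2, struct_radius_2 = 1,
                                min_area = 20, connectivity = 8,
                                voting_mode = c("per_image_argmax", "global_calibration"),
                                gate_bin = 3, gate_min_photons = 50) {
  voting_mode <- match.arg(voting_mode)
  of_check(gate_low < gate_high, "gate_low must be below gate_high", "omiflim_config_error")
  of_check(min_area >= 1, "min_area must be >= 1", "omiflim_config_error")
  of_check(connectivity %in% c(4, 8), "connectivity must be 4 or 8", "omiflim_config_error")
  of_check(all(expansion_modes %in% c("dilate", "close")) && length(expansion_modes) >= 1,
           "expansion_modes must be a subset of {dilate, close}", "omiflim_config_error")
  structure(list(gate_low = gate_low, gate_high = gate_high,
                 threshold_methods = threshold_methods,
                 local_block = local_block, local_offset = local_offset,
                 canny_sigma = canny_sigma, canny_low = canny_low, canny_high = canny_high,
                 expansion_modes = expansion_modes,
                 struct_radius_1 = struct_radius_1, struct_radius_2 = struct_radius_2,
                 min_area = min_area, connectivity = connectivity,
                 voting_mode = voting_mode,
                 gate_bin = gate_bin, gate_min_photons = gate_min_photons),
            class = "segmentation_config")
}

#' Lifetime gate
#'
#' Keeps pixels whose mean lifetime lies inside the inclusive
#' `[low, high]` band; `NaN`/`NA` pixels (unfittable) are excluded.
#'
#' @param lifetime numeric matrix of lifetimes in picoseconds.
#' @param low,high gate bounds in picoseconds, `low < high`.
#' @return logical matrix.
#' @export
gate_lifetime <- function(lifetime, low = 800, high = 1500) {
  of_check(low < high, "inverted lifetime gate", "omiflim_config_error")
  m <- !is.na(lifetime) & lifetime >= low & lifetime <= high
  m[is.na(m)] <- FALSE
  m
}

#' Merge intensity foreground with the lifetime gate
#'
#' Pixelwise conjunction: the thresholded-intensity mask supplies the
#' candidate ("left") pixels, the lifetime gate prunes them.
#'
#' @param fg,gate logical matrices of identical shape.
#' @return logical matrix.
#' @export
merge_intensity_lifetime <- function(fg, gate) {
  of_check(all(dim(fg) == dim(gate)), "mask shapes differ", "omiflim_dimension_error")
  fg & gate
}

#' Connected-component labelling
#'
#' Labels foreground regions 1..K in raster (column-major) first-occurrence
#' order. 4-connectivity labels come from a two-pass pass; 8-connectivity
#' additionally merges diagonal-adjacent regions.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  of_check(connectivity %in% c(4, 8), "connectivity must be 4 or 8", "omiflim_config_error")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)  # 4-connected base labelling
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1) {
    ny <- nrow(lab); nx <- ncol(lab)
    a1 <- lab[-ny, -nx]; b1 <- lab[-1, -1]    # down-right diagonal pairs
    a2 <- lab[-1, -nx];  b2 <- lab[-ny, -1]   # up-right diagonal pairs
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  relabel_contiguous(lab)
}

# Renumber labels 1..K in column-major first-occurrence order (deterministic).
relabel_contiguous <- function(lab) {
  v <- as.vector(lab)
  u <- unique(v[v > 0])
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- integer(length(v)); out[v > 0] <- map[v[v > 0]]
  matrix(out, nrow(lab), ncol(lab))
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding at gradient-magnitude quantiles.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian smoothing in pixels.
#' @param low_q,high_q hysteresis quantiles of the positive gradient
#'   magnitudes.
#' @return logical edge matrix.
#' @export
canny_edges <- function(img, sigma = 1, low_q = 0.1, high_q = 0.9) {
  g <- EBImage::gblur(img, sigma = sigma, boundary = "replicate")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(g, kx, boundary = "replicate")
  gy <- EBImage::filter2(g, t(kx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(matrix(FALSE, nrow(img), ncol(img)))
  ny <- nrow(img); nx <- ncol(img)
  shift <- function(m, dy, dx) {
    out <- matrix(0, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
    out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  dyx <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(FALSE, ny, nx)
  for (s in 0:3) {
    d <- dyx[[s + 1]]
    keep <- sector == s & mag >= shift(mag, d[1], d[2]) & mag >= shift(mag, -d[1], -d[2])
    nms <- nms | keep
  }
  nms <- nms & mag > 0
  qs <- stats::quantile(mag[mag > 0], c(low_q, high_q), names = FALSE)
  strong <- nms & mag >= qs[2]
  weak <- nms & mag >= qs[1]
  if (!any(strong)) return(strong)
  wl <- label_components(weak, 8)
  keep_labels <- unique(wl[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  matrix(wl %in% keep_labels, ny, nx) & weak
}

# Distance-based nearest-label assignment for a set of pixel indices.
# Ties go to the lower label; max_dist (if finite) caps how far a region may
# claim pixels.
assign_nearest <- function(labels, idx, max_dist = Inf) {
  if (!length(idx)) return(labels)
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) return(labels)
  D <- vapply(labs, function(l) {
    dm <- EBImage::distmap(matrix(as.numeric(labels != l), nrow(labels), ncol(labels)))
    as.vector(dm)[idx]
  }, numeric(length(idx)))
  D <- matrix(D, nrow = length(idx))
  best <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_along(idx), best)]
  ok <- dmin <= max_dist
  labels[idx[ok]] <- labs[best[ok]]
  labels
}

#' Label regions in a binary mask via edge-guided labelling
#'
#' Canny edges delineate region boundaries; connected components of the
#' edge-free interior seed the labels and remaining mask pixels are assigned
#' to the nearest seed (label-aware, ties to the lower label).
#'
#' @param mask logical matrix.
#' @param canny_sigma edge-detector smoothing (px).
#' @param connectivity 4 or 8.
#' @param canny_low,canny_high hysteresis quantiles.
#' @return integer label matrix.
#' @export
label_rois <- function(mask, canny_sigma = 1, connectivity = 8,
                       canny_low = 0.1, canny_high = 0.9) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  edges <- canny_edges(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       sigma = canny_sigma, low_q = canny_low, high_q = canny_high)
  core <- mask & !edges
  if (!any(core)) return(label_components(mask, connectivity))
  labels <- label_components(core, connectivity)
  assign_nearest(labels, which(mask & !core))
}

#' Label-aware region expansion
#'
#' Expands every labelled region by binary dilation or closing with a disc
#' structuring element. Expansion is label-aware: a region never absorbs
#' another region's pixels; contested new pixels go to the nearest region
#' (ties to the lower label).
#'
#' @param labels integer label matrix.
#' @param radius disc radius in pixels (0 = no-op).
#' @param mode `"dilate"` or `"close"`.
#' @return integer label matrix.
#' @export
expand_labels <- function(labels, radius, mode = c("dilate", "close")) {
  mode <- match.arg(mode)
  if (radius < 1 || !any(labels > 0)) return(labels)
  fg <- matrix(as.numeric(labels > 0), nrow(labels), ncol(labels))
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  allowed <- if (mode == "dilate") EBImage::dilate(fg, brush) else EBImage::closing(fg, brush)
  new_idx <- which(allowed > 0 & fg == 0)
  assign_nearest(labels, new_idx)
}

# Remove regions touching the image boundary.
clear_border <- function(labels) {
  edge_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)]))
  edge_labels <- edge_labels[edge_labels > 0]
  if (length(edge_labels)) labels[labels %in% edge_labels] <- 0L
  relabel_contiguous(labels)
}

# Boundary recomputation: split any label whose support is no longer a single
# connected component.
split_disconnected <- function(labels, connectivity = 8) {
  labs <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  for (l in labs) {
    sub <- label_components(labels == l, connectivity)
    k <- max(sub)
    out[sub > 0] <- sub[sub > 0] + nxt
    nxt <- nxt + k
  }
  relabel_contiguous(out)
}

# Drop regions smaller than min_area pixels.
area_filter <- function(labels, min_area) {
  if (!any(labels > 0)) return(labels)
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_contiguous(labels)
}

#' Morphological refinement of labelled regions
#'
#' Applies, in order: expansion round 1, border clearing (any region touching
#' the frame is removed), boundary recomputation (disconnected labels are
#' split), expansion round 2 (clipped at the frame), and the small-item area
#' filter. Output labels are contiguous.
#'
#' @param labels integer label matrix.
#' @param cfg a [segmentation_config].
#' @param expansion_mode `"dilate"` or `"close"` (defaults to the first
#'   entry of `cfg$expansion_modes`).
#' @return integer label matrix.
#' @export
refine_rois <- function(labels, cfg = segmentation_config(),
                        expansion_mode = cfg$expansion_modes[1]) {
  l <- expand_labels(labels, cfg$struct_radius_1, expansion_mode)
  l <- clear_border(l)
  l <- split_disconnected(l, cfg$connectivity)
  l <- expand_labels(l, cfg$struct_radius_2, expansion_mode)
  area_filter(l, cfg$min_area)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`; symmetric.
#'
#' @param a,b logical (or coercible) masks of identical shape, not both empty.
#' @return the Dice coefficient.
#' @export
dice_coefficient <- function(a, b) {
  of_check(all(dim(a) == dim(b)), "mask shapes differ", "omiflim_dimension_error")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) of_stop("Dice undefined for two empty masks", "omiflim_undefined_dice")
  2 * sum(a & b) / (na + nb)
}

#' Run one segmentation variant
#'
#' Executes gate, threshold, merge, edge labelling and refinement for a single
#' (threshold method, expansion mode) variant. Deterministic for fixed inputs.
#' A degenerate (constant) image under a histogram method falls back to an
#' empty foreground with a message.
#'
#' @param intensity photon-count matrix.
#' @param lifetime lifetime map in picoseconds (`NaN` = unfittable).
#' @param variant list with elements `method` (threshold spec) and
#'   `expansion` (`"dilate"` or `"close"`).
#' @param cfg a [segmentation_config].
#' @return a candidate: list with `variant_id`, `mask` (label matrix),
#'   `n_cells`, `dice` (`NA` until scored).
#' @export
run_variant <- function(intensity, lifetime, variant, cfg = segmentation_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, omiflim_error = function(e) {
      of_stop(sprintf("[%s] %s", name, conditionMessage(e)), class(e)[1])
    })
  }
  gate <- stage("gate", gate_lifetime(lifetime, cfg$gate_low, cfg$gate_high))
  fg <- tryCatch(
    threshold_intensity(intensity, variant$method, cfg$local_block, cfg$local_offset),
    omiflim_degenerate_image = function(e) {
      message(sprintf("[threshold %s] degenerate image; empty foreground", variant$method))
      matrix(FALSE, nrow(intensity), ncol(intensity))
    })
  merged <- stage("merge", merge_intensity_lifetime(fg, gate))
  labels <- stage("label", label_rois(merged, cfg$canny_sigma, cfg$connectivity,
                                      cfg$canny_low, cfg$canny_high))
  refined <- stage("refine", refine_rois(labels, cfg, variant$expansion))
  list(variant_id = paste(variant$method, variant$expansion, sep = "/"),
       mask = refined, n_cells = max(refined), dice = NA_real_)
}

#' Run the full variant ensemble on one field of view
#'
#' Evaluates every (threshold spec, expansion mode) combination of the
#' configuration. Threshold masks and edge labelling are shared across
#' expansion modes for speed.
#'
#' @inheritParams run_variant
#' @return list of candidates (see [run_variant]).
#' @export
run_variants <- function(intensity, lifetime, cfg = segmentation_config()) {
  gate <- gate_lifetime(lifetime, cfg$gate_low, cfg$gate_high)
  empty <- matrix(FALSE, nrow(intensity), ncol(intensity))
  out <- list()
  # distinct threshold specs often yield identical merged masks; label and
  # refine each distinct mask once
  cache_masks <- list(); cache_refined <- list()
  for (method in cfg$threshold_methods) {
    fg <- tryCatch(
      threshold_intensity(intensity, method, cfg$local_block, cfg$local_offset),
      omiflim_degenerate_image = function(e) {
        message(sprintf("[threshold %s] degenerate image; empty foreground", method))
        empty
      })
    merged <- merge_intensity_lifetime(fg, gate)
    hit <- 0L
    for (j in seq_along(cache_masks)) {
      if (identical(cache_masks[[j]], merged)) { hit <- j; break }
    }
    if (!hit) {
      labels <- label_rois(merged, cfg$canny_sigma, cfg$connectivity,
                           cfg$canny_low, cfg$canny_high)
      refined <- lapply(cfg$expansion_modes, function(expansion)
        refine_rois(labels, cfg, expansion))
      names(refined) <- cfg$expansion_modes
      cache_masks[[length(cache_masks) + 1L]] <- merged
      cache_refined[[length(cache_refined) + 1L]] <- refined
      hit <- length(cache_masks)
    }
    for (expansion in cfg$expansion_modes) {
      refined <- cache_refined[[hit]][[expansion]]
      out[[length(out) + 1L]] <- list(
        variant_id = paste(method, expansion, sep = "/"),
        mask = refined, n_cells = max(refined), dice = NA_real_)
    }
  }
  out
}

#' Select the best candidate mask from an ensemble
#'
#' In `"per_image_argmax"` mode the candidate with maximal Dice against the
#' ground-truth mask wins (ties broken by variant order). In
#' `"global_calibration"` mode `candidates` is a list of per-image candidate
#' lists (identical variant order) and `truth` a list of ground-truth masks
#' (`NULL` for images lacking truth); the single variant with the highest mean
#' Dice over the calibration images is applied to every image.
#'
#' @param candidates candidate list (argmax mode) or list of candidate lists
#'   (global mode).
#' @param truth ground-truth label/binary mask, or list of them (global mode).
#' @param mode voting mode.
#' @return argmax mode: list with `mask`, `variant_id`, `dice`, `report`
#'   (data frame of every variant's Dice). Global mode: list with
#'   `variant_id`, `mean_dice`, `report`, `masks`.
#' @export
ensemble_select <- function(candidates, truth = NULL,
                            mode = c("per_image_argmax", "global_calibration")) {
  mode <- match.arg(mode)
  if (!length(candidates)) of_stop("no candidates supplied", "omiflim_empty_ensemble")
  if (mode == "per_image_argmax") {
    if (is.null(truth)) of_stop("per_image_argmax requires a ground-truth mask",
                                "omiflim_missing_truth")
    dice <- vapply(candidates, function(cc) {
      if (sum(cc$mask > 0) + sum(truth > 0) == 0) return(NA_real_)
      dice_coefficient(cc$mask, truth)
    }, numeric(1))
    report <- data.frame(
      variant_id = vapply(candidates, `[[`, character(1), "variant_id"),
      dice = dice,
      n_cells = vapply(candidates, `[[`, numeric(1), "n_cells"),
      stringsAsFactors = FALSE)
    best <- if (all(is.na(dice))) 1L else which.max(dice)  # empty truth, empty masks
    list(mask = candidates[[best]]$mask, variant_id = report$variant_id[best],
         dice = dice[best], report = report)
  } else {
    has_truth <- !vapply(truth, is.null, logical(1))
    of_check(any(has_truth), "global calibration needs at least one image with truth",
             "omiflim_missing_truth")
    variant_ids <- vapply(candidates[[1]], `[[`, character(1), "variant_id")
    dice_tab <- sapply(which(has_truth), function(i) {
      vapply(candidates[[i]], function(cc) {
        if (sum(cc$mask > 0) + sum(truth[[i]] > 0) == 0) return(NA_real_)
        dice_coefficient(cc$mask, truth[[i]])
      }, numeric(1))
    })
    dice_tab <- matrix(dice_tab, nrow = length(variant_ids))
    mean_dice <- rowMeans(dice_tab, na.rm = TRUE)
    best <- which.max(mean_dice)
    report <- data.frame(variant_id = variant_ids, mean_dice = mean_dice,
                         stringsAsFactors = FALSE)
    list(variant_id = variant_ids[best], mean_dice = mean_dice[best],
         report = report,
         masks = lapply(candidates, function(img) img[[best]]$mask))
  }
}

#' Segment one field of view end to end
#'
#' Runs the full variant ensemble and, when ground truth is available and the
#' voting mode is `per_image_argmax`, selects the Dice-optimal mask.
#'
#' @inheritParams run_variant
#' @param truth ground-truth label mask (required for argmax voting).
#' @param keep_candidates retain every candidate mask in the result.
#' @return list with `mask`, `variant_id`, `dice`, `report` and optionally
#'   `candidates`.
#' @export
segment_fov <- function(intensity, lifetime, cfg = segmentation_config(),
                        truth = NULL, keep_candidates = FALSE) {
  cands <- run_variants(intensity, lifetime, cfg)
  sel <- ensemble_select(cands, truth, cfg$voting_mode)
  if (keep_candidates) sel$candidates <- cands
  sel
}

#' Mask-dilation sensitivity of per-cell OMI parameters
#'
#' Recomputes the per-cell OMI parameters under masks dilated by each radius
#' and reports the two-sided Mann-Whitney p-value against the original mask
#' for every parameter. Whole-cell masks are insensitive to small dilations
#' when the surrounding signal belongs to the same cell.
#'
#' @param labels integer label mask.
#' @param nadph_maps,fad_maps per-pixel fit maps (see [fit_pixels]).
#' @param nadph_intensity,fad_intensity photon-count matrices.
#' @param radii dilation radii in pixels.
#' @return data frame with columns `radius`, `parameter`, `p_value`; empty
#'   when the mask has no cells.
#' @export
dilation_sensitivity <- function(labels, nadph_maps, fad_maps,
                                 nadph_intensity, fad_intensity, radii = 1:3) {
  if (!any(labels > 0)) {
    return(data.frame(radius = integer(), parameter = character(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  feats0 <- extract_cell_features(labels, nadph_maps, fad_maps,
                                  nadph_intensity, fad_intensity)
  params <- omi_parameters()
  out <- list()
  for (r in radii) {
    lab_r <- if (r >= 1) expand_labels(labels, r, "dilate") else labels
    feats_r <- extract_cell_features(lab_r, nadph_maps, fad_maps,
                                     nadph_intensity, fad_intensity)
    p <- vapply(params, function(pp) mw_p(feats_r[[pp]], feats0[[pp]]), numeric(1))
    out[[length(out) + 1L]] <- data.frame(radius = r, parameter = params,
                                          p_value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
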