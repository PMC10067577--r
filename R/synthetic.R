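# Synthetic FLIM scenes with known ground truth: nuclear-labelled immune
# cells (mCherry), cytoplasmic NAD(P)H/FAD autofluorescence with two-component
# decays, out-of-gate red distractors, and Poisson photon noise.

#' Spleen-like immune-cell population defaults
#'
#' Per-cell parameter distributions (mean, SD) patterned on splenic immune
#' cells: a homogeneous small-lymphocyte population with tight size and
#' weight distributions. Lifetimes in picoseconds, weights and redox as
#' fractions, size as the whole-cell pixel area.
#'
#' @return a population spec list.
#' @export
population_spleen <- function() {
  list(
    nadph = list(tau1 = c(400, 60), tau2 = c(2500, 300), alpha1 = c(0.84, 0.05)),
    fad = list(tau1 = c(213, 25), tau2 = c(2490, 380), alpha1 = c(0.85, 0.05)),
    mcherry_tau_range = c(1300, 1450),
    redox = c(0.48, 0.05),
    size_px = c(95, 20)
  )
}

# Delta-method SD of tau_m = a1 t1 + (1-a1) t2 from component (mean, SD)s.
tau_m_sd <- function(ch) {
  sqrt((ch$alpha1[1] * ch$tau1[2])^2 +
         ((ch$tau1[1] - ch$tau2[1]) * ch$alpha1[2])^2 +
         ((1 - ch$alpha1[1]) * ch$tau2[2])^2)
}

tau_m_mean <- function(ch) ch$alpha1[1] * ch$tau1[1] + (1 - ch$alpha1[1]) * ch$tau2[1]

#' Built-in tissue contrast (control-SD units)
#'
#' Effect sizes of the tumor-infiltrating population relative to the
#' spleen control, in units of the control's per-parameter SD: lower FAD
#' mean lifetime (-1.5), more protein-bound FAD (+1.0 on its weight), larger
#' cells (+2.7), a mild NAD(P)H mean-lifetime decrease (-0.5366) with a small
#' bound-weight increase (+0.6), and a higher optical redox ratio (+2.0)
#' consistent with a glycolytic shift of activated immune cells.
#'
#' @return named numeric vector of effect sizes.
#' @export
default_tissue_effects <- function() {
  c(fad_alpha1 = 1.0, fad_tau_m = -1.5,
    nadph_alpha1 = 0.6, nadph_tau_m = -0.5366,
    cell_size = 2.7, redox_ratio = 2.0)
}

# Shift one channel's population so that alpha1 moves by e_alpha control-SDs
# and the *net* tau_m shift equals e_taum control-SDs (the residual after the
# alpha shift is applied to the long-lifetime mean).
shift_channel <- function(ch, e_alpha, e_taum) {
  sd_tm <- tau_m_sd(ch)
  da <- e_alpha * ch$alpha1[2]
  ch$alpha1[1] <- ch$alpha1[1] + da
  target <- e_taum * sd_tm
  from_alpha <- da * (ch$tau1[1] - ch$tau2[1])
  ch$tau2[1] <- ch$tau2[1] + (target - from_alpha) / (1 - ch$alpha1[1])
  ch
}

#' Apply tissue effect sizes to a control population
#'
#' @param effects named vector in control-SD units (see
#'   [default_tissue_effects]); zero entries leave the population unchanged.
#' @param base the control population.
#' @param size_sd SD of the shifted size distribution (tumor cell size is
#'   more heterogeneous than spleen).
#' @return a population spec list.
#' @export
apply_tissue_effects <- function(effects = default_tissue_effects(),
                                 base = population_spleen(),
                                 size_sd = 35) {
  g <- function(nm) if (nm %in% names(effects)) effects[[nm]] else 0
  p <- base
  p$fad <- shift_channel(base$fad, g("fad_alpha1"), g("fad_tau_m"))
  p$nadph <- shift_channel(base$nadph, g("nadph_alpha1"), g("nadph_tau_m"))
  p$size_px <- c(base$size_px[1] + g("cell_size") * base$size_px[2],
                 if (g("cell_size") != 0) size_sd else base$size_px[2])
  p$redox <- c(base$redox[1] + g("redox_ratio") * base$redox[2], base$redox[2])
  p
}

#' Tumor-like immune-cell population defaults
#'
#' The spleen control shifted by [default_tissue_effects].
#'
#' @inheritParams apply_tissue_effects
#' @return a population spec list.
#' @export
population_tumor <- function(effects = default_tissue_effects(), size_sd = 35) {
  apply_tissue_effects(effects, population_spleen(), size_sd)
}

#' Specify a synthetic FLIM scene
#'
#' @param size image side length in pixels.
#' @param n_cells number of labelled immune cells.
#' @param population per-cell parameter distributions (see
#'   [population_spleen]).
#' @param axis_ratio_max cells are ellipses with axis ratio up to this value.
#' @param nucleus_scale the nuclear (mCherry) region is the cell ellipse
#'   scaled by this factor.
#' @param cyto_extend the autofluorescent cytoplasm extends this many pixels
#'   beyond the whole-cell ground-truth ellipse.
#' @param photons_per_cell expected autofluorescence photons per cell per
#'   channel on average (split between NAD(P)H and FAD by the cell's redox
#'   ratio).
#' @param mcherry_photons_per_cell expected label photons per cell.
#' @param n_distractors number of non-specific red blobs with lifetimes
#'   outside the 800-1500 ps gate.
#' @param distractor_radius radius range (px) of distractor blobs.
#' @param distractor_tau candidate distractor lifetimes (ps), all outside the
#'   gate.
#' @param distractor_photons expected photons per distractor.
#' @param background_rate expected background photons per pixel per channel.
#' @param background_tau background decay lifetime (ps).
#' @param n_bins,bin_width_ps TCSPC time axis (default 128 bins over 12.5 ns,
#'   an 80 MHz repetition window).
#' @param irf instrument response used for all channels.
#' @param min_gap minimum clearance (px) between cytoplasm regions.
#' @param max_place_tries placement attempts per object before a packing
#'   error.
#' @param seed integer seed; all stochastic draws descend from it.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(size = 256L, n_cells = 10L, population = population_spleen(),
                       axis_ratio_max = 2, nucleus_scale = 0.7, cyto_extend = 3,
                       photons_per_cell = 5000, mcherry_photons_per_cell = 5000,
                       n_distractors = 3L, distractor_radius = c(2, 4),
                       distractor_tau = c(400, 2600), distractor_photons = 3000,
                       background_rate = 1, background_tau = 300,
                       n_bins = 128L, bin_width_ps = 12500 / n_bins,
                       irf = irf_gaussian(1220, 250),
                       min_gap = 3, max_place_tries = 2000L, seed = 1L) {
  of_check(size >= 32, "scene size must be at least 32 px")
  of_check(n_cells >= 0 && n_distractors >= 0, "object counts must be >= 0")
  of_check(background_rate >= 0 && photons_per_cell >= 0 &&
             mcherry_photons_per_cell >= 0 && distractor_photons >= 0,
           "all rates must be >= 0")
  of_check(nucleus_scale > 0 && nucleus_scale <= 1, "nucleus_scale must be in (0, 1]")
  structure(as.list(environment()), class = "scene_spec")
}

clamp_norm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

ellipse_mask <- function(size, cy, cx, a, b, theta) {
  y <- matrix(seq_len(size), size, size) - cy
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Draw one decay curve of expected counts summing to `photons`.
expected_curve <- function(tau1, tau2, alpha1, photons, spec) {
  biexp_forward(tau1, tau2, alpha1, 0, spec$irf, spec$bin_width_ps,
                spec$n_bins, photons)$counts
}

#' Generate a synthetic FLIM scene
#'
#' Draws non-overlapping elliptical cells, assigns every cell true decay
#' parameters from the population spec, builds expected decay cubes for the
#' NAD(P)H, FAD and mCherry channels, and adds Poisson photon noise.
#' Reproducible: the output is a pure function of the spec (including its
#' seed).
#'
#' @param spec a [scene_spec].
#' @return list with `spec`, `channels` (named list of `[bins, ny, nx]`
#'   count cubes), `intensity` (named list of photon-count matrices),
#'   `lifetime` (gating lifetime map of the mCherry channel), and `truth`
#'   (list: `mask` label matrix, `cells` per-cell true parameter table,
#'   `distractor_mask`).
#' @export
generate_scene <- function(spec) {
  of_check(inherits(spec, "scene_spec"), "spec must be a scene_spec")
  set.seed(spec$seed)
  size <- spec$size
  npx <- size * size

  # --- geometry -------------------------------------------------------------
  cells <- list()
  if (spec$n_cells > 0) {
    areas <- pmax(clamp_norm(spec$n_cells, spec$population$size_px[1],
                             spec$population$size_px[2], 30, Inf), 30)
    for (i in seq_len(spec$n_cells)) {
      q <- stats::runif(1, 1, spec$axis_ratio_max)
      b <- sqrt(areas[i] / (pi * q)); a <- q * b
      theta <- stats::runif(1, 0, pi)
      margin <- a + spec$cyto_extend + 2
      placed <- FALSE
      for (try in seq_len(spec$max_place_tries)) {
        cy <- stats::runif(1, margin, size - margin)
        cx <- stats::runif(1, margin, size - margin)
        ok <- TRUE
        for (cc in cells) {
          lim <- a + cc$a + 2 * spec$cyto_extend + spec$min_gap
          if ((cy - cc$cy)^2 + (cx - cc$cx)^2 < lim^2) { ok <- FALSE; break }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) of_stop(sprintf("could not place cell %d of %d", i, spec$n_cells),
                           "omiflim_packing_error")
      cells[[i]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta)
    }
  }

  distractors <- list()
  if (spec$n_distractors > 0) {
    for (i in seq_len(spec$n_distractors)) {
      r <- stats::runif(1, spec$distractor_radius[1], spec$distractor_radius[2])
      placed <- FALSE
      for (try in seq_len(spec$max_place_tries)) {
        cy <- stats::runif(1, r + 2, size - r - 2)
        cx <- stats::runif(1, r + 2, size - r - 2)
        ok <- TRUE
        for (cc in cells) {
          lim <- r + cc$a + spec$cyto_extend + 2
          if ((cy - cc$cy)^2 + (cx - cc$cx)^2 < lim^2) { ok <- FALSE; break }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) of_stop(sprintf("could not place distractor %d", i),
                           "omiflim_packing_error")
      distractors[[i]] <- list(cy = cy, cx = cx, r = r,
                               tau = sample(spec$distractor_tau, 1))
    }
  }

  # --- true per-cell parameters ----------------------------------------------
  pop <- spec$population
  nc <- length(cells)
  draws <- list(
    nadph_tau1 = clamp_norm(nc, pop$nadph$tau1[1], pop$nadph$tau1[2], 30, Inf),
    nadph_tau2 = clamp_norm(nc, pop$nadph$tau2[1], pop$nadph$tau2[2], 30, Inf),
    nadph_alpha1 = clamp_norm(nc, pop$nadph$alpha1[1], pop$nadph$alpha1[2], 0.02, 0.98),
    fad_tau1 = clamp_norm(nc, pop$fad$tau1[1], pop$fad$tau1[2], 30, Inf),
    fad_tau2 = clamp_norm(nc, pop$fad$tau2[1], pop$fad$tau2[2], 30, Inf),
    fad_alpha1 = clamp_norm(nc, pop$fad$alpha1[1], pop$fad$alpha1[2], 0.02, 0.98),
    mcherry_tau = stats::runif(nc, pop$mcherry_tau_range[1], pop$mcherry_tau_range[2]),
    redox = clamp_norm(nc, pop$redox[1], pop$redox[2], 0.02, 0.98)
  )

  # --- expected decay cubes ---------------------------------------------------
  # autofluorescence channels: flat (dark-count / ambient) background, the
  # component the fit model's offset C represents; mCherry channel: decaying
  # red-autofluorescence background with background_tau (out of the gate)
  bg_flat <- rep(spec$background_rate / spec$n_bins, spec$n_bins)
  bg_red <- expected_curve(spec$background_tau, spec$background_tau, 1,
                           spec$background_rate, spec)
  lam <- list(NADPH = matrix(bg_flat, spec$n_bins, npx),
              FAD = matrix(bg_flat, spec$n_bins, npx),
              MCHERRY = matrix(bg_red, spec$n_bins, npx))

  truth_mask <- matrix(0L, size, size)
  cell_rows <- list()
  for (i in seq_len(nc)) {
    cc <- cells[[i]]
    cell <- ellipse_mask(size, cc$cy, cc$cx, cc$a, cc$b, cc$theta)
    nuc <- ellipse_mask(size, cc$cy, cc$cx, cc$a * spec$nucleus_scale,
                        cc$b * spec$nucleus_scale, cc$theta)
    cyto <- ellipse_mask(size, cc$cy, cc$cx, cc$a + spec$cyto_extend,
                         cc$b + spec$cyto_extend, cc$theta)
    truth_mask[cell] <- i
    idx_cyto <- which(cyto); idx_nuc <- which(nuc)
    n_photons <- 2 * spec$photons_per_cell * draws$redox[i]
    f_photons <- 2 * spec$photons_per_cell * (1 - draws$redox[i])
    lam$NADPH[, idx_cyto] <- lam$NADPH[, idx_cyto] +
      expected_curve(draws$nadph_tau1[i], draws$nadph_tau2[i],
                     draws$nadph_alpha1[i], n_photons, spec) / length(idx_cyto)
    lam$FAD[, idx_cyto] <- lam$FAD[, idx_cyto] +
      expected_curve(draws$fad_tau1[i], draws$fad_tau2[i],
                     draws$fad_alpha1[i], f_photons, spec) / length(idx_cyto)
    if (length(idx_nuc)) {
      lam$MCHERRY[, idx_nuc] <- lam$MCHERRY[, idx_nuc] +
        expected_curve(draws$mcherry_tau[i], draws$mcherry_tau[i], 1,
                       spec$mcherry_photons_per_cell, spec) / length(idx_nuc)
    }
    cell_rows[[i]] <- data.frame(
      cell_id = i, fov_id = "FOV1", mouse_id = "M1",
      tissue = NA_character_, cell_type = "immune",
      nadph_tau1 = draws$nadph_tau1[i], nadph_tau2 = draws$nadph_tau2[i],
      nadph_alpha1 = draws$nadph_alpha1[i], nadph_alpha2 = 1 - draws$nadph_alpha1[i],
      nadph_tau_m = mean_lifetime(draws$nadph_alpha1[i], draws$nadph_tau1[i],
                                  1 - draws$nadph_alpha1[i], draws$nadph_tau2[i]),
      fad_tau1 = draws$fad_tau1[i], fad_tau2 = draws$fad_tau2[i],
      fad_alpha1 = draws$fad_alpha1[i], fad_alpha2 = 1 - draws$fad_alpha1[i],
      fad_tau_m = mean_lifetime(draws$fad_alpha1[i], draws$fad_tau1[i],
                                1 - draws$fad_alpha1[i], draws$fad_tau2[i]),
      cell_size = sum(cell), redox_ratio = draws$redox[i],
      mcherry_tau = draws$mcherry_tau[i],
      stringsAsFactors = FALSE)
  }

  distractor_mask <- matrix(0L, size, size)
  for (i in seq_along(distractors)) {
    dd <- distractors[[i]]
    blob <- ellipse_mask(size, dd$cy, dd$cx, dd$r, dd$r, 0)
    distractor_mask[blob] <- i
    idx <- which(blob)
    lam$MCHERRY[, idx] <- lam$MCHERRY[, idx] +
      expected_curve(dd$tau, dd$tau, 1, spec$distractor_photons, spec) / length(idx)
  }

  # --- Poisson photon noise ---------------------------------------------------
  channels <- lapply(lam, function(m)
    array(stats::rpois(length(m), m), dim = c(spec$n_bins, size, size)))
  intensity <- lapply(channels, function(cube)
    matrix(colSums(matrix(cube, nrow = spec$n_bins)), size, size))
  lifetime <- lifetime_map_com(channels$MCHERRY, spec$bin_width_ps, spec$irf,
                               min_photons = 50, bin = 3)

  cells_df <- if (length(cell_rows)) do.call(rbind, cell_rows) else empty_feature_table()
  list(spec = spec, channels = channels, intensity = intensity,
       lifetime = lifetime,
       truth = list(mask = truth_mask, cells = cells_df,
                    distractor_mask = distractor_mask))
}

#' Generate a two-tissue synthetic dataset
#'
#' Emits labelled scenes for a control ("spleen") and a shifted ("tumor")
#' population so the statistics layer can demonstrate recovery of the
#' built-in contrasts. Mouse labels alternate between scenes. Tumor scenes
#' get a doubled background rate (worse signal-to-noise, as in tumor tissue).
#'
#' @param n_scenes scenes per tissue.
#' @param cells_per_scene cells per scene.
#' @param seed master seed; every scene seed derives from it.
#' @param control,case population specs for the two tissues.
#' @param collect optional function applied to each generated scene; its
#'   return value is stored in place of the full scene (use it to stream
#'   large datasets without holding every decay cube in memory).
#' @param ... further arguments to [scene_spec].
#' @return list with `scenes` (list of scenes or collected values, each with
#'   attributes `tissue`, `fov_id`, `mouse_id`) and `truth` (combined
#'   ground-truth feature table).
#' @export
generate_dataset <- function(n_scenes = 4, cells_per_scene = 25, seed = 1L,
                             control = population_spleen(),
                             case = population_tumor(),
                             collect = NULL, ...) {
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max, 2 * n_scenes)
  extra <- list(...)
  scenes <- list()
  truth_tabs <- list()
  k <- 0L
  for (tissue in c("spleen", "tumor")) {
    pop <- if (tissue == "spleen") control else case
    for (i in seq_len(n_scenes)) {
      k <- k + 1L
      args <- c(list(n_cells = cells_per_scene, population = pop,
                     seed = scene_seeds[k]), extra)
      if (tissue == "tumor" && is.null(extra$background_rate)) {
        args$background_rate <- 2
      }
      spec <- do.call(scene_spec, args)
      scene <- generate_scene(spec)
      fov <- sprintf("%s_FOV%d", tissue, i)
      mouse <- sprintf("M%d", (i - 1L) %% 2L + 1L)
      scene$truth$cells$fov_id <- fov
      scene$truth$cells$mouse_id <- mouse
      scene$truth$cells$tissue <- tissue
      truth_tabs[[k]] <- scene$truth$cells
      val <- if (is.null(collect)) scene else collect(scene)
      attr(val, "tissue") <- tissue
      attr(val, "fov_id") <- fov
      attr(val, "mouse_id") <- mouse
      scenes[[k]] <- val
    }
  }
  truth <- build_feature_table(lapply(truth_tabs, function(tb)
    tb[, feature_schema(), drop = FALSE]))
  list(scenes = scenes, truth = truth)
}

#' Fitted per-cell features for a whole dataset
#'
#' End-to-end measurement path: for every scene, sums each ground-truth
#' cell's decays, fits the pooled NAD(P)H and FAD histograms and assembles
#' the per-cell OMI feature table. Scenes are generated and reduced one at a
#' time so memory stays bounded.
#'
#' @inheritParams generate_dataset
#' @param fit_ctrl a [fit_control] for the pooled per-cell fits.
#' @return list with `features` (fitted feature table) and `truth`
#'   (ground-truth feature table).
#' @export
dataset_features <- function(n_scenes = 4, cells_per_scene = 25, seed = 1L,
                             control = population_spleen(),
                             case = population_tumor(),
                             fit_ctrl = fit_control(min_photons = 500), ...) {
  collect <- function(scene) {
    sp <- scene$spec
    n_tab <- fit_cells(scene$channels$NADPH, scene$truth$mask, sp$bin_width_ps,
                       sp$irf, "NADPH", fit_ctrl)
    f_tab <- fit_cells(scene$channels$FAD, scene$truth$mask, sp$bin_width_ps,
                       sp$irf, "FAD", fit_ctrl)
    extract_cell_features(scene$truth$mask, n_tab, f_tab,
                          scene$intensity$NADPH, scene$intensity$FAD)
  }
  ds <- generate_dataset(n_scenes, cells_per_scene, seed, control, case,
                         collect = collect, ...)
  feats <- lapply(seq_along(ds$scenes), function(i) {
    tb <- ds$scenes[[i]]
    tb[["fov_id"]] <- rep(attr(ds$scenes[[i]], "fov_id"), nrow(tb))
    tb[["mouse_id"]] <- rep(attr(ds$scenes[[i]], "mouse_id"), nrow(tb))
    tb[["tissue"]] <- rep(attr(ds$scenes[[i]], "tissue"), nrow(tb))
    tb
  })
  list(features = build_feature_table(feats), truth = ds$truth)
}
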