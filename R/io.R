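# Artifact I/O. Every array travels as a (multi-page) TIFF plus a JSON
# sidecar `<file>.json` holding dtype kind, dimensions and acquisition
# metadata. Counts and label masks are stored as exact 16-bit integers;
# float maps (lifetimes, fit parameters) are stored scaled to [0,1] at
# 32 bits with their range in the sidecar (quantization <= range * 2^-32)
# and NaN encoded as an exact-zero sentinel.

FLOAT_EPS <- 2^-20

#' Write an image stack with a JSON sidecar
#'
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param data a matrix or a `[n_bins, ny, nx]` array.
#' @param kind `"counts"` (non-negative integers), `"labels"` (integer label
#'   mask) or `"float"`.
#' @param metadata named list merged into the sidecar (e.g. `channel`,
#'   `bin_width_ps`, `excitation_nm`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(path, data, kind = c("counts", "labels", "float"),
                        metadata = list()) {
  kind <- match.arg(kind)
  dims <- dim(data)
  of_check(length(dims) %in% 2:3, "data must be a matrix or a 3-D array",
           "omiflim_format_error")
  pages <- if (length(dims) == 2L) list(data) else
    lapply(seq_len(dims[1]), function(k) data[k, , ])
  side <- c(list(kind = kind, dims = dims, version = as.character(utils::packageVersion("omiflim"))),
            metadata)
  if (kind %in% c("counts", "labels")) {
    mx <- max(vapply(pages, max, numeric(1)), 0)
    of_check(mx <= 65535 && all(vapply(pages, function(p) all(p >= 0 & p == round(p)), logical(1))),
             sprintf("%s data must be integers in [0, 65535]", kind),
             "omiflim_format_error")
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path, bits.per.sample = 16L)
  } else {
    flat <- unlist(pages)
    finite <- flat[is.finite(flat)]
    lo <- if (length(finite)) min(finite) else 0
    hi <- if (length(finite)) max(finite) else 0
    side$float_range <- c(lo, hi)
    scale <- if (hi > lo) (hi - lo) else 1
    enc <- lapply(pages, function(p) {
      q <- (p - lo) / scale * (1 - FLOAT_EPS) + FLOAT_EPS
      q[!is.finite(p)] <- 0
      q
    })
    tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return list with `data` (matrix or array, reconstructed dtype) and
#'   `metadata` (the sidecar).
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    of_stop(sprintf("missing sidecar %s", sidecar), "omiflim_metadata_error")
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  of_check(!is.null(side$kind) && side$kind %in% c("counts", "labels", "float"),
           "sidecar lacks a valid 'kind'", "omiflim_metadata_error")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = side$kind != "float"),
    error = function(e) of_stop(sprintf("cannot read TIFF %s: %s", path,
                                        conditionMessage(e)), "omiflim_format_error"))
  dims <- as.integer(side$dims)
  decode <- function(p) {
    if (side$kind == "float") {
      rng <- as.numeric(side$float_range)
      scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
      out <- (p - FLOAT_EPS) / (1 - FLOAT_EPS) * scale + rng[1]
      out[p == 0] <- NaN
      out
    } else {
      storage.mode(p) <- "integer"
      p
    }
  }
  pages <- lapply(pages, decode)
  data <- if (length(dims) == 2L) pages[[1]] else {
    arr <- array(if (side$kind == "float") NA_real_ else 0L, dim = dims)
    for (k in seq_len(dims[1])) arr[k, , ] <- pages[[k]]
    arr
  }
  of_check(identical(as.integer(dim(data)), dims),
           "TIFF dimensions disagree with the sidecar", "omiflim_format_error")
  list(data = data, metadata = side)
}

spec_to_json <- function(spec) {
  s <- unclass(spec)
  s$irf <- unclass(s$irf)
  s
}

#' Write / read a synthetic scene directory
#'
#' Persists a [generate_scene] result as per-channel decay-cube TIFFs,
#' intensity and lifetime maps, ground-truth masks, a per-cell truth CSV and
#' a JSON echo of the scene spec.
#'
#' @param dir output directory (created if needed).
#' @param scene a scene from [generate_scene].
#' @return `dir`, invisibly.
#' @export
write_scene <- function(dir, scene) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- scene$spec
  for (ch in names(scene$channels)) {
    write_stack(file.path(dir, paste0(ch, ".tif")), scene$channels[[ch]],
                "counts", list(channel = ch, bin_width_ps = sp$bin_width_ps,
                               n_bins = sp$n_bins))
    write_stack(file.path(dir, paste0("intensity_", ch, ".tif")),
                scene$intensity[[ch]], "counts", list(channel = ch))
  }
  write_stack(file.path(dir, "lifetime_MCHERRY.tif"), scene$lifetime, "float",
              list(channel = "MCHERRY", units = "ps"))
  write_stack(file.path(dir, "truth_mask.tif"), scene$truth$mask, "labels")
  write_stack(file.path(dir, "distractor_mask.tif"), scene$truth$distractor_mask,
              "labels")
  utils::write.csv(scene$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(spec_to_json(sp), file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  sj <- file.path(dir, "scene.json")
  if (!file.exists(sj)) of_stop(sprintf("no scene.json in %s", dir),
                                "omiflim_metadata_error")
  side <- jsonlite::read_json(sj, simplifyVector = TRUE)
  channels <- list(); intensity <- list()
  for (ch in c("NADPH", "FAD", "MCHERRY")) {
    channels[[ch]] <- read_stack(file.path(dir, paste0(ch, ".tif")))$data
    intensity[[ch]] <- read_stack(file.path(dir, paste0("intensity_", ch, ".tif")))$data
  }
  irf <- if (identical(side$irf$type, "gaussian"))
    irf_gaussian(side$irf$center_ps, side$irf$fwhm_ps) else side$irf
  list(spec = side, irf = irf, bin_width_ps = side$bin_width_ps,
       channels = channels, intensity = intensity,
       lifetime = read_stack(file.path(dir, "lifetime_MCHERRY.tif"))$data,
       truth = list(mask = read_stack(file.path(dir, "truth_mask.tif"))$data,
                    cells = utils::read.csv(file.path(dir, "truth_cells.csv")),
                    distractor_mask = read_stack(file.path(dir, "distractor_mask.tif"))$data))
}

#' Write a provenance record
#'
#' Config echo + seed + package version; together with the input files it
#' suffices to regenerate an output directory exactly.
#'
#' @param dir output directory.
#' @param config named list (configuration echo).
#' @param seed integer seed used for the run.
#' @export
write_provenance <- function(dir, config, seed) {
  jsonlite::write_json(
    list(package = "omiflim",
         version = as.character(utils::packageVersion("omiflim")),
         seed = seed, config = config),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "provenance.json"))
}
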