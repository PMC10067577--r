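#' Construct a TCSPC decay histogram
#'
#' A decay histogram holds photon counts per arrival-time bin for one pixel
#' (or one pooled region) in one spectral channel. Time bins are uniform;
#' the bin centers are at `(k - 1/2) * bin_width_ps`.
#'
#' @param counts numeric vector of non-negative photon counts per bin. Model
#'   (expected) decays may carry non-integer values; measured decays are
#'   integers.
#' @param bin_width_ps width of one time bin in picoseconds (> 0).
#' @param channel one of `"NADPH"`, `"FAD"`, `"MCHERRY"`.
#' @return an object of class `decay_histogram` with fields `counts`,
#'   `bin_width_ps`, `n_bins`, `channel`.
#' @export
decay_histogram <- function(counts, bin_width_ps, channel = c("NADPH", "FAD", "MCHERRY")) {
  channel <- match.arg(channel)
  counts <- as.numeric(counts)
  of_check(length(counts) >= 8L, "a decay histogram needs at least 8 bins")
  of_check(all(is.finite(counts)) && all(counts >= 0), "counts must be finite and non-negative")
  of_check(is.numeric(bin_width_ps) && length(bin_width_ps) == 1L && bin_width_ps > 0,
           "bin_width_ps must be a single positive number")
  structure(
    list(counts = counts, bin_width_ps = as.numeric(bin_width_ps),
         n_bins = length(counts), channel = channel),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %s: %d bins x %.2f ps, %.0f photons\n",
              x$channel, x$n_bins, x$bin_width_ps, sum(x$counts)))
  invisible(x)
}

bin_centers <- function(n_bins, bin_width_ps) (seq_len(n_bins) - 0.5) * bin_width_ps

#' Gaussian instrument response model
#'
#' The instrument response function (IRF) is the temporal blur of the
#' detection chain; the measured decay is the true decay convolved with it.
#' When no measured IRF (e.g. second-harmonic signal from urea crystals) is
#' available, a Gaussian model is a standard stand-in.
#'
#' @param center_ps center of the Gaussian in picoseconds.
#' @param fwhm_ps full width at half maximum in picoseconds (> 0).
#' @return an object of class `instrument_response`.
#' @export
irf_gaussian <- function(center_ps = 1220, fwhm_ps = 250) {
  of_check(fwhm_ps > 0, "IRF fwhm must be > 0")
  of_check(center_ps >= 0, "IRF center must be >= 0")
  structure(list(type = "gaussian", center_ps = center_ps, fwhm_ps = fwhm_ps),
            class = "instrument_response")
}

#' Measured instrument response
#'
#' Wraps a measured IRF decay histogram (normalized to unit area before any
#' convolution). Takes precedence over the Gaussian model wherever both could
#' apply.
#'
#' @param decay a [decay_histogram] holding the measured IRF.
#' @return an object of class `instrument_response`.
#' @export
irf_measured <- function(decay) {
  of_check(inherits(decay, "decay_histogram"), "decay must be a decay_histogram")
  of_check(sum(decay$counts) > 0, "measured IRF has no photons")
  structure(list(type = "measured", decay = decay), class = "instrument_response")
}

#' Discretize an IRF to a unit-area kernel
#'
#' @param irf an [instrument_response].
#' @param bin_width_ps,n_bins time axis to discretize on.
#' @return numeric vector of length `n_bins` summing to 1.
#' @export
irf_kernel <- function(irf, bin_width_ps, n_bins) {
  of_check(inherits(irf, "instrument_response"), "irf must be an instrument_response")
  if (irf$type == "gaussian") {
    t <- bin_centers(n_bins, bin_width_ps)
    sd <- irf$fwhm_ps / (2 * sqrt(2 * log(2)))
    k <- exp(-0.5 * ((t - irf$center_ps) / sd)^2)
  } else {
    k <- irf$decay$counts
    of_check(length(k) == n_bins && isTRUE(all.equal(irf$decay$bin_width_ps, bin_width_ps)),
             "measured IRF time axis does not match the decay time axis",
             "omiflim_format_error")
  }
  s <- sum(k)
  of_check(s > 0, "IRF kernel has zero area")
  k / s
}

#' IRF centroid (mean arrival time of the instrument response)
#'
#' @inheritParams irf_kernel
#' @return centroid in picoseconds.
#' @export
irf_centroid <- function(irf, bin_width_ps, n_bins) {
  if (irf$type == "gaussian") return(irf$center_ps)
  k <- irf_kernel(irf, bin_width_ps, n_bins)
  sum(bin_centers(n_bins, bin_width_ps) * k)
}

# Causal discrete convolution of a unit-area kernel with a signal, truncated
# to the acquisition window. Direct (non-FFT) evaluation: exact to double
# rounding, so tests can compare bin-by-bin against a loop oracle.
conv_matrix <- function(kernel) {
  n <- length(kernel)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) K[j:n, j] <- kernel[seq_len(n - j + 1L)]
  K
}

conv_causal <- function(kernel, signal) {
  as.vector(conv_matrix(kernel) %*% signal)
}

#' Bi-exponential forward decay model
#'
#' Evaluates the two-component decay
#' \deqn{I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C}
#' with \eqn{\alpha_2 = 1 - \alpha_1}, convolves the decaying part with the
#' unit-area instrument response, and scales it so the expected photon sum
#' over the acquisition window equals `total_photons` (the constant offset
#' `offset_C` is kept fixed per bin and the decay amplitude absorbs the
#' scaling). Deterministic: photon (Poisson) noise is added by the synthetic
#' scene generator, not here.
#'
#' @param tau1,tau2 lifetimes of the two components in picoseconds (> 0).
#' @param alpha1 fractional weight of component 1 in `[0, 1]`.
#' @param offset_C constant background counts per bin (>= 0).
#' @param irf an [instrument_response].
#' @param bin_width_ps,n_bins time axis.
#' @param total_photons expected photon sum over the window (>= 0).
#' @param channel spectral channel tag for the returned histogram.
#' @return a [decay_histogram] of expected (non-integer) counts.
#' @examples
#' irf <- irf_gaussian(center_ps = 500, fwhm_ps = 250)
#' d <- biexp_forward(400, 2500, 0.7, 0, irf, bin_width_ps = 48.8, n_bins = 256,
#'                    total_photons = 1e5)
#' sum(d$counts)  # 1e5
#' @export
biexp_forward <- function(tau1, tau2, alpha1, offset_C = 0, irf,
                          bin_width_ps, n_bins, total_photons,
                          channel = c("NADPH", "FAD", "MCHERRY")) {
  channel <- match.arg(channel)
  of_check(is.numeric(tau1) && tau1 > 0 && is.numeric(tau2) && tau2 > 0,
           "lifetimes must be positive")
  of_check(alpha1 >= 0 && alpha1 <= 1, "alpha1 must lie in [0, 1]")
  of_check(offset_C >= 0, "offset_C must be >= 0")
  of_check(total_photons >= 0, "total_photons must be >= 0")
  t <- bin_centers(n_bins, bin_width_ps)
  shape <- alpha1 * exp(-t / tau1) + (1 - alpha1) * exp(-t / tau2)
  conv <- conv_causal(irf_kernel(irf, bin_width_ps, n_bins), shape)
  base <- offset_C * n_bins
  of_check(base <= total_photons || total_photons == 0,
           "offset_C alone exceeds the photon budget")
  amp <- if (total_photons == 0) 0 else (total_photons - base) / sum(conv)
  counts <- amp * conv + offset_C
  decay_histogram(counts, bin_width_ps, channel)
}
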