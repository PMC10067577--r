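# Automatic intensity thresholding. Histogram methods (otsu, yen, minimum,
# triangle) operate on a 256-bin histogram of the image; "local" is adaptive
# mean thresholding. Combination specs are pixelwise unions ("a|b") and
# intersections ("a&b") of two base methods.

THRESHOLD_BASE <- c("otsu", "yen", "min", "triangle", "local")

image_histogram <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    of_stop("image is constant; histogram thresholding is undefined",
            "omiflim_degenerate_image")
  }
  # integer images (photon counts) bin at unit width when that is finer than
  # the default, avoiding empty-bin artifacts between histogram modes
  if (all(img == round(img)) && diff(rng) <= n_bins) {
    n_bins <- max(as.integer(diff(rng)), 2L)
  }
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  idx <- pmin(pmax(floor((img - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, mids = mids)
}

# Otsu: exhaustive maximization of between-class variance over bin cuts.
otsu_threshold <- function(h) {
  p <- h$counts / sum(h$counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  k <- which.max(sigma_b[-length(sigma_b)])
  h$mids[k]
}

# Yen: maximum correlation criterion (Yen, Chang & Chang 1995).
yen_threshold <- function(h) {
  p <- h$counts / sum(h$counts)
  p1 <- cumsum(p)
  p1sq <- cumsum(p^2)
  p2sq <- sum(p^2) - p1sq
  n <- length(p)
  crit <- rep(-Inf, n - 1)
  for (k in seq_len(n - 1)) {
    a <- p1sq[k] * (sum(p^2) - p1sq[k])
    b <- p1[k] * (1 - p1[k])
    if (a > 0 && b > 0) crit[k] <- -log(a) + 2 * log(b)
  }
  h$mids[which.max(crit)]
}

# Minimum: smooth the histogram with a length-3 mean until bimodal, threshold
# at the minimum between the two remaining maxima (Prewitt & Mendelsohn).
minimum_threshold <- function(h) {
  y <- as.numeric(h$counts)
  smooth3 <- function(v) (c(v[1], v[-length(v)]) + v + c(v[-1], v[length(v)])) / 3
  local_maxima <- function(v) which(diff(sign(diff(v))) < 0) + 1L
  for (i in seq_len(10000L)) {
    mx <- local_maxima(y)
    if (length(mx) == 2L) {
      seg <- seq(mx[1], mx[2])
      return(h$mids[seg[which.min(y[seg])]])
    }
    if (length(mx) < 2L) break
    y <- smooth3(y)
  }
  of_stop("minimum method failed to find a bimodal histogram",
          "omiflim_degenerate_image")
}

# Triangle (Zack): maximal distance between histogram and the chord from the
# peak to the far tail.
triangle_threshold <- function(h) {
  y <- as.numeric(h$counts)
  peak <- which.max(y)
  nz <- which(y > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  far <- if ((peak - lo) >= (hi - peak)) lo else hi
  idx <- seq(min(peak, far), max(peak, far))
  # normalized axes, as in the standard formulation
  xs <- (idx - peak) / (far - peak)
  ys <- y[idx] / y[peak]
  d <- abs(ys - (1 + xs * (y[far] / y[peak] - 1)))
  h$mids[idx[which.max(d)]]
}

#' Threshold an intensity image
#'
#' Computes a foreground mask with one of the standard automatic threshold
#' methods (`"otsu"`, `"yen"`, `"min"`, `"triangle"`, `"local"`) or a pairwise
#' combination written `"a|b"` (pixelwise union) or `"a&b"` (pixelwise
#' intersection).
#'
#' @param img non-negative numeric matrix of photon counts.
#' @param method a threshold spec string.
#' @param local_block odd block width of the adaptive mean filter.
#' @param local_offset counts a pixel must exceed its local mean by.
#' @return logical matrix, `TRUE` = foreground.
#' @export
threshold_intensity <- function(img, method = "otsu", local_block = 33,
                                local_offset = 1) {
  of_check(is.matrix(img) && all(is.finite(img)) && all(img >= 0),
           "img must be a finite non-negative matrix")
  if (grepl("|", method, fixed = TRUE) || grepl("&", method, fixed = TRUE)) {
    op <- if (grepl("|", method, fixed = TRUE)) "|" else "&"
    parts <- trimws(strsplit(method, op, fixed = TRUE)[[1]])
    of_check(length(parts) == 2L, sprintf("bad combination spec '%s'", method),
             "omiflim_config_error")
    a <- threshold_intensity(img, parts[1], local_block, local_offset)
    b <- threshold_intensity(img, parts[2], local_block, local_offset)
    return(if (op == "|") a | b else a & b)
  }
  of_check(method %in% THRESHOLD_BASE,
           sprintf("unknown threshold method '%s'", method), "omiflim_config_error")
  if (method == "local") {
    half <- (local_block - 1) / 2
    local_mean <- EBImage::filter2(img, matrix(1 / local_block^2, local_block, local_block),
                                   boundary = "replicate")
    return(img > local_mean + local_offset)
  }
  h <- image_histogram(img)
  thr <- switch(method,
                otsu = otsu_threshold(h),
                yen = yen_threshold(h),
                min = minimum_threshold(h),
                triangle = triangle_threshold(h))
  img > thr
}

#' Default threshold ensemble
#'
#' The five base methods plus all pairwise unions and intersections
#' (25 specs in total).
#'
#' @return character vector of threshold specs.
#' @export
default_threshold_specs <- function() {
  pairs <- utils::combn(THRESHOLD_BASE, 2)
  c(THRESHOLD_BASE,
    apply(pairs, 2, paste, collapse = "|"),
    apply(pairs, 2, paste, collapse = "&"))
}
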