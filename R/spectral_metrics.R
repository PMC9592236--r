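#' Frequency-band specification for ALFF/fALFF
#'
#' The metric band defaults to 0.01-0.15 Hz; the fALFF denominator spans the
#' positive-frequency axis up to 0.25 Hz (the Nyquist frequency at TR = 2 s).
#' Alternate bands 0.01-0.08 and 0.01-0.10 Hz are accepted the same way.
#'
#' @param low_hz,high_hz band edges in Hz, `0 <= low < high`.
#' @param full_low_hz,full_high_hz denominator band for fALFF; must contain
#'   the metric band.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(low_hz = 0.01, high_hz = 0.15,
                      full_low_hz = 0, full_high_hz = 0.25) {
  if (!(low_hz >= 0 && high_hz > low_hz)) {
    stop("band edges must satisfy 0 <= low < high")
  }
  if (full_low_hz > low_hz || full_high_hz < high_hz) {
    stop("the full band must contain the metric band")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 full_low_hz = full_low_hz, full_high_hz = full_high_hz),
            class = "band_spec")
}

#' Single-sided amplitude spectrum
#'
#' Amplitudes are scaled so a unit-amplitude sinusoid at an exact DFT bin has
#' unit amplitude: `a_k = (2/N) |X_k|` for `k = 1 .. floor(N/2)`, with the
#' Nyquist bin (present for even N) scaled by `1/N`. The DC bin is excluded.
#'
#' @param series numeric time series of length >= 8, finite values.
#' @param tr_s sampling interval in seconds.
#' @return list with `freq` (Hz, `k/(N*tr_s)`) and `amplitude`.
#' @export
amplitude_spectrum <- function(series, tr_s) {
  if (length(series) < 8L) stop("need at least 8 time points")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  if (tr_s <= 0) stop("`tr_s` must be positive")
  n <- length(series)
  X <- fft(series)
  kmax <- n %/% 2L
  k <- seq_len(kmax)
  a <- 2 * Mod(X[k + 1]) / n
  if (n %% 2L == 0L) a[kmax] <- Mod(X[kmax + 1]) / n
  list(freq = k / (n * tr_s), amplitude = a)
}

# Indices of spectrum bins with low <= f <= high (closed interval on bin
# frequencies, with a small tolerance against floating-point edge effects).
band_bin_index <- function(freq, low, high) {
  tol <- 1e-9 * max(freq)
  which(freq >= low - tol & freq <= high + tol)
}

#' ALFF of a single time series
#'
#' Mean single-sided spectral amplitude over the bins whose frequencies fall
#' inside the band (inclusive edges). For a 230-point series at TR = 2 s and
#' the 0.01-0.15 Hz band this averages bins 5..69 (65 bins).
#'
#' @param series numeric time series.
#' @param tr_s sampling interval (s).
#' @param band a [band_spec()].
#' @return scalar ALFF value.
#' @export
alff <- function(series, tr_s, band = band_spec()) {
  stopifnot(inherits(band, "band_spec"))
  sp <- amplitude_spectrum(series, tr_s)
  idx <- band_bin_index(sp$freq, band$low_hz, band$high_hz)
  if (!length(idx)) stop("the band contains no frequency bins for this series")
  mean(sp$amplitude[idx])
}

#' fALFF of a single time series
#'
#' Ratio of the amplitude sum inside the metric band to the amplitude sum
#' over the full band (DC excluded from both); 0 when the denominator is 0.
#'
#' @inheritParams alff
#' @return scalar in `[0, 1]`.
#' @export
falff <- function(series, tr_s, band = band_spec()) {
  stopifnot(inherits(band, "band_spec"))
  sp <- amplitude_spectrum(series, tr_s)
  idx <- band_bin_index(sp$freq, band$low_hz, band$high_hz)
  if (!length(idx)) stop("the band contains no frequency bins for this series")
  full <- band_bin_index(sp$freq, band$full_low_hz, band$full_high_hz)
  if (!length(full)) stop("the full band contains no frequency bins")
  den <- sum(sp$amplitude[full])
  if (den == 0) return(0)
  sum(sp$amplitude[idx]) / den
}

#' Voxel-wise ALFF/fALFF map
#'
#' Applies the scalar metric within the mask (zeros outside) using a single
#' FFT over all masked voxels.
#'
#' @param bold a preprocessed `volume4d`.
#' @param mask non-empty logical 3D array.
#' @param metric `"alff"` or `"falff"`.
#' @param band a [band_spec()].
#' @return Object of class `metric_map`: `values` (3D array), `metric`
#'   (`"ALFF"`/`"fALFF"`), `band`, `normalization` (`"raw"`), `mask`,
#'   `tr_s`.
#' @export
metric_map <- function(bold, mask, metric = c("alff", "falff"),
                       band = band_spec()) {
  metric <- match.arg(metric)
  stopifnot(inherits(bold, "volume4d"), inherits(band, "band_spec"))
  if (!any(mask)) stop("mask is empty")
  Y <- ts_matrix(bold$data, mask)
  n <- nrow(Y)
  if (n < 8L) stop("need at least 8 time points")
  X <- mvfft(Y)
  kmax <- n %/% 2L
  amp <- 2 * Mod(X[1 + seq_len(kmax), , drop = FALSE]) / n
  if (n %% 2L == 0L) amp[kmax, ] <- amp[kmax, ] / 2
  freq <- seq_len(kmax) / (n * bold$tr_s)
  idx <- band_bin_index(freq, band$low_hz, band$high_hz)
  if (!length(idx)) stop("the band contains no frequency bins for this series")
  vals <- if (metric == "alff") {
    colMeans(amp[idx, , drop = FALSE])
  } else {
    full <- band_bin_index(freq, band$full_low_hz, band$full_high_hz)
    den <- colSums(amp[full, , drop = FALSE])
    num <- colSums(amp[idx, , drop = FALSE])
    ifelse(den == 0, 0, num / den)
  }
  out <- array(0, dim(mask))
  out[which(mask)] <- vals
  structure(list(values = out,
                 metric = if (metric == "alff") "ALFF" else "fALFF",
                 band = band, normalization = "raw", mask = mask,
                 tr_s = bold$tr_s),
            class = "metric_map")
}

#' mALFF normalisation
#'
#' Divides an ALFF map by its mean over the mask, yielding a relative map
#' with mask mean 1.
#'
#' @param map a raw ALFF `metric_map` with positive mask mean.
#' @return The normalised `metric_map` (`normalization = "mALFF"`).
#' @export
malff_normalize <- function(map) {
  stopifnot(inherits(map, "metric_map"))
  if (map$metric != "ALFF") stop("mALFF normalisation applies to ALFF maps")
  m <- mean(map$values[map$mask])
  if (!(m > 0)) stop("mask mean is not positive; cannot normalise")
  map$values[map$mask] <- map$values[map$mask] / m
  map$normalization <- "mALFF"
  map
}

#' z-transform a metric map over its mask
#'
#' Subtracts the mask mean and divides by the mask SD (population
#' convention, divisor n), giving mask mean 0 and SD 1.
#'
#' @param map a `metric_map` with positive mask SD.
#' @return The transformed `metric_map` (`normalization = "z"`).
#' @export
ztransform_map <- function(map) {
  stopifnot(inherits(map, "metric_map"))
  v <- map$values[map$mask]
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (!(sdev > 0)) stop("mask SD is zero; cannot z-transform")
  map$values[map$mask] <- (v - mu) / sdev
  map$values[!map$mask] <- 0
  map$normalization <- "z"
  map
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s (%s), band %g-%g Hz, %d mask voxels\n",
              x$metric, x$normalization, x$band$low_hz, x$band$high_hz,
              sum(x$mask)))
  invisible(x)
}
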