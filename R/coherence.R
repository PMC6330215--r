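#' Configuration for windowed wavelet-coherence networks
#'
#' Collects every tunable of the coherence stage. Defaults follow common
#' practice for resting-state BOLD: a 3 s sampling interval, the 0.02-0.08 Hz
#' band, 20-sample windows with 90% overlap, and a complex Morlet mother
#' wavelet with center frequency `omega0 = 6` smoothed in time by a
#' scale-matched Gaussian and in scale by a 0.6-octave boxcar.
#'
#' @param tr_seconds sampling interval in seconds.
#' @param band_low,band_high coherence band in Hz; must satisfy
#'   `0 < band_low < band_high < 1/(2 * tr_seconds)` (the Nyquist limit).
#' @param window_len window length in samples.
#' @param overlap_frac fractional window overlap in `[0, 1)`.
#' @param omega0 Morlet center frequency (dimensionless).
#' @param dj scale resolution in octaves (scales are `s0 * 2^(dj * 0:J)`).
#' @param scale_smooth_octaves width of the boxcar smoother along the scale
#'   axis, in octaves.
#' @return a `coherence_config` list.
#' @export
coherence_config <- function(tr_seconds = 3, band_low = 0.02, band_high = 0.08,
                             window_len = 20, overlap_frac = 0.9,
                             omega0 = 6, dj = 1 / 12,
                             scale_smooth_octaves = 0.6) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(band_low > 0 && band_low < band_high && band_high < nyquist)) {
    stop("band [", band_low, ", ", band_high,
         "] Hz must lie strictly inside (0, Nyquist = ", nyquist, " Hz)")
  }
  stopifnot(window_len >= 2, overlap_frac >= 0, overlap_frac < 1,
            omega0 > 0, dj > 0, scale_smooth_octaves > 0)
  structure(list(tr_seconds = tr_seconds, band_low = band_low,
                 band_high = band_high, window_len = window_len,
                 overlap_frac = overlap_frac, omega0 = omega0, dj = dj,
                 scale_smooth_octaves = scale_smooth_octaves),
            class = "coherence_config")
}

# Fourier factor of the Morlet wavelet: period = scale * fourier_factor.
morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# Geometric scale grid covering the analysis band (with a small margin).
morlet_scales <- function(cfg, n_samples) {
  dt <- cfg$tr_seconds
  ff <- morlet_fourier_factor(cfg$omega0)
  s0 <- 2 * dt
  s_max <- 1.2 / (cfg$band_low * ff)
  s_max <- min(s_max, n_samples * dt)   # never beyond the record length
  if (s_max < s0) stop("analysis band requires scales shorter than 2*dt")
  J <- ceiling(log2(s_max / s0) / cfg$dj)
  scales <- s0 * 2^(cfg$dj * (0:J))
  list(scales = scales, freqs = 1 / (ff * scales))
}

# Continuous Morlet wavelet transform via the FFT (zero-padded to a power
# of two). Returns an n_scales x n_samples complex matrix.
morlet_cwt <- function(x, dt, scales, omega0) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, npad - n))
  fx <- fft(xp)
  k <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) * (2 * pi / (npad * dt))
  wave <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  norm_const <- pi^(-1 / 4)
  for (s in seq_along(scales)) {
    sc <- scales[s]
    daughter <- sqrt(2 * pi * sc / dt) * norm_const *
      exp(-((sc * k - omega0)^2) / 2) * (k > 0)
    w <- fft(fx * daughter, inverse = TRUE) / npad
    wave[s, ] <- w[seq_len(n)]
  }
  wave
}

# Smoothing operator for coherence: Gaussian in time with standard
# deviation equal to the scale (per row), boxcar across scales.
smooth_time <- function(mat, scales, dt) {
  n <- ncol(mat)
  npad <- 2^ceiling(log2(n))
  pad <- cbind(mat, matrix(0, nrow(mat), npad - n))
  fm <- t(mvfft(t(pad)))
  om <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) * (2 * pi / npad)
  for (s in seq_len(nrow(mat))) {
    fm[s, ] <- fm[s, ] * exp(-0.5 * (scales[s] / dt)^2 * om^2)
  }
  sm <- t(mvfft(t(fm), inverse = TRUE)) / npad
  sm[, seq_len(n), drop = FALSE]
}

smooth_scale <- function(mat, dj, octaves) {
  half <- max(0L, floor(octaves / dj / 2))
  if (half == 0L) return(mat)
  ns <- nrow(mat)
  out <- mat
  for (s in seq_len(ns)) {
    idx <- max(1L, s - half):min(ns, s + half)
    out[s, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  out
}

smooth_spectrum <- function(mat, scales, dt, dj, octaves) {
  smooth_scale(smooth_time(mat, scales, dt), dj, octaves)
}

#' Wavelet coherence between two series
#'
#' Magnitude-squared wavelet coherence from the continuous Morlet transform,
#' smoothed in time and scale before forming the ratio
#' `|S(Wxy / s)|^2 / (S(|Wx|^2 / s) * S(|Wy|^2 / s))`, and clipped to
#' `[0, 1]`. Smoothing is essential: without it the ratio is identically one.
#' A constant (zero-power) input is flagged degenerate and its coherence is
#' defined as zero everywhere.
#'
#' @param x,y numeric series of equal length (at least two windows long).
#' @param cfg a [coherence_config()].
#' @return list with `coherence` (n_scales x n_samples matrix in `[0, 1]`),
#'   `scales`, `freqs`, `band_scales` (indices of in-band scales) and
#'   `degenerate` flag.
#' @export
wavelet_coherence <- function(x, y, cfg = coherence_config()) {
  stopifnot(inherits(cfg, "coherence_config"), length(x) == length(y))
  if (length(x) < 2 * cfg$window_len) {
    stop("series must be at least two windows long")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  grid <- morlet_scales(cfg, length(x))
  band <- which(grid$freqs >= cfg$band_low & grid$freqs <= cfg$band_high)
  if (!length(band)) stop("no wavelet scales fall inside the analysis band")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(coherence = matrix(0, length(grid$scales), length(x)),
                scales = grid$scales, freqs = grid$freqs,
                band_scales = band, degenerate = TRUE))
  }
  dt <- cfg$tr_seconds
  Wx <- morlet_cwt(x, dt, grid$scales, cfg$omega0)
  Wy <- morlet_cwt(y, dt, grid$scales, cfg$omega0)
  inv_s <- 1 / grid$scales
  Sxx <- Re(smooth_spectrum(Mod(Wx)^2 * inv_s, grid$scales, dt, cfg$dj,
                            cfg$scale_smooth_octaves))
  Syy <- Re(smooth_spectrum(Mod(Wy)^2 * inv_s, grid$scales, dt, cfg$dj,
                            cfg$scale_smooth_octaves))
  Sxy <- smooth_spectrum(Wx * Conj(Wy) * inv_s, grid$scales, dt, cfg$dj,
                         cfg$scale_smooth_octaves)
  coh <- Mod(Sxy)^2 / pmax(Sxx * Syy, .Machine$double.eps)
  coh <- pmin(pmax(coh, 0), 1)
  list(coherence = coh, scales = grid$scales, freqs = grid$freqs,
       band_scales = band, degenerate = FALSE)
}

#' Build a multilayer coherence network from region time series
#'
#' For every node pair the wavelet coherence is computed once on the
#' full-length series (20-sample windows are shorter than the slowest
#' in-band period, so per-window transforms would be ill-posed) and then
#' averaged over the in-band scales and the samples of each sliding window.
#' The result is the N x N x T stack of symmetric, zero-diagonal coherence
#' layers.
#'
#' @param series numeric matrix, regions x samples.
#' @param cfg a [coherence_config()].
#' @return a `multilayer_network`: list with `values` (N x N x T array),
#'   `windows` (from [sliding_windows()]), `node_ids`, and a logical
#'   `degenerate` vector marking zero-power nodes (their edges are zero).
#' @export
build_multilayer <- function(series, cfg = coherence_config()) {
  stopifnot(is.matrix(series), nrow(series) >= 2)
  n_reg <- nrow(series)
  n_samp <- ncol(series)
  win <- sliding_windows(n_samp, cfg$window_len, cfg$overlap_frac)
  n_win <- nrow(win)
  grid <- morlet_scales(cfg, n_samp)
  band <- which(grid$freqs >= cfg$band_low & grid$freqs <= cfg$band_high)
  if (!length(band)) stop("no wavelet scales fall inside the analysis band")
  dt <- cfg$tr_seconds
  inv_s <- 1 / grid$scales

  degen <- apply(series, 1L, sd) == 0
  cwt <- vector("list", n_reg)
  auto <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    if (degen[r]) next
    W <- morlet_cwt(series[r, ], dt, grid$scales, cfg$omega0)
    cwt[[r]] <- W
    auto[[r]] <- Re(smooth_spectrum(Mod(W)^2 * inv_s, grid$scales, dt,
                                    cfg$dj, cfg$scale_smooth_octaves))
  }

  A <- array(0, dim = c(n_reg, n_reg, n_win))
  for (i in seq_len(n_reg - 1L)) {
    for (j in (i + 1L):n_reg) {
      if (degen[i] || degen[j]) next
      Sxy <- smooth_spectrum(cwt[[i]] * Conj(cwt[[j]]) * inv_s, grid$scales,
                             dt, cfg$dj, cfg$scale_smooth_octaves)
      coh <- Mod(Sxy)^2 / pmax(auto[[i]] * auto[[j]], .Machine$double.eps)
      coh <- pmin(pmax(coh, 0), 1)
      band_coh <- colMeans(coh[band, , drop = FALSE])
      for (l in seq_len(n_win)) {
        A[i, j, l] <- A[j, i, l] <- mean(band_coh[win$start[l]:win$end[l]])
      }
    }
  }
  structure(list(values = A, windows = win,
                 node_ids = rownames(series) %||% paste0("n", seq_len(n_reg)),
                 degenerate = degen),
            class = "multilayer_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.multilayer_network <- function(x, ...) {
  d <- dim(x$values)
  cat("multilayer_network:", d[1], "nodes x", d[3], "windows\n")
  invisible(x)
}

#' Normalize each layer of a multilayer network by its mean edge weight
#'
#' Divides every layer by the mean of its upper-triangle off-diagonal
#' entries, so each layer's mean edge weight is exactly one afterwards (the
#' structurally zero diagonal is excluded from the mean). Idempotent.
#'
#' @param A a `multilayer_network`.
#' @return the network with normalized layers.
#' @export
normalize_layers <- function(A) {
  stopifnot(inherits(A, "multilayer_network"))
  n <- dim(A$values)[1]
  ep <- edge_pairs(n)
  lin <- ep[, 1] + (ep[, 2] - 1L) * n
  for (l in seq_len(dim(A$values)[3])) {
    layer <- A$values[, , l]
    m <- mean(layer[lin])
    if (m <= 0) stop("layer ", l, " has non-positive mean edge weight; ",
                     "cannot normalize")
    A$values[, , l] <- layer / m
  }
  A
}
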