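#' Sliding-window layout over a sampled series
#'
#' Computes the window placements used for windowed connectivity: windows of
#' `window_len` samples advanced by `step = round(window_len * (1 -
#' overlap_frac))` samples. With 120 samples, 20-sample windows and 90%
#' overlap this yields the canonical T = 51 windows. Trailing samples that do
#' not fill a complete window are dropped.
#'
#' @param n_samples number of samples in the series.
#' @param window_len window length in samples (>= 2).
#' @param overlap_frac fractional overlap between consecutive windows, in
#'   `[0, 1)`; the implied step must be at least one sample.
#' @return data.frame with 1-based inclusive `start` and `end` sample
#'   indices, one row per window.
#' @examples
#' nrow(sliding_windows(120, 20, 0.9)) # 51
#' @export
sliding_windows <- function(n_samples, window_len, overlap_frac) {
  stopifnot(length(n_samples) == 1L, length(window_len) == 1L,
            length(overlap_frac) == 1L,
            window_len >= 2, overlap_frac >= 0, overlap_frac < 1)
  if (n_samples < window_len) {
    stop("n_samples (", n_samples, ") is smaller than window_len (",
         window_len, ")")
  }
  step <- round(window_len * (1 - overlap_frac))
  if (step < 1) stop("window step rounds to zero; decrease overlap_frac")
  n_win <- floor((n_samples - window_len) / step) + 1L
  start <- (seq_len(n_win) - 1L) * step + 1L
  data.frame(start = as.integer(start),
             end = as.integer(start + window_len - 1L))
}
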