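# Welch power spectral density and the derived spectral summaries.

#' Welch power spectral density estimate
#'
#' Overlapped-segment averaged periodogram: Hann window, segment length
#' `min(n, nperseg)`, 50% overlap, per-segment mean removal, one-sided
#' density scaling.
#'
#' @param x numeric series on a uniform grid.
#' @param fs sampling rate in Hz.
#' @param nperseg maximum segment length (default 1024).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welchPsd <- function(x, fs, nperseg = 1024) {
  n <- length(x)
  stopifnot(n >= 8, fs > 0)
  nseg <- min(n, nperseg)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  k <- seq_len(nseg) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / nseg))      # periodic Hann
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs * u)
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when nseg even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = acc / length(starts))
}

.power_quantile_freq <- function(freq, psd, q) {
  cs <- cumsum(psd)
  tot <- cs[length(cs)]
  if (tot <= 0) return(NA_real_)
  target <- q * tot
  i <- which(cs >= target)[1]
  if (i == 1) return(freq[1])
  # linear interpolation within the crossing bin
  frac <- (target - cs[i - 1]) / (cs[i] - cs[i - 1])
  freq[i - 1] + frac * (freq[i] - freq[i - 1])
}

#' Spectral summary features of a uniformly sampled series
#'
#' Welch PSD (DC bin excluded from the power accounting), from which are
#' derived: the median frequency (below which 50% of in-band power lies),
#' the 95% spectral edge frequency (SEF95), and the spectral entropy
#' (Shannon entropy of the power-normalized PSD divided by `log(#bins)`,
#' hence in \[0, 1\]).
#'
#' @param x numeric series (at least 256 samples).
#' @param fs sampling rate in Hz.
#' @param nperseg Welch segment length cap (default 1024).
#' @return Named list `median_freq`, `sef95`, `spec_entropy`; all `NA` for
#'   an all-zero (or too short) series.
#' @export
psdSpectralFeatures <- function(x, fs, nperseg = 1024) {
  na <- list(median_freq = NA_real_, sef95 = NA_real_,
             spec_entropy = NA_real_)
  if (length(x) < 256 || all(x == 0) || any(!is.finite(x))) return(na)
  ps <- welchPsd(x, fs, nperseg)
  keep <- ps$freq > 0                    # exclude DC from power accounting
  freq <- ps$freq[keep]; psd <- ps$psd[keep]
  if (sum(psd) <= 0) return(na)
  p <- psd / sum(psd)
  h <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  list(median_freq = .power_quantile_freq(freq, psd, 0.5),
       sef95 = .power_quantile_freq(freq, psd, 0.95),
       spec_entropy = h)
}
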