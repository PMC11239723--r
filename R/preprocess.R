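#' Create a denoising configuration
#'
#' @param bandpassLow,bandpassHigh band-pass corner frequencies (Hz).
#' @param bandpassOrder Butterworth prototype order of the band-pass.
#' @param waveletName wavelet for the shrinkage step (db4 supported).
#' @param waveletLevel decomposition level.
#' @param highpassCutoff baseline-wander high-pass cutoff (Hz).
#' @param highpassOrder Butterworth order of the high-pass.
#' @return a [DenoiseConfig-class].
#' @export
denoiseConfig <- function(bandpassLow = 0.5, bandpassHigh = 40,
                          bandpassOrder = 4L, waveletName = "db4",
                          waveletLevel = 8L, highpassCutoff = 0.1,
                          highpassOrder = 6L) {
  new("DenoiseConfig", bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
      bandpassOrder = as.integer(bandpassOrder), waveletName = waveletName,
      waveletLevel = as.integer(waveletLevel),
      highpassCutoff = highpassCutoff, highpassOrder = as.integer(highpassOrder))
}

# ---- Butterworth second-order sections -------------------------------------
# Filters are designed in zero-pole-gain form and applied as cascaded
# biquads: the ECG cutoffs sit at extremely small normalized frequencies
# (0.1 Hz at 500 Hz), where a single high-order transfer function is
# numerically fragile but cascaded sections are well conditioned.

butterAnalogPoles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# zeros/poles/gain of the digital filter via bilinear transform with
# prewarped corner frequencies; fs in Hz, corners in Hz
butterZpk <- function(n, corners, type, fs) {
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  p <- butterAnalogPoles(n)
  if (type == "low") {
    wc <- warp(corners[1])
    pa <- p * wc; za <- complex(0); k <- wc^n
  } else if (type == "high") {
    wc <- warp(corners[1])
    pa <- wc / p; za <- rep(0 + 0i, n)
    k <- 1   # |H| -> 1 as s -> infinity
  } else {  # bandpass
    w1 <- warp(corners[1]); w2 <- warp(corners[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    pb <- p * bw / 2
    disc <- sqrt(pb^2 - w0^2)
    pa <- c(pb + disc, pb - disc)
    za <- rep(0 + 0i, n)
    k <- bw^n
  }
  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pa) / (fs2 - pa)
  kd <- k * Re(prod(fs2 - za) / prod(fs2 - pa))
  extra <- length(pa) - length(za)
  if (extra > 0) zd <- c(zd, rep(-1 + 0i, extra))
  list(z = zd, p = pd, k = kd)
}

# pair conjugate poles/zeros into biquad sections (b, a coefficient rows)
zpk2sos <- function(zpk) {
  pairUp <- function(v) {
    out <- list()
    v <- v[order(Im(v), Re(v))]
    used <- rep(FALSE, length(v))
    for (i in seq_along(v)) {
      if (used[i]) next
      if (abs(Im(v[i])) > 1e-10) {
        j <- which(!used & abs(v - Conj(v[i])) < 1e-8)[1]
      } else {
        j <- which(!used & abs(Im(v)) <= 1e-10 & seq_along(v) != i)[1]
      }
      if (is.na(j)) { out[[length(out) + 1]] <- v[i]; used[i] <- TRUE }
      else { out[[length(out) + 1]] <- c(v[i], v[j]); used[c(i, j)] <- TRUE }
    }
    out
  }
  ppairs <- pairUp(zpk$p)
  zpairs <- pairUp(zpk$z)
  ns <- max(length(ppairs), length(zpairs))
  sos <- matrix(0, ns, 6)
  for (s in seq_len(ns)) {
    pp <- if (s <= length(ppairs)) ppairs[[s]] else complex(0)
    zz <- if (s <= length(zpairs)) zpairs[[s]] else complex(0)
    a <- Re(switch(as.character(length(pp)),
                   "0" = c(1, 0, 0),
                   "1" = c(1, -Re(pp), 0),
                   c(1, -(Re(pp[1]) + Re(pp[2])), Re(pp[1] * pp[2]))))
    b <- Re(switch(as.character(length(zz)),
                   "0" = c(1, 0, 0),
                   "1" = c(1, -Re(zz), 0),
                   c(1, -(Re(zz[1]) + Re(zz[2])), Re(zz[1] * zz[2]))))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

# zero-phase (forward-backward) application of cascaded biquads with
# odd-reflection padding and steady-state initial conditions (no start-up
# transient on constant inputs); compiled for speed
sosFiltFilt <- function(sos, x) {
  .cppSosFiltFilt(sos, as.numeric(x))
}

applyPerLead <- function(record, fun) {
  out <- record
  for (i in seq_len(nrow(record@signal)))
    out@signal[i, ] <- fun(record@signal[i, ])
  out
}

#' Band-pass filter a record
#'
#' Zero-phase Butterworth band-pass (cascaded biquads, forward-backward),
#' applied independently per lead; length preserving.
#'
#' @param record an [ECGRecord-class].
#' @param config a [DenoiseConfig-class].
#' @return the filtered record.
#' @export
bandpass <- function(record, config = denoiseConfig()) {
  fs <- record@samplingRate
  assertFlag(config@bandpassHigh < fs / 2,
             "bandpass high cutoff %g Hz is not below Nyquist (%g Hz)",
             config@bandpassHigh, fs / 2)
  sos <- zpk2sos(butterZpk(config@bandpassOrder,
                           c(config@bandpassLow, config@bandpassHigh),
                           "pass", fs))
  applyPerLead(record, function(x) sosFiltFilt(sos, x))
}

#' Baseline-wander high-pass filter
#'
#' Zero-phase Butterworth high-pass at the configured cutoff (default
#' 0.1 Hz, order 6), removing residual baseline drift.
#'
#' @inheritParams bandpass
#' @return the filtered record.
#' @export
baselineHighpass <- function(record, config = denoiseConfig()) {
  fs <- record@samplingRate
  assertFlag(config@highpassCutoff < fs / 2,
             "highpass cutoff %g Hz is not below Nyquist (%g Hz)",
             config@highpassCutoff, fs / 2)
  sos <- zpk2sos(butterZpk(config@highpassOrder, config@highpassCutoff,
                           "high", fs))
  applyPerLead(record, function(x) sosFiltFilt(sos, x))
}

# ---- db4 wavelet shrinkage -------------------------------------------------

# Daubechies-4 (8-tap, 4 vanishing moments) decomposition low-pass filter
db4DecLo <- function() {
  c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
    -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
    0.7148465705525415, 0.23037781330885523)
}

# one periodized analysis level; inverse is the exact transpose
dwtPeriodic <- function(x, h, g) {
  n <- length(x)
  K <- length(h)
  idx <- outer(seq(0, n - 2, by = 2), 0:(K - 1), `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.numeric(xm %*% h), d = as.numeric(xm %*% g))
}

idwtPeriodic <- function(a, d, h, g) {
  n <- 2L * length(a)
  K <- length(h)
  x <- numeric(n)
  pos <- outer(seq(0, n - 2, by = 2), 0:(K - 1), `+`) %% n + 1L
  contrib <- outer(a, h) + outer(d, g)
  for (k in seq_len(K))
    x[pos[, k]] <- x[pos[, k]] + contrib[, k]
  x
}

#' Wavelet denoising (db4, universal soft threshold)
#'
#' Multilevel periodized orthogonal db4 decomposition to the configured
#' level; detail coefficients are soft-thresholded with the universal
#' threshold `sigma * sqrt(2 log n)`, where `sigma` is the
#' median-absolute-deviation noise estimate taken from the finest detail
#' level. Reconstruction is exact (transpose) and length preserving.
#'
#' @inheritParams bandpass
#' @return the denoised record.
#' @export
waveletDenoise <- function(record, config = denoiseConfig()) {
  assertFlag(config@waveletName == "db4",
             "unsupported wavelet '%s' (db4 available)", config@waveletName)
  lev <- config@waveletLevel
  n0 <- ncol(record@signal)
  assertFlag(n0 >= 2^lev,
             "signal length %d too short for level %d (needs >= %d)",
             n0, lev, 2^lev)
  h <- db4DecLo()
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  blk <- 2^lev
  nPad <- ceiling(n0 / blk) * blk
  applyPerLead(record, function(x) {
    if (nPad > n0) {                       # reflect-pad to a dyadic multiple
      x <- c(x, rev(x)[seq_len(nPad - n0)])
    }
    a <- x
    details <- vector("list", lev)
    for (l in seq_len(lev)) {
      w <- dwtPeriodic(a, h, g)
      a <- w$a
      details[[l]] <- w$d
    }
    sigma <- stats::median(abs(details[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
    details <- lapply(details, function(d) sign(d) * pmax(abs(d) - thr, 0))
    for (l in rev(seq_len(lev)))
      a <- idwtPeriodic(a, details[[l]], h, g)
    a[seq_len(n0)]
  })
}

#' Full denoising pipeline
#'
#' Band-pass, then wavelet shrinkage, then the baseline high-pass, in that
#' order; the classical "pre-processed" arm against which raw-input models
#' are compared.
#'
#' @inheritParams bandpass
#' @return the denoised record.
#' @export
denoisePipeline <- function(record, config = denoiseConfig()) {
  baselineHighpass(waveletDenoise(bandpass(record, config), config), config)
}
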