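#' Initialize a bank of diagonal state-space models
#'
#' Creates the continuous-time parameters of `nChannels` independent
#' single-input single-output diagonal SSMs using the linear diagonal
#' initialization: mode `n` (0-based) gets `a_n = -1/2 + i*pi*n`, the input
#' map is fixed at `b = 1`, the output map `c` is drawn from the standard
#' complex normal, and `log(Delta)` is drawn log-uniformly over
#' `deltaRange`. Only `stateSize/2` conjugate-representative modes are
#' stored; the conjugate partners are implicit and guarantee a real kernel.
#'
#' @param nChannels number of model channels H.
#' @param stateSize state dimension N per channel; must be even.
#' @param deltaRange length-2 positive numeric `(lo, hi)`; `Delta` is the
#'   step size in seconds per sample, drawn log-uniformly.
#' @param seed integer; identical seeds give bit-identical parameters.
#' @return a [ContinuousDiagonalSSM-class].
#' @examples
#' ssm <- initS4D(2, 8, c(1e-3, 1e-1), seed = 7)
#' Re(ssm@a[, 1])   # all -0.5
#' @export
initS4D <- function(nChannels, stateSize, deltaRange = c(1e-3, 1e-1), seed) {
  assertFlag(nChannels >= 1, "nChannels must be a positive integer")
  assertFlag(stateSize >= 2 && stateSize %% 2 == 0,
             "stateSize must be a positive even integer, got %s", stateSize)
  assertFlag(length(deltaRange) == 2 && all(deltaRange > 0) &&
               deltaRange[1] < deltaRange[2],
             "deltaRange must be (lo, hi) with 0 < lo < hi")
  H <- as.integer(nChannels)
  M <- as.integer(stateSize) %/% 2L
  a <- matrix(complex(real = -0.5, imaginary = pi * (seq_len(M) - 1)),
              nrow = M, ncol = H)
  b <- matrix(1 + 0i, M, H)
  params <- withSeed(seed, {
    cre <- matrix(stats::rnorm(M * H, sd = sqrt(0.5)), M, H)
    cim <- matrix(stats::rnorm(M * H, sd = sqrt(0.5)), M, H)
    d <- stats::rnorm(H)
    logDelta <- stats::runif(H, log(deltaRange[1]), log(deltaRange[2]))
    list(c = matrix(complex(real = cre, imaginary = cim), M, H),
         d = d, logDelta = logDelta)
  })
  new("ContinuousDiagonalSSM",
      nChannels = H, stateSize = as.integer(stateSize),
      a = a, b = b, c = params$c, d = params$d,
      logDelta = params$logDelta, conjugatePairs = TRUE)
}

#' Zero-order-hold discretization
#'
#' Converts continuous diagonal SSM parameters to their discrete-time
#' counterparts under a zero-order hold with step `Delta = exp(logDelta)`:
#' `aBar = exp(Delta*a)` and `bBar = (exp(Delta*a) - 1)/a * b`, using the
#' analytic limit `bBar = Delta*b` when `|a| < 1e-12`. The output map and
#' feedthrough are unchanged.
#'
#' @param ssm a [ContinuousDiagonalSSM-class].
#' @return a [DiscreteDiagonalSSM-class].
#' @export
setMethod("discretizeZOH", "ContinuousDiagonalSSM", function(ssm) {
  validObject(ssm)
  delta <- exp(ssm@logDelta)
  da <- sweep(ssm@a, 2L, delta, `*`)
  aBar <- exp(da)
  small <- Mod(ssm@a) < 1e-12
  bBar <- (aBar - 1) / ssm@a
  if (any(small))
    bBar[small] <- sweep(ssm@a * 0 + 1, 2L, delta, `*`)[small]
  bBar <- bBar * ssm@b
  new("DiscreteDiagonalSSM",
      nChannels = ssm@nChannels, stateSize = ssm@stateSize,
      aBar = aBar, bBar = bBar, c = ssm@c, d = ssm@d,
      conjugatePairs = ssm@conjugatePairs)
})

#' Construct a discrete diagonal SSM directly
#'
#' Convenience constructor used by oracles and tests that want explicit
#' discrete parameters rather than going through [discretizeZOH()].
#'
#' @param aBar,bBar,c complex matrices (modes x channels) or vectors
#'   (coerced to one channel).
#' @param d numeric feedthrough per channel (default 0).
#' @param conjugatePairs logical; `TRUE` treats the stored modes as
#'   conjugate-pair representatives (output `2*Re(.)`), `FALSE` takes them
#'   literally (output `Re(.)`).
#' @return a [DiscreteDiagonalSSM-class].
#' @export
discreteSSM <- function(aBar, bBar, c, d = NULL, conjugatePairs = TRUE) {
  toMat <- function(x) {
    x <- as.complex(x)
    if (is.null(dim(x))) matrix(x, ncol = 1L) else x
  }
  aBar <- toMat(aBar); bBar <- toMat(bBar); c <- toMat(c)
  H <- ncol(aBar)
  if (is.null(d)) d <- numeric(H)
  M <- nrow(aBar)
  new("DiscreteDiagonalSSM",
      nChannels = as.integer(H),
      stateSize = as.integer(if (conjugatePairs) 2L * M else M),
      aBar = aBar, bBar = bBar, c = c, d = as.numeric(d),
      conjugatePairs = conjugatePairs)
}

#' Materialize the convolution kernel
#'
#' Evaluates the impulse response `K[n] = f * Re( sum_m c*bBar*aBar^n )`
#' for `n = 0..L-1` and every channel, where the factor `f` is 2 under the
#' conjugate-pair convention and 1 otherwise. Powers are formed through a
#' Vandermonde structure (`exp(n * log(aBar))`), not a per-step recurrence.
#' The feedthrough `d` is not part of the kernel.
#'
#' @param dssm a [DiscreteDiagonalSSM-class].
#' @param length kernel length L (>= 1).
#' @return a [ConvolutionKernel-class] with a `nChannels x L` value matrix.
#' @export
setMethod("materializeKernel", "DiscreteDiagonalSSM", function(dssm, length) {
  assertFlag(length >= 1, "kernel length must be >= 1, got %s", length)
  L <- as.integer(length)
  H <- dssm@nChannels
  fac <- if (dssm@conjugatePairs) 2 else 1
  w <- dssm@c * dssm@bBar
  K <- matrix(0, H, L)
  n <- 0:(L - 1L)
  for (h in seq_len(H)) {
    ab <- dssm@aBar[, h]
    V <- exp(log(ab) %o% n)          # modes x L Vandermonde
    zero <- Mod(ab) == 0
    if (any(zero)) {                 # 0^0 = 1, 0^n = 0 for n > 0
      V[zero, ] <- 0
      V[zero, 1L] <- 1
    }
    row <- as.vector(w[, h] %*% V)   # complex length L
    resid <- max(abs(Im(fac * row)) * (if (fac == 2) 0 else 1))
    K[h, ] <- fac * Re(row)
    if (!dssm@conjugatePairs && resid > 1e-8)
      warning("kernel has non-negligible imaginary residue: ", resid)
  }
  new("ConvolutionKernel", values = K, length = L)
})

#' Causal convolution by FFT
#'
#' Computes the causal linear convolution of each channel of `u` with the
#' matching kernel row, truncated to the input length. The transform length
#' is the next 5-smooth size at least `2L`, so no circular wrap-around can
#' reach the retained samples: output index `n` depends only on
#' `u[, 1..n+1]`.
#'
#' @param u numeric matrix, channels x L (a single vector is treated as one
#'   channel).
#' @param kernel a [ConvolutionKernel-class] whose length equals `ncol(u)`
#'   and whose row count equals `nrow(u)`.
#' @return numeric matrix, channels x L.
#' @export
causalFftConvolve <- function(u, kernel) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  stopifnot(is(kernel, "ConvolutionKernel"))
  L <- ncol(u)
  assertFlag(L == kernel@length,
             "input length %d does not match kernel length %d",
             L, kernel@length)
  assertFlag(nrow(u) == nrow(kernel@values),
             "input has %d channels but kernel has %d rows",
             nrow(u), nrow(kernel@values))
  Lf <- nextFastLength(2L * L)
  Upad <- rbind(t(u), matrix(0, Lf - L, nrow(u)))
  Kpad <- rbind(t(kernel@values), matrix(0, Lf - L, nrow(u)))
  Y <- stats::mvfft(stats::mvfft(Upad) * stats::mvfft(Kpad),
                    inverse = TRUE) / Lf
  t(Re(Y[seq_len(L), , drop = FALSE]))
}

#' Sequential recurrence scan (correctness oracle)
#'
#' Steps the discrete recurrence `x_n = aBar x_{n-1} + bBar u_n`,
#' `y_n = f*Re(c' x_n) + d u_n` from a zero state, channel by channel.
#' This is the slow but transparent reference against which the FFT
#' convolution path is validated.
#'
#' @param dssm a [DiscreteDiagonalSSM-class].
#' @param u numeric matrix, channels x L (vector = one channel).
#' @return numeric matrix, channels x L.
#' @export
recurrentScan <- function(dssm, u) {
  stopifnot(is(dssm, "DiscreteDiagonalSSM"))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  H <- dssm@nChannels
  assertFlag(nrow(u) == H, "input has %d channels; model expects %d",
             nrow(u), H)
  L <- ncol(u)
  fac <- if (dssm@conjugatePairs) 2 else 1
  M <- nrow(dssm@aBar)
  x <- matrix(0 + 0i, M, H)
  y <- matrix(0, H, L)
  for (n in seq_len(L)) {
    un <- u[, n]
    x <- dssm@aBar * x + dssm@bBar * matrix(un, M, H, byrow = TRUE)
    y[, n] <- fac * Re(colSums(dssm@c * x)) + dssm@d * un
  }
  y
}

# ---- accessors & show ------------------------------------------------------

#' @rdname accessors
setMethod("nChannels", "ContinuousDiagonalSSM", function(object) object@nChannels)
#' @rdname accessors
setMethod("nChannels", "DiscreteDiagonalSSM", function(object) object@nChannels)
#' @rdname accessors
setMethod("stateSize", "ContinuousDiagonalSSM", function(object) object@stateSize)
#' @rdname accessors
setMethod("stateSize", "DiscreteDiagonalSSM", function(object) object@stateSize)
#' @rdname accessors
setMethod("kernelValues", "ConvolutionKernel", function(object) object@values)

setMethod("show", "ContinuousDiagonalSSM", function(object) {
  cat(sprintf(
    "ContinuousDiagonalSSM: %d channel(s), state size %d (%d stored modes)\n",
    object@nChannels, object@stateSize, nrow(object@a)))
  cat(sprintf("  Delta range: [%.3g, %.3g] s/sample\n",
              exp(min(object@logDelta)), exp(max(object@logDelta))))
})

setMethod("show", "DiscreteDiagonalSSM", function(object) {
  cat(sprintf(
    "DiscreteDiagonalSSM: %d channel(s), %d stored modes, max |aBar| = %.6f\n",
    object@nChannels, nrow(object@aBar), max(Mod(object@aBar))))
})

setMethod("show", "ConvolutionKernel", function(object) {
  cat(sprintf("ConvolutionKernel: %d channel(s) x L = %d\n",
              nrow(object@values), object@length))
})
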