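test_that("linear initialization places modes on the -1/2 + i*pi*n grid", {
  ssm <- initS4D(1, 4, c(1e-3, 1e-1), seed = 7)
  expect_equal(ssm@a[, 1], c(-0.5 + 0i, -0.5 + pi * 1i))
  ssm2 <- initS4D(2, 8, c(1e-3, 1e-1), seed = 7)
  expect_true(all(Re(ssm2@a) == -0.5))
  expect_true(all(ssm2@b == 1 + 0i))
  expect_true(all(exp(ssm2@logDelta) >= 1e-3 & exp(ssm2@logDelta) <= 1e-1))
})

test_that("initialization is a pure function of the seed", {
  a <- initS4D(3, 16, seed = 7)
  b <- initS4D(3, 16, seed = 7)
  expect_identical(a@c, b@c)
  expect_identical(a@d, b@d)
  expect_identical(a@logDelta, b@logDelta)
  expect_false(identical(a@c, initS4D(3, 16, seed = 8)@c))
})

test_that("invalid initializer arguments are rejected", {
  expect_error(initS4D(2, 5, seed = 1), "even")
  expect_error(initS4D(2, 8, c(0, 1e-1), seed = 1), "deltaRange")
  expect_error(initS4D(2, 8, c(1e-1, 1e-3), seed = 1), "deltaRange")
})

test_that("zero-order hold matches the scalar closed forms", {
  s <- manualSSM(-1 + 0i, 1 + 0i, 1 + 0i, 0, log(log(2)))
  d <- discretizeZOH(s)
  expect_equal(as.complex(d@aBar[1, 1]), 0.5 + 0i, tolerance = 1e-12)
  expect_equal(as.complex(d@bBar[1, 1]), 0.5 + 0i, tolerance = 1e-12)
  # a -> 0 analytic limit
  s0 <- manualSSM(0 + 0i, 1 + 0i, 1 + 0i, 0, log(0.01))
  d0 <- discretizeZOH(s0)
  expect_equal(as.complex(d0@aBar[1, 1]), 1 + 0i)
  expect_equal(as.complex(d0@bBar[1, 1]), 0.01 + 0i)
  # near-zero step size behaves as the identity map
  sZ <- manualSSM(-2 + 1i, 1 + 0i, 1 + 0i, 0, -700)
  dZ <- discretizeZOH(sZ)
  expect_lt(Mod(dZ@aBar[1, 1] - 1), 1e-10)
  expect_lt(Mod(dZ@bBar[1, 1]), 1e-10)
})

test_that("ZOH matches closed forms over 1000 random stable modes", {
  set.seed(101)
  n <- 1000
  a <- complex(real = -runif(n, 0, 5), imaginary = runif(n, -20, 20))
  a[sample(n, 20)] <- 0 + 0i   # exercise the limit branch
  delta <- exp(runif(n, log(1e-4), log(1)))
  s <- manualSSM(matrix(a, ncol = 1), matrix(1 + 0i, n), matrix(1 + 0i, n),
                 0, 0)
  # per-mode check with per-mode delta: loop channels of a wide model
  worst <- 0
  for (i in seq_len(n)) {
    si <- manualSSM(a[i], 1 + 0i, 1 + 0i, 0, log(delta[i]))
    di <- discretizeZOH(si)
    aRef <- exp(delta[i] * a[i])
    bRef <- if (a[i] == 0) delta[i] + 0i else (exp(delta[i] * a[i]) - 1) / a[i]
    worst <- max(worst,
                 Mod(di@aBar[1, 1] - aRef) / max(1e-300, Mod(aRef)),
                 Mod(di@bBar[1, 1] - bRef) / max(1e-300, Mod(bRef)))
  }
  expect_lt(worst, 1e-12)
})

test_that("kernel materialization follows the mode power series", {
  d <- discreteSSM(0.5 + 0i, 0.5 + 0i, 1 + 0i, conjugatePairs = FALSE)
  k <- materializeKernel(d, 4L)
  expect_equal(as.numeric(kernelValues(k)), c(0.5, 0.25, 0.125, 0.0625))
  k1 <- materializeKernel(discreteSSM(0.3 + 0.2i, 0.7 + 0i, 1 - 1i), 1L)
  expect_equal(as.numeric(kernelValues(k1)),
               2 * Re((1 - 1i) * (0.7 + 0i)))
  expect_error(materializeKernel(d, 0L), ">= 1")
})

test_that("conjugate-pair kernels equal full-spectrum evaluation", {
  # explicit evaluation with both conjugate partners must agree with the
  # doubled-real-part shortcut, and the full-spectrum imaginary residue
  # must vanish
  set.seed(5)
  M <- 6; L <- 256
  aBar <- complex(real = runif(M, -0.9, 0.9), imaginary = runif(M, -0.5, 0.5))
  aBar <- aBar / pmax(1, Mod(aBar))
  bBar <- complex(real = rnorm(M), imaginary = rnorm(M))
  cc <- complex(real = rnorm(M), imaginary = rnorm(M))
  K <- kernelValues(materializeKernel(discreteSSM(aBar, bBar, cc), L))
  full <- vapply(0:(L - 1), function(n) {
    s <- sum(cc * bBar * aBar^n) + sum(Conj(cc) * Conj(bBar) * Conj(aBar)^n)
    expect_lt(abs(Im(s)), 1e-10)
    Re(s)
  }, numeric(1))
  expect_equal(as.numeric(K), full, tolerance = 1e-10)
})

test_that("FFT convolution is the identity on a unit impulse and on zeros", {
  ssm <- initS4D(2, 8, seed = 3)
  d <- discretizeZOH(ssm)
  L <- 64L
  k <- materializeKernel(d, L)
  u <- matrix(0, 2, L); u[, 1] <- 1
  y <- causalFftConvolve(u, k)
  expect_equal(y, kernelValues(k), tolerance = 1e-10)
  expect_equal(causalFftConvolve(matrix(0, 2, L), k), matrix(0, 2, L))
  expect_error(causalFftConvolve(matrix(0, 2, 32), k), "length")
  expect_error(causalFftConvolve(matrix(0, 3, L), k), "channels")
})

test_that("FFT convolution agrees with the recurrent-scan oracle", {
  set.seed(11)
  for (trial in 1:25) {
    H <- sample(1:4, 1); N <- 2 * sample(1:16, 1); L <- sample(16:512, 1)
    ssm <- initS4D(H, N, seed = trial)
    d <- discretizeZOH(ssm)
    u <- matrix(rnorm(H * L), H, L)
    y1 <- causalFftConvolve(u, materializeKernel(d, L)) + d@d * u
    y2 <- recurrentScan(d, u)
    expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-5)
  }
})

test_that("recurrent scan obeys its closed-form special cases", {
  d <- discreteSSM(0 + 0i, 0.4 + 0.1i, 0.2 - 0.3i, d = 0.5)
  u <- matrix(c(1, -2, 3), 1)
  y <- recurrentScan(d, u)
  gain <- 2 * Re((0.2 - 0.3i) * (0.4 + 0.1i)) + 0.5
  expect_equal(as.numeric(y), gain * as.numeric(u))     # memoryless when aBar=0
  expect_equal(recurrentScan(d, matrix(0, 1, 5)), matrix(0, 1, 5))
  # first step from zero state
  d2 <- discreteSSM(0.9 + 0i, 0.4 + 0.1i, 0.2 - 0.3i, d = 1.5)
  y2 <- recurrentScan(d2, matrix(2, 1, 1))
  expect_equal(as.numeric(y2), (2 * Re((0.2 - 0.3i) * (0.4 + 0.1i)) + 1.5) * 2)
})

test_that("convolution output is causal", {
  set.seed(21)
  ssm <- initS4D(2, 8, seed = 4)
  d <- discretizeZOH(ssm)
  L <- 100L
  k <- materializeKernel(d, L)
  u <- matrix(rnorm(2 * L), 2, L)
  y <- causalFftConvolve(u, k)
  m <- 40L
  u2 <- u; u2[, m] <- u2[, m] + 1
  y2 <- causalFftConvolve(u2, k)
  expect_equal(y2[, seq_len(m - 1)], y[, seq_len(m - 1)], tolerance = 1e-12)
  expect_gt(max(abs(y2[, m:L] - y[, m:L])), 0)
})

test_that("initialized models are discretely stable with decaying kernels", {
  for (seed in 1:5) {
    ssm <- initS4D(3, 16, seed = seed)
    d <- discretizeZOH(ssm)
    expect_true(all(Mod(d@aBar) <= 1))
    K <- kernelValues(materializeKernel(d, 128L))
    # |K[n]| bounded by the decaying mode envelope
    env <- vapply(0:127, function(n)
      2 * colSums(Mod(d@c * d@bBar) * Mod(d@aBar)^n), numeric(3))
    expect_true(all(abs(K) <= env + 1e-12))
  }
})

test_that("validity catches unstable or malformed models", {
  expect_error(manualSSM(1 + 0i, 1 + 0i, 1 + 0i, 0, 0), "stability")
  expect_error(new("DiscreteDiagonalSSM", nChannels = 1L, stateSize = 2L,
                   aBar = matrix(1.5 + 0i), bBar = matrix(1 + 0i),
                   c = matrix(1 + 0i), d = 0, conjugatePairs = TRUE)
               , "aBar")
})
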