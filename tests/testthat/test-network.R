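test_that("builds are seeded and configs are validated", {
  cfg <- tinyConfig()
  m1 <- buildClassifier(cfg, seed = 3)
  m2 <- buildClassifier(cfg, seed = 3)
  expect_identical(m1@params, m2@params)
  m3 <- buildClassifier(cfg, seed = 4)
  expect_false(identical(m1@params, m3@params))
  expect_gt(nParameters(m1), 0)
  expect_error(modelConfig(nLayers = 0), "nLayers")
  expect_error(modelConfig(dropout = 1), "dropout")
  expect_error(modelConfig(stateSize = 7), "stateSize")
})

test_that("forward pass satisfies the shape contract at any length", {
  cfg <- modelConfig(nLayers = 2, modelDim = 16, stateSize = 8, nClasses = 3,
                     nLeads = 12, dropout = 0)
  m <- buildClassifier(cfg, seed = 3)
  set.seed(1)
  x <- array(rnorm(5 * 12 * 1024), c(5, 12, 1024))
  pb <- modelForward(m, x)
  expect_equal(dim(probabilities(pb)), c(5L, 3L))
  for (L in c(1L, 7L, 100L)) {
    xi <- array(rnorm(2 * 12 * L), c(2, 12, L))
    expect_equal(dim(probabilities(modelForward(m, xi))), c(2L, 3L))
  }
  expect_error(modelForward(m, array(0, c(2, 7, 64))), "expected 12.*found 7")
})

test_that("inference is deterministic, batch-equivariant and in (0,1)", {
  cfg <- tinyConfig(dropout = 0.3)   # dropout must be inert at inference
  m <- buildClassifier(cfg, seed = 5)
  set.seed(2)
  x <- array(rnorm(4 * 4 * 96), c(4, 4, 96))
  p1 <- probabilities(modelForward(m, x))
  p2 <- probabilities(modelForward(m, x))
  expect_identical(p1, p2)
  perm <- c(3, 1, 4, 2)
  p3 <- probabilities(modelForward(m, x[perm, , ]))
  expect_equal(p3, p1[perm, ], tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  # identical rows give identical outputs
  x0 <- array(0, c(3, 4, 64))
  pz <- probabilities(modelForward(m, x0))
  expect_true(all(is.finite(pz)))
  expect_equal(pz[1, ], pz[2, ], tolerance = 0)
})

test_that("compiled forward equals the reference composition of SSM ops", {
  cfg <- tinyConfig(nLayers = 2, modelDim = 5, stateSize = 8, nClasses = 2,
                    nLeads = 3)
  m <- buildClassifier(cfg, seed = 11)
  set.seed(7)
  x <- array(rnorm(2 * 3 * 40), c(2, 3, 40))
  ref <- referenceForward(m, x)
  got <- modelForward(m, x)@logits
  expect_equal(got, ref, tolerance = 1e-10, ignore_attr = TRUE)
  gotF <- modelForward(m, x, precision = "single")@logits
  expect_equal(gotF, ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  cfg <- tinyConfig(nLayers = 2, modelDim = 6, stateSize = 8, nClasses = 3,
                    nLeads = 4)
  m <- buildClassifier(cfg, seed = 3)
  set.seed(42)
  B <- 3; P <- 4; L <- 32
  x <- aperm(array(rnorm(B * P * L), c(B, P, L)), c(2, 3, 1))
  y <- matrix(rbinom(3 * B, 1, 0.5), 3, B)
  lossAt <- function(params)
    s4decg:::.cppS4DLossGrad(params, as.numeric(x), c(P, L, B),
                             s4decg:::cppConfig(cfg), y, 0, 1L, FALSE)$loss
  out <- s4decg:::.cppS4DLossGrad(m@params, as.numeric(x), c(P, L, B),
                                  s4decg:::cppConfig(cfg), y, 0, 1L, FALSE)
  worst <- 0
  for (nm in names(m@params)) {
    g <- out$grads[[nm]]
    expect_false(is.null(g), info = nm)
    idx <- sample(length(m@params[[nm]]), min(2, length(m@params[[nm]])))
    for (i in idx) {
      eps <- 1e-4
      pp <- m@params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m@params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("every parameter receives gradient on a random batch", {
  cfg <- tinyConfig()
  m <- buildClassifier(cfg, seed = 9)
  set.seed(8)
  B <- 4; P <- 4; L <- 48
  x <- array(rnorm(P * L * B), c(P, L, B))
  y <- matrix(rbinom(3 * B, 1, 0.5), 3, B)
  out <- s4decg:::.cppS4DLossGrad(m@params, as.numeric(x), c(P, L, B),
                                  s4decg:::cppConfig(cfg), y, 0, 1L, FALSE)
  for (nm in names(m@params))
    expect_gt(max(abs(out$grads[[nm]])), 0, label = paste("grad", nm))
})

test_that("label binarization applies the >= threshold rule", {
  p <- matrix(c(0.7, 0.2, 0.5), 1)
  expect_equal(as.numeric(predictLabels(p, 0.5)), c(1L, 0L, 1L))
  expect_equal(as.numeric(predictLabels(matrix(0.5, 2, 3), 0.5)),
               rep(1L, 6))                      # ties go positive
  expect_equal(as.numeric(predictLabels(matrix(0.1, 1, 4), 0.5)),
               rep(0L, 4))                      # all-zero rows allowed
  expect_error(predictLabels(p, 0), "threshold")
  expect_error(predictLabels(p, 1), "threshold")
})

test_that("checkpoints round-trip through the JSON container", {
  dir <- withr::local_tempdir()
  cfg <- tinyConfig()
  m <- buildClassifier(cfg, seed = 21)
  path <- file.path(dir, "model.json")
  writeModel(m, path)
  back <- readModel(path)
  expect_equal(back@config@nLayers, cfg@nLayers)
  expect_equal(back@config@classNames, cfg@classNames)
  for (nm in names(m@params))
    expect_equal(back@params[[nm]], m@params[[nm]], tolerance = 1e-12,
                 label = nm)
  set.seed(3)
  x <- array(rnorm(2 * 4 * 64), c(2, 4, 64))
  expect_equal(probabilities(modelForward(back, x)),
               probabilities(modelForward(m, x)), tolerance = 1e-12)
})
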