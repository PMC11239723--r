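# Shared fixtures and reference implementations used across test files.

# tiny model config used by most network/trainer tests
tinyConfig <- function(nLayers = 2L, modelDim = 6L, stateSize = 8L,
                       nClasses = 3L, nLeads = 4L, dropout = 0) {
  modelConfig(nLayers = nLayers, modelDim = modelDim, stateSize = stateSize,
              nClasses = nClasses, nLeads = nLeads, dropout = dropout)
}

# continuous SSM with explicit parameters (bypasses the seeded initializer)
manualSSM <- function(a, b, c, d, logDelta, conjugatePairs = TRUE) {
  toMat <- function(x) if (is.null(dim(x))) matrix(as.complex(x), ncol = 1) else x
  a <- toMat(a); b <- toMat(b); c <- toMat(c)
  new("ContinuousDiagonalSSM", nChannels = ncol(a),
      stateSize = as.integer(if (conjugatePairs) 2 * nrow(a) else nrow(a)),
      a = a, b = b, c = c, d = as.numeric(d), logDelta = as.numeric(logDelta),
      conjugatePairs = conjugatePairs)
}

# independent reference forward pass for the classifier, composed from the
# exposed SSM operations plus plain R; used to validate the compiled core
referenceForward <- function(model, x) {
  cfg <- model@config
  p <- model@params
  gelu <- function(z) z * stats::pnorm(z)
  B <- dim(x)[1]
  t(vapply(seq_len(B), function(b) {
    u <- matrix(x[b, , ], dim(x)[2], dim(x)[3])
    h <- p$emb_W %*% u + p$emb_b
    L <- ncol(u)
    chanNorm <- function(h, g, bta) {
      # per-timepoint channel standardization with a variance floor
      mu <- colMeans(h)
      v <- colMeans(sweep(h, 2, mu)^2)
      sweep(sweep(h, 2, mu), 2, sqrt(v + 1e-2), "/") * g + bta
    }
    for (l in seq_len(cfg@nLayers)) {
      pre <- sprintf("l%d_", l)
      un <- chanNorm(h, p[[paste0(pre, "ln_g")]], p[[paste0(pre, "ln_b")]])
      M <- nrow(p[[paste0(pre, "s")]])
      ssm <- manualSSM(
        a = matrix(complex(real = -exp(p[[paste0(pre, "s")]]),
                           imaginary = p[[paste0(pre, "a_im")]]), M),
        b = matrix(1 + 0i, M, cfg@modelDim),
        c = matrix(complex(real = p[[paste0(pre, "c_re")]],
                           imaginary = p[[paste0(pre, "c_im")]]), M),
        d = p[[paste0(pre, "d")]],
        logDelta = p[[paste0(pre, "log_delta")]])
      K <- materializeKernel(discretizeZOH(ssm), L)
      z <- causalFftConvolve(un, K) + un * p[[paste0(pre, "d")]]
      g <- gelu(z)
      a <- p[[paste0(pre, "mix_W")]] %*% g + p[[paste0(pre, "mix_b")]]
      s <- 1 / (1 + exp(-(p[[paste0(pre, "gate_W")]] %*% g +
                          p[[paste0(pre, "gate_b")]])))
      h <- h + a * s
    }
    feat <- rowMeans(h) * p$fln_g + p$fln_b
    as.numeric(p$dec_W %*% feat + p$dec_b)
  }, numeric(cfg@nClasses)))
}

# brute-force metric oracles (exhaustive pair counting / per-positive
# precision averaging)
bruteAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

bruteAuprc <- function(scores, labels) {
  ord <- order(scores, labels, decreasing = TRUE)
  y <- labels[ord]
  precAt <- numeric(0)
  for (k in which(y == 1)) precAt <- c(precAt, sum(y[1:k]) / k)
  mean(precAt)
}

# small synthetic cohort with short records, for fast training tests
shortCohort <- function(n, seed, length = 512L, classMix = NULL) {
  if (is.null(classMix))
    classMix <- stats::setNames(rep(0.25, 2), c("AF", "RBBB"))
  synthDataset(syntheticCohortConfig(
    nRecords = n, classMix = classMix, length = length, seed = seed))
}
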