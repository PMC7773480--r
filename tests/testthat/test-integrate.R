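test_that("VAE loss components follow the closed-form Gaussian KL", {
  d <- 6L
  X <- matrix(rnorm(4 * d), 4)
  # posterior == prior: KL exactly zero
  m0 <- makeConstantEncoderModel(d, 2L, mu = 0, logvar = 0)
  l0 <- vaeLoss(m0, X, beta = 1)
  expect_equal(l0$kl, 0)
  # mu = 1, sigma = 1, one latent dim: KL = 0.5 (0.5 * (mu^2 + s2 - 1 - ln s2))
  m1 <- makeConstantEncoderModel(d, 1L, mu = 1, logvar = 0)
  expect_equal(vaeLoss(m1, X, beta = 1)$kl, 0.5)
  # beta = 0 reduces the total to the reconstruction NLL
  lb <- vaeLoss(m1, X, beta = 0)
  expect_equal(lb$total, lb$nll)
  # closed form equals a Monte-Carlo estimate within 3 standard errors
  set.seed(61)
  mu <- 0.7; s <- 1.4
  m2 <- makeConstantEncoderModel(d, 1L, mu = mu, logvar = 2 * log(s))
  closed <- vaeLoss(m2, X, beta = 1)$kl
  z <- rnorm(10000, mu, s)
  samples <- dnorm(z, mu, s, log = TRUE) - dnorm(z, log = TRUE)
  expect_lt(abs(closed - mean(samples)),
            3 * sd(samples) / sqrt(length(samples)))
})

test_that("an uninformative discriminator scores ln 2 per cell", {
  disc <- makeZeroDiscriminator(3L)
  Zs <- matrix(rnorm(30), 10)
  Zt <- matrix(rnorm(30), 10)
  expect_equal(discriminatorLoss(disc, Zs, Zt), log(2))
  expect_error(discriminatorLoss(disc, matrix(0, 2, 4), Zt), "latentDim")
})

test_that("discriminator training on identical distributions converges to ln 2,
           and separable codes drive its loss toward zero", {
  set.seed(71)
  ld <- 2L
  trainDisc <- function(Zs, Zt, steps = 400) {
    net <- scMatcher:::.mlpInit(c(ld + 1L, 8L, 8L, 1L))
    sn <- scMatcher:::.spectralNormalize(net)
    net <- sn$net; u <- sn$u
    st <- scMatcher:::.adamInit(net)
    lab <- matrix(1, nrow(Zs) + nrow(Zt), 1)
    X <- cbind(rbind(Zs, Zt), lab)
    y <- c(rep(1, nrow(Zs)), rep(0, nrow(Zt)))
    losses <- numeric(steps)
    for (i in seq_len(steps)) {
      fc <- scMatcher:::.mlpForward(net, X)
      s <- fc$out[, 1]
      losses[i] <- scMatcher:::.bceWithLogits(s, y)
      gd <- scMatcher:::.mlpBackward(
        net, fc, matrix((scMatcher:::.sigmoid(s) - y) / length(y), ncol = 1))
      up <- scMatcher:::.adamStep(net, gd, st, 5e-3)
      net <- up$net; st <- up$state
      sn <- scMatcher:::.spectralNormalize(net, u)
      net <- sn$net; u <- sn$u
    }
    losses
  }
  # same class-conditionals: the Bayes-optimal loss is ln 2
  same <- trainDisc(matrix(rnorm(2000 * ld), ncol = ld),
                    matrix(rnorm(2000 * ld), ncol = ld))
  expect_lt(abs(tail(same, 1) - log(2)), 0.05)
  # far-separated codes: loss decreases monotonically (smoothed) toward 0
  apart <- trainDisc(matrix(rnorm(500 * ld), ncol = ld),
                     matrix(rnorm(500 * ld), ncol = ld) + 8)
  expect_lt(tail(apart, 1), 0.3)
  expect_lt(tail(apart, 1), apart[1])
  sm <- stats::filter(apart, rep(1 / 50, 50), sides = 1)
  expect_true(all(diff(na.omit(as.vector(sm))) < 0.01))
})

test_that("backprop gradients match central finite differences", {
  set.seed(81)
  d <- 5L; ld <- 2L; B <- 4L
  X <- matrix(rnorm(B * d), B)
  enc <- scMatcher:::.mlpInit(c(d, 6L, 2L * ld))
  dec <- scMatcher:::.mlpInit(c(ld, 6L, d))
  disc <- scMatcher:::.mlpInit(c(ld + 1L, 4L, 1L))
  eps <- matrix(rnorm(B * ld), B)
  lab <- matrix(1, B, 1)
  lossOf <- function(enc, dec) {
    st <- scMatcher:::.aeStep(enc, dec, X, ld, betaKL = 0.3, eps = eps,
                              disc = disc, lab1h = lab, betaAdv = 2)
    st$nll + 0.3 * st$kl + 2 * st$adv
  }
  st <- scMatcher:::.aeStep(enc, dec, X, ld, betaKL = 0.3, eps = eps,
                            disc = disc, lab1h = lab, betaAdv = 2)
  h <- 1e-5
  for (probe in list(list(net = "dec", l = 1, i = 2, j = 3),
                     list(net = "dec", l = 2, i = 1, j = 4),
                     list(net = "enc", l = 1, i = 3, j = 2),
                     list(net = "enc", l = 2, i = 5, j = ld + 1))) {
    pert <- function(s) {
      e2 <- enc; d2 <- dec
      if (probe$net == "enc") e2$W[[probe$l]][probe$i, probe$j] <-
          e2$W[[probe$l]][probe$i, probe$j] + s
      else d2$W[[probe$l]][probe$i, probe$j] <-
          d2$W[[probe$l]][probe$i, probe$j] + s
      lossOf(e2, d2)
    }
    fd <- (pert(h) - pert(-h)) / (2 * h)
    gr <- if (probe$net == "enc") st$encGrads$W[[probe$l]][probe$i, probe$j]
          else st$decGrads$W[[probe$l]][probe$i, probe$j]
    expect_lt(abs(fd - gr) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("the adversarial objective ignores the fixed source codes", {
  set.seed(91)
  d <- 4L
  sim <- smallSim(nCells = 60, nFeatures = d)
  cfg <- scimConfig(vaeEpochs = 2L, scimEpochs = 1L, seed = 1L)
  vf <- trainVAE(sim[[1]], cfg)
  disc <- makeZeroDiscriminator(8L)
  X <- matrix(rnorm(12 * d), 12)
  eps <- matrix(rnorm(12 * 8), 12)
  o1 <- scimObjective(vf$model, disc, X, zS = matrix(rnorm(80), 10),
                      beta = 1, eps = eps)
  o2 <- scimObjective(vf$model, disc, X, zS = matrix(rnorm(160), 20),
                      beta = 1, eps = eps)
  expect_identical(o1, o2)
  # beta = 0 reduces to pure reconstruction
  o0 <- scimObjective(vf$model, disc, X, beta = 0, eps = eps)
  expect_equal(o0$total, o0$nll)
})

test_that("spectral normalization bounds every discriminator layer", {
  set.seed(99)
  net <- scMatcher:::.mlpInit(c(10L, 8L, 8L, 1L))
  net$W <- lapply(net$W, function(W) W * 5)  # inflate far beyond norm 1
  u <- NULL
  for (i in 1:50) {
    sn <- scMatcher:::.spectralNormalize(net, u)
    net <- sn$net; u <- sn$u
  }
  for (W in net$W) expect_lte(max(svd(W)$d), 1 + 1e-3)
})

test_that("encoding is deterministic, row-equivariant and eight-dimensional", {
  sim <- smallSim(nCells = 80, nFeatures = 16)
  cfg <- scimConfig(vaeEpochs = 4L, seed = 3L)
  vf <- trainVAE(sim[[1]], cfg)
  Z <- codeMatrix(vf$codes)
  expect_identical(dim(Z), c(80L, 8L))
  expect_identical(codeMatrix(encodeCells(sim[[1]], vf$model)), Z)
  perm <- sample(80)
  Zp <- codeMatrix(encodeCells(sim[[1]][, perm], vf$model))
  expect_identical(Zp, Z[perm, ])
  expect_error(encodeCells(sim[[2]][1:10, ], vf$model), "feature count")
})

test_that("a single repeated cell collapses to one latent point with
           near-zero reconstruction error", {
  x <- rnbinom(24, mu = 20, size = 5)
  counts <- matrix(x, nrow = 24, ncol = 50)
  rownames(counts) <- sprintf("g%d", 1:24)
  colnames(counts) <- sprintf("c%d", 1:50)
  cfg <- scimConfig(vaeEpochs = 300L, seed = 7L, batchSize = 16L)
  vf <- trainVAE(counts, cfg)
  # constant features standardize to zero, so reconstruction NLL should sit
  # at its floor 0.5 * d * log(2 pi) and all codes coincide
  X0 <- matrix(0, 50, 24)  # the preprocessed form of 50 identical cells
  l <- vaeLoss(vf$model, X0, beta = 0)
  expect_lt(l$nll - 0.5 * 24 * log(2 * pi), 0.1)
  Z <- codeMatrix(vf$codes)
  expect_lt(max(apply(Z, 2, function(col) diff(range(col)))), 1e-8)
})

test_that("VAE latent space separates the simulated branches", {
  sim <- smallSim(nCells = 2500, nFeatures = 256, seeds = c(31, 32))
  cfg <- scimConfig(vaeEpochs = 128L, seed = 13L)
  vf <- trainVAE(sim[[1]], cfg)
  set.seed(1)
  km <- kmeans(codeMatrix(vf$codes), 5L, nstart = 25)
  ari <- adjustedRandIndex(km$cluster,
                           SummarizedExperiment::colData(sim[[1]])$branch)
  expect_gt(ari, 0.5)
})

test_that("training runs are bit-reproducible under a fixed seed", {
  sim <- smallSim(nCells = 120, nFeatures = 12)
  cfg <- scimConfig(vaeEpochs = 3L, scimEpochs = 3L, seed = 17L,
                    batchSize = 64L)
  f1 <- trainSCIM(sim, 1L, cfg)
  f2 <- trainSCIM(sim, 1L, cfg)
  expect_identical(codeMatrix(f1@codes[[2]]), codeMatrix(f2@codes[[2]]))
  expect_identical(f1@history, f2@history)
  # the training log carries every loss component per epoch
  expect_true(all(c("epoch", "technology", "nll", "adv", "discLoss",
                    "divergence") %in% names(f1@history)))
})

test_that("semi-supervised censoring hides the configured label share", {
  labs <- rep(c("A", "B"), 500)
  shown <- scMatcher:::.censorLabels(labs, 0.1, seed = 3L)
  frac <- mean(shown != scMatcher:::.censoredLabel)
  expect_lt(abs(frac - 0.1), 0.04)
  expect_true(all(shown[shown != scMatcher:::.censoredLabel] ==
                    labs[shown != scMatcher:::.censoredLabel]))
  expect_identical(scMatcher:::.censorLabels(labs, 0.1, seed = 3L), shown)
})
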