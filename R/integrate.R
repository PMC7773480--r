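#' Integration configuration
#'
#' Creates the hyperparameter bundle for latent-space integration. Defaults
#' follow the settings that work well for branching single-cell data: latent
#' dimension 8, two 64-unit hidden layers for the autoencoders, two 8-unit
#' layers for the discriminator, 256 VAE-initialization epochs with KL weight
#' 0.01 and ADAM learning rate 5e-4.
#'
#' @param latentDim latent dimensionality.
#' @param betaVAE KL weight during VAE initialization.
#' @param betaAdv adversarial weight during integration. The reconstruction
#'   term is a negative log-likelihood summed over features, so the
#'   adversarial term needs a weight of comparable magnitude; the default
#'   (100) balances the two for a few hundred features and was selected on
#'   simulated data by divergence-based model selection (see
#'   [divergenceScore()]).
#' @param lrAE,lrDisc ADAM learning rates. The discriminator default
#'   (2e-3) is deliberately above the autoencoder rate: with a small
#'   spectrally-normalized discriminator, a faster adversary produces a
#'   markedly more reliable alignment (selected on simulated data via
#'   divergence-based model selection).
#' @param vaeEpochs,scimEpochs epochs for the two phases.
#' @param hiddenAE,hiddenDisc hidden layer widths.
#' @param batchSize minibatch size.
#' @param labelFraction fraction of cells whose label is revealed to the
#'   discriminator (1 = fully supervised; the rest are censored).
#' @param discSteps discriminator updates per autoencoder update; a fresh
#'   source/target batch is drawn for each.
#' @param transform input transform applied to counts before
#'   standardization: `"log1p"` (scRNA-style), `"arcsinh"` (CyTOF-style,
#'   `asinh(x/5)`) or `"none"`.
#' @param divergenceK neighbor count for the divergence logged during
#'   training.
#' @param seed integer seed for all randomness of a run.
#' @return a [ScimConfig-class].
#' @examples
#' scimConfig(vaeEpochs = 8L, scimEpochs = 8L)
#' @export
scimConfig <- function(latentDim = 8L, betaVAE = 0.01, betaAdv = 100,
                       lrAE = 5e-4, lrDisc = 2e-3, vaeEpochs = 256L,
                       scimEpochs = 64L, hiddenAE = c(64L, 64L),
                       hiddenDisc = c(8L, 8L), batchSize = 256L,
                       labelFraction = 1.0, discSteps = 1L,
                       transform = "log1p", divergenceK = 5L, seed = 1L) {
  new("ScimConfig", latentDim = as.integer(latentDim),
      betaVAE = betaVAE, betaAdv = betaAdv, lrAE = lrAE, lrDisc = lrDisc,
      vaeEpochs = as.integer(vaeEpochs), scimEpochs = as.integer(scimEpochs),
      hiddenAE = as.integer(hiddenAE), hiddenDisc = as.integer(hiddenDisc),
      batchSize = as.integer(batchSize), labelFraction = labelFraction,
      discSteps = as.integer(discSteps), transform = transform,
      divergenceK = as.integer(divergenceK), seed = as.integer(seed))
}

.censoredLabel <- "<censored>"

# counts (features x cells) -> transformed, standardized cells x features
.preprocessMatrix <- function(counts, transform, center = NULL,
                              scale = NULL) {
  X <- t(as.matrix(counts))
  X <- switch(transform,
              log1p = log1p(X),
              arcsinh = asinh(X / 5),
              none = X,
              stop("unknown transform: ", transform))
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[scale < 1e-8] <- 1
  }
  X <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  list(X = X, center = center, scale = scale)
}

.datasetMatrix <- function(data) {
  if (is(data, "SummarizedExperiment")) as.matrix(assay(data, "counts"))
  else if (is.matrix(data)) data
  else stop("expected a SingleCellExperiment or a features-x-cells matrix")
}

.encoderPosterior <- function(encNet, X, latentDim) {
  ef <- .mlpForward(encNet, X)
  mu <- ef$out[, seq_len(latentDim), drop = FALSE]
  lvRaw <- ef$out[, latentDim + seq_len(latentDim), drop = FALSE]
  lv <- pmin(pmax(lvRaw, -10), 10)
  list(mu = mu, lv = lv, lvRaw = lvRaw, cache = ef)
}

.stableSoftplusNeg <- function(s) pmax(-s, 0) + log1p(exp(-abs(s)))

# Forward + backward pass for one autoencoder batch. betaKL > 0 gives the
# VAE objective; a non-NULL disc adds the adversarial term betaAdv *
# (-log D(z_t)) with the discriminator frozen.
.aeStep <- function(enc, dec, X, latentDim, betaKL, eps, disc = NULL,
                    lab1h = NULL, betaAdv = 0) {
  B <- nrow(X)
  d <- ncol(X)
  post <- .encoderPosterior(enc, X, latentDim)
  mu <- post$mu
  lv <- post$lv
  sdz <- exp(0.5 * lv)
  z <- mu + sdz * eps
  df <- .mlpForward(dec, z)
  xhat <- df$out
  nll <- mean(0.5 * rowSums((X - xhat)^2)) + 0.5 * d * log(2 * pi)
  kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
  dxhat <- (xhat - X) / B
  db <- .mlpBackward(dec, df, dxhat)
  dz <- db$dX
  adv <- 0
  dmuAdv <- 0
  if (!is.null(disc)) {
    # the adversarial term acts on the posterior means: these are the codes
    # used downstream for matching, so their distribution is what must align
    din <- cbind(mu, lab1h)
    dfc <- .mlpForward(disc, din)
    s <- dfc$out[, 1]
    adv <- mean(.stableSoftplusNeg(s))
    ds <- -(1 - .sigmoid(s)) / B * betaAdv
    dd <- .mlpBackward(disc, dfc, matrix(ds, ncol = 1))
    dmuAdv <- dd$dX[, seq_len(latentDim), drop = FALSE]
  }
  dmu <- dz + dmuAdv + betaKL * mu / B
  dlv <- dz * eps * 0.5 * sdz + betaKL * 0.5 * (exp(lv) - 1) / B
  dlv <- dlv * (post$lvRaw > -10 & post$lvRaw < 10)
  eb <- .mlpBackward(enc, post$cache, cbind(dmu, dlv))
  list(nll = nll, kl = kl, adv = adv,
       total = nll + betaKL * kl + betaAdv * adv,
       encGrads = eb, decGrads = db, z = z, mu = mu)
}

#' Variational autoencoder loss
#'
#' Evaluates the VAE objective for a batch: Gaussian reconstruction negative
#' log-likelihood (unit decoder variance) plus `beta` times the closed-form
#' KL divergence between the Gaussian posterior and the standard-normal
#' prior, averaged over cells.
#'
#' @param model a [TechnologyModel-class].
#' @param x either a `SingleCellExperiment` (preprocessed with the model's
#'   stored transform and standardization) or an already-preprocessed
#'   cells-by-features matrix.
#' @param beta KL weight.
#' @param eps optional matrix of standard-normal draws for the
#'   reparameterized latent sample (cells x latentDim); drawn internally when
#'   `NULL`.
#' @return list with `total`, `nll` and `kl` components.
#' @export
vaeLoss <- function(model, x, beta = 0.01, eps = NULL) {
  if (is(x, "SummarizedExperiment")) {
    X <- .preprocessMatrix(.datasetMatrix(x), model@transform,
                           model@center, model@scale)$X
  } else if (is.matrix(x)) {
    X <- x
  } else stop("x must be a matrix or SingleCellExperiment")
  ld <- model@latentDim
  if (is.null(eps)) eps <- matrix(rnorm(nrow(X) * ld), ncol = ld)
  st <- .aeStep(model@encoder, model@decoder, X, ld, betaKL = beta,
                eps = eps)
  .checkFinite(st$total, "loss")
  list(total = st$nll + beta * st$kl, nll = st$nll, kl = st$kl)
}

#' Discriminator binary cross-entropy
#'
#' Loss of the discriminator classifying label-conditioned source codes
#' (positive class) against target codes (negative class). Cells without a
#' label receive the censored class.
#'
#' @param disc a [ScimDiscriminator-class].
#' @param codesS,codesT [LatentCodes-class] or plain matrices.
#' @param labelsS,labelsT optional per-cell labels.
#' @return mean binary cross-entropy (scalar).
#' @export
discriminatorLoss <- function(disc, codesS, codesT, labelsS = NULL,
                              labelsT = NULL) {
  Zs <- if (is(codesS, "LatentCodes")) codesS@codes else codesS
  Zt <- if (is(codesT, "LatentCodes")) codesT@codes else codesT
  if (ncol(Zs) != disc@latentDim || ncol(Zt) != disc@latentDim)
    stop("code dimension does not match the discriminator's latentDim")
  lev <- disc@labelLevels
  labS <- if (is.null(labelsS)) rep(.censoredLabel, nrow(Zs)) else labelsS
  labT <- if (is.null(labelsT)) rep(.censoredLabel, nrow(Zt)) else labelsT
  Xd <- rbind(cbind(Zs, .oneHot(labS, lev)), cbind(Zt, .oneHot(labT, lev)))
  y <- c(rep(1, nrow(Zs)), rep(0, nrow(Zt)))
  s <- .mlpForward(disc@net, Xd)$out[, 1]
  .bceWithLogits(s, y)
}

#' Adversarial autoencoder objective for a target technology
#'
#' Evaluates the integration objective for a target batch: reconstruction
#' negative log-likelihood plus `beta` times the adversarial term, i.e. the
#' loss the target encoder incurs when the discriminator recognizes its
#' codes as non-source. The source codes `zS` are constants: no gradient
#' reaches the source encoder.
#'
#' @param modelT target [TechnologyModel-class].
#' @param disc the [ScimDiscriminator-class] (held fixed).
#' @param xT preprocessed target batch (cells x features matrix) or a
#'   `SingleCellExperiment`.
#' @param zS fixed source codes (unused in the value; they enter only the
#'   discriminator's own update).
#' @param beta adversarial weight.
#' @param labels optional target labels for the discriminator conditioning.
#' @param eps optional reparameterization noise.
#' @return list with `total`, `nll` and `adv` components.
#' @export
scimObjective <- function(modelT, disc, xT, zS = NULL, beta = 1.0,
                          labels = NULL, eps = NULL) {
  if (is(xT, "SummarizedExperiment"))
    xT <- .preprocessMatrix(.datasetMatrix(xT), modelT@transform,
                            modelT@center, modelT@scale)$X
  ld <- modelT@latentDim
  if (is.null(eps)) eps <- matrix(rnorm(nrow(xT) * ld), ncol = ld)
  lab <- if (is.null(labels)) rep(.censoredLabel, nrow(xT)) else labels
  st <- .aeStep(modelT@encoder, modelT@decoder, xT, ld, betaKL = 0,
                eps = eps, disc = disc@net,
                lab1h = .oneHot(lab, disc@labelLevels), betaAdv = beta)
  list(total = st$nll + beta * st$adv, nll = st$nll, adv = st$adv)
}

#' Train a VAE on the source technology
#'
#' Initializes the shared latent space by fitting a variational autoencoder
#' to one technology with the ADAM optimizer. The posterior means of all
#' cells become the first set of fixed source codes for the adversarial
#' phase.
#'
#' @param source a `SingleCellExperiment` (or features-x-cells matrix).
#' @param config a [ScimConfig-class]; `vaeEpochs`, `betaVAE` and `lrAE`
#'   govern this phase.
#' @param technology tag stored in the model; defaults to the dataset's
#'   metadata tag.
#' @return list with elements `model` ([TechnologyModel-class]), `codes`
#'   ([LatentCodes-class], posterior means) and `history` (per-epoch
#'   data.frame of loss components).
#' @export
trainVAE <- function(source, config = scimConfig(), technology = NULL) {
  counts <- .datasetMatrix(source)
  if (is.null(technology))
    technology <- if (is(source, "SummarizedExperiment") &&
                      !is.null(metadata(source)$technology))
      metadata(source)$technology else "source"
  pp <- .preprocessMatrix(counts, config@transform)
  X <- pp$X
  n <- nrow(X)
  d <- ncol(X)
  ld <- config@latentDim
  .withSeed(.deriveSeed(config@seed, "vae"), {
    enc <- .mlpInit(c(d, config@hiddenAE, 2L * ld))
    dec <- .mlpInit(c(ld, rev(config@hiddenAE), d))
    sE <- .adamInit(enc)
    sD <- .adamInit(dec)
    hist <- data.frame()
    for (epoch in seq_len(config@vaeEpochs)) {
      perm <- sample(n)
      splits <- split(perm, ceiling(seq_along(perm) / config@batchSize))
      tot <- c(nll = 0, kl = 0)
      for (bi in seq_along(splits)) {
        idx <- splits[[bi]]
        eps <- matrix(rnorm(length(idx) * ld), ncol = ld)
        st <- .aeStep(enc, dec, X[idx, , drop = FALSE], ld,
                      betaKL = config@betaVAE, eps = eps)
        .checkFinite(st$total, "VAE loss", epoch, bi)
        up <- .adamStep(enc, st$encGrads, sE, config@lrAE)
        enc <- up$net; sE <- up$state
        up <- .adamStep(dec, st$decGrads, sD, config@lrAE)
        dec <- up$net; sD <- up$state
        tot <- tot + c(st$nll, st$kl) * length(idx)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, nll = tot[["nll"]] / n,
                                     kl = tot[["kl"]] / n))
    }
    model <- new("TechnologyModel", technology = technology,
                 features = rownames(counts) %||% sprintf("f%d", seq_len(d)),
                 encoder = enc, decoder = dec, latentDim = ld,
                 transform = config@transform, center = pp$center,
                 scale = pp$scale)
    # center and unit-scale the code distribution: downstream consumers
    # (discriminator, Euclidean matching, divergence) are all conditioned
    # on the code geometry, so an isotropic source anchor helps each
    raw <- .encoderPosterior(enc, X, ld)$mu
    cc <- colMeans(raw)
    cs <- apply(raw, 2, sd)
    cs[cs < 1e-8] <- 1
    model@codeCenter <- cc
    model@codeScale <- cs
    list(model = model, codes = encodeCells(source, model), history = hist)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode cells into the shared latent space
#'
#' Deterministically maps cells to their posterior-mean latent codes under a
#' trained model. Row order follows the input; permuting input cells
#' permutes codes identically.
#'
#' @param data a `SingleCellExperiment` or features-x-cells matrix with the
#'   model's feature space.
#' @param model a [TechnologyModel-class].
#' @return a [LatentCodes-class] (cells x latentDim).
#' @export
encodeCells <- function(data, model) {
  counts <- .datasetMatrix(data)
  if (nrow(counts) != length(model@features))
    stop("feature count mismatch: model expects ", length(model@features),
         " features, data has ", nrow(counts))
  X <- .preprocessMatrix(counts, model@transform, model@center,
                         model@scale)$X
  mu <- .encoderPosterior(model@encoder, X, model@latentDim)$mu
  if (length(model@codeCenter))
    mu <- sweep(sweep(mu, 2, model@codeCenter, "-"), 2,
                model@codeScale, "/")
  rownames(mu) <- colnames(counts) %||% sprintf("cell%d", seq_len(nrow(X)))
  new("LatentCodes", codes = mu, technology = model@technology)
}

.censorLabels <- function(labels, fraction, seed) {
  .withSeed(seed, {
    out <- as.character(labels)
    hide <- runif(length(out)) > fraction
    out[hide] <- .censoredLabel
    out
  })
}

.datasetLabels <- function(data) {
  if (is(data, "SummarizedExperiment") && "label" %in% names(colData(data)))
    as.character(colData(data)$label)
  else rep(.censoredLabel, ncol(.datasetMatrix(data)))
}

#' Adversarial integration of technologies into a shared latent space
#'
#' Runs the full integration: a VAE is trained on the source technology
#' (unless a fit is supplied), its posterior-mean codes are frozen, and each
#' target technology's autoencoder is then trained to reconstruct its own
#' features while fooling a shared label-conditioned discriminator into
#' classifying its codes as source. After every autoencoder update the
#' discriminator is updated to separate source from target codes, followed
#' by spectral normalization of its weights. All networks use ADAM.
#'
#' Because adversarial optimization is not monotone, the divergence between
#' source and target codes is logged every epoch and the returned models
#' are the snapshots from each target's lowest-divergence epoch (see the
#' `selectedEpoch` slot).
#'
#' @param datasets named list of `SingleCellExperiment`s (>= 2).
#' @param sourceIndex which dataset anchors the latent space.
#' @param config a [ScimConfig-class].
#' @param sourceFit optional result of [trainVAE()] to reuse.
#' @return a [ScimFit-class].
#' @seealso [matchCells()], [divergenceScore()]
#' @export
trainSCIM <- function(datasets, sourceIndex = 1L, config = scimConfig(),
                      sourceFit = NULL) {
  if (length(datasets) < 2) stop("need at least 2 datasets")
  sourceIndex <- as.integer(sourceIndex)
  if (sourceIndex < 1 || sourceIndex > length(datasets))
    stop("sourceIndex out of range")
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("tech%d", seq_along(datasets))
  ld <- config@latentDim

  labels <- lapply(datasets, .datasetLabels)
  lev <- c(sort(unique(unlist(lapply(labels, function(x)
    setdiff(x, .censoredLabel))))), .censoredLabel)
  shown <- lapply(seq_along(datasets), function(i)
    .censorLabels(labels[[i]], config@labelFraction,
                  .deriveSeed(config@seed, "censor", i)))

  if (is.null(sourceFit)) sourceFit <- trainVAE(datasets[[sourceIndex]],
                                                config)
  zS <- codeMatrix(sourceFit$codes)
  nS <- nrow(zS)
  lab1hS <- .oneHot(shown[[sourceIndex]], lev)

  targets <- setdiff(seq_along(datasets), sourceIndex)
  pp <- vector("list", length(datasets))
  models <- vector("list", length(datasets))
  names(models) <- names(datasets)
  models[[sourceIndex]] <- sourceFit$model

  .withSeed(.deriveSeed(config@seed, "scim"), {
    encs <- list(); decs <- list(); sE <- list(); sD <- list()
    for (i in targets) {
      counts <- .datasetMatrix(datasets[[i]])
      prep <- .preprocessMatrix(counts, config@transform)
      pp[[i]] <- prep
      d <- ncol(prep$X)
      encs[[i]] <- .mlpInit(c(d, config@hiddenAE, 2L * ld))
      decs[[i]] <- .mlpInit(c(ld, rev(config@hiddenAE), d))
      sE[[i]] <- .adamInit(encs[[i]])
      sD[[i]] <- .adamInit(decs[[i]])
    }
    disc <- .mlpInit(c(ld + length(lev), config@hiddenDisc, 1L))
    sn <- .spectralNormalize(disc)
    disc <- sn$net; snU <- sn$u
    sDisc <- .adamInit(disc)

    mkModel <- function(i) new("TechnologyModel",
      technology = names(datasets)[i],
      features = rownames(.datasetMatrix(datasets[[i]])) %||%
        sprintf("f%d", seq_len(ncol(pp[[i]]$X))),
      encoder = encs[[i]], decoder = decs[[i]], latentDim = ld,
      transform = config@transform, center = pp[[i]]$center,
      scale = pp[[i]]$scale)

    initDiv <- vapply(targets, function(i) {
      zi <- codeMatrix(encodeCells(datasets[[i]], mkModel(i)))
      divergenceValue(divergenceScore(zS, zi, k = config@divergenceK))
    }, numeric(1))
    names(initDiv) <- names(datasets)[targets]

    # adversarial optimization is not monotone: keep per-epoch snapshots
    # and select each target's model afterwards by logged divergence,
    # gated on reconstruction quality
    snaps <- vector("list", length(datasets))
    for (i in targets) snaps[[i]] <- vector("list", config@scimEpochs)
    bestEpoch <- rep(NA_real_, length(datasets))

    hist <- data.frame()
    for (epoch in seq_len(config@scimEpochs)) {
      for (i in targets) {
        X <- pp[[i]]$X
        nT <- nrow(X)
        lab1hT <- .oneHot(shown[[i]], lev)
        perm <- sample(nT)
        splits <- split(perm, ceiling(seq_along(perm) / config@batchSize))
        acc <- c(nll = 0, adv = 0, disc = 0)
        for (bi in seq_along(splits)) {
          idx <- splits[[bi]]
          B <- length(idx)
          eps <- matrix(rnorm(B * ld), ncol = ld)
          st <- .aeStep(encs[[i]], decs[[i]], X[idx, , drop = FALSE], ld,
                        betaKL = 0, eps = eps, disc = disc,
                        lab1h = lab1hT[idx, , drop = FALSE],
                        betaAdv = config@betaAdv)
          .checkFinite(st$total, "integration loss", epoch, bi)
          up <- .adamStep(encs[[i]], st$encGrads, sE[[i]], config@lrAE)
          encs[[i]] <- up$net; sE[[i]] <- up$state
          up <- .adamStep(decs[[i]], st$decGrads, sD[[i]], config@lrAE)
          decs[[i]] <- up$net; sD[[i]] <- up$state

          dl <- NA_real_
          for (ds in seq_len(config@discSteps)) {
            sidx <- sample(nS, B, replace = nS < B)
            tidx <- if (ds == 1L) idx else sample(nT, B, replace = nT < B)
            zT <- if (ds == 1L) st$mu else
              .encoderPosterior(encs[[i]], X[tidx, , drop = FALSE], ld)$mu
            Xd <- rbind(cbind(zS[sidx, , drop = FALSE],
                              lab1hS[sidx, , drop = FALSE]),
                        cbind(zT, lab1hT[tidx, , drop = FALSE]))
            y <- c(rep(1, B), rep(0, B))
            fc <- .mlpForward(disc, Xd)
            s <- fc$out[, 1]
            dl <- .bceWithLogits(s, y)
            .checkFinite(dl, "discriminator loss", epoch, bi)
            gd <- .mlpBackward(disc, fc,
                               matrix((.sigmoid(s) - y) / length(y),
                                      ncol = 1))
            up <- .adamStep(disc, gd, sDisc, config@lrDisc)
            disc <- up$net; sDisc <- up$state
            sn <- .spectralNormalize(disc, snU)
            disc <- sn$net; snU <- sn$u
          }

          acc <- acc + c(st$nll, st$adv, dl) * B
        }
        zi <- .encoderPosterior(encs[[i]], X, ld)$mu
        ns <- min(1000L, nS, nT)
        div <- .withSeed(.deriveSeed(config@seed, "divergence", epoch), {
          divergenceValue(divergenceScore(
            zS[sample(nS, ns), , drop = FALSE],
            zi[sample(nT, ns), , drop = FALSE], k = config@divergenceK))
        })
        hist <- rbind(hist, data.frame(
          epoch = epoch, technology = names(datasets)[i],
          nll = acc[["nll"]] / nT, adv = acc[["adv"]] / nT,
          discLoss = acc[["disc"]] / nT, divergence = div))
        snaps[[i]][[epoch]] <- list(enc = encs[[i]], dec = decs[[i]])
      }
    }
    # select per target the lowest-divergence epoch among epochs whose
    # reconstruction is close to the best achieved (a low divergence with
    # poor reconstruction means overlap without structure, not alignment)
    for (i in targets) {
      hi <- hist[hist$technology == names(datasets)[i], , drop = FALSE]
      ok <- hi$nll <= 1.05 * min(hi$nll)
      sel <- hi$epoch[ok][which.min(hi$divergence[ok])]
      bestEpoch[[i]] <- sel
      encs[[i]] <- snaps[[i]][[sel]]$enc
      decs[[i]] <- snaps[[i]][[sel]]$dec
    }
    snaps <- NULL
    for (i in targets) models[[i]] <- mkModel(i)
    codes <- vector("list", length(datasets))
    names(codes) <- names(datasets)
    codes[[sourceIndex]] <- sourceFit$codes
    for (i in targets) codes[[i]] <- encodeCells(datasets[[i]], models[[i]])
    new("ScimFit", models = models,
        discriminator = new("ScimDiscriminator", net = disc,
                            labelLevels = lev, latentDim = ld),
        config = config, sourceIndex = sourceIndex, history = hist,
        codes = codes, initialDivergence = initDiv,
        selectedEpoch = setNames(bestEpoch[targets],
                                 names(datasets)[targets]))
  })
}
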