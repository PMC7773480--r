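#' Rooted lineage tree with branch lengths in pseudotime units
#'
#' Ground-truth generative structure for the branching-process simulator.
#' Each branch covers a contiguous pseudotime interval; a branch starts where
#' its parent ends, so pseudotime is monotone non-decreasing along every
#' root-to-leaf path.
#'
#' @slot branches character vector of branch identifiers.
#' @slot parent named character vector mapping each branch to its parent
#'   (`NA` for the root).
#' @slot lengths named numeric vector of positive branch lengths.
#' @seealso [makeDefaultTree()], [sampleCells()]
#' @export
setClass("LineageTree",
  representation(branches = "character", parent = "character",
                 lengths = "numeric"))

setValidity("LineageTree", function(object) {
  b <- object@branches
  if (length(b) < 1) return("tree must have at least one branch")
  if (anyDuplicated(b)) return("branch ids must be unique")
  if (!identical(sort(names(object@parent)), sort(b)) ||
      !identical(sort(names(object@lengths)), sort(b)))
    return("parent and lengths must be named by branch id")
  if (any(!is.finite(object@lengths)) || any(object@lengths <= 0))
    return("all branch lengths must be positive and finite")
  root <- b[is.na(object@parent[b])]
  if (length(root) != 1) return("tree must have exactly one root")
  nonroot <- setdiff(b, root)
  if (!all(object@parent[nonroot] %in% b))
    return("every non-root parent must be a branch of the tree")
  # connected & acyclic: every branch must reach the root
  for (x in b) {
    seen <- character(0)
    while (!is.na(object@parent[[x]])) {
      if (x %in% seen) return("tree contains a cycle")
      seen <- c(seen, x)
      x <- object@parent[[x]]
    }
    if (x != root) return("tree is not connected")
  }
  TRUE
})

#' Branch-wise expression program on a pseudotime grid
#'
#' Per-feature negative-binomial means along the lineage tree. Log-means
#' follow a Gaussian random walk over a unit-step pseudotime grid, each child
#' branch continuing from its parent's terminal value, and are scaled so that
#' the expected per-cell library size is constant.
#'
#' @slot tree the generating [LineageTree-class].
#' @slot means list (one entry per branch) of features-by-gridpoint matrices
#'   of non-negative NB means on the count scale.
#' @slot grid list of pseudotime offsets (within branch) for each grid column.
#' @slot dispersion per-feature NB dispersion (size) parameters, so that
#'   `Var = mu + mu^2 / dispersion`.
#' @slot walkSd standard deviation of the log-mean random walk per unit
#'   pseudotime.
#' @slot libSize expected per-cell total count.
#' @seealso [simulatePrograms()], [sampleCounts()]
#' @export
setClass("ExpressionProgram",
  representation(tree = "LineageTree", means = "list", grid = "list",
                 dispersion = "numeric", walkSd = "numeric",
                 libSize = "numeric"))

setValidity("ExpressionProgram", function(object) {
  b <- object@tree@branches
  if (!identical(sort(names(object@means)), sort(b)))
    return("means must have one matrix per branch")
  nf <- nrow(object@means[[1]])
  for (x in b) {
    m <- object@means[[x]]
    if (!is.matrix(m) || nrow(m) != nf) return("inconsistent feature count")
    if (any(!is.finite(m)) || any(m < 0))
      return("all means must be finite and non-negative")
    if (ncol(m) != length(object@grid[[x]]))
      return(paste0("grid/means column mismatch for branch ", x))
  }
  if (length(object@dispersion) != nf)
    return("dispersion must have one entry per feature")
  if (any(object@dispersion <= 0)) return("dispersions must be positive")
  TRUE
})

#' Hyperparameters for latent-space integration
#'
#' Bundles the settings of the variational-autoencoder initialization and of
#' the adversarial integration phase.
#'
#' @slot latentDim latent dimensionality (default 8).
#' @slot betaVAE weight of the KL term during VAE initialization
#'   (default 0.01).
#' @slot betaAdv weight of the adversarial term during integration
#'   (default 1).
#' @slot lrAE,lrDisc ADAM learning rates for the autoencoders and the
#'   discriminator (defaults 5e-4).
#' @slot vaeEpochs,scimEpochs training epochs for the two phases.
#' @slot hiddenAE,hiddenDisc hidden layer widths.
#' @slot batchSize minibatch size.
#' @slot labelFraction fraction of cells whose label is revealed to the
#'   discriminator; the rest receive the censored class.
#' @slot discSteps discriminator updates per autoencoder update.
#' @slot transform input transform: "log1p", "arcsinh" or "none".
#' @slot divergenceK neighbor count for the latent divergence log.
#' @slot seed integer seed governing all randomness of a training run.
#' @seealso [scimConfig()], [trainSCIM()]
#' @export
setClass("ScimConfig",
  representation(latentDim = "integer", betaVAE = "numeric",
                 betaAdv = "numeric", lrAE = "numeric", lrDisc = "numeric",
                 vaeEpochs = "integer", scimEpochs = "integer",
                 hiddenAE = "integer", hiddenDisc = "integer",
                 batchSize = "integer", labelFraction = "numeric",
                 discSteps = "integer", transform = "character",
                 divergenceK = "integer", seed = "integer"))

setValidity("ScimConfig", function(object) {
  if (object@latentDim < 1L) return("latentDim must be >= 1")
  if (object@labelFraction < 0 || object@labelFraction > 1)
    return("labelFraction must lie in [0, 1]")
  if (!object@transform %in% c("log1p", "arcsinh", "none"))
    return("transform must be one of log1p, arcsinh, none")
  if (any(c(object@lrAE, object@lrDisc) <= 0))
    return("learning rates must be positive")
  TRUE
})

#' Encoder/decoder pair for one technology
#'
#' Holds the fitted network parameters mapping a technology's feature space
#' to the shared latent space and back, together with the input
#' standardization applied before encoding. The encoder outputs posterior
#' mean and log-variance (`2 * latentDim` units); the decoder outputs a
#' per-feature Gaussian mean with unit variance.
#'
#' @slot technology technology tag.
#' @slot features feature names the model was trained on.
#' @slot encoder,decoder lists of layer weights (`W`) and biases (`b`).
#' @slot latentDim latent dimensionality.
#' @slot transform input transform name.
#' @slot center,scale per-feature standardization parameters.
#' @slot codeCenter,codeScale optional per-dimension affine correction of
#'   the latent codes (set for the source model so its code distribution is
#'   centered and unit-scaled, which conditions both the discriminator and
#'   the Euclidean matching); empty when unused.
#' @seealso [trainVAE()], [encodeCells()]
#' @export
setClass("TechnologyModel",
  representation(technology = "character", features = "character",
                 encoder = "list", decoder = "list", latentDim = "integer",
                 transform = "character", center = "numeric",
                 scale = "numeric", codeCenter = "numeric",
                 codeScale = "numeric"),
  prototype(codeCenter = numeric(0), codeScale = numeric(0)))

#' Label-conditioned adversarial discriminator
#'
#' Binary classifier on (latent code, one-hot label) inputs distinguishing
#' source-technology codes from target-technology codes. Spectral
#' normalization is applied to every weight matrix after each update.
#'
#' @slot net list of layer weights and biases.
#' @slot labelLevels label vocabulary; the final level is the censored class.
#' @slot latentDim latent dimensionality of the code inputs.
#' @export
setClass("ScimDiscriminator",
  representation(net = "list", labelLevels = "character",
                 latentDim = "integer"))

#' Latent codes of one technology
#'
#' Cells-by-dimension matrix of posterior-mean latent representations.
#'
#' @slot codes numeric matrix (cells in rows, rownames are cell ids).
#' @slot technology technology tag.
#' @export
setClass("LatentCodes",
  representation(codes = "matrix", technology = "character"))

setValidity("LatentCodes", function(object) {
  if (!is.numeric(object@codes)) return("codes must be numeric")
  if (any(!is.finite(object@codes))) return("codes must be finite")
  if (is.null(rownames(object@codes))) return("codes must carry cell ids as rownames")
  TRUE
})

#' Result of a full integration run
#'
#' @slot models list of [TechnologyModel-class], one per technology.
#' @slot discriminator the shared [ScimDiscriminator-class].
#' @slot config the [ScimConfig-class] used.
#' @slot sourceIndex index of the source technology.
#' @slot history per-epoch training log (losses and divergence).
#' @slot codes list of [LatentCodes-class] from the selected epoch.
#' @slot initialDivergence divergence between source and each target at
#'   initialization (named numeric).
#' @slot selectedEpoch per-target epoch whose model snapshot was kept (the
#'   epoch with the lowest logged divergence; adversarial optimization is
#'   not monotone, so the last epoch is not necessarily the best).
#' @export
setClass("ScimFit",
  representation(models = "list", discriminator = "ScimDiscriminator",
                 config = "ScimConfig", sourceIndex = "integer",
                 history = "data.frame", codes = "list",
                 initialDivergence = "numeric",
                 selectedEpoch = "numeric"))

#' kNN divergence estimate between two code sets
#'
#' Symmetrized nearest-neighbour Kullback-Leibler divergence estimate;
#' near zero when the two sets are drawn from the same distribution.
#'
#' @slot value the estimate.
#' @slot k neighbor count used.
#' @slot nP,nQ sample sizes of the two sets.
#' @seealso [divergenceScore()]
#' @export
setClass("DivergenceEstimate",
  representation(value = "numeric", k = "integer", nP = "integer",
                 nQ = "integer"))

#' Candidate edges for bipartite matching
#'
#' Union of the two directed kNN queries between code sets, with Euclidean
#' costs.
#'
#' @slot edges data.frame with integer columns `source`, `target` and a
#'   numeric `cost`.
#' @slot k neighbors per directed query.
#' @slot nSource,nTarget side sizes.
#' @export
setClass("CandidateEdges",
  representation(edges = "data.frame", k = "integer", nSource = "integer",
                 nTarget = "integer"))

#' Capacitated flow network for cell matching
#'
#' Directed graph (root, left cells = bigger side, right cells, optional null
#' node, sink) with integerized costs, ready for the network simplex solver.
#'
#' @slot arcs data.frame of arcs (`tail`, `head`, `cap`, `cost`, `role`,
#'   `left`, `right`).
#' @slot nNodes node count.
#' @slot n,m sizes of the bigger (left) and smaller (right) sides.
#' @slot nullCost null-match penalty on the original cost scale (`NA` when
#'   the null node is disabled).
#' @slot p percentile used for the null penalty.
#' @slot swapped `TRUE` when the caller's source side is the smaller one and
#'   sides were interchanged internally.
#' @slot costScale multiplier used to integerize costs.
#' @export
setClass("FlowNetwork",
  representation(arcs = "data.frame", nNodes = "integer", n = "integer",
                 m = "integer", nullCost = "numeric", p = "numeric",
                 swapped = "logical", costScale = "numeric",
                 leftIds = "character", rightIds = "character"))

#' Cross-technology cell matching result
#'
#' @slot pairs data.frame with columns `source`, `target` (cell ids) and
#'   `cost` (Euclidean latent distance).
#' @slot nullAssigned ids of cells from the bigger side routed to the null
#'   node.
#' @slot k,p matching hyperparameters used.
#' @slot nSource,nTarget dataset sizes.
#' @slot totalCost total matched cost on the original scale.
#' @export
setClass("MatchResult",
  representation(pairs = "data.frame", nullAssigned = "character",
                 k = "integer", p = "numeric", nSource = "integer",
                 nTarget = "integer", totalCost = "numeric"))

setValidity("MatchResult", function(object) {
  p <- object@pairs
  if (!all(c("source", "target", "cost") %in% names(p)))
    return("pairs must have source, target, cost columns")
  big <- if (object@nSource >= object@nTarget) p$source else p$target
  if (anyDuplicated(c(big, object@nullAssigned)))
    return("each bigger-side cell may appear at most once")
  TRUE
})
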