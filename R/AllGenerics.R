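#' @name accessors
#' @title Accessors for scMatcher objects
#' @description Small accessor generics for the S4 classes of the package.
#' @param object an scMatcher S4 object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("branchNames", function(object) standardGeneric("branchNames"))
#' @rdname accessors
#' @export
setGeneric("branchLengths", function(object) standardGeneric("branchLengths"))
#' @rdname accessors
#' @export
setGeneric("branchParents", function(object) standardGeneric("branchParents"))
#' @rdname accessors
#' @export
setGeneric("rootBranch", function(object) standardGeneric("rootBranch"))
#' @rdname accessors
#' @export
setGeneric("branchStarts", function(object) standardGeneric("branchStarts"))
#' @rdname accessors
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setGeneric("codeMatrix", function(object) standardGeneric("codeMatrix"))
#' @rdname accessors
#' @export
setGeneric("technology", function(object) standardGeneric("technology"))
#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(object) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setGeneric("nullAssigned", function(object) standardGeneric("nullAssigned"))
#' @rdname accessors
#' @export
setGeneric("divergenceValue", function(object) standardGeneric("divergenceValue"))

#' @rdname accessors
#' @export
setMethod("branchNames", "LineageTree", function(object) object@branches)
#' @rdname accessors
#' @export
setMethod("branchLengths", "LineageTree",
          function(object) object@lengths[object@branches])
#' @rdname accessors
#' @export
setMethod("branchParents", "LineageTree",
          function(object) object@parent[object@branches])
#' @rdname accessors
#' @export
setMethod("rootBranch", "LineageTree",
          function(object) object@branches[is.na(object@parent[object@branches])])

#' @rdname accessors
#' @export
setMethod("branchStarts", "LineageTree", function(object) {
  starts <- setNames(numeric(length(object@branches)), object@branches)
  for (b in object@branches) {
    x <- object@parent[[b]]
    s <- 0
    while (!is.na(x)) {
      s <- s + object@lengths[[x]]
      x <- object@parent[[x]]
    }
    starts[[b]] <- s
  }
  starts
})

#' @rdname accessors
#' @export
setMethod("totalLength", "LineageTree",
          function(object) sum(object@lengths))

#' @rdname accessors
#' @export
setMethod("codeMatrix", "LatentCodes", function(object) object@codes)
#' @rdname accessors
#' @export
setMethod("technology", "LatentCodes", function(object) object@technology)
#' @rdname accessors
#' @export
setMethod("matchedPairs", "MatchResult", function(object) object@pairs)
#' @rdname accessors
#' @export
setMethod("nullAssigned", "MatchResult", function(object) object@nullAssigned)
#' @rdname accessors
#' @export
setMethod("divergenceValue", "DivergenceEstimate", function(object) object@value)

setMethod("show", "LineageTree", function(object) {
  cat("LineageTree with", length(object@branches), "branches, total length",
      format(sum(object@lengths)), "\n")
  for (b in object@branches) {
    p <- object@parent[[b]]
    cat(sprintf("  %s  length %-6s parent %s\n", b,
                format(object@lengths[[b]]),
                if (is.na(p)) "(root)" else p))
  }
})

setMethod("show", "ExpressionProgram", function(object) {
  cat("ExpressionProgram:", nrow(object@means[[1]]), "features over",
      length(object@means), "branches (grid step 1, walkSd",
      format(object@walkSd), ", libSize", format(object@libSize), ")\n")
})

setMethod("show", "ScimConfig", function(object) {
  cat("ScimConfig: latentDim", object@latentDim,
      "| vaeEpochs", object@vaeEpochs, "(betaVAE", format(object@betaVAE),
      ") | scimEpochs", object@scimEpochs, "(betaAdv", format(object@betaAdv),
      ")\n  lrAE", format(object@lrAE), "lrDisc", format(object@lrDisc),
      "batch", object@batchSize, "labelFraction", format(object@labelFraction),
      "transform", object@transform, "seed", object@seed, "\n")
})

setMethod("show", "TechnologyModel", function(object) {
  cat("TechnologyModel for", object@technology, ":",
      length(object@features), "features ->", object@latentDim,
      "latent dims (", object@transform, "input transform )\n")
})

setMethod("show", "LatentCodes", function(object) {
  cat("LatentCodes:", nrow(object@codes), "cells x", ncol(object@codes),
      "dims, technology", object@technology, "\n")
})

setMethod("show", "ScimFit", function(object) {
  cat("ScimFit:", length(object@models), "technologies, source =",
      names(object@models)[object@sourceIndex], "\n")
  fin <- object@history[object@history$epoch == max(object@history$epoch), ,
                        drop = FALSE]
  if (nrow(fin))
    cat("  final epoch divergence:",
        paste(sprintf("%s=%.3f", fin$technology, fin$divergence),
              collapse = ", "), "\n")
})

setMethod("show", "DivergenceEstimate", function(object) {
  cat(sprintf("DivergenceEstimate: %.4f (k = %d, n = %d/%d)\n",
              object@value, object@k, object@nP, object@nQ))
})

setMethod("show", "CandidateEdges", function(object) {
  cat("CandidateEdges:", nrow(object@edges), "edges between",
      object@nSource, "and", object@nTarget, "cells (k =", object@k, ")\n")
})

setMethod("show", "FlowNetwork", function(object) {
  cat("FlowNetwork:", object@nNodes, "nodes,", nrow(object@arcs), "arcs;",
      "left", object@n, "right", object@m, "\n")
  if (is.finite(object@nullCost))
    cat("  null penalty", format(object@nullCost), "(percentile",
        object@p, ")\n")
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult:", nrow(object@pairs), "pairs,",
      length(object@nullAssigned), "null-assigned (k =", object@k,
      ", p =", object@p, ")\n  total matched cost",
      format(object@totalCost), "\n")
})
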