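#' Construct a lineage tree
#'
#' @param branches character vector of branch ids.
#' @param parent named character vector mapping each branch to its parent
#'   (`NA` for the root).
#' @param lengths named numeric vector of positive branch lengths in
#'   pseudotime units.
#' @return a [LineageTree-class].
#' @examples
#' lineageTree(c("A", "B"), c(A = NA, B = "A"), c(A = 10, B = 5))
#' @export
lineageTree <- function(branches, parent, lengths) {
  branches <- as.character(branches)
  parent <- structure(as.character(parent[branches]), names = branches)
  lengths <- structure(as.numeric(lengths[branches]), names = branches)
  new("LineageTree", branches = branches, parent = parent,
      lengths = lengths)
}

#' Default five-branch lineage tree
#'
#' A fixed rooted tree with five branches of pairwise-distinct lengths: a
#' root branch of length 20 splits into branches of lengths 15 and 25; the
#' length-25 branch splits again into branches of lengths 10 and 30. The
#' shape mixes shallow and deep tips so that both early and late cell states
#' are represented. Deterministic: no randomness is involved.
#'
#' @return a [LineageTree-class] with 5 branches and total length 100.
#' @examples
#' makeDefaultTree()
#' @export
makeDefaultTree <- function() {
  lineageTree(
    branches = c("B1", "B2", "B3", "B4", "B5"),
    parent = c(B1 = NA, B2 = "B1", B3 = "B1", B4 = "B3", B5 = "B3"),
    lengths = c(B1 = 20, B2 = 15, B3 = 25, B4 = 10, B5 = 30))
}

# Branches in an order that guarantees parents precede children.
.topoBranches <- function(tree) {
  ord <- rootBranch(tree)
  repeat {
    nxt <- tree@branches[!tree@branches %in% ord &
                           tree@parent[tree@branches] %in% ord]
    if (!length(nxt)) break
    ord <- c(ord, nxt)
  }
  ord
}

#' Simulate per-feature expression programs along a lineage tree
#'
#' Each feature's log-mean follows a Gaussian random walk over a unit-step
#' pseudotime grid along every branch, with each child branch continuing
#' from its parent's terminal value, so means are continuous at branch
#' points. Grid columns are scaled so the expected per-cell library size is
#' constant, and each feature receives a negative-binomial dispersion drawn
#' log-uniformly from `dispersionRange`.
#'
#' @param tree a [LineageTree-class].
#' @param nFeatures number of features (>= 1).
#' @param walkSd standard deviation of the log-mean increments per unit
#'   pseudotime (> 0, or exactly 0 for flat programs).
#' @param seed integer seed; the same seed reproduces the program exactly.
#' @param libSize expected total count per cell (default 1e4).
#' @param dispersionRange range for the log-uniform per-feature dispersion
#'   draw (default `c(1, 100)`).
#' @return an [ExpressionProgram-class].
#' @examples
#' prog <- simulatePrograms(makeDefaultTree(), nFeatures = 16, seed = 1)
#' @export
simulatePrograms <- function(tree, nFeatures, walkSd = 0.3, seed = 1L,
                             libSize = 1e4, dispersionRange = c(1, 100)) {
  stopifnot(is(tree, "LineageTree"))
  if (length(nFeatures) != 1 || nFeatures < 1)
    stop("nFeatures must be a positive integer")
  if (length(walkSd) != 1 || walkSd < 0 || !is.finite(walkSd))
    stop("walkSd must be a non-negative finite scalar")
  nFeatures <- as.integer(nFeatures)
  .withSeed(seed, {
    ord <- .topoBranches(tree)
    logm <- list()
    grid <- list()
    for (b in ord) {
      L <- tree@lengths[[b]]
      offs <- seq(0, ceiling(L))
      p <- tree@parent[[b]]
      start <- if (is.na(p)) rnorm(nFeatures, 0, 1)
               else logm[[p]][, ncol(logm[[p]])]
      steps <- matrix(rnorm(nFeatures * (length(offs) - 1), 0, walkSd),
                      nrow = nFeatures)
      cums <- if (ncol(steps) == 1) steps else t(apply(steps, 1, cumsum))
      lm <- cbind(start, start + cums)
      dimnames(lm) <- NULL
      logm[[b]] <- lm
      grid[[b]] <- offs
    }
    disp <- exp(runif(nFeatures, log(dispersionRange[1]),
                      log(dispersionRange[2])))
    means <- lapply(logm, function(lm) {
      raw <- exp(lm)
      sweep(raw, 2, colSums(raw) / libSize, "/")
    })
    new("ExpressionProgram", tree = tree, means = means[tree@branches],
        grid = grid[tree@branches], dispersion = disp,
        walkSd = walkSd, libSize = libSize)
  })
}

#' Sample cells uniformly along a lineage tree
#'
#' Cell positions are drawn uniformly over the total tree length, so the
#' expected fraction of cells on a branch equals its length share and the
#' pseudotime marginal is uniform over the tree-length measure.
#'
#' @param tree a [LineageTree-class].
#' @param nCells number of cells (>= 1).
#' @param seed integer seed.
#' @param prefix prefix for generated cell ids.
#' @return a `data.frame` with columns `cell_id`, `branch` and `pseudotime`
#'   (one row per cell); pseudotime lies within the sampled branch's
#'   interval.
#' @examples
#' head(sampleCells(makeDefaultTree(), 100, seed = 1))
#' @export
sampleCells <- function(tree, nCells, seed = 1L, prefix = "cell") {
  stopifnot(is(tree, "LineageTree"))
  if (length(nCells) != 1 || nCells < 1)
    stop("nCells must be a positive integer")
  nCells <- as.integer(nCells)
  .withSeed(seed, {
    lens <- branchLengths(tree)
    cum <- cumsum(lens)
    u <- runif(nCells, 0, sum(lens))
    idx <- findInterval(u, cum, left.open = TRUE) + 1L
    branch <- names(lens)[idx]
    offset <- u - c(0, cum)[idx]
    starts <- branchStarts(tree)
    data.frame(cell_id = sprintf("%s%05d", prefix, seq_len(nCells)),
               branch = branch,
               pseudotime = starts[branch] + offset,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

# Map (branch, pseudotime) to the program's nearest grid column.
.gridColumn <- function(program, branch, pseudotime) {
  starts <- branchStarts(program@tree)
  off <- pseudotime - starts[branch]
  mapply(function(b, o) {
    g <- program@grid[[b]]
    which.min(abs(g - o))
  }, branch, off, USE.NAMES = FALSE)
}

#' Sample negative-binomial counts for cells from an expression program
#'
#' Counts are drawn as `NB(mean = mu, size = dispersion)` where `mu` is the
#' program mean at the grid point nearest the cell's pseudotime, so
#' `Var = mu + mu^2 / dispersion`.
#'
#' @param program an [ExpressionProgram-class].
#' @param truth a `data.frame` as returned by [sampleCells()].
#' @param seed integer seed.
#' @param technology tag recorded in the returned dataset.
#' @param featurePrefix prefix for generated feature names; defaults to the
#'   technology tag so feature spaces of different technologies are disjoint.
#' @return a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with a `counts` assay (features x cells) and `colData` columns `branch`,
#'   `pseudotime` and `label`.
#' @examples
#' tree <- makeDefaultTree()
#' prog <- simulatePrograms(tree, nFeatures = 8, seed = 1)
#' cells <- sampleCells(tree, 50, seed = 2)
#' sce <- sampleCounts(prog, cells, seed = 3)
#' @export
sampleCounts <- function(program, truth, seed = 1L, technology = "tech1",
                         featurePrefix = technology) {
  stopifnot(is(program, "ExpressionProgram"), is.data.frame(truth),
            all(c("cell_id", "branch", "pseudotime") %in% names(truth)))
  if (!all(truth$branch %in% program@tree@branches))
    stop("truth contains branches unknown to the program")
  nf <- nrow(program@means[[1]])
  nc <- nrow(truth)
  .withSeed(seed, {
    cols <- .gridColumn(program, truth$branch, truth$pseudotime)
    mu <- matrix(0, nrow = nf, ncol = nc)
    for (i in seq_len(nc))
      mu[, i] <- program@means[[truth$branch[i]]][, cols[i]]
    counts <- matrix(rnbinom(nf * nc, size = program@dispersion,
                             mu = as.vector(mu)),
                     nrow = nf, ncol = nc)
    counts[mu == 0] <- 0L
    rownames(counts) <- sprintf("%s_f%04d", featurePrefix, seq_len(nf))
    colnames(counts) <- truth$cell_id
    sce <- SingleCellExperiment(
      assays = list(counts = counts),
      colData = DataFrame(branch = truth$branch,
                          pseudotime = truth$pseudotime,
                          label = truth$branch,
                          row.names = truth$cell_id))
    metadata(sce)$technology <- technology
    sce
  })
}

#' Generate multiple technologies from a shared branching process
#'
#' Every technology receives an independent expression program (its own
#' program seed) but cells are drawn from the same tree and sampling
#' density, emulating aliquots of one cell suspension profiled by different
#' platforms. Feature spaces are disjoint by construction (features are
#' named per technology), so no feature correspondences exist across
#' datasets, while the latent branching structure is common.
#'
#' @param tree a [LineageTree-class].
#' @param nTech number of technologies (>= 2).
#' @param nCells cells per technology.
#' @param nFeatures features per technology.
#' @param seeds integer vector of length `nTech`; per-technology seeds from
#'   which program, cell and count seeds are derived.
#' @param walkSd,libSize,dispersionRange passed to [simulatePrograms()].
#' @return a named list of
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   objects, one per technology.
#' @examples
#' sim <- generateTechnologies(makeDefaultTree(), nTech = 2, nCells = 100,
#'                             nFeatures = 8, seeds = c(1, 2))
#' @export
generateTechnologies <- function(tree, nTech = 2L, nCells = 1000L,
                                 nFeatures = 256L, seeds = seq_len(nTech),
                                 walkSd = 0.3, libSize = 1e4,
                                 dispersionRange = c(1, 100)) {
  if (nTech < 2) stop("nTech must be at least 2")
  if (length(seeds) != nTech) stop("seeds must have length nTech")
  out <- vector("list", nTech)
  names(out) <- sprintf("tech%d", seq_len(nTech))
  for (i in seq_len(nTech)) {
    tech <- names(out)[i]
    prog <- simulatePrograms(tree, nFeatures, walkSd = walkSd,
                             seed = .deriveSeed(seeds[i], "program"),
                             libSize = libSize,
                             dispersionRange = dispersionRange)
    cells <- sampleCells(tree, nCells, seed = .deriveSeed(seeds[i], "cells"),
                         prefix = paste0(tech, "_c"))
    out[[i]] <- sampleCounts(prog, cells,
                             seed = .deriveSeed(seeds[i], "counts"),
                             technology = tech)
  }
  out
}
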