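.asCodeMatrix <- function(Z, what = "codes") {
  M <- if (is(Z, "LatentCodes")) Z@codes else as.matrix(Z)
  if (nrow(M) == 0) stop(what, " must contain at least one cell")
  if (is.null(rownames(M))) rownames(M) <- sprintf("c%d", seq_len(nrow(M)))
  M
}

#' Candidate match edges from mutual kNN queries
#'
#' Builds the union of the two directed k-nearest-neighbor queries between
#' code sets (source queried against target and vice versa) under Euclidean
#' distance. Duplicated edges found by both queries are kept once. Every
#' cell on each side therefore has at least `k` incident edges.
#'
#' @param Zs,Zt [LatentCodes-class] or matrices (cells x dims).
#' @param k neighbors per directed query; at most `min(|Zs|, |Zt|)`.
#' @return a [CandidateEdges-class] whose `edges` hold 1-based row indices
#'   into `Zs` (`source`) and `Zt` (`target`).
#' @export
buildCandidateEdges <- function(Zs, Zt, k = 50L) {
  A <- .asCodeMatrix(Zs, "Zs")
  B <- .asCodeMatrix(Zt, "Zt")
  if (ncol(A) != ncol(B)) stop("code sets must share the latent dimension")
  k <- as.integer(k)
  if (k < 1 || k > min(nrow(A), nrow(B)))
    stop("k must lie in [1, min(|Zs|, |Zt|)]")
  f <- RANN::nn2(B, A, k = k)
  g <- RANN::nn2(A, B, k = k)
  e <- data.frame(
    source = c(rep(seq_len(nrow(A)), k), as.vector(g$nn.idx)),
    target = c(as.vector(f$nn.idx), rep(seq_len(nrow(B)), k)),
    cost = c(as.vector(f$nn.dists), as.vector(g$nn.dists)))
  e <- e[!duplicated(e[, c("source", "target")]), , drop = FALSE]
  e <- e[order(e$source, e$target), , drop = FALSE]
  rownames(e) <- NULL
  new("CandidateEdges", edges = e, k = k,
      nSource = nrow(A), nTarget = nrow(B))
}

# Balanced integer partition of n over m sink arcs: floor(n/m) everywhere,
# with the first n %% m arcs incremented.
.sinkCapacities <- function(n, m) {
  base <- n %/% m
  u <- rep(base, m)
  r <- n %% m
  if (r > 0) u[seq_len(r)] <- u[seq_len(r)] + 1L
  u
}

#' Build the capacitated flow network for cell matching
#'
#' Assembles the min-cost max-flow network from candidate edges: a root
#' feeds every left cell (the bigger side, size `n`) with capacity-1 arcs;
#' candidate edges connect left to right cells with capacity 1 and their
#' Euclidean cost; each right cell drains into the sink with capacity
#' `u_i` (a balanced partition of `n` over the `m` right cells, or `n` when
#' `bounded = FALSE`); and an optional null node with capacity `n` absorbs
#' left cells at a penalty equal to the `p`-th percentile (linear
#' interpolation) of the candidate costs. Costs are integerized by
#' multiplying with 1e6 and rounding.
#'
#' The caller must pass the sides so that `n >= m`; [matchCells()] relabels
#' automatically.
#'
#' @param cands a [CandidateEdges-class] with `nSource >= nTarget`.
#' @param p percentile in (0, 100) for the null penalty.
#' @param nullNode include the null node (default `TRUE`).
#' @param bounded bound sink capacities to the balanced partition (default
#'   `TRUE`); `FALSE` gives the unbounded one-to-many variant.
#' @return a [FlowNetwork-class].
#' @export
buildFlowNetwork <- function(cands, p = 95, nullNode = TRUE,
                             bounded = TRUE) {
  stopifnot(is(cands, "CandidateEdges"))
  e <- cands@edges
  if (nrow(e) == 0) stop("candidate edge set is empty")
  if (p <= 0 || p >= 100) stop("p must lie strictly between 0 and 100")
  n <- cands@nSource
  m <- cands@nTarget
  if (n < m)
    stop("the bigger dataset must occupy the left (source) side; swap sides")
  costScale <- 1e6
  nullCost <- if (nullNode) unname(quantile(e$cost, p / 100, type = 7))
              else NA_real_
  # nodes: 1 root | 1+1..n left | 1+n+1..m right | null | sink
  rootN <- 1L
  leftN <- 1L + seq_len(n)
  rightN <- 1L + n + seq_len(m)
  nullN <- 2L + n + m
  sinkN <- nullN + if (nullNode) 1L else 0L
  nNodes <- sinkN
  u <- if (bounded) .sinkCapacities(n, m) else rep(n, m)
  arcs <- rbind(
    data.frame(tail = rootN, head = leftN, cap = 1, cost = 0,
               role = "root", left = seq_len(n), right = NA),
    data.frame(tail = leftN[e$source], head = rightN[e$target], cap = 1,
               cost = round(e$cost * costScale), role = "match",
               left = e$source, right = e$target),
    data.frame(tail = rightN, head = sinkN, cap = u, cost = 0,
               role = "sink", left = NA, right = seq_len(m)))
  if (nullNode) {
    arcs <- rbind(arcs,
      data.frame(tail = leftN, head = nullN, cap = 1,
                 cost = round(nullCost * costScale), role = "null",
                 left = seq_len(n), right = NA),
      data.frame(tail = nullN, head = sinkN, cap = n, cost = 0,
                 role = "nullsink", left = NA, right = NA))
  }
  new("FlowNetwork", arcs = arcs, nNodes = nNodes, n = as.integer(n),
      m = as.integer(m), nullCost = nullCost, p = as.numeric(p),
      swapped = FALSE, costScale = costScale,
      leftIds = character(0), rightIds = character(0))
}

#' Solve the matching flow network
#'
#' Pushes `n` units (one per left cell) from root to sink at minimum total
#' cost with the network simplex solver; the integral unit flows on
#' left-right arcs become cell pairs and flow through the null node becomes
#' the null assignment. When the null node is disabled the network is only
#' feasible if the sink capacities can absorb all left cells.
#'
#' @param net a [FlowNetwork-class].
#' @return a [MatchResult-class]; cell ids are taken from the network's
#'   `leftIds`/`rightIds` when set (as by [matchCells()]), else indices are
#'   used.
#' @export
solveMinCostFlow <- function(net) {
  stopifnot(is(net, "FlowNetwork"))
  supply <- rep(0, net@nNodes)
  supply[1L] <- net@n
  supply[net@nNodes] <- -net@n
  sol <- minCostFlow(net@nNodes, net@arcs, supply)
  if (!sol$feasible)
    stop("flow network infeasible: not all cells can be routed ",
         "(did you disable the null node with n > sum of capacities?)")
  a <- net@arcs
  fl <- sol$flow
  mi <- which(a$role == "match" & fl > 0.5)
  ni <- which(a$role == "null" & fl > 0.5)
  lid <- if (length(net@leftIds)) net@leftIds else
    sprintf("L%d", seq_len(net@n))
  rid <- if (length(net@rightIds)) net@rightIds else
    sprintf("R%d", seq_len(net@m))
  pairs <- data.frame(source = lid[a$left[mi]], target = rid[a$right[mi]],
                      cost = a$cost[mi] / net@costScale,
                      stringsAsFactors = FALSE)
  if (net@swapped)
    pairs <- data.frame(source = pairs$target, target = pairs$source,
                        cost = pairs$cost, stringsAsFactors = FALSE)
  ord <- order(pairs$source, pairs$target)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  nSrc <- if (net@swapped) net@m else net@n
  nTgt <- if (net@swapped) net@n else net@m
  new("MatchResult", pairs = pairs,
      nullAssigned = sort(lid[a$left[ni]]),
      k = NA_integer_, p = net@p, nSource = as.integer(nSrc),
      nTarget = as.integer(nTgt), totalCost = sum(pairs$cost))
}

#' Match cells across two technologies from latent codes
#'
#' End-to-end pairwise matching: builds the mutual-kNN candidate graph,
#' extends it with the null node and balanced sink capacities, and solves
#' the minimum-cost maximum-flow problem. The bigger dataset always feeds
#' the root side internally; results are reported in the caller's
#' (source, target) orientation regardless. For more than two technologies
#' call this function pairwise.
#'
#' @param Zs,Zt [LatentCodes-class] or matrices for the two technologies.
#' @param k neighbors per directed kNN query (default 50).
#' @param p percentile of candidate edge costs defining the null-match
#'   penalty (default 95).
#' @param nullNode include the null node (default `TRUE`).
#' @param bounded bound per-cell match multiplicity to the balanced
#'   capacity partition (default `TRUE`).
#' @return a [MatchResult-class].
#' @examples
#' set.seed(1)
#' A <- matrix(rnorm(100 * 2), 100)
#' B <- matrix(rnorm(80 * 2), 80)
#' matchCells(A, B, k = 10)
#' @export
matchCells <- function(Zs, Zt, k = 50L, p = 95, nullNode = TRUE,
                       bounded = TRUE) {
  A <- .asCodeMatrix(Zs, "Zs")
  B <- .asCodeMatrix(Zt, "Zt")
  # canonical cell order: results (including which sink arcs receive the
  # +1 capacities when n %% m > 0) must not depend on input row order
  A <- A[order(rownames(A)), , drop = FALSE]
  B <- B[order(rownames(B)), , drop = FALSE]
  swapped <- nrow(A) < nrow(B)
  L <- if (swapped) B else A
  R <- if (swapped) A else B
  cands <- buildCandidateEdges(L, R, k = k)
  net <- buildFlowNetwork(cands, p = p, nullNode = nullNode,
                          bounded = bounded)
  net@swapped <- swapped
  net@leftIds <- rownames(L)
  net@rightIds <- rownames(R)
  res <- solveMinCostFlow(net)
  res@k <- as.integer(k)
  res
}
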