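#' Minimum-cost b-flow on a capacitated directed graph
#'
#' Low-level interface to the network simplex solver used by
#' [solveMinCostFlow()]. Finds an integral flow satisfying the node supplies
#' at minimum total cost.
#'
#' @param nNodes number of nodes; nodes are indexed `1:nNodes`.
#' @param arcs a `data.frame` with columns `tail`, `head`, `cap`, `cost`
#'   (1-based node indices, non-negative integer capacities, integer costs).
#' @param supply numeric vector of length `nNodes`; positive entries are
#'   sources, negative entries sinks. Must sum to zero.
#' @return list with `flow` (per-arc integral flow), `cost` (total cost) and
#'   `feasible` (logical; `FALSE` when the supplies cannot be routed).
#' @examples
#' arcs <- data.frame(tail = c(1, 1, 2, 3), head = c(2, 3, 4, 4),
#'                    cap = 1, cost = c(1, 2, 1, 1))
#' minCostFlow(4, arcs, c(1, 0, 0, -1))
#' @export
minCostFlow <- function(nNodes, arcs, supply) {
  stopifnot(is.data.frame(arcs),
            all(c("tail", "head", "cap", "cost") %in% names(arcs)))
  if (any(abs(arcs$cost - round(arcs$cost)) > 1e-9))
    stop("arc costs must be integers; integerize before solving")
  if (any(abs(arcs$cap - round(arcs$cap)) > 1e-9) || any(arcs$cap < 0))
    stop("arc capacities must be non-negative integers")
  res <- .Call_network_simplex(as.integer(nNodes),
                               as.integer(arcs$tail) - 1L,
                               as.integer(arcs$head) - 1L,
                               as.numeric(round(arcs$cap)),
                               as.numeric(round(arcs$cost)),
                               as.numeric(supply))
  res
}
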