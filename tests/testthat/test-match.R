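test_that("candidate edges equal the brute-force union of both kNN queries", {
  set.seed(31)
  A <- matrix(rnorm(100 * 2), 100)
  B <- matrix(rnorm(100 * 2), 100)
  k <- 5L
  cands <- buildCandidateEdges(A, B, k = k)
  f <- bruteKnn(A, B, k)
  g <- bruteKnn(B, A, k)
  want <- unique(rbind(
    data.frame(source = rep(seq_len(100), k), target = as.vector(f$idx)),
    data.frame(source = as.vector(g$idx), target = rep(seq_len(100), k))))
  got <- cands@edges[, c("source", "target")]
  key <- function(d) sort(paste(d$source, d$target))
  expect_identical(key(got), key(want))
  # costs are Euclidean distances
  d <- sqrt(rowSums((A[got$source, ] - B[got$target, ])^2))
  expect_equal(cands@edges$cost, d, tolerance = 1e-12)
  # every cell has at least k incident edges
  expect_true(all(table(got$source) >= k))
  expect_true(all(table(got$target) >= k))
})

test_that("identical code sets yield zero-cost self edges and saturation at full k", {
  set.seed(8)
  Z <- matrix(rnorm(40 * 3), 40)
  cands <- buildCandidateEdges(Z, Z, k = 1)
  self <- cands@edges[cands@edges$source == cands@edges$target, ]
  expect_equal(nrow(self), 40L)
  expect_true(all(self$cost == 0))
  full <- buildCandidateEdges(matrix(rnorm(20), 10), matrix(rnorm(20), 10),
                              k = 10)
  expect_equal(nrow(full@edges), 100L)  # complete bipartite graph
  expect_error(buildCandidateEdges(Z, Z, k = 0), "k must")
  expect_error(buildCandidateEdges(Z, Z, k = 41), "k must")
})

test_that("null penalty is the interpolated percentile of candidate costs", {
  cands <- new("CandidateEdges",
               edges = data.frame(source = rep(1L, 100), target = 1:100,
                                  cost = as.numeric(1:100)),
               k = 1L, nSource = 100L, nTarget = 100L)
  net <- buildFlowNetwork(cands, p = 95)
  expect_equal(net@nullCost, 95.05)
  expect_error(buildFlowNetwork(cands, p = 0), "between 0 and 100")
  expect_error(buildFlowNetwork(cands, p = 100), "between 0 and 100")
})

test_that("sink capacities form a balanced partition of n over m", {
  expect_identical(scMatcher:::.sinkCapacities(7, 3), c(3, 2, 2))
  expect_identical(scMatcher:::.sinkCapacities(6, 3), c(2, 2, 2))
  expect_identical(scMatcher:::.sinkCapacities(5, 5), rep(1, 5))
  set.seed(5)
  for (i in 1:20) {
    m <- sample(1:10, 1); n <- m + sample(0:15, 1)
    u <- scMatcher:::.sinkCapacities(n, m)
    expect_equal(sum(u), n)
    expect_lte(max(u), ceiling(n / m))
    expect_gte(min(u), floor(n / m))
  }
})

test_that("solver recovers the enumerated optimum on the 3x3 instance", {
  C <- matrix(c(1, 4, 5,
                6, 2, 7,
                8, 9, 3), nrow = 3, byrow = TRUE)
  # exhaustive enumeration over all 3! assignments
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  costs <- vapply(perms, function(p) sum(C[cbind(1:3, p)]), numeric(1))
  expect_equal(min(costs), 6)
  res <- flowAssignment(C)
  expect_equal(res@totalCost, 6)
  expect_identical(matchedPairs(res)$target, c("R1", "R2", "R3"))
})

test_that("outliers beyond the null penalty are routed to the null node", {
  # two tight clusters per side plus one far-out left cell
  Zs <- rbind(matrix(0.01 * rnorm(6), 3), matrix(5 + 0.01 * rnorm(6), 3),
              c(100, 100))
  Zt <- rbind(matrix(0.01 * rnorm(6), 3), matrix(5 + 0.01 * rnorm(8), 4))
  rownames(Zs) <- sprintf("s%d", 1:7)
  rownames(Zt) <- sprintf("t%d", 1:7)
  set.seed(2)
  # cost blocks: ~21 intra-cluster edges (~0), ~21 cross-cluster (~7), 7
  # outlier edges (>130); p = 75 puts the penalty in the cross block, far
  # below the outlier's cheapest edge
  res <- matchCells(Zs, Zt, k = 7, p = 75)
  expect_identical(nullAssigned(res), "s7")
  p <- matchedPairs(res)
  expect_equal(nrow(p), 6L)
  lowS <- paste0("s", 1:3); lowT <- paste0("t", 1:3)
  expect_true(all((p$source %in% lowS) == (p$target %in% lowT)))
})

test_that("identical point sets match one-to-one at zero cost", {
  set.seed(12)
  Z <- matrix(rnorm(60 * 4), 60)
  rownames(Z) <- sprintf("c%02d", 1:60)
  res <- matchCells(Z, Z, k = 3, p = 95)
  expect_length(nullAssigned(res), 0L)
  p <- matchedPairs(res)
  expect_identical(p$source, p$target)
  expect_equal(res@totalCost, 0)
})

test_that("matching is invariant to input row order", {
  set.seed(41)
  A <- matrix(rnorm(80 * 2), 80)
  B <- matrix(rnorm(70 * 2), 70)
  rownames(A) <- sprintf("a%02d", 1:80)
  rownames(B) <- sprintf("b%02d", 1:70)
  res1 <- matchCells(A, B, k = 10, p = 95)
  pa <- sample(80); pb <- sample(70)
  res2 <- matchCells(A[pa, ], B[pb, ], k = 10, p = 95)
  key <- function(r) sort(paste(matchedPairs(r)$source,
                                matchedPairs(r)$target))
  expect_identical(key(res1), key(res2))
  expect_identical(nullAssigned(res1), nullAssigned(res2))
})

test_that("raising the null percentile never increases null assignments", {
  set.seed(90)
  A <- matrix(rnorm(150 * 2), 150)
  B <- matrix(rnorm(150 * 2), 150) + 0.8
  nulls <- vapply(c(50, 75, 90, 95, 99), function(p)
    length(nullAssigned(matchCells(A, B, k = 20, p = p))), numeric(1))
  expect_true(all(diff(nulls) <= 0))
  expect_gt(nulls[1], 0)  # the check is vacuous if nothing is ever null
})

test_that("capacities bound per-cell multiplicity; unbounded variant lifts it", {
  set.seed(55)
  A <- matrix(rnorm(14), 7)
  B <- A[1:3, , drop = FALSE] + 0.01
  rownames(A) <- sprintf("a%d", 1:7)
  rownames(B) <- sprintf("b%d", 1:3)
  res <- matchCells(A, B, k = 3, p = 99, nullNode = FALSE)
  cnt <- table(matchedPairs(res)$target)
  expect_lte(max(cnt), ceiling(7 / 3))
  expect_equal(nrow(matchedPairs(res)), 7L)
  # unbounded: all mass may collapse onto nearest cells
  resU <- matchCells(A, B, k = 3, p = 99, nullNode = FALSE, bounded = FALSE)
  expect_equal(nrow(matchedPairs(resU)), 7L)
  expect_gte(max(table(matchedPairs(resU)$target)), max(cnt))
})

test_that("network simplex agrees with the Hungarian algorithm on dense instances", {
  skip_if_not_installed("clue")
  set.seed(17)
  for (trial in 1:3) {
    n <- 120
    C <- matrix(runif(n * n, 0, 10), n)
    res <- flowAssignment(C)
    hung <- clue::solve_LSAP(C)
    hcost <- sum(C[cbind(seq_len(n), as.integer(hung))])
    expect_lt(abs(res@totalCost - hcost), 1e-3)
  }
})
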