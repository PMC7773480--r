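# Independent oracles and small fixtures used across the suite.

# exhaustive kNN by full distance matrix (oracle for RANN-based searches)
bruteKnn <- function(query, ref, k) {
  D <- as.matrix(dist(rbind(query, ref)))
  D <- D[seq_len(nrow(query)), nrow(query) + seq_len(nrow(ref)),
         drop = FALSE]
  idx <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  dst <- t(vapply(seq_len(nrow(D)), function(i) D[i, idx[i, ]],
                  numeric(k)))
  list(idx = idx, dist = dst)
}

# naive O(n^2) directed kNN KL estimator (oracle for knnKL)
naiveKnnKL <- function(P, Q, k) {
  n <- nrow(P); m <- nrow(Q); d <- ncol(P)
  total <- 0
  for (i in seq_len(n)) {
    dq <- sqrt(colSums((t(Q) - P[i, ])^2))
    dp <- sqrt(colSums((t(P[-i, , drop = FALSE]) - P[i, ])^2))
    nu <- max(sort(dq)[k], 1e-12)
    rho <- max(sort(dp)[k], 1e-12)
    total <- total + log(nu / rho)
  }
  (d / n) * total + log(n / (m - 1))
}

# DP over right-cell usage states: exact min-cost assignment of n left
# cells to m right cells with per-cell capacities u (oracle for the flow
# solver on small instances)
dpAssignment <- function(C, u) {
  n <- nrow(C); m <- ncol(C)
  best <- new.env(parent = emptyenv())
  assign(paste(rep(0L, m), collapse = ","), 0, envir = best)
  for (i in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(best)) {
      v <- get(key, envir = best)
      s <- as.integer(strsplit(key, ",")[[1]])
      for (j in seq_len(m)) {
        if (s[j] < u[j]) {
          s2 <- s; s2[j] <- s2[j] + 1L
          k2 <- paste(s2, collapse = ",")
          val <- v + C[i, j]
          if (!exists(k2, envir = nxt) || get(k2, envir = nxt) > val)
            assign(k2, val, envir = nxt)
        }
      }
    }
    best <- nxt
  }
  vals <- unlist(as.list(best))
  if (!length(vals)) Inf else min(vals)
}

# solve a dense assignment instance through the package's flow pipeline
flowAssignment <- function(C, u = rep(1L, ncol(C)), nullNode = FALSE,
                           p = 95) {
  n <- nrow(C); m <- ncol(C)
  Zs <- matrix(0, n, 1); Zt <- matrix(0, m, 1)
  rownames(Zs) <- sprintf("L%d", seq_len(n))
  rownames(Zt) <- sprintf("R%d", seq_len(m))
  cands <- new("CandidateEdges",
               edges = data.frame(source = rep(seq_len(n), m),
                                  target = rep(seq_len(m), each = n),
                                  cost = as.vector(C)),
               k = m, nSource = n, nTarget = m)
  net <- buildFlowNetwork(cands, p = p, nullNode = nullNode)
  net@leftIds <- rownames(Zs)
  net@rightIds <- rownames(Zt)
  solveMinCostFlow(net)
}

adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  sx <- sum(choose(tab, 2))
  e <- sr * sc / choose(n, 2)
  (sx - e) / ((sr + sc) / 2 - e)
}

# tiny deterministic TechnologyModel whose encoder outputs fixed (mu,
# logvar) regardless of input: all-zero weights, biases set the output
makeConstantEncoderModel <- function(dIn, latentDim, mu, logvar) {
  enc <- list(W = list(matrix(0, dIn, 2 * latentDim)),
              b = list(c(rep(mu, latentDim), rep(logvar, latentDim))),
              sizes = c(dIn, 2 * latentDim))
  dec <- list(W = list(matrix(0, latentDim, dIn)),
              b = list(rep(0, dIn)),
              sizes = c(latentDim, dIn))
  new("TechnologyModel", technology = "toy",
      features = sprintf("f%d", seq_len(dIn)), encoder = enc,
      decoder = dec, latentDim = as.integer(latentDim),
      transform = "none", center = rep(0, dIn), scale = rep(1, dIn))
}

makeZeroDiscriminator <- function(latentDim, labelLevels = "<censored>") {
  dIn <- latentDim + length(labelLevels)
  net <- list(W = list(matrix(0, dIn, 1)), b = list(0),
              sizes = c(dIn, 1))
  new("ScimDiscriminator", net = net, labelLevels = labelLevels,
      latentDim = as.integer(latentDim))
}

smallSim <- function(nCells = 300, nFeatures = 32, seeds = c(1, 2)) {
  generateTechnologies(makeDefaultTree(), nTech = 2, nCells = nCells,
                       nFeatures = nFeatures, seeds = seeds)
}
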