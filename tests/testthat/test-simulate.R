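test_that("default tree has five distinctly-sized branches forming one lineage", {
  tree <- makeDefaultTree()
  expect_s4_class(tree, "LineageTree")
  expect_length(branchNames(tree), 5L)
  expect_equal(anyDuplicated(branchLengths(tree)), 0L)
  expect_equal(totalLength(tree), sum(branchLengths(tree)))
  expect_identical(makeDefaultTree(), tree)  # deterministic
  # pseudotime is monotone along every root-to-leaf path
  starts <- branchStarts(tree)
  par <- branchParents(tree)
  for (b in branchNames(tree)) {
    p <- par[[b]]
    if (!is.na(p))
      expect_equal(starts[[b]], starts[[p]] + branchLengths(tree)[[p]])
  }
})

test_that("lineage tree validity rejects malformed trees", {
  expect_error(lineageTree("A", c(A = NA), c(A = -1)), "positive")
  expect_error(lineageTree(c("A", "B"), c(A = NA, B = NA),
                           c(A = 1, B = 1)), "exactly one root")
  expect_error(lineageTree(c("A", "B"), c(A = "B", B = "A"),
                           c(A = 1, B = 1)), "root|cycle")
})

test_that("expression programs diffuse continuously along the tree", {
  tree <- makeDefaultTree()
  prog <- simulatePrograms(tree, nFeatures = 40, walkSd = 0.4, seed = 7)
  # continuity at branch points: child's first grid column equals parent's
  # last column (identical log-means, identical library scaling)
  par <- branchParents(tree)
  for (b in branchNames(tree)) {
    p <- par[[b]]
    if (!is.na(p)) {
      parentEnd <- prog@means[[p]][, ncol(prog@means[[p]])]
      expect_equal(prog@means[[b]][, 1], parentEnd, tolerance = 1e-12)
    }
  }
  # determinism
  expect_identical(simulatePrograms(tree, 40, walkSd = 0.4, seed = 7), prog)
  expect_false(identical(
    simulatePrograms(tree, 40, walkSd = 0.4, seed = 8)@means, prog@means))
  # zero diffusion: every feature constant along the whole tree
  flat <- simulatePrograms(tree, nFeatures = 10, walkSd = 0, seed = 1)
  for (b in branchNames(tree))
    expect_lt(max(apply(flat@means[[b]], 1, function(r) diff(range(r)))),
              1e-9)
  expect_error(simulatePrograms(tree, 0), "nFeatures")
  expect_error(simulatePrograms(tree, 10, walkSd = -1), "walkSd")
})

test_that("log-mean increment variance grows linearly with branch length", {
  tree <- makeDefaultTree()
  walkSd <- 0.3
  prog <- simulatePrograms(tree, nFeatures = 2000, walkSd = walkSd,
                           seed = 11)
  for (b in c("B2", "B5")) {
    m <- prog@means[[b]]
    steps <- ncol(m) - 1L   # unit grid spacing
    # column-wise library scaling adds a per-column constant in log space,
    # leaving the across-feature variance of log differences untouched
    d <- log(m[, ncol(m)]) - log(m[, 1])
    v <- var(d)
    expected <- walkSd^2 * steps
    se <- expected * sqrt(2 / (length(d) - 1))
    expect_lt(abs(v - expected), 3 * se)
  }
})

test_that("cells are sampled uniformly over total tree length", {
  oneBranch <- lineageTree("A", c(A = NA), c(A = 12.5))
  cells <- sampleCells(oneBranch, 500, seed = 3)
  expect_true(all(cells$pseudotime >= 0 & cells$pseudotime <= 12.5))
  expect_setequal(unique(cells$branch), "A")

  tree <- makeDefaultTree()
  n <- 10000
  cells <- sampleCells(tree, n, seed = 4)
  lens <- branchLengths(tree)
  frac <- table(factor(cells$branch, names(lens))) / n
  for (b in names(lens)) {
    p0 <- lens[[b]] / sum(lens)
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(frac[[b]] - p0), 4 * se)
  }
  # pseudotime within each branch's interval
  starts <- branchStarts(tree)
  expect_true(all(cells$pseudotime >= starts[cells$branch] &
                  cells$pseudotime <= starts[cells$branch] +
                    lens[cells$branch]))
  expect_identical(sampleCells(tree, n, seed = 4), cells)
  expect_error(sampleCells(tree, 0), "nCells")
})

test_that("pseudotime marginal is uniform on the tree-length measure", {
  tree <- makeDefaultTree()
  cells <- sampleCells(tree, 10000, seed = 9)
  # uniformity holds for arc length, i.e. position along the concatenated
  # branch intervals, not for raw pseudotime (branches overlap in time)
  lens <- branchLengths(tree)
  starts <- branchStarts(tree)
  offset <- cells$pseudotime - starts[cells$branch]
  arc <- c(0, cumsum(lens))[match(cells$branch, names(lens))] + offset
  ks <- suppressWarnings(ks.test(arc, "punif", 0, sum(lens)))
  expect_gt(ks$p.value, 0.01)
})

test_that("counts follow the program's negative binomial law", {
  # single-branch program with hand-set means, one cell replicated 10000x
  tree <- lineageTree("A", c(A = NA), c(A = 2))
  mu <- c(0, 50, 5)
  disp <- c(10, 10, 1e8)
  prog <- new("ExpressionProgram", tree = tree,
              means = list(A = matrix(rep(mu, 3), nrow = 3)),
              grid = list(A = 0:2), dispersion = disp, walkSd = 0,
              libSize = sum(mu))
  truth <- data.frame(cell_id = sprintf("c%05d", 1:10000), branch = "A",
                      pseudotime = 1)
  sce <- sampleCounts(prog, truth, seed = 21)
  counts <- SummarizedExperiment::assay(sce, "counts")
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  expect_identical(dim(counts), c(3L, 10000L))
  # mu = 0 -> all zero
  expect_true(all(counts[1, ] == 0))
  # NB moments: mean within 3 SE, variance ~ mu + mu^2/r
  x <- counts[2, ]
  nbVar <- 50 + 50^2 / 10
  expect_lt(abs(mean(x) - 50), 3 * sqrt(nbVar / 10000))
  expect_lt(abs(var(x) / nbVar - 1), 0.15)
  # Poisson limit at huge dispersion: variance/mean ratio near 1
  y <- counts[3, ]
  expect_gt(var(y) / mean(y), 0.9)
  expect_lt(var(y) / mean(y), 1.1)
  expect_identical(sampleCounts(prog, truth, seed = 21), sce)
})

test_that("technologies share the lineage but not features", {
  tree <- makeDefaultTree()
  sim <- generateTechnologies(tree, nTech = 3, nCells = 2000,
                              nFeatures = 16, seeds = c(5, 6, 7))
  expect_length(sim, 3L)
  expect_error(generateTechnologies(tree, nTech = 1), "at least 2")
  # disjoint feature spaces by construction
  expect_length(intersect(rownames(sim[[1]]), rownames(sim[[2]])), 0L)
  expect_length(intersect(rownames(sim[[2]]), rownames(sim[[3]])), 0L)
  # same sampling density: per-branch proportions agree within binomial CI
  lens <- branchLengths(tree)
  for (i in 2:3) {
    f1 <- table(factor(SummarizedExperiment::colData(sim[[1]])$branch,
                       names(lens))) / 2000
    fi <- table(factor(SummarizedExperiment::colData(sim[[i]])$branch,
                       names(lens))) / 2000
    for (b in names(lens)) {
      p0 <- lens[[b]] / sum(lens)
      se <- sqrt(2 * p0 * (1 - p0) / 2000)
      expect_lt(abs(f1[[b]] - fi[[b]]), 4 * se)
    }
  }
  # identical seeds give bit-identical datasets, distinct seeds distinct
  # programs
  sim2 <- generateTechnologies(tree, nTech = 3, nCells = 2000,
                               nFeatures = 16, seeds = c(5, 6, 7))
  expect_identical(
    SummarizedExperiment::assay(sim[[1]]), SummarizedExperiment::assay(sim2[[1]]))
  expect_false(identical(SummarizedExperiment::assay(sim[[1]]),
                         SummarizedExperiment::assay(sim[[2]])))
})
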