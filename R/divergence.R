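#' Directed kNN Kullback-Leibler divergence estimate
#'
#' Nonparametric estimate of `KL(P || Q)` from two samples using kth
#' nearest-neighbor distances:
#' `(d / |P|) * sum_i log(nu_k(p_i) / rho_k(p_i)) + log(|P| / (|Q| - 1))`,
#' where `nu_k(p_i)` is the distance from `p_i` to its kth nearest neighbor
#' in `Q` and `rho_k(p_i)` the distance to its kth nearest neighbor in `P`
#' excluding `p_i` itself. Distances are Euclidean and are floored at 1e-12
#' so coincident points cannot produce infinities.
#'
#' @param P,Q numeric matrices (points in rows, same dimension).
#' @param k neighbor count; requires `|P| > k` and `|Q| >= k`.
#' @return scalar estimate (can be negative at finite sample sizes).
#' @examples
#' set.seed(1)
#' P <- matrix(rnorm(2000), ncol = 2)
#' Q <- matrix(rnorm(2000), ncol = 2)
#' knnKL(P, Q, k = 5)   # close to 0
#' @export
knnKL <- function(P, Q, k = 5L) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  if (ncol(P) != ncol(Q)) stop("P and Q must have the same dimension")
  k <- as.integer(k)
  n <- nrow(P)
  m <- nrow(Q)
  if (k >= n) stop("k must be smaller than |P|")
  if (k > m) stop("k must not exceed |Q|")
  d <- ncol(P)
  nu <- RANN::nn2(Q, P, k = k)$nn.dists[, k]
  rho <- RANN::nn2(P, P, k = k + 1L)$nn.dists[, k + 1L]
  nu <- pmax(nu, 1e-12)
  rho <- pmax(rho, 1e-12)
  (d / n) * sum(log(nu / rho)) + log(n / (m - 1))
}

#' Symmetric divergence score between two sets of latent codes
#'
#' Averages the two directed kNN KL estimates,
#' `0.5 * KL(Zs || Zt) + 0.5 * KL(Zt || Zs)`, giving a score that is
#' symmetric by construction and near zero when the code sets are drawn from
#' the same distribution. Used to monitor latent-space integration quality
#' and for model selection.
#'
#' @param Zs,Zt [LatentCodes-class] objects or plain matrices.
#' @param k neighbor count (default 5).
#' @return a [DivergenceEstimate-class].
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(1000), ncol = 2)
#' b <- matrix(rnorm(1000), ncol = 2)
#' divergenceScore(a, b)
#' @export
divergenceScore <- function(Zs, Zt, k = 5L) {
  A <- if (is(Zs, "LatentCodes")) Zs@codes else as.matrix(Zs)
  B <- if (is(Zt, "LatentCodes")) Zt@codes else as.matrix(Zt)
  if (ncol(A) != ncol(B)) stop("code sets must share the latent dimension")
  val <- 0.5 * knnKL(A, B, k) + 0.5 * knnKL(B, A, k)
  new("DivergenceEstimate", value = val, k = as.integer(k),
      nP = nrow(A), nQ = nrow(B))
}

#' Select an integration run by divergence and reconstruction thresholds
#'
#' Implements threshold-based model selection over a grid of training runs:
#' a run is successful when both its latent divergence and its
#' reconstruction error fall below the supplied thresholds; among successful
#' runs the one with minimal divergence is returned (ties broken by lower
#' reconstruction error). When no run passes, an explicit failure marker is
#' returned rather than an arbitrary pick.
#'
#' @param runs a `data.frame` with columns `divergence` and
#'   `reconstruction` (one row per run; other columns such as a config id
#'   are carried through).
#' @param divThreshold,recThreshold the empirically set thresholds.
#' @return list with `success` (logical), `index` (row index of the chosen
#'   run or `NA`), and `run` (the chosen row or `NULL`).
#' @examples
#' runs <- data.frame(id = 1:3, divergence = c(0.2, 0.4, 2),
#'                    reconstruction = c(10, 8, 3))
#' selectModel(runs, divThreshold = 1, recThreshold = 20)
#' @export
selectModel <- function(runs, divThreshold, recThreshold) {
  if (!is.data.frame(runs) || nrow(runs) == 0)
    stop("runs must be a non-empty data.frame")
  stopifnot(all(c("divergence", "reconstruction") %in% names(runs)))
  pass <- which(runs$divergence < divThreshold &
                  runs$reconstruction < recThreshold)
  if (!length(pass))
    return(list(success = FALSE, index = NA_integer_, run = NULL))
  ord <- pass[order(runs$divergence[pass], runs$reconstruction[pass])]
  list(success = TRUE, index = ord[1], run = runs[ord[1], , drop = FALSE])
}
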