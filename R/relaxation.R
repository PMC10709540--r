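## Continuous relaxation of biparental crossing: soft parents as weighted
## averages of the population over per-cross simplex weights.

#' Validate cross weights
#'
#' Cross weights generalize a cross plan: a (k, n, 2) array where slice
#' `[c, , s]` is a point on the n-simplex (non-negative, summing to 1)
#' giving the contribution of every population member to parent slot s of
#' cross c. A one-hot slice recovers an ordinary parent choice.
#'
#' @param w numeric array of dimension (k, n, 2).
#' @param tol tolerance on the per-slot normalization (default 1e-8).
#'   Weights outside tolerance are rejected, never silently renormalized
#'   (renormalization would corrupt gradient-based optimizer steps).
#' @return `w`, invisibly, after validation.
#' @export
crossWeights <- function(w, tol = 1e-8) {
  d <- dim(w)
  if (length(d) != 3L || d[3] != 2L)
    stop("cross weights must be a (k, n, 2) array")
  if (any(w < 0))
    stop("cross weights must be non-negative")
  s <- apply(w, c(1L, 3L), sum)
  if (any(abs(s - 1) > tol))
    stop(sprintf(
      "cross weights must sum to 1 over the population axis (max |sum-1| = %.3g, tol %.1g)",
      max(abs(s - 1)), tol))
  invisible(w)
}

#' One-hot cross weights from a cross plan
#'
#' @param plan a k x 2 matrix of parent indices (see [crossPlan()]).
#' @param n population size.
#' @return A (k, n, 2) weight array with a 1 at each planned parent.
#' @export
oneHotWeights <- function(plan, n) {
  plan <- crossPlan(plan, n = n)
  k <- nrow(plan)
  w <- array(0, c(k, n, 2L))
  w[cbind(seq_len(k), plan[, 1], 1L)] <- 1
  w[cbind(seq_len(k), plan[, 2], 2L)] <- 1
  w
}

#' Differentiable (soft) crossing over parent weights
#'
#' Relaxes biparental crossing to a continuous operation: for each cross and
#' parent slot, a "soft parent" (an m x 2 real genome) is the weighted
#' average of all population members' genomes under the slot's simplex
#' weights; a recombination mask is then sampled once per gamete and applied
#' to the soft parent exactly as in [cross()]. With the masks held fixed the
#' output is a linear function of the weights, so any automatic-
#' differentiation backend — or a hand-coded linear adjoint — delivers exact
#' gradients with respect to the weights (the masks are treated as fixed
#' samples, a pathwise estimator). At one-hot weights and shared masks the
#' output coincides exactly with the hard [cross()].
#'
#' @param pop a [Population-class] (binary genomes give output in [0, 1];
#'   real-valued "genomes" from previous soft crosses are accepted by
#'   passing the array directly via `genomeArray`).
#' @param w a (k, n, 2) weight array (validated by [crossWeights()]).
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @param masks optional (k, m, 2) mask array shared with [cross()].
#' @param genomeArray optional (n, m, 2) numeric array overriding
#'   `genome(pop)`, for chaining soft crosses.
#' @return A numeric array of dimension (k, m, 2): the k soft offspring.
#' @export
softCross <- function(pop, w, map, seed = NULL, masks = NULL,
                      genomeArray = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  g <- if (is.null(genomeArray)) genome(pop) else genomeArray
  if (!is.null(genomeArray) && (any(g < 0) || any(g > 1)))
    stop("genomeArray entries must lie in [0, 1] (soft genomes)")
  n <- dim(g)[1]; m <- dim(g)[2]
  crossWeights(w)
  if (dim(w)[2] != n)
    stop(sprintf("weights population axis (%d) != population size (%d)",
                 dim(w)[2], n))
  k <- dim(w)[1]
  if (is.null(masks)) {
    masks <- array(0L, c(k, m, 2L))
    masks[, , 1] <- recombinationMasks(map, k)
    masks[, , 2] <- recombinationMasks(map, k)
  }
  out <- array(0, c(k, m, 2L))
  for (s in 1:2) {
    ws <- matrix(w[, , s], k, n)
    sp1 <- ws %*% matrix(g[, , 1], n, m)   # soft parent, haplotype 1
    sp2 <- ws %*% matrix(g[, , 2], n, m)   # soft parent, haplotype 2
    msk <- matrix(masks[, , s], k, m)
    out[, , s] <- sp1 * (1 - msk) + sp2 * msk
  }
  out
}
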