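## Truncation selection and the built-in score functions: breeding value,
## optimal haploid value, and phenotype.

#' Truncation selection of the top-k individuals
#'
#' Scores the population (a score function maps a population to one finite
#' real score per individual) and keeps the k highest-scoring individuals.
#' Ties are broken by lower original index, so the result is deterministic
#' and independent of any RNG. The selected indices are returned in
#' ascending order: with k = n the operation is the identity.
#'
#' @param pop a [Population-class].
#' @param k number of individuals to keep, 1 <= k <= n.
#' @param score either a numeric vector of length n, or a function
#'   `function(pop, ...)` returning one; e.g. [scoreGEBV()], [scoreOHV()],
#'   [scorePhenotype()].
#' @param ... passed on to `score` when it is a function.
#' @return A list with `population` (the k selected individuals, original
#'   order), `indices` (their 1-based positions in `pop`, ascending) and
#'   `scores` (the full score vector).
#' @export
selectTop <- function(pop, k, score, ...) {
  n <- nIndividuals(pop)
  if (k < 1L || k > n)
    stop(sprintf("k must lie in [1, n]; got k = %d with n = %d", k, n))
  s <- if (is.function(score)) score(pop, ...) else score
  s <- as.numeric(s)
  if (length(s) != n)
    stop(sprintf("score returned %d values for %d individuals", length(s), n))
  if (any(!is.finite(s)))
    stop("non-finite score for individual(s): ",
         paste(utils::head(which(!is.finite(s)), 5L), collapse = ", "))
  keep <- sort(order(-s, seq_len(n))[seq_len(k)])
  list(population = pop[keep], indices = keep, scores = s)
}

# linear trait index used by the score functions (default: equal weights)
.traitIndex <- function(values, traitWeights) {
  nt <- ncol(values)
  if (is.null(traitWeights)) traitWeights <- rep(1 / nt, nt)
  if (length(traitWeights) != nt)
    stop("traitWeights must have one weight per trait")
  unname(drop(values %*% traitWeights))
}

#' Score by genomic estimated breeding value
#'
#' The weighted sum of per-trait GEBVs (a linear selection index; equal
#' weights by default, so a single-trait map scores by its GEBV directly).
#'
#' @param pop a [Population-class].
#' @param map a [GeneticMap-class].
#' @param traitWeights optional length-t index weights.
#' @return A numeric vector of n scores.
#' @export
scoreGEBV <- function(pop, map, traitWeights = NULL) {
  .traitIndex(gebv(pop, map), traitWeights)
}

#' Score by optimal haploid value
#'
#' The optimal haploid value (OHV) of an individual is the breeding value
#' of the best doubled haploid it could produce: twice the sum, over genome
#' segments, of the better of its two haplotypes' summed marker-effect
#' contributions in that segment. The default segmentation is one segment
#' per chromosome (recombination can recombine chromosomes freely across
#' meioses but a single gamete inherits each segment intact at this
#' granularity); `blockSize` instead cuts each chromosome into fixed-size
#' marker blocks. For a fully homozygous individual OHV equals GEBV, and
#' OHV >= GEBV always. Multi-trait maps are reduced to a linear index with
#' `traitWeights` before segment maximization.
#'
#' @param pop a [Population-class].
#' @param map a [GeneticMap-class].
#' @param traitWeights optional length-t index weights.
#' @param segments optional integer/factor vector of length m assigning
#'   each marker to a segment; overrides the default.
#' @param blockSize optional number of markers per within-chromosome block.
#' @return A numeric vector of n scores.
#' @export
scoreOHV <- function(pop, map, traitWeights = NULL, segments = NULL,
                     blockSize = NULL) {
  m <- nMarkers(map)
  if (nMarkers(pop) != m)
    stop(sprintf("marker-count mismatch: population has %d markers, map has %d",
                 nMarkers(pop), m))
  nt <- nTraits(map)
  w <- if (is.null(traitWeights)) rep(1 / nt, nt) else traitWeights
  if (length(w) != nt) stop("traitWeights must have one weight per trait")
  eff <- drop(crossprod(w, markerEffects(map)))   # length-m index effects

  if (is.null(segments)) {
    segments <- if (is.null(blockSize)) chromosomes(map) else {
      within <- stats::ave(seq_len(m), chromosomes(map), FUN = seq_along)
      paste(chromosomes(map), (within - 1L) %/% blockSize, sep = ":")
    }
  }
  if (length(segments) != m)
    stop("segments must assign every marker to a segment")
  seg <- factor(segments, levels = unique(segments))
  # m x S indicator-weighted effect matrix: column s holds eff on segment s
  S <- nlevels(seg)
  E <- matrix(0, m, S)
  E[cbind(seq_len(m), as.integer(seg))] <- eff
  n <- nIndividuals(pop)
  v1 <- matrix(genome(pop)[, , 1], n, m) %*% E
  v2 <- matrix(genome(pop)[, , 2], n, m) %*% E
  2 * rowSums(pmax(v1, v2))
}

#' Score by simulated phenotype
#'
#' The mean simulated phenotype across environments, reduced to a linear
#' trait index. With a low heritability this realizes low-accuracy visual
#' selection; with h² = 1 it ranks identically to the GEBV.
#'
#' @param pop a [Population-class].
#' @param map a [GeneticMap-class] (heritability from the map unless `h2`).
#' @param nEnvs environments to average over.
#' @param traitWeights optional length-t index weights.
#' @param h2,gxe,gxeRatio,calibration,seed passed to [phenotype()].
#' @return A numeric vector of n scores.
#' @export
scorePhenotype <- function(pop, map, nEnvs = 1L, traitWeights = NULL,
                           h2 = NULL, gxe = NULL, gxeRatio = 0.5,
                           calibration = pop, seed = NULL) {
  ph <- phenotype(pop, map, nEnvs = nEnvs, h2 = h2, gxe = gxe,
                  gxeRatio = gxeRatio, calibration = calibration, seed = seed)
  .traitIndex(meanPhenotype(ph), traitWeights)
}
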