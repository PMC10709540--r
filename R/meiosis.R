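## Gamete sampling under the Poisson crossover model, crossing plans,
## random crosses, diallels, and doubled-haploid induction.

# Per-marker switch probabilities for the haplotype-indicator Markov chain:
# at the first marker of each chromosome the contributing haplotype is
# re-randomized (a flip with probability 1/2 yields a uniform, independent
# start); afterwards it switches with the recombination probability of the
# preceding interval. This is the exact marginal of the Poisson crossover
# process at marker resolution.
.switchProbs <- function(map) {
  m <- nMarkers(map)
  chr <- map@chromosome
  first <- !duplicated(chr)
  p <- numeric(m)
  p[first] <- 0.5
  idx <- which(!first)
  p[idx] <- map@recomb[idx - 1L]
  if (anyNA(p))
    stop("recombination probabilities contain NA at a within-chromosome interval")
  p
}

#' Sample recombination masks
#'
#' A recombination mask is one realized meiosis outcome: a binary vector of
#' length m selecting, at every marker, which of the two parental haplotypes
#' contributes the allele (0 = first, 1 = second). Within a chromosome the
#' mask follows a first-order Markov switching process — uniform start at
#' the first marker, then a switch between adjacent markers with that
#' interval's recombination probability. Masks for different gametes (rows)
#' and different chromosomes are independent.
#'
#' @param map a [GeneticMap-class].
#' @param n number of masks (gametes) to sample.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return An n x m integer matrix with entries in {0, 1}.
#' @seealso [cross()], [softCross()]
#' @export
recombinationMasks <- function(map, n, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  p <- .switchProbs(map)
  m <- length(p)
  mask <- matrix(0L, n, m)
  if (n == 0L) return(mask)
  state <- rep(FALSE, n)
  for (j in seq_len(m)) {
    state <- xor(state, stats::runif(n) < p[j])
    mask[, j] <- state
  }
  mask
}

# gametes for a vector of parent indices, one row per gamete
.sampleGametes <- function(pop, parents, map, masks = NULL) {
  m <- nMarkers(pop)
  if (m != nMarkers(map))
    stop(sprintf("marker-count mismatch: population has %d markers, map has %d",
                 m, nMarkers(map)))
  if (is.null(masks)) masks <- recombinationMasks(map, length(parents))
  h1 <- matrix(pop@genome[parents, , 1, drop = FALSE], length(parents), m)
  h2 <- matrix(pop@genome[parents, , 2, drop = FALSE], length(parents), m)
  h1 * (1L - masks) + h2 * masks
}

#' Sample one gamete from an individual
#'
#' Simulates the recombination taking place during one meiosis: the
#' contributing haplotype starts uniformly at the first marker of each
#' chromosome and switches between adjacent markers with the interval's
#' recombination probability; the returned allele at each marker is the
#' parent's allele on the contributing haplotype.
#'
#' @param pop a [Population-class].
#' @param individual index of the parent in `pop`.
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @param mask optional pre-sampled length-m mask (see
#'   [recombinationMasks()]).
#' @return An integer vector of length m (one haplotype).
#' @export
sampleGamete <- function(pop, individual, map, seed = NULL, mask = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (individual < 1L || individual > nIndividuals(pop))
    stop("individual index out of range")
  if (!is.null(mask)) mask <- matrix(as.integer(mask), 1L)
  drop(.sampleGametes(pop, individual, map, masks = mask))
}

#' Build and validate a cross plan
#'
#' A cross plan is an ordered list of k parent pairs; each pair produces one
#' offspring under [cross()]. Indices are 1-based positions in the
#' population.
#'
#' @param mother,father equal-length integer vectors of parent indices; or
#'   pass a two-column matrix as `mother`.
#' @param n optional population size to validate indices against.
#' @return A k x 2 integer matrix with columns `mother`, `father`.
#' @export
crossPlan <- function(mother, father = NULL, n = NULL) {
  plan <- if (is.null(father)) as.matrix(mother) else cbind(mother, father)
  if (ncol(plan) != 2L) stop("a cross plan needs exactly two parent columns")
  storage.mode(plan) <- "integer"
  colnames(plan) <- c("mother", "father")
  if (anyNA(plan) || any(plan < 1L))
    stop("parent indices must be positive integers")
  if (!is.null(n) && any(plan > n)) {
    bad <- which(rowSums(plan > n) > 0)[1]
    stop(sprintf("cross plan pair %d (%d, %d) is out of range for n = %d",
                 bad, plan[bad, 1], plan[bad, 2], n))
  }
  plan
}

#' Perform biparental crosses
#'
#' Executes a batch of k biparental crosses: offspring i receives two
#' independently sampled gametes, one from each parent of pair i. The result
#' has genome shape (k, m, 2).
#'
#' @param pop a [Population-class].
#' @param plan a k x 2 matrix of 1-based parent indices (see [crossPlan()]).
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @param masks optional (k, m, 2) array of pre-sampled recombination masks;
#'   `masks[, , 1]` drives the maternal gamete and `masks[, , 2]` the
#'   paternal one (used by the relaxation's vertex-equivalence contract).
#' @return A [Population-class] of k offspring.
#' @export
cross <- function(pop, plan, map, seed = NULL, masks = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  plan <- crossPlan(plan, n = nIndividuals(pop))
  k <- nrow(plan); m <- nMarkers(pop)
  m1 <- if (is.null(masks)) NULL else matrix(masks[, , 1], k, m)
  m2 <- if (is.null(masks)) NULL else matrix(masks[, , 2], k, m)
  g <- array(0L, c(k, m, 2L))
  g[, , 1] <- .sampleGametes(pop, plan[, 1], map, masks = m1)
  g[, , 2] <- .sampleGametes(pop, plan[, 2], map, masks = m2)
  Population(g)
}

#' Random biparental crosses
#'
#' Samples k parent pairs uniformly (pairs with replacement across crosses;
#' the two parents within a pair are distinct — "biparental") and performs
#' the crosses.
#'
#' @param pop a [Population-class] with at least two individuals.
#' @param k number of crosses (= offspring).
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @return A [Population-class] of k offspring.
#' @export
randomCrosses <- function(pop, k, map, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nIndividuals(pop)
  if (n < 2L) stop("random crosses need a population of at least 2 individuals")
  if (k == 0L) return(Population(array(0L, c(0L, nMarkers(pop), 2L))))
  mother <- sample.int(n, k, replace = TRUE)
  shift  <- sample.int(n - 1L, k, replace = TRUE)
  father <- 1L + (mother - 1L + shift) %% n   # uniform over the n-1 others
  cross(pop, cbind(mother, father), map)
}

#' Full-diallel cross plan and execution
#'
#' `diallelPlan()` enumerates every unordered pair of distinct parents
#' (n(n-1)/2 pairs, no selfs); `diallel()` performs the corresponding
#' crosses with a fixed number of offspring per pair, yielding
#' n(n-1)/2 * offspringPerCross offspring (e.g. 10 parents with 10
#' offspring per cross give 450 offspring; 20 parents give 1900).
#'
#' @param pop a [Population-class] with at least two individuals.
#' @param n number of parents (for `diallelPlan()`).
#' @param offspringPerCross offspring produced per parent pair.
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @return `diallelPlan()`: a (n(n-1)/2) x 2 matrix of parent indices.
#'   `diallel()`: a [Population-class] of n(n-1)/2 * offspringPerCross
#'   offspring, ordered pair-major.
#' @export
diallelPlan <- function(n) {
  if (n < 2L) stop("a diallel needs at least 2 parents")
  pairs <- utils::combn(n, 2L)
  crossPlan(pairs[1L, ], pairs[2L, ])
}

#' @rdname diallelPlan
#' @export
diallel <- function(pop, offspringPerCross, map, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (offspringPerCross < 1L) stop("offspringPerCross must be >= 1")
  plan <- diallelPlan(nIndividuals(pop))
  full <- plan[rep(seq_len(nrow(plan)), each = offspringPerCross), ,
               drop = FALSE]
  cross(pop, full, map)
}

#' Doubled-haploid induction
#'
#' Simulates fixation of genomes by doubled-haploid induction: each of the
#' dh offspring of individual j is built by sampling one gamete of j and
#' duplicating it onto both haplotypes, so every output individual is fully
#' homozygous. The result keeps the line structure as a rank-4 array of
#' shape (n, dh, m, d); use [dhToPopulation()] to flatten it for downstream
#' operations.
#'
#' @param pop a [Population-class] of n individuals.
#' @param dh number of doubled-haploid offspring per individual (>= 1).
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @return An integer array of dimension (n, dh, m, 2).
#' @export
doubleHaploid <- function(pop, dh, map, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (dh < 1L) stop("dh (offspring per individual) must be >= 1")
  n <- nIndividuals(pop); m <- nMarkers(pop)
  parents <- rep(seq_len(n), each = dh)
  gam <- .sampleGametes(pop, parents, map)        # (n*dh) x m, line-major rows
  # row r = (p-1)*dh + l  ->  array [l, p, j] column-major, then permute
  lines <- aperm(array(t(gam), c(m, dh, n)), c(3L, 2L, 1L))
  out <- array(0L, c(n, dh, m, 2L))
  out[, , , 1] <- lines
  out[, , , 2] <- lines
  out
}

#' Flatten a doubled-haploid array into a Population
#'
#' @param dhArray a (n, dh, m, 2) array as returned by [doubleHaploid()].
#' @return A [Population-class] of n * dh individuals, line-major order
#'   (all DH of line 1, then line 2, ...).
#' @export
dhToPopulation <- function(dhArray) {
  d <- dim(dhArray)
  if (length(d) != 4L) stop("expected a rank-4 (n, dh, m, d) array")
  g <- array(0L, c(d[1] * d[2], d[3], d[4]))
  for (h in seq_len(d[4]))
    g[, , h] <- matrix(aperm(dhArray[, , , h, drop = FALSE],
                             c(2L, 1L, 3L, 4L)),
                       d[1] * d[2], d[3])
  Population(g)
}
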