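## GEBV by tensor contraction and phenotype simulation with heritability
## and genotype-by-environment interaction.

#' Genomic estimated breeding values
#'
#' Contracts the (t, m) marker-effect matrix with the (n, m, d) population
#' array: the arrays are multiplied along the marker axis and sum-reduced
#' along the marker and ploidy axes, giving
#' `values[i, tau] = sum_j sum_h effects[tau, j] * genome[i, j, h]` — an
#' (n, t) matrix of GEBVs.
#'
#' @param pop a [Population-class].
#' @param map a [GeneticMap-class] supplying the marker effects.
#' @param ... unused.
#' @return An n x t numeric matrix; columns named by trait, rows by
#'   individual ids when present.
#' @rdname gebv
#' @export
setMethod("gebv", signature(pop = "Population", map = "GeneticMap"),
  function(pop, map, ...) {
    n <- nIndividuals(pop); m <- nMarkers(pop)
    if (m != nMarkers(map))
      stop(sprintf("marker-count mismatch: population has %d markers, map has %d",
                   m, nMarkers(map)))
    dosage <- matrix(genome(pop)[, , 1] + genome(pop)[, , 2], n, m)
    v <- dosage %*% t(markerEffects(map))
    dimnames(v) <- list(if (length(ids(pop))) ids(pop) else NULL,
                        traitNames(map))
    v
  })

#' Draw the fixed genotype-by-environment marker effects
#'
#' The G×E interaction is driven by a random additive trait fixed at the
#' beginning of a simulation: one standard-normal marker-effect vector per
#' trait. [phenotype()] draws this internally when not supplied; for a
#' multi-stage simulation draw it once here and pass it to every call.
#'
#' @param map a [GeneticMap-class].
#' @param seed optional seed.
#' @return A t x m numeric matrix of G×E marker effects.
#' @export
gxeEffects <- function(map, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  matrix(stats::rnorm(nTraits(map) * nMarkers(map)),
         nrow = nTraits(map), dimnames = list(traitNames(map), NULL))
}

#' Simulate phenotypes with G×E interaction
#'
#' The phenotype of individual i for trait tau in environment e is
#' \deqn{P_{i\tau e} = G_{i\tau} + z_e \, g_{i\tau} + \varepsilon_{i\tau e}}
#' where G is the GEBV, z_e ~ Normal(0, 1) is the environment draw (one per
#' environment), g is the individual's value on a fixed random additive G×E
#' trait (see [gxeEffects()]), centered and scaled on the calibration
#' population, and epsilon is Gaussian residual noise. The non-genetic
#' variance is set so that Var(G) / Var(P) equals the trait's heritability
#' in the calibration population, and is split between the G×E and residual
#' components in proportion `gxeRatio` : `1 - gxeRatio`. The environment
#' scalar multiplies only the G×E term, not the residual. With h² = 1 both
#' non-genetic components vanish and the phenotype equals the GEBV.
#'
#' @param pop a [Population-class].
#' @param map a [GeneticMap-class]; its `heritability` is used unless `h2`
#'   is given.
#' @param nEnvs number of environments (>= 1).
#' @param h2 optional per-trait heritability override, each in (0, 1].
#' @param gxe optional t x m matrix of fixed G×E marker effects; drawn
#'   internally when `NULL`.
#' @param gxeRatio fraction of the non-genetic variance assigned to the G×E
#'   component (default 0.5, an even split).
#' @param calibration population on which variances are calibrated; default
#'   `pop` itself.
#' @param seed optional seed.
#' @return A numeric array of dimension (n, t, nEnvs).
#' @export
phenotype <- function(pop, map, nEnvs = 1L, h2 = NULL, gxe = NULL,
                      gxeRatio = 0.5, calibration = pop, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  nt <- nTraits(map)
  if (is.null(h2)) h2 <- heritability(map)
  if (!length(h2))
    stop("no heritability available: supply it in the map or via 'h2'")
  if (length(h2) == 1L) h2 <- rep(h2, nt)
  if (length(h2) != nt) stop("h2 must have one value per trait")
  if (any(h2 <= 0 | h2 > 1)) stop("heritability must lie in (0, 1]")
  if (gxeRatio < 0 || gxeRatio > 1) stop("gxeRatio must lie in [0, 1]")
  if (nEnvs < 1L) stop("nEnvs must be >= 1")

  if (is.null(gxe)) gxe <- gxeEffects(map)
  n <- nIndividuals(pop)
  G <- gebv(pop, map)
  Gc <- if (identical(calibration, pop)) G else gebv(calibration, map)
  nc <- nrow(Gc)
  vg <- if (nc > 1L) apply(Gc, 2L, stats::var) else rep(0, nt)
  vng <- vg * (1 - h2) / h2                      # non-genetic variance target

  # individual values on the fixed G×E trait, scaled on the calibration pop
  dosage <- matrix(genome(pop)[, , 1] + genome(pop)[, , 2], n, nMarkers(pop))
  graw <- dosage %*% t(gxe)
  dc <- if (identical(calibration, pop)) dosage else
    matrix(genome(calibration)[, , 1] + genome(calibration)[, , 2],
           nrow(Gc), nMarkers(calibration))
  grawc <- dc %*% t(gxe)
  vraw <- if (nc > 1L) apply(grawc, 2L, stats::var) else rep(0, nt)
  ctr <- colMeans(grawc)

  resVar <- (1 - gxeRatio) * vng
  gxeVar <- gxeRatio * vng
  # a monomorphic G×E trait cannot carry variance; fold it into the residual
  dead <- vraw <= 0
  resVar[dead] <- resVar[dead] + gxeVar[dead]
  gxeVar[dead] <- 0
  scl <- ifelse(dead, 0, sqrt(gxeVar / pmax(vraw, .Machine$double.eps)))
  gval <- sweep(graw, 2L, ctr) %*% diag(scl, nt, nt)

  z <- stats::rnorm(nEnvs)
  out <- array(0, c(n, nt, nEnvs),
               dimnames = list(NULL, traitNames(map), NULL))
  sdRes <- sqrt(resVar)
  for (e in seq_len(nEnvs)) {
    eps <- matrix(stats::rnorm(n * nt), n, nt) %*% diag(sdRes, nt, nt)
    out[, , e] <- G + z[e] * gval + eps
  }
  out
}

#' Average phenotypes over environments
#'
#' @param pheno a (n, t, nEnvs) array from [phenotype()].
#' @return An n x t matrix of per-individual means across environments.
#' @export
meanPhenotype <- function(pheno) {
  stopifnot(length(dim(pheno)) == 3L)
  out <- apply(pheno, c(1L, 2L), mean)
  dimnames(out) <- dimnames(pheno)[1:2]
  out
}
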