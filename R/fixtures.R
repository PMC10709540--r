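## Seeded synthetic generators: linkage maps and founder populations.

#' Generate a synthetic genetic linkage map
#'
#' Builds a map with `nChr` chromosomes of `markersPerChr` markers each,
#' positions spaced uniformly (or uniform-random, sorted) over
#' `[0, chrLength]` centimorgans, and marker effects drawn from a normal
#' distribution with standard deviation `effectSd`.
#'
#' @param nChr number of chromosomes.
#' @param markersPerChr markers per chromosome.
#' @param chrLength chromosome length in centimorgans (default 100).
#' @param nTraits number of traits.
#' @param traitNames trait labels (default `Trait1`, ...).
#' @param heritability optional per-trait heritability in (0, 1].
#' @param effectSd standard deviation of the marker effects.
#' @param spacing `"uniform"` (evenly spaced) or `"random"` (uniform draws,
#'   sorted within chromosome).
#' @param seed optional seed.
#' @return A [GeneticMap-class] with `nChr * markersPerChr` markers.
#' @examples
#' makeMap(10, 100, seed = 1)   # 1000 markers across ten chromosomes
#' @export
makeMap <- function(nChr, markersPerChr, chrLength = 100, nTraits = 1L,
                    traitNames = paste0("Trait", seq_len(nTraits)),
                    heritability = NULL, effectSd = 1,
                    spacing = c("uniform", "random"), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  spacing <- match.arg(spacing)
  stopifnot(nChr >= 1L, markersPerChr >= 1L, chrLength > 0)
  m <- nChr * markersPerChr
  chromosome <- rep(paste0("chr", seq_len(nChr)), each = markersPerChr)
  onePos <- function() {
    if (spacing == "uniform") {
      if (markersPerChr == 1L) 0 else
        seq(0, chrLength, length.out = markersPerChr)
    } else sort(stats::runif(markersPerChr, 0, chrLength))
  }
  positions <- unlist(lapply(seq_len(nChr), function(i) onePos()))
  effects <- matrix(stats::rnorm(length(traitNames) * m, sd = effectSd),
                    nrow = length(traitNames),
                    dimnames = list(traitNames, NULL))
  GeneticMap(chromosome, positions = positions, effects = effects,
             traitNames = traitNames, heritability = heritability)
}

#' Generate a synthetic founder population
#'
#' Draws phased binary genomes site-independently (no linkage
#' disequilibrium): each haplotype allele is Bernoulli with the per-marker
#' allele frequency. In `inbred` mode one haplotype is drawn and duplicated,
#' so every founder is fully homozygous (doubled-haploid-style founders for
#' an inbred species).
#'
#' @param map a [GeneticMap-class]; fixes the marker count.
#' @param n number of founders.
#' @param alleleFreq alternate-allele frequency, a scalar or a length-m
#'   vector, each in [0, 1].
#' @param inbred if `TRUE`, founders are fully homozygous.
#' @param ids individual labels (default `F0_001`, ...).
#' @param seed optional seed.
#' @return A [Population-class] of n founders.
#' @export
makeFounders <- function(map, n, alleleFreq = 0.5, inbred = FALSE,
                         ids = sprintf("F0_%03d", seq_len(n)), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  m <- nMarkers(map)
  if (any(alleleFreq < 0 | alleleFreq > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (length(alleleFreq) == 1L) alleleFreq <- rep(alleleFreq, m)
  if (length(alleleFreq) != m)
    stop("alleleFreq must be a scalar or one frequency per marker")
  drawHap <- function()
    matrix(stats::rbinom(n * m, 1L, rep(alleleFreq, each = n)), n, m)
  g <- array(0L, c(n, m, 2L))
  h1 <- drawHap()
  g[, , 1] <- h1
  g[, , 2] <- if (inbred) h1 else drawHap()
  Population(g, ids = ids)
}
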