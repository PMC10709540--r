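#' @import methods
NULL

#' GeneticMap: a genetic linkage map with per-trait marker effects
#'
#' The static parameterization of the simulator: one row per marker, with a
#' chromosome identifier, a genetic position in centimorgans (optional when
#' per-interval recombination probabilities are supplied directly), a
#' per-interval recombination probability, and a matrix of additive marker
#' effects (one row per trait).
#'
#' @slot chromosome character vector of length m; markers of one chromosome
#'   must be stored contiguously.
#' @slot positions numeric vector of length m with genetic positions in
#'   centimorgans, or `numeric(0)` when only recombination probabilities are
#'   known.
#' @slot recomb numeric vector of length m; element j is the probability that
#'   a recombination occurs between marker j and marker j + 1 of the same
#'   chromosome, in [0, 0.5]. The last marker of each chromosome carries `NA`
#'   (no following interval).
#' @slot effects t x m numeric matrix of additive marker effects, rownames
#'   are the trait names.
#' @slot traitNames character vector of length t.
#' @slot heritability numeric vector of length t with narrow-sense
#'   heritabilities in (0, 1], or `numeric(0)` when not supplied.
#'
#' @seealso [loadMap()], [makeMap()], [positionsToRecomb()]
#' @export
setClass("GeneticMap",
  representation(
    chromosome   = "character",
    positions    = "numeric",
    recomb       = "numeric",
    effects      = "matrix",
    traitNames   = "character",
    heritability = "numeric"
  )
)

setValidity("GeneticMap", function(object) {
  m <- length(object@chromosome)
  msgs <- character(0)
  if (m == 0L) msgs <- c(msgs, "map must contain at least one marker")
  # chromosomes must form contiguous runs so marker indices are stable
  runs <- rle(object@chromosome)$values
  if (anyDuplicated(runs))
    msgs <- c(msgs, "markers of one chromosome must be contiguous in the map")
  if (length(object@positions) && length(object@positions) != m)
    msgs <- c(msgs, sprintf("positions length (%d) != marker count (%d)",
                            length(object@positions), m))
  if (length(object@positions)) {
    bad <- tapply(object@positions, factor(object@chromosome,
                                           levels = unique(object@chromosome)),
                  function(p) is.unsorted(p, strictly = FALSE))
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "positions not sorted within chromosome(s): %s",
        paste(names(bad)[bad], collapse = ", ")))
  }
  if (length(object@recomb) != m)
    msgs <- c(msgs, sprintf("recomb length (%d) != marker count (%d)",
                            length(object@recomb), m))
  r <- object@recomb[!is.na(object@recomb)]
  if (any(r < 0 | r > 0.5))
    msgs <- c(msgs, "recombination probabilities must lie in [0, 0.5]")
  if (!is.numeric(object@effects))
    msgs <- c(msgs, "effects must be a numeric matrix")
  if (ncol(object@effects) != m)
    msgs <- c(msgs, sprintf("effects columns (%d) != marker count (%d)",
                            ncol(object@effects), m))
  if (nrow(object@effects) != length(object@traitNames))
    msgs <- c(msgs, sprintf("effect rows (%d) != number of trait names (%d)",
                            nrow(object@effects), length(object@traitNames)))
  if (length(object@heritability)) {
    if (length(object@heritability) != length(object@traitNames))
      msgs <- c(msgs, "heritability must have one value per trait")
    if (any(object@heritability <= 0 | object@heritability > 1))
      msgs <- c(msgs, "heritability values must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Population: phased genomes of n individuals
#'
#' A population is a rank-3 binary array of shape (n, m, d): n individuals,
#' m markers, d = 2 haplotypes per individual (diploid). Entry
#' `genome[i, j, h]` is the allele (0 = reference, 1 = alternate) carried by
#' haplotype h of individual i at marker j. The encoding requires phased
#' input data.
#'
#' @slot genome integer array of dimension (n, m, 2) with entries in {0, 1}.
#' @slot ids character vector of individual labels, length n or `character(0)`.
#'
#' @seealso [Population()], [loadPopulation()], [makeFounders()]
#' @export
setClass("Population",
  representation(genome = "array", ids = "character")
)

setValidity("Population", function(object) {
  d <- dim(object@genome)
  msgs <- character(0)
  if (length(d) != 3L)
    return("genome must be a rank-3 array (individuals x markers x ploidy)")
  if (d[3] != 2L)
    msgs <- c(msgs, sprintf("ploidy dimension must be 2, got %d", d[3]))
  g <- object@genome
  if (length(g) && (anyNA(g) || !all(g == 0L | g == 1L)))
    msgs <- c(msgs, "genome entries must all be 0 or 1")
  if (length(object@ids) && length(object@ids) != d[1])
    msgs <- c(msgs, sprintf("ids length (%d) != number of individuals (%d)",
                            length(object@ids), d[1]))
  if (length(msgs)) msgs else TRUE
})

#' SchemaConfig: stage-by-stage description of a breeding program
#'
#' Describes an inbred breeding schema: an F0 founder set, random biparental
#' F1 crosses, doubled-haploid induction, then a sequence of
#' phenotype-selection stages (head rows and yield trials) with decreasing
#' population sizes and increasing evaluation accuracy. All sizes are
#' multiplied by `scale`.
#'
#' @slot founders number of F0 lines.
#' @slot f1Crosses number of random biparental crosses producing F1.
#' @slot dhPerLine doubled haploids induced per F1 line.
#' @slot stageNames labels of the selection stages, in order.
#' @slot stageKeep population size kept after selection at each stage;
#'   strictly positive and non-increasing.
#' @slot stageH2 heritability used by phenotype scoring at each stage
#'   (operationalizes evaluation accuracy; low for visual selection).
#' @slot stageEnvs number of environments (locations) phenotyped per stage.
#' @slot scale scaling factor (>= 1) multiplying all population sizes.
#' @slot f0Diallel offspring per pair for an optional diallel pre-step that
#'   regenerates F0 from the supplied parents; 0 disables it.
#'
#' @seealso [schemaConfig()], [runSchema()]
#' @export
setClass("SchemaConfig",
  representation(
    founders  = "numeric",
    f1Crosses = "numeric",
    dhPerLine = "numeric",
    stageNames = "character",
    stageKeep  = "numeric",
    stageH2    = "numeric",
    stageEnvs  = "numeric",
    scale      = "numeric",
    f0Diallel  = "numeric"
  )
)

setValidity("SchemaConfig", function(object) {
  msgs <- character(0)
  s <- length(object@stageNames)
  if (length(object@stageKeep) != s || length(object@stageH2) != s ||
      length(object@stageEnvs) != s)
    msgs <- c(msgs, "stageKeep, stageH2 and stageEnvs must match stageNames in length")
  if (any(c(object@founders, object@f1Crosses, object@dhPerLine,
            object@stageKeep, object@stageEnvs) < 1))
    msgs <- c(msgs, "all sizes and environment counts must be strictly positive")
  if (s > 1L && any(diff(object@stageKeep) > 0))
    msgs <- c(msgs, "stage sizes must be non-increasing across stages")
  if (any(object@stageH2 <= 0 | object@stageH2 > 1))
    msgs <- c(msgs, "stage heritabilities must lie in (0, 1]")
  if (object@scale < 1)
    msgs <- c(msgs, "scale must be >= 1")
  if (object@f0Diallel < 0)
    msgs <- c(msgs, "f0Diallel must be >= 0")
  if (length(msgs)) msgs else TRUE
})
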