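## Linkage-map construction, Haldane mapping function, and delimited I/O.

# column-name aliases recognised by loadMap (exact, case-sensitive matching)
.CHR_ALIASES    <- c("CHR.PHYS", "chromosome", "Chromosome", "chrom", "chr", "CHR")
.POS_ALIASES    <- c("cM", "position_cM", "pos_cM", "position", "Position")
.RECOMB_ALIASES <- c("RecombRate", "recomb_prob", "recomb", "r")

#' Construct a GeneticMap
#'
#' Low-level constructor; most users will call [loadMap()] or [makeMap()].
#' When `positions` are supplied, per-interval recombination probabilities
#' are derived with the Haldane mapping function via [positionsToRecomb()];
#' when `recomb` is supplied it is used verbatim.
#'
#' @param chromosome character vector of chromosome identifiers, one per
#'   marker; markers of one chromosome must be contiguous.
#' @param positions genetic positions in centimorgans (sorted within each
#'   chromosome), or `NULL` when `recomb` is given.
#' @param recomb per-interval recombination probabilities in [0, 0.5]; the
#'   value at the last marker of each chromosome is ignored (set to `NA`).
#' @param effects t x m matrix of additive marker effects (a vector is taken
#'   as a single trait).
#' @param traitNames trait labels; default taken from `rownames(effects)` or
#'   `"Trait1"`, ... .
#' @param heritability optional per-trait narrow-sense heritability in (0, 1].
#' @return A validated [GeneticMap-class] object.
#' @export
GeneticMap <- function(chromosome, positions = NULL, recomb = NULL,
                       effects, traitNames = NULL, heritability = NULL) {
  chromosome <- as.character(chromosome)
  m <- length(chromosome)
  if (is.null(positions) && is.null(recomb))
    stop("one of 'positions' or 'recomb' must be supplied")
  if (!is.null(dim(effects))) effects <- as.matrix(effects) else
    effects <- matrix(as.numeric(effects), nrow = 1L)
  if (is.null(traitNames))
    traitNames <- if (!is.null(rownames(effects))) rownames(effects) else
      paste0("Trait", seq_len(nrow(effects)))
  rownames(effects) <- traitNames
  if (!is.null(positions)) {
    positions <- as.numeric(positions)
    if (is.null(recomb))
      recomb <- positionsToRecomb(positions, chromosome)
  } else positions <- numeric(0)
  recomb <- as.numeric(recomb)
  # the trailing marker of each chromosome has no following interval
  if (length(recomb) == m)
    recomb[.chromosomeLast(chromosome)] <- NA_real_
  new("GeneticMap",
      chromosome = chromosome, positions = positions, recomb = recomb,
      effects = effects, traitNames = as.character(traitNames),
      heritability = if (is.null(heritability)) numeric(0) else
        as.numeric(heritability))
}

# logical index of the last marker of each chromosome
.chromosomeLast <- function(chromosome) {
  m <- length(chromosome)
  c(chromosome[-m] != chromosome[-1L], TRUE)
}

#' Haldane mapping function
#'
#' Converts a genetic distance in centimorgans into a recombination
#' probability under a Poisson crossover process (no interference):
#' r = (1 - exp(-2 d / 100)) / 2. `haldaneInverse()` is its inverse.
#'
#' @param d_cM genetic distance(s) in centimorgans, non-negative.
#' @param r recombination probability(ies) in [0, 0.5).
#' @return `haldane()`: probabilities in [0, 0.5); `haldaneInverse()`:
#'   distances in centimorgans.
#' @examples
#' haldane(10)            # ~0.0906
#' haldaneInverse(haldane(25))
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distances must be non-negative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' @rdname haldane
#' @export
haldaneInverse <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination probability must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Derive per-interval recombination probabilities from cM positions
#'
#' For adjacent markers j, j + 1 on the same chromosome at distance delta
#' centimorgans, the probability of an odd number of crossovers in the
#' interval under the Poisson model is given by the Haldane mapping function
#' r_j = (1 - exp(-2 delta / 100)) / 2. Chromosome boundaries (the last
#' marker of each chromosome) carry `NA`: no inter-chromosome interval
#' exists.
#'
#' @param positions numeric vector of cM positions, sorted non-decreasingly
#'   within each chromosome.
#' @param chromosome chromosome identifier per marker (contiguous runs).
#' @return numeric vector of length `length(positions)`; element j is the
#'   recombination probability between markers j and j + 1, `NA` at the last
#'   marker of each chromosome.
#' @export
positionsToRecomb <- function(positions, chromosome) {
  m <- length(positions)
  if (length(chromosome) != m)
    stop("positions and chromosome must have equal length")
  if (m == 0L) return(numeric(0))
  last <- .chromosomeLast(chromosome)
  delta <- c(positions[-1L] - positions[-m], NA_real_)
  delta[last] <- NA_real_
  if (any(delta < 0, na.rm = TRUE))
    stop("positions must be sorted non-decreasingly within each chromosome")
  r <- rep(NA_real_, m)
  r[!last] <- haldane(delta[!last])
  r
}

#' Load a genetic linkage map from a delimited file or data frame
#'
#' The table must have one row per marker with a chromosome column (any of
#' `CHR.PHYS`, `chromosome`, `chrom`, `chr`, `CHR`), and either a
#' centimorgan position column (`cM`, ...) or a per-interval recombination
#' probability column (`RecombRate`, ...), plus one numeric column per trait
#' holding linear marker effects. Column matching is exact and
#' case-sensitive. When positions are given, recombination probabilities are
#' derived with the Haldane mapping function; when probabilities are given
#' they are used verbatim. Markers must already be sorted by position within
#' each chromosome: the loader rejects unsorted input rather than silently
#' reordering, so marker indices stay aligned with population arrays.
#'
#' @param source path to a CSV/TSV file (delimiter sniffed from the header
#'   line) or a data frame.
#' @param traitNames traits to load; default: every column that is neither
#'   the chromosome, position nor recombination column.
#' @param heritability optional per-trait heritability in (0, 1].
#' @param drawMissingEffects if `TRUE`, a requested trait absent from the
#'   table has its effects drawn from a standard normal distribution;
#'   requires an explicit `seed`.
#' @param seed seed for drawn effects.
#' @return A [GeneticMap-class].
#' @export
loadMap <- function(source, traitNames = NULL, heritability = NULL,
                    drawMissingEffects = FALSE, seed = NULL) {
  tab <- if (is.character(source)) .readDelimited(source) else
    as.data.frame(source, stringsAsFactors = FALSE)
  cn <- names(tab)
  chrCol <- intersect(.CHR_ALIASES, cn)[1]
  if (is.na(chrCol))
    stop("map table lacks a chromosome column (expected one of: ",
         paste(.CHR_ALIASES, collapse = ", "), ")")
  posCol <- intersect(.POS_ALIASES, cn)[1]
  recCol <- intersect(.RECOMB_ALIASES, cn)[1]
  if (is.na(posCol) && is.na(recCol))
    stop("map table lacks both a position column ('cM') and a ",
         "recombination-probability column ('RecombRate')")
  reserved <- c(chrCol, posCol, recCol)
  if (is.null(traitNames))
    traitNames <- setdiff(cn, reserved)
  if (!length(traitNames)) stop("no trait columns found or requested")
  missing <- setdiff(traitNames, cn)
  if (length(missing) && !drawMissingEffects)
    stop("trait column(s) not found in map table: ",
         paste(missing, collapse = ", "))
  if (length(missing) && is.null(seed))
    stop("drawMissingEffects = TRUE requires an explicit seed")

  chromosome <- as.character(tab[[chrCol]])
  m <- length(chromosome)
  effects <- matrix(NA_real_, nrow = length(traitNames), ncol = m,
                    dimnames = list(traitNames, NULL))
  for (tr in setdiff(traitNames, missing))
    effects[tr, ] <- as.numeric(tab[[tr]])
  if (length(missing)) {
    if (!is.null(seed)) withr::local_seed(seed)
    for (tr in missing) effects[tr, ] <- stats::rnorm(m)
  }

  if (!is.na(posCol)) {
    positions <- as.numeric(tab[[posCol]])
    unsorted <- tapply(positions,
                       factor(chromosome, levels = unique(chromosome)),
                       is.unsorted)
    if (any(unsorted))
      stop("marker positions are not sorted within chromosome(s): ",
           paste(names(unsorted)[unsorted], collapse = ", "),
           " (re-sort the table; the loader does not reorder)")
    GeneticMap(chromosome, positions = positions, effects = effects,
               traitNames = traitNames, heritability = heritability)
  } else {
    recomb <- as.numeric(tab[[recCol]])
    live <- !.chromosomeLast(chromosome) & !is.na(recomb)
    if (any(recomb[live] < 0 | recomb[live] > 0.5))
      stop("recombination probabilities must lie in [0, 0.5]")
    GeneticMap(chromosome, recomb = recomb, effects = effects,
               traitNames = traitNames, heritability = heritability)
  }
}

.readDelimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a GeneticMap to a delimited file
#'
#' Writes the canonical comma-separated layout read back by [loadMap()]:
#' a `chromosome` column, a `cM` column when positions are known (otherwise
#' a `RecombRate` column), and one column per trait. Re-loading reproduces
#' the map field-for-field (heritability is not stored in the table and must
#' be passed again).
#'
#' @param map a [GeneticMap-class].
#' @param path destination file; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
writeMap <- function(map, path) {
  tab <- data.frame(chromosome = map@chromosome, stringsAsFactors = FALSE)
  if (length(map@positions)) tab$cM <- map@positions else
    tab$RecombRate <- ifelse(is.na(map@recomb), 0, map@recomb)
  for (tr in map@traitNames) tab[[tr]] <- map@effects[tr, ]
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Accessors ----------------------------------------------------------------

#' Accessors for GeneticMap
#'
#' `nMarkers()` and `nTraits()` return the marker and trait counts;
#' `chromosomes()` the per-marker chromosome identifiers; `mapPositions()`
#' the cM positions (length 0 when the map was built from probabilities);
#' `recombProb()` the per-interval recombination probabilities (`NA` at the
#' last marker of each chromosome); `markerEffects()` the t x m effect
#' matrix; `traitNames()` and `heritability()` the trait metadata.
#'
#' @param x a [GeneticMap-class].
#' @param value replacement heritability vector (length t, each in (0, 1]).
#' @name GeneticMap-accessors
NULL

#' @rdname GeneticMap-accessors
setMethod("nMarkers", "GeneticMap", function(x) length(x@chromosome))

#' @rdname GeneticMap-accessors
setMethod("nTraits", "GeneticMap", function(x) length(x@traitNames))

#' @rdname GeneticMap-accessors
setMethod("traitNames", "GeneticMap", function(x) x@traitNames)

#' @rdname GeneticMap-accessors
setMethod("chromosomes", "GeneticMap", function(x) x@chromosome)

#' @rdname GeneticMap-accessors
setMethod("markerEffects", "GeneticMap", function(x) x@effects)

#' @rdname GeneticMap-accessors
setMethod("recombProb", "GeneticMap", function(x) x@recomb)

#' @rdname GeneticMap-accessors
setMethod("mapPositions", "GeneticMap", function(x) x@positions)

#' @rdname GeneticMap-accessors
setMethod("heritability", "GeneticMap", function(x) x@heritability)

#' @rdname GeneticMap-accessors
setMethod("heritability<-", "GeneticMap", function(x, value) {
  x@heritability <- as.numeric(value)
  validObject(x)
  x
})

setMethod("show", "GeneticMap", function(object) {
  nchr <- length(unique(object@chromosome))
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s), %d trait(s)\n",
              nMarkers(object), nchr, nTraits(object)))
  cat("  traits: ", paste(object@traitNames, collapse = ", "), "\n", sep = "")
  if (length(object@heritability))
    cat("  heritability: ",
        paste(format(object@heritability), collapse = ", "), "\n", sep = "")
  if (length(object@positions))
    cat(sprintf("  positions: %.1f-%.1f cM\n",
                min(object@positions), max(object@positions)))
})
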