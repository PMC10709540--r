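## Population container and I/O: native RDS container and phased VCF.

#' Construct a Population
#'
#' @param genome array of dimension (n, m, 2) with entries in {0, 1}; a
#'   matrix of shape (m, 2) is promoted to a single individual.
#' @param ids optional character vector of individual labels (length n).
#' @return A validated [Population-class].
#' @examples
#' g <- array(0L, c(3, 5, 2))
#' Population(g, ids = c("A", "B", "C"))
#' @export
Population <- function(genome, ids = NULL) {
  if (is.matrix(genome)) genome <- array(genome, c(1L, dim(genome)))
  storage.mode(genome) <- "integer"
  dimnames(genome) <- NULL
  new("Population", genome = genome,
      ids = if (is.null(ids)) character(0) else as.character(ids))
}

## Accessors ----------------------------------------------------------------

#' Accessors for Population
#'
#' `nIndividuals()` returns n, `genome()` the (n, m, 2) integer array,
#' `ploidy()` the size of the third axis (always 2 here), `ids()` the
#' individual labels (possibly empty). `x[i]` subsets individuals.
#'
#' @param x a [Population-class].
#' @name Population-accessors
NULL

#' @rdname Population-accessors
setMethod("nIndividuals", "Population", function(x) dim(x@genome)[1])

#' @rdname Population-accessors
setMethod("genome", "Population", function(x) x@genome)

#' @rdname Population-accessors
setMethod("ploidy", "Population", function(x) dim(x@genome)[3])

#' @rdname Population-accessors
setMethod("ids", "Population", function(x) x@ids)

#' @rdname Population-accessors
setMethod("nMarkers", "Population", function(x) dim(x@genome)[2])

#' @param i individual indices (integer or logical).
#' @param j,...,drop ignored.
#' @rdname Population-accessors
#' @export
setMethod("[", "Population", function(x, i, j, ..., drop = FALSE) {
  Population(x@genome[i, , , drop = FALSE],
             ids = if (length(x@ids)) x@ids[i] else NULL)
})

setMethod("show", "Population", function(object) {
  d <- dim(object@genome)
  cat(sprintf("Population: %d individual(s), %d marker(s), ploidy %d\n",
              d[1], d[2], d[3]))
  if (d[1] > 0 && d[2] > 0) {
    het <- mean(object@genome[, , 1] != object@genome[, , 2])
    cat(sprintf("  mean heterozygosity: %.3f\n", het))
  }
})

#' Concatenate populations (row-wise over individuals)
#'
#' @param ... [Population-class] objects with identical marker counts.
#' @return A single [Population-class] holding all individuals in order.
#' @export
bindPopulations <- function(...) {
  pops <- list(...)
  if (length(pops) == 1L && is.list(pops[[1]]) && !is(pops[[1]], "Population"))
    pops <- pops[[1]]
  m <- unique(vapply(pops, nMarkers, integer(1)))
  if (length(m) != 1L)
    stop("populations have differing marker counts: ",
         paste(m, collapse = ", "))
  ns <- vapply(pops, nIndividuals, integer(1))
  g <- array(0L, c(sum(ns), m, 2L))
  at <- 0L
  for (p in pops) {
    if (nIndividuals(p) > 0)
      g[at + seq_len(nIndividuals(p)), , ] <- p@genome
    at <- at + nIndividuals(p)
  }
  allIds <- unlist(lapply(pops, function(p)
    if (length(p@ids)) p@ids else rep(NA_character_, nIndividuals(p))))
  Population(g, ids = if (all(is.na(allIds))) NULL else allIds)
}

## Native container ---------------------------------------------------------

#' Save and load populations
#'
#' `savePopulation()` writes the native single-object binary container
#' (RDS holding the genome array and ids); `loadPopulation()` reads it back
#' bit-exactly, or imports a phased VCF when the path ends in `.vcf` /
#' `.vcf.gz`. When a `map` is supplied the marker count (and, for VCF,
#' chromosome identifiers when comparable) are validated against it.
#'
#' @param pop a [Population-class].
#' @param dest,source file path; `.vcf`/`.vcf.gz` selects VCF in
#'   `loadPopulation()`.
#' @param map optional [GeneticMap-class] to validate against.
#' @return `savePopulation()`: `dest`, invisibly. `loadPopulation()`: a
#'   [Population-class].
#' @export
savePopulation <- function(pop, dest) {
  stopifnot(is(pop, "Population"))
  ok <- tryCatch({
    saveRDS(list(dim = dim(pop@genome), genome = pop@genome, ids = pop@ids),
            dest)
    TRUE
  }, error = function(e)
    stop("failed to write population to '", dest, "': ", conditionMessage(e)))
  invisible(dest)
}

#' @rdname savePopulation
#' @export
loadPopulation <- function(source, map = NULL) {
  if (!file.exists(source)) stop("file not found: ", source)
  pop <- if (grepl("\\.vcf(\\.gz)?$", source)) importVCF(source, map = map)
         else {
    obj <- readRDS(source)
    Population(obj$genome, ids = if (length(obj$ids)) obj$ids else NULL)
  }
  if (!is.null(map) && nMarkers(pop) != nMarkers(map))
    stop(sprintf("marker-count mismatch: population has %d markers, map has %d",
                 nMarkers(pop), nMarkers(map)))
  pop
}

## Phased VCF ---------------------------------------------------------------

#' Import a phased VCF as a Population
#'
#' Sites must be biallelic and every genotype phased (`a|b`); the REF allele
#' maps to 0 and the single ALT allele to 1, and `a|b` maps to `(a, b)` on
#' the haplotype axis. Unphased genotypes (`a/b`) are rejected: the (n, m, d)
#' encoding requires phased input (use external phasing software first).
#' Marker (row) order must match the linkage-map order.
#'
#' @param path path to a VCF (optionally gzipped).
#' @param map optional [GeneticMap-class]; marker count and, when the
#'   identifier sets agree, per-marker chromosomes are checked.
#' @return A [Population-class] with `ids` from the VCF sample names.
#' @export
importVCF <- function(path, map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multi-allelic sites are not supported (REF -> 0, single ALT -> 1)")
  gt <- vcfR::extract.gt(vcf)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype ('/' separator) found: the population encoding ",
         "requires phased input data; phase the VCF first")
  if (anyNA(gt) || any(grepl("\\.", gt)))
    stop("missing genotypes are not supported")
  m <- nrow(gt); n <- ncol(gt)
  # gt is markers x samples of "a|b"
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  if (anyNA(a1) || anyNA(a2) || any(a1 > 1L) || any(a2 > 1L))
    stop("genotype entries must be phased biallelic '0|0', '0|1', '1|0' or '1|1'")
  g <- array(0L, c(n, m, 2L))
  g[, , 1] <- t(matrix(a1, m, n))
  g[, , 2] <- t(matrix(a2, m, n))
  if (!is.null(map)) {
    if (m != nMarkers(map))
      stop(sprintf("marker-count mismatch: VCF has %d sites, map has %d markers",
                   m, nMarkers(map)))
    vchr <- as.character(fix[, "CHROM"])
    if (setequal(unique(vchr), unique(chromosomes(map))) &&
        !identical(vchr, chromosomes(map)))
      stop("VCF site order does not match the linkage-map marker order")
  }
  Population(g, ids = colnames(gt))
}

#' Export a Population as a phased VCF
#'
#' Writes a minimal text VCF with one biallelic site per marker (REF `A`,
#' ALT `T`), GT-only FORMAT, and phased `a|b` genotypes reflecting the two
#' haplotypes in order. Positions are the marker ordinal within each
#' chromosome (the container is marker-indexed; physical coordinates are out
#' of scope).
#'
#' @param pop a [Population-class].
#' @param map a [GeneticMap-class] supplying chromosome identifiers.
#' @param path destination `.vcf` path.
#' @return `path`, invisibly.
#' @export
exportVCF <- function(pop, map, path) {
  if (nMarkers(pop) != nMarkers(map))
    stop(sprintf("marker-count mismatch: population has %d markers, map has %d",
                 nMarkers(pop), nMarkers(map)))
  n <- nIndividuals(pop); m <- nMarkers(pop)
  samples <- if (length(pop@ids)) pop@ids else sprintf("IND%03d", seq_len(n))
  chr <- chromosomes(map)
  pos <- stats::ave(seq_len(m), chr, FUN = seq_along)
  gtm <- matrix("", m, n)
  for (i in seq_len(n))
    gtm[, i] <- paste0(pop@genome[i, , 1], "|", pop@genome[i, , 2])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=breedsim",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(chr, pos, sprintf("M%d", seq_len(m)), "A", "T", ".", "PASS",
                ".", "GT", sep = "\t")
  if (n > 0) body <- paste(body, apply(gtm, 1L, paste, collapse = "\t"),
                           sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
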