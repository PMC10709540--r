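## Multi-stage inbred breeding-schema runner: F0 -> random F1 crosses ->
## doubled-haploid induction -> phenotype-selection stages (head rows and
## yield trials of decreasing size and increasing accuracy).

#' Build a breeding-schema configuration
#'
#' Defaults describe the reference inbred program: 50 F0 lines, 200 random
#' biparental F1 crosses, 100 doubled haploids per F1 line (20 000 DH lines
#' before selection), then visual selection on head rows (HDRW, low
#' accuracy) followed by preliminary, advanced and elite yield trials (PYT,
#' AYT, EYT) with shrinking sizes and growing accuracy. Accuracy is
#' operationalized as the heritability used by phenotype scoring at each
#' stage. All sizes are multiplied by `scale`.
#'
#' @param founders F0 size.
#' @param f1Crosses number of random biparental crosses producing F1.
#' @param dhPerLine doubled haploids induced per F1 line.
#' @param stageNames,stageKeep,stageH2,stageEnvs per-stage label, size kept
#'   after selection (strictly positive, non-increasing), scoring
#'   heritability in (0, 1], and number of environments phenotyped.
#' @param scale scaling factor (>= 1) applied to founders, crosses and
#'   stage sizes.
#' @param f0Diallel offspring per pair for an optional diallel pre-step
#'   regenerating F0 from the supplied parents; 0 (default) starts directly
#'   from the founders.
#' @return A validated [SchemaConfig-class].
#' @export
schemaConfig <- function(founders = 50, f1Crosses = 200, dhPerLine = 100,
                         stageNames = c("HDRW", "PYT", "AYT", "EYT"),
                         stageKeep = c(500, 50, 10, 5),
                         stageH2   = c(0.1, 0.4, 0.6, 0.8),
                         stageEnvs = c(1, 1, 2, 3),
                         scale = 1, f0Diallel = 0) {
  new("SchemaConfig", founders = founders, f1Crosses = f1Crosses,
      dhPerLine = dhPerLine, stageNames = stageNames, stageKeep = stageKeep,
      stageH2 = stageH2, stageEnvs = stageEnvs, scale = scale,
      f0Diallel = f0Diallel)
}

setMethod("show", "SchemaConfig", function(object) {
  cat(sprintf(
    "SchemaConfig: %d founders, %d F1 crosses, %d DH/line (scale %gx)\n",
    object@founders, object@f1Crosses, object@dhPerLine, object@scale))
  for (i in seq_along(object@stageNames))
    cat(sprintf("  %-5s keep %5d  h2 = %.2f  envs = %d\n",
                object@stageNames[i], object@stageKeep[i] * object@scale,
                object@stageH2[i], object@stageEnvs[i]))
})

#' Default linkage map for the reference schema
#'
#' A map with the reference geometry — 21 chromosomes of 100 QTL each by
#' default — uniformly spaced over `chrLength` centimorgans, standard-normal
#' effects for a single yield trait.
#'
#' @param chromosomes number of chromosomes (default 21).
#' @param qtlPerChromosome markers per chromosome (default 100).
#' @param chrLength chromosome length in centimorgans.
#' @param heritability trait heritability recorded in the map.
#' @param seed optional seed.
#' @return A [GeneticMap-class] with `chromosomes * qtlPerChromosome`
#'   markers and one trait `"Yield"`.
#' @export
defaultSchemaMap <- function(chromosomes = 21L, qtlPerChromosome = 100L,
                             chrLength = 100, heritability = 0.4,
                             seed = NULL) {
  makeMap(chromosomes, qtlPerChromosome, chrLength = chrLength,
          nTraits = 1L, traitNames = "Yield", heritability = heritability,
          seed = seed)
}

# per-trait summary of genetic values at one stage
.stageReport <- function(stage, pop, map) {
  g <- gebv(pop, map)
  do.call(rbind, lapply(seq_len(ncol(g)), function(tau) data.frame(
    stage = stage, n = nrow(g), trait = colnames(g)[tau],
    meanGV = mean(g[, tau]),
    sdGV = if (nrow(g) > 1L) stats::sd(g[, tau]) else NA_real_,
    maxGV = max(g[, tau]),
    stringsAsFactors = FALSE)))
}

#' Run a breeding schema
#'
#' Executes the configured program: optional diallel F0 pre-step, random
#' biparental F1 crosses, doubled-haploid induction, then each selection
#' stage in order, scoring by simulated phenotype at that stage's
#' heritability and environment count (the G×E marker effects are drawn
#' once at the start of the run and held fixed across stages). After each
#' step the per-trait mean, standard deviation and maximum of the genetic
#' values (GEBV) are recorded.
#'
#' @param config a [SchemaConfig-class].
#' @param map a [GeneticMap-class] with at least one trait.
#' @param founders optional [Population-class] of `founders * scale`
#'   individuals; generated with [makeFounders()] (inbred mode) when `NULL`.
#' @param seed optional seed governing the whole run.
#' @return A list with `report` (a data frame with one row per stage and
#'   trait: `stage`, `n`, `trait`, `meanGV`, `sdGV`, `maxGV`) and
#'   `population` (the final elite lines).
#' @examples
#' map <- makeMap(3, 20, heritability = 0.4, seed = 1)
#' cfg <- schemaConfig(founders = 10, f1Crosses = 15, dhPerLine = 4,
#'                     stageKeep = c(30, 10, 5, 2))
#' res <- runSchema(cfg, map, seed = 1)
#' res$report
#' @export
runSchema <- function(config, map, founders = NULL, seed = NULL) {
  stopifnot(is(config, "SchemaConfig"))
  validObject(config)
  if (!is.null(seed)) withr::local_seed(seed)
  sc <- config@scale
  nF0 <- as.integer(config@founders * sc)

  if (is.null(founders))
    founders <- makeFounders(map, nF0, inbred = TRUE)
  if (nIndividuals(founders) != nF0)
    stop(sprintf("founders must contain %d individuals (founders * scale), got %d",
                 nF0, nIndividuals(founders)))
  gxe <- gxeEffects(map)    # fixed for the lifetime of this simulation

  pop <- founders
  if (config@f0Diallel > 0)
    pop <- diallel(pop, as.integer(config@f0Diallel), map)
  report <- .stageReport("F0", pop, map)

  f1 <- randomCrosses(pop, as.integer(config@f1Crosses * sc), map)
  report <- rbind(report, .stageReport("F1", f1, map))

  dhArr <- doubleHaploid(f1, as.integer(config@dhPerLine), map)
  pop <- dhToPopulation(dhArr)
  report <- rbind(report, .stageReport("DH", pop, map))

  for (i in seq_along(config@stageNames)) {
    keep <- as.integer(config@stageKeep[i] * sc)
    if (keep > nIndividuals(pop))
      stop(sprintf("stage %s keeps %d individuals but only %d are available",
                   config@stageNames[i], keep, nIndividuals(pop)))
    sel <- selectTop(pop, keep, scorePhenotype, map = map,
                     nEnvs = as.integer(config@stageEnvs[i]),
                     h2 = config@stageH2[i], gxe = gxe)
    pop <- sel$population
    report <- rbind(report, .stageReport(config@stageNames[i], pop, map))
  }
  rownames(report) <- NULL
  list(report = report, population = pop)
}

#' Plot a schema trajectory (cosmetic helper)
#'
#' Draws the per-stage mean genetic value with a +/- 1 SD ribbon from a
#' [runSchema()] report. Requires ggplot2.
#'
#' @param report the `report` data frame from [runSchema()].
#' @param trait trait to plot (default: first).
#' @return A ggplot object.
#' @export
plotSchema <- function(report, trait = report$trait[1]) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSchema requires the ggplot2 package")
  d <- report[report$trait == trait, , drop = FALSE]
  d$stage <- factor(d$stage, levels = unique(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = stage, y = meanGV, group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = meanGV - sdGV,
                                      ymax = meanGV + sdGV), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = sprintf("genetic value (%s)", trait))
}
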