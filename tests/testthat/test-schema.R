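test_that("schema configuration invariants are enforced before simulation", {
  expect_s4_class(schemaConfig(), "SchemaConfig")
  expect_error(schemaConfig(stageKeep = c(100, 200, 10, 5)), "non-increasing")
  expect_error(schemaConfig(stageH2 = c(0.1, 0.4, 0.6, 1.2)), "\\(0, 1\\]")
  expect_error(schemaConfig(scale = 0.5), ">= 1")
  expect_error(schemaConfig(founders = 0), "positive")
  expect_error(schemaConfig(stageKeep = c(10, 5)), "length")
})

test_that("defaultSchemaMap produces the reference geometry", {
  map <- defaultSchemaMap(seed = 300)
  expect_equal(nMarkers(map), 21L * 100L)
  expect_equal(length(unique(chromosomes(map))), 21L)
  expect_equal(traitNames(map), "Yield")
  expect_identical(markerEffects(defaultSchemaMap(seed = 300)),
                   markerEffects(map))
  # degenerate single-marker geometry still loads and runs
  one <- defaultSchemaMap(chromosomes = 1, qtlPerChromosome = 1, seed = 301)
  expect_equal(nMarkers(one), 1L)
  cfg <- schemaConfig(founders = 6, f1Crosses = 8, dhPerLine = 3,
                      stageKeep = c(12, 6, 3, 2))
  expect_no_error(runSchema(cfg, one, seed = 302))
})

test_that("the default schema reaches 20000 DH lines before selection", {
  map <- makeMap(10, 100, heritability = 0.4, seed = 310)  # 1000 markers
  res <- runSchema(schemaConfig(), map, seed = 311)
  rep <- res$report
  expect_equal(rep$n[rep$stage == "F0"], 50)
  expect_equal(rep$n[rep$stage == "F1"], 200)
  expect_equal(rep$n[rep$stage == "DH"], 200 * 100)
  expect_equal(rep$n[rep$stage == "HDRW"], 500)
  expect_equal(rep$n[rep$stage == "EYT"], 5)
  expect_equal(nIndividuals(res$population), 5L)
  # doubled haploids: the final lines are fully homozygous
  g <- genome(res$population)
  expect_identical(g[, , 1], g[, , 2])
})

test_that("the scaling factor multiplies every stage size exactly", {
  map <- makeMap(3, 15, heritability = 0.4, seed = 320)
  base <- schemaConfig(founders = 8, f1Crosses = 10, dhPerLine = 4,
                       stageKeep = c(20, 10, 4, 2))
  scaled <- schemaConfig(founders = 8, f1Crosses = 10, dhPerLine = 4,
                         stageKeep = c(20, 10, 4, 2), scale = 3)
  r1 <- runSchema(base, map, seed = 321)$report
  r3 <- runSchema(scaled, map, seed = 321)$report
  expect_equal(r3$n, r1$n * 3)
})

test_that("schema runs are reproducible under a fixed seed", {
  map <- makeMap(3, 15, heritability = 0.4, seed = 330)
  cfg <- schemaConfig(founders = 8, f1Crosses = 10, dhPerLine = 4,
                      stageKeep = c(20, 10, 4, 2))
  a <- runSchema(cfg, map, seed = 331)
  b <- runSchema(cfg, map, seed = 331)
  expect_identical(a$report, b$report)
  expect_identical(genome(a$population), genome(b$population))
})

test_that("selection stages are provenance subsets of their predecessors", {
  map <- makeMap(3, 15, heritability = 0.4, seed = 340)
  cfg <- schemaConfig(founders = 8, f1Crosses = 10, dhPerLine = 4,
                      stageKeep = c(20, 10, 4, 2))
  res <- runSchema(cfg, map, seed = 341)
  # every final individual appears in the DH population: selection only
  # ever subsets, while crossing/DH stages create new genomes
  final <- genome(res$population)
  keyFinal <- apply(final[, , 1, drop = FALSE], 1, paste, collapse = "")
  # rebuild the DH pool of the same run
  withr::with_seed(341, {
    founders <- makeFounders(map, 8, inbred = TRUE)
    gxe <- gxeEffects(map)
    f1 <- randomCrosses(founders, 10, map)
    dhp <- dhToPopulation(doubleHaploid(f1, 4, map))
  })
  keyDH <- apply(genome(dhp)[, , 1], 1, paste, collapse = "")
  expect_true(all(keyFinal %in% keyDH))
})

test_that("the genetic value climbs and variance erodes over the program", {
  map <- makeMap(4, 25, heritability = 0.4, seed = 350)
  cfg <- schemaConfig(founders = 12, f1Crosses = 20, dhPerLine = 6,
                      stageKeep = c(40, 15, 6, 3))
  gains <- logical(12); vDH <- numeric(12); vEYT <- numeric(12)
  for (s in seq_len(12)) {
    rep <- runSchema(cfg, map, seed = 3500 + s)$report
    gains[s] <- rep$meanGV[rep$stage == "EYT"] > rep$meanGV[rep$stage == "F0"]
    vDH[s] <- rep$sdGV[rep$stage == "DH"]^2
    vEYT[s] <- rep$sdGV[rep$stage == "EYT"]^2
  }
  expect_gte(mean(gains), 11 / 12)
  expect_lte(median(vEYT), median(vDH))
})

test_that("an optional diallel pre-step regenerates F0 from the parents", {
  map <- makeMap(3, 10, heritability = 0.4, seed = 360)
  cfg <- schemaConfig(founders = 6, f1Crosses = 10, dhPerLine = 3,
                      stageKeep = c(15, 8, 4, 2), f0Diallel = 2)
  res <- runSchema(cfg, map, seed = 361)
  # 6 parents -> 15 pairs x 2 offspring = 30 F0 individuals
  expect_equal(res$report$n[res$report$stage == "F0"], 30)
})

test_that("undersized founder populations are rejected", {
  map <- makeMap(3, 10, heritability = 0.4, seed = 370)
  cfg <- schemaConfig(founders = 10, f1Crosses = 5, dhPerLine = 2,
                      stageKeep = c(8, 4, 2, 1))
  few <- makeFounders(map, 4, seed = 371)
  expect_error(runSchema(cfg, map, founders = few, seed = 372), "10")
})
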