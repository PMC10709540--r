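test_that("selectTop keeps the k best, ties broken by lower original index", {
  map <- tinyMap(perChr = 4)
  set.seed(200)
  pop <- makeFounders(map, 5)
  # scores equal to the original indices: top 2 are the last two individuals
  sel <- selectTop(pop, 2, score = 1:5)
  expect_equal(sel$indices, c(4L, 5L))
  # k = n is the identity (ascending indices restore original order)
  all5 <- selectTop(pop, 5, score = c(3, 1, 2, 5, 4))
  expect_equal(all5$indices, 1:5)
  expect_identical(genome(all5$population), genome(pop))
  # ties: equal scores fall back to lower index
  tied <- selectTop(pop, 2, score = c(1, 2, 2, 2, 1))
  expect_equal(tied$indices, c(2L, 3L))
})

test_that("selectTop agrees with a full-sort oracle for all k", {
  map <- tinyMap(perChr = 3)
  set.seed(201)
  pop <- makeFounders(map, 12)
  for (rep in 1:10) {
    s <- rnorm(12)
    oracle <- order(s, decreasing = TRUE)
    for (k in c(1, 3, 7, 12)) {
      sel <- selectTop(pop, k, score = s)
      expect_setequal(sel$indices, oracle[seq_len(k)])
    }
  }
})

test_that("selectTop validates its arguments", {
  map <- tinyMap(perChr = 3)
  set.seed(202)
  pop <- makeFounders(map, 4)
  expect_error(selectTop(pop, 5, score = 1:4), "k must lie")
  expect_error(selectTop(pop, 0, score = 1:4), "k must lie")
  expect_error(selectTop(pop, 2, score = c(1, NA, 3, 4)), "individual\\(s\\): 2")
  expect_error(selectTop(pop, 2, score = 1:3), "3 values for 4")
})

test_that("GEBV scoring forms a linear trait index", {
  map <- tinyMap(perChr = 5, nTraits = 1)
  set.seed(203)
  pop <- makeFounders(map, 6)
  expect_equal(scoreGEBV(pop, map), unname(gebv(pop, map)[, 1]))
  # duplicated trait with unit weights doubles the single-trait score
  map2 <- GeneticMap(chromosomes(map), positions = mapPositions(map),
                     effects = rbind(markerEffects(map), markerEffects(map)),
                     traitNames = c("A", "B"))
  expect_equal(scoreGEBV(pop, map2, traitWeights = c(1, 1)),
               2 * scoreGEBV(pop, map))
  # brute-force weighted-sum oracle
  w <- c(0.3, 0.7)
  expect_equal(scoreGEBV(pop, map2, traitWeights = w),
               unname(gebv(pop, map2) %*% w)[, 1])
})

test_that("selection by GEBV increases the mean GEBV (selection differential)", {
  map <- tinyMap(perChr = 8)
  set.seed(204)
  pop <- makeFounders(map, 40)
  sel <- selectTop(pop, 10, scoreGEBV, map = map)
  expect_gt(mean(gebv(sel$population, map)), mean(gebv(pop, map)))
})

test_that("OHV equals GEBV on homozygotes and dominates it pointwise", {
  map <- tinyMap(perChr = 6, nChr = 3)
  set.seed(205)
  hom <- makeFounders(map, 8, inbred = TRUE)
  expect_equal(scoreOHV(hom, map), scoreGEBV(hom, map), tolerance = 1e-12)
  het <- makeFounders(map, 20)
  expect_true(all(scoreOHV(het, map) >= scoreGEBV(het, map) - 1e-12))
})

test_that("OHV matches exhaustive haplotype enumeration per segment", {
  # oracle: the best doubled haploid picks one haplotype per chromosome;
  # enumerate all 2^C combinations and take the best DH breeding value
  for (rep in 1:10) {
    map <- makeMap(3, 5, seed = 210 + rep)
    pop <- makeFounders(map, 6, seed = 220 + rep)
    eff <- markerEffects(map)[1, ]
    chr <- chromosomes(map)
    combos <- as.matrix(expand.grid(1:2, 1:2, 1:2))
    oracle <- sapply(seq_len(6), function(i) {
      vals <- apply(combos, 1, function(cho) {
        hap <- numeric(nMarkers(map))
        for (c in 1:3) {
          idx <- which(chr == unique(chr)[c])
          hap[idx] <- genome(pop)[i, idx, cho[c]]
        }
        2 * sum(eff * hap)   # DH duplicates the gamete
      })
      max(vals)
    })
    expect_equal(scoreOHV(pop, map), oracle, tolerance = 1e-12,
                 label = sprintf("OHV oracle, instance %d", rep))
  }
})

test_that("finer OHV segmentation can only increase the score", {
  map <- makeMap(2, 10, seed = 230)
  pop <- makeFounders(map, 15, seed = 231)
  perChrom <- scoreOHV(pop, map)
  perBlock <- scoreOHV(pop, map, blockSize = 2)
  perMarker <- scoreOHV(pop, map, segments = seq_len(nMarkers(map)))
  expect_true(all(perBlock >= perChrom - 1e-12))
  expect_true(all(perMarker >= perBlock - 1e-12))
})

test_that("phenotype scoring at h2 = 1 ranks exactly like the GEBV", {
  map <- tinyMap(perChr = 6)
  set.seed(240)
  pop <- makeFounders(map, 25)
  s <- scorePhenotype(pop, map, nEnvs = 1, h2 = 1, seed = 241)
  expect_equal(order(s), order(scoreGEBV(pop, map)))
  expect_identical(scorePhenotype(pop, map, nEnvs = 2, h2 = 0.5, seed = 242),
                   scorePhenotype(pop, map, nEnvs = 2, h2 = 0.5, seed = 242))
})

test_that("selection accuracy grows with heritability", {
  map <- makeMap(5, 30, seed = 250)
  pop <- makeFounders(map, 1000, seed = 251)
  G <- scoreGEBV(pop, map)
  acc <- sapply(c(0.1, 0.4, 0.9), function(h2)
    cor(scorePhenotype(pop, map, nEnvs = 1, h2 = h2, seed = 252), G))
  expect_true(all(diff(acc) > 0))
  expect_gt(acc[3], 0.9)
})
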