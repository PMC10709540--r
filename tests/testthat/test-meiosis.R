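test_that("a fully homozygous parent yields its haplotype regardless of mask", {
  map <- tinyMap(perChr = 6, nChr = 2)
  h <- rep(c(0L, 1L), 6)
  pop <- popFromHaplotypes(h, h)
  for (s in 1:3)
    expect_identical(sampleGamete(pop, 1, map, seed = s), h)
})

test_that("with zero recombination a gamete is one intact parental haplotype", {
  map <- zeroRecombMap(m = 10)
  pop <- popFromHaplotypes(rep(0L, 10), rep(1L, 10))
  for (s in 1:10) {
    g <- sampleGamete(pop, 1, map, seed = s)
    expect_true(all(g == 0L) || all(g == 1L))
  }
})

test_that("cross returns (k, m, 2) offspring whose alleles come from the parents", {
  map <- tinyMap(perChr = 8, nChr = 3)
  set.seed(21)
  pop <- makeFounders(map, 6)
  plan <- cbind(c(1, 2, 5, 6), c(4, 3, 6, 1))
  off <- cross(pop, plan, map, seed = 22)
  expect_equal(dim(genome(off)), c(4L, 24L, 2L))
  for (i in seq_len(nrow(plan))) for (h in 1:2) {
    par <- genome(pop)[plan[i, h], , ]
    allele <- genome(off)[i, , h]
    expect_true(all(allele == par[, 1] | allele == par[, 2]),
                label = sprintf("offspring %d haplotype %d provenance", i, h))
  }
})

test_that("homozygous-reference parents give all-zero offspring", {
  map <- tinyMap(perChr = 5)
  pop <- Population(array(0L, c(2, 15, 2)))
  off <- cross(pop, cbind(1, 2), map, seed = 1)
  expect_true(all(genome(off) == 0L))
})

test_that("out-of-range plan indices raise an error naming the pair", {
  map <- tinyMap(perChr = 5)
  pop <- Population(array(0L, c(3, 15, 2)))
  expect_error(cross(pop, cbind(1, 9), map), "pair 1 \\(1, 9\\)")
})

test_that("selfing a fully heterozygous parent segregates ~1:2:1", {
  map <- zeroRecombMap(m = 1)
  pop <- popFromHaplotypes(0L, 1L)
  nOff <- 4000
  off <- cross(pop, cbind(rep(1, nOff), rep(1, nOff)), map, seed = 33)
  dosage <- genome(off)[, 1, 1] + genome(off)[, 1, 2]
  counts <- tabulate(dosage + 1L, nbins = 3L)
  expected <- nOff * c(0.25, 0.5, 0.25)
  sds <- sqrt(nOff * c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)))
  expect_true(all(abs(counts - expected) <= 4 * sds))
})

test_that("identical seeds reproduce identical offspring arrays", {
  map <- tinyMap(perChr = 10)
  set.seed(41)
  pop <- makeFounders(map, 8)
  expect_identical(genome(cross(pop, cbind(1:4, 5:8), map, seed = 7)),
                   genome(cross(pop, cbind(1:4, 5:8), map, seed = 7)))
  expect_identical(genome(randomCrosses(pop, 20, map, seed = 7)),
                   genome(randomCrosses(pop, 20, map, seed = 7)))
  expect_identical(doubleHaploid(pop, 3, map, seed = 7),
                   doubleHaploid(pop, 3, map, seed = 7))
})

test_that("randomCrosses draws distinct biparental pairs of the right count", {
  map <- tinyMap(perChr = 4)
  # one all-0 and one all-1 founder: any truly biparental offspring has
  # dosage exactly 1 everywhere; a self would be homozygous at every marker
  g <- array(0L, c(2, 12, 2)); g[2, , ] <- 1L
  pop <- Population(g)
  off <- randomCrosses(pop, 50, map, seed = 5)
  expect_equal(dim(genome(off)), c(50L, 12L, 2L))
  dosage <- genome(off)[, , 1] + genome(off)[, , 2]
  expect_true(all(dosage == 1L))
  expect_equal(nIndividuals(randomCrosses(pop, 0, map, seed = 1)), 0L)
  expect_error(randomCrosses(pop[1], 3, map), "at least 2")
})

test_that("diallel offspring counts match C(n,2) * offspring for n <= 30", {
  for (n in c(2, 3, 5, 10, 17, 30)) {
    plan <- diallelPlan(n)
    # brute-force enumeration of unordered distinct pairs
    brute <- 0L
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i < j) brute <- brute + 1L
    expect_equal(nrow(plan), brute)
    expect_true(all(plan[, 1] < plan[, 2]))
    expect_equal(anyDuplicated(paste(plan[, 1], plan[, 2])), 0L)
  }
  map <- tinyMap(perChr = 3)
  set.seed(6)
  pop <- makeFounders(map, 5)
  off <- diallel(pop, 4, map, seed = 8)
  expect_equal(nIndividuals(off), 5 * 4 / 2 * 4)
  expect_error(diallel(pop[1], 2, map), "at least 2")
})

test_that("doubled haploids have shape (n, dh, m, d) and are fully homozygous", {
  map <- tinyMap(perChr = 6, nChr = 2)
  set.seed(51)
  pop <- makeFounders(map, 4)
  dh <- doubleHaploid(pop, 5, map, seed = 52)
  expect_equal(dim(dh), c(4L, 5L, 12L, 2L))
  expect_identical(dh[, , , 1], dh[, , , 2])
  flat <- dhToPopulation(dh)
  expect_equal(nIndividuals(flat), 20L)
  expect_identical(genome(flat)[7, , 1], dh[2, 2, , 1])  # line-major order
  expect_error(doubleHaploid(pop, 0, map), ">= 1")
})

test_that("DH lines of a homozygous individual are identical to it", {
  map <- tinyMap(perChr = 6)
  set.seed(53)
  pop <- makeFounders(map, 2, inbred = TRUE)
  dh <- doubleHaploid(pop, 3, map, seed = 54)
  for (l in 1:3)
    expect_identical(dh[1, l, , 1], genome(pop)[1, , 1])
})

test_that("empirical recombinant fractions recover every interval probability", {
  map <- makeMap(2, 6, chrLength = 120, spacing = "random", seed = 61)
  n <- 10000
  masks <- recombinationMasks(map, n, seed = 62)
  r <- recombProb(map)
  for (j in which(!is.na(r))) {
    frac <- mean(masks[, j] != masks[, j + 1])
    tol <- 4 * sqrt(r[j] * (1 - r[j]) / n) + 1e-9
    expect_lt(abs(frac - r[j]), max(tol, 0.004),
              label = sprintf("interval %d (r = %.4f)", j, r[j]))
  }
})

test_that("masks on different chromosomes are independent", {
  map <- tinyMap(perChr = 5, nChr = 2)
  masks <- recombinationMasks(map, 5000, seed = 63)
  # first marker of chr1 vs first marker of chr2
  tb <- table(masks[, 1], masks[, 6])
  p <- suppressWarnings(chisq.test(tb)$p.value)
  expect_gt(p, 1e-3)
  # uniform start at each chromosome
  expect_lt(abs(mean(masks[, 1]) - 0.5), 4 * sqrt(0.25 / 5000))
  expect_lt(abs(mean(masks[, 6]) - 0.5), 4 * sqrt(0.25 / 5000))
})
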