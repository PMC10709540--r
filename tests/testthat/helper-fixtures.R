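# shared in-code fixtures

# tiny deterministic map: 3 chromosomes x `perChr` markers, 100 cM each
tinyMap <- function(perChr = 10, nChr = 3, nTraits = 1, h2 = NULL, seed = 11) {
  makeMap(nChr, perChr, chrLength = 100, nTraits = nTraits,
          heritability = h2, seed = seed)
}

# map whose intervals never recombine (single chromosome unless nChr given)
zeroRecombMap <- function(m = 8, nChr = 1, seed = 12) {
  chromosome <- rep(paste0("chr", seq_len(nChr)), each = m %/% nChr)
  GeneticMap(chromosome, recomb = rep(0, length(chromosome)),
             effects = matrix(rnorm(length(chromosome)), 1))
}

# population holding explicit haplotypes for one individual
popFromHaplotypes <- function(h1, h2) {
  g <- array(0L, c(1L, length(h1), 2L))
  g[1, , 1] <- h1
  g[1, , 2] <- h2
  Population(g)
}

# probability of an odd Poisson(lambda) count, truncated series (oracle for
# the Haldane mapping function)
poissonOddProb <- function(lambda, tol = 1e-12) {
  j <- 1; term <- exp(-lambda) * lambda; acc <- 0
  while (term > tol || j < 3) {
    if (j %% 2 == 1) acc <- acc + term
    j <- j + 1
    term <- term * lambda / j
    if (j > 500) break
  }
  acc
}
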