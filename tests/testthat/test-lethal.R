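triple <- function(pAA, pAa, paa) c(pAA, pAa, paa)

test_that("pair mortality matches the worked identities", {
  expect_equal(pair_mortality(triple(1, 0, 0), triple(1, 0, 0)), 0)
  expect_equal(pair_mortality(triple(0, 1, 0), triple(0, 1, 0)), 0.25)
  two <- rbind(triple(0, 1, 0), triple(0, 1, 0))
  expect_equal(pair_mortality(two, two), 1 - (3 / 4)^2)   # = 0.4375
  p <- triple(1 / 3, 2 / 3, 0)
  expect_equal(pair_mortality(p, p), 1 / 9)
})

test_that("pair mortality equals brute-force offspring enumeration", {
  set.seed(99)
  for (rep in 1:25) {
    L <- sample(1:5, 1)
    rand_triples <- function() {
      x <- matrix(stats::rexp(3 * L), L, 3)
      x / rowSums(x)
    }
    ps <- rand_triples()
    pd <- rand_triples()
    expect_lt(abs(pair_mortality(ps, pd) - oracle_pair_mortality(ps, pd)),
              1e-12)
  }
})

test_that("lethal_g averages pair mortality over the list", {
  # 100 matings, one known Aa x Aa pair at a single locus, rest clean
  geno_s <- matrix(0L, 3, 1)
  geno_s[1, 1] <- 1L
  geno_d <- matrix(0L, 100, 1)
  geno_d[1, 1] <- 1L
  ctx_geno <- rbind(geno_s, geno_d)
  rownames(ctx_geno) <- c(paste0("S", 1:3), paste0("D", 1:100))
  colnames(ctx_geno) <- "L1"
  probs <- genotype_point_probs(ctx_geno)
  matings <- data.frame(sire = rep(paste0("S", 1:3), length.out = 100)[
                          order(rep(1:3, length.out = 100))],
                        dam = paste0("D", 1:100))
  matings$sire <- c("S1", rep(c("S2", "S3"), length.out = 99))
  expect_equal(lethal_g(matings, probs), 0.25 / 100)   # 0.0025
  # carrier-free list
  clean <- matings
  clean$sire <- "S2"
  expect_equal(lethal_g(clean, probs), 0)
  expect_error(lethal_g(matings[0, ], probs), "empty")
})

test_that("lethal_g with known genotypes matches Monte-Carlo offspring", {
  set.seed(5)
  n <- 100000
  # sire Aa, dam Aa at locus 1; sire Aa, dam AA at locus 2
  gs <- c(1L, 1L)
  gd <- c(1L, 0L)
  geno <- rbind(S = gs, D = gd)
  colnames(geno) <- c("L1", "L2")
  probs <- genotype_point_probs(geno)
  lg <- lethal_g(data.frame(sire = "S", dam = "D"), probs)
  # simulate conceptions without rejection and count any-aa outcomes
  a1 <- stats::rbinom(n, 1, 0.5) & stats::rbinom(n, 1, 0.5)
  a2 <- stats::rbinom(n, 1, 0.5) & FALSE
  mc <- mean(a1 | a2)
  expect_lt(abs(lg - mc), 3 * sqrt(lg * (1 - lg) / n))
})

test_that("lethal_a matches its hand expansion and invariances", {
  # single mating, sire Aa, dam AA, one locus q = 0.1 -> 0.25 * 0.1
  geno <- rbind(S = 1L, D = 0L)
  colnames(geno) <- "L1"
  probs <- genotype_point_probs(geno)
  one <- data.frame(sire = "S", dam = "D")
  expect_equal(lethal_a(one, probs, q = 0.1, freq = "panel"), 0.025)
  # no carriers anywhere
  geno0 <- rbind(S = 0L, D = 0L)
  colnames(geno0) <- "L1"
  expect_equal(lethal_a(one, genotype_point_probs(geno0), q = 0.1,
                        freq = "panel"), 0)
  # doubling q strictly increases lethal_a when transmission is positive
  l1 <- lethal_a(one, probs, q = 0.1, freq = "panel")
  l2 <- lethal_a(one, probs, q = 0.2, freq = "panel")
  expect_gt(l2, l1)
  # invariant to permuting dam assignments among fully genotyped parents
  set.seed(12)
  L <- 4
  geno_m <- matrix(stats::rbinom(8 * L, 1, 0.4), 8, L)
  rownames(geno_m) <- c(paste0("S", 1:4), paste0("D", 1:4))
  colnames(geno_m) <- paste0("L", 1:L)
  pm <- genotype_point_probs(geno_m)
  ml <- data.frame(sire = paste0("S", 1:4), dam = paste0("D", 1:4))
  ml_perm <- data.frame(sire = paste0("S", 1:4), dam = paste0("D", c(3, 1, 4, 2)))
  q <- rep(0.1, L)
  expect_equal(lethal_a(ml, pm, q, freq = "panel", survivor_condition = FALSE),
               lethal_a(ml_perm, pm, q, freq = "panel",
                        survivor_condition = FALSE))
})

test_that("genetic load score follows the weighted q-squared formula", {
  # one sire Aa at a single locus q = 0.1, 50 of 100 matings -> 0.005
  geno <- rbind(S1 = 1L, S2 = 0L)
  colnames(geno) <- "L1"
  probs <- genotype_point_probs(geno)
  ml <- data.frame(sire = c(rep("S1", 50), rep("S2", 50)))
  expect_equal(genetic_load_score(ml, probs, q = 0.1), 50 * 0.01 / 100)
  # all 100 matings to one sire Aa at two loci q = 0.1 and 0.2 -> 0.05
  geno2 <- rbind(S1 = c(1L, 1L), S2 = c(0L, 0L))
  colnames(geno2) <- c("L1", "L2")
  probs2 <- genotype_point_probs(geno2)
  ml2 <- data.frame(sire = rep("S1", 100))
  expect_equal(genetic_load_score(ml2, probs2, q = c(0.1, 0.2)),
               100 * (0.01 + 0.04) / 100)
  # no carrier sires
  ml3 <- data.frame(sire = rep("S2", 100))
  expect_equal(genetic_load_score(ml3, probs2, q = c(0.1, 0.2)), 0)
  # linear in n_s and in q^2
  g1 <- genetic_load_score(ml, probs, q = 0.1)
  ml_25 <- data.frame(sire = c(rep("S1", 25), rep("S2", 75)))
  expect_equal(genetic_load_score(ml_25, probs, q = 0.1), g1 / 2)
  expect_equal(genetic_load_score(ml, probs, q = 0.2), g1 * 4)
})
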