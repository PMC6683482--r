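test_that("genotyping schemes are nested uniform random subsets", {
  ped <- generate_pedigree(60, 20, 20, 3, seed = 1)
  sch <- assign_genotyping(ped, tiers = c(0, 10, 20, 100), seed = 2)
  s0 <- sch$sets[["0"]]
  s10 <- sch$sets[["10"]]
  s20 <- sch$sets[["20"]]
  s100 <- sch$sets[["100"]]
  expect_equal(sum(s0), 0)
  expect_equal(sum(s10), 10)
  expect_equal(sum(s20), 20)
  expect_true(all(s100))
  expect_true(all(names(s10)[s10] %in% names(s20)[s20]))   # nesting
  expect_identical(assign_genotyping(ped, c(0, 10, 20, 100), seed = 2)$sets,
                   sch$sets)
  expect_false(identical(assign_genotyping(ped, 10, seed = 3)$sets[["10"]],
                         s10))
})

test_that("posterior genotype probabilities match textbook cases", {
  trio <- build_pedigree(ped_df(c("S", "D", "C"), c("0", "0", "S"),
                                c("0", "0", "D"), c("M", "F", "F")))
  # isolated ungenotyped founder: HWE prior at q = 0.1
  pr <- genotype_probabilities(trio, c(NA, NA, NA), 0.1, method = "exact")
  expect_equal(unname(pr["S", 1, ]), c(0.81, 0.18, 0.01))
  # offspring of observed Aa x Aa
  pr2 <- genotype_probabilities(trio, c(1L, 1L, NA), 0.1, method = "exact")
  expect_equal(unname(pr2["C", 1, ]), c(0.25, 0.5, 0.25))
  # ungenotyped parent with an observed aa offspring: P propto HWE(g) t(g)
  pr3 <- genotype_probabilities(trio, c(NA, NA, 2L), 0.1, method = "exact")
  expect_equal(unname(pr3["S", 1, ]), c(0, 0.09, 0.01) / 0.1)
  expect_equal(unname(pr3["C", 1, ]), c(0, 0, 1))
  # everyone genotyped: point masses reproduced
  pr4 <- genotype_probabilities(trio, c(0L, 1L, 1L), 0.1, method = "exact")
  expect_equal(unname(pr4[cbind(1:3, 1, c(1, 2, 2))]), rep(1, 3))
  # triples always sum to 1
  expect_lt(max(abs(apply(pr3, c(1, 2), sum) - 1)), 1e-9)
})

test_that("exact inference equals exhaustive enumeration, loops included", {
  n_match <- 0
  for (seed in 1:20) {
    n <- sample(4:9, 1)
    ped <- random_small_pedigree(n, seed = 300 + seed)
    q <- stats::runif(1, 0.05, 0.3)
    # observe a random subset (drawn from HWE, may be locally implausible
    # but always honest: genotypes come from a gene drop)
    pool <- list(H1 = matrix(stats::rbinom(40 * 1, 1, q), 40, 1),
                 H2 = matrix(0L, 40, 1), loci = "L1", freq = q)
    class(pool) <- "lof_founder_pool"
    geno <- drop_genotypes(ped, pool, seed = seed)
    obs <- geno[, 1]
    obs[sample(n, ceiling(n / 2))] <- NA
    got <- genotype_probabilities(ped, obs, q, method = "exact")
    want <- oracle_genotype_posterior(ped, obs, q)
    tv <- max(rowSums(abs(got[, 1, ] - want)) / 2)
    expect_lt(tv, 1e-6)
    n_match <- n_match + 1
  }
  expect_equal(n_match, 20)
})

test_that("iterative peeling is exact on loop-free pedigrees", {
  # chains/trees: founders plus non-inbred descent
  for (seed in 1:8) {
    set.seed(400 + seed)
    n <- 8
    # a tree: each non-founder gets a fresh unknown mate side
    ids <- paste0("X", 1:n)
    sire <- dam <- rep("0", n)
    sex <- c("M", "F", sample(c("M", "F"), n - 2, replace = TRUE))
    for (i in 3:n) {
      p <- sample(seq_len(i - 1), 1)   # single known parent -> tree
      if (sex[p] == "M") sire[i] <- ids[p] else dam[i] <- ids[p]
    }
    ped <- build_pedigree(ped_df(ids, sire, dam, sex))
    q <- 0.15
    obs <- rep(NA_integer_, n)
    obs[sample(n, 3)] <- stats::rbinom(3, 1, 0.4)
    exact <- genotype_probabilities(ped, obs, q, method = "exact")
    loopy <- genotype_probabilities(ped, obs, q, method = "loopy")
    expect_lt(max(abs(exact - loopy)), 1e-6)
  }
})

test_that("extra genotyping reduces expected posterior entropy (exact)", {
  # conditioning cannot raise entropy in expectation: for an extra genotyped
  # animal j, sum_g P(g_j | obs) H(posterior | obs, g_j) <= H(posterior | obs)
  entropy <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  trio <- build_pedigree(ped_df(c("S", "D", "C1", "C2"),
                                c("0", "0", "S", "S"),
                                c("0", "0", "D", "D"), c("M", "F", "F", "F")))
  q <- 0.2
  obs <- c(NA, NA, 1L, NA)
  base <- genotype_probabilities(trio, obs, q, method = "exact")
  h_base <- entropy(base["S", 1, ])
  p_c2 <- base["C2", 1, ]
  h_cond <- 0
  for (g in 0:2) {
    if (p_c2[g + 1] == 0) next
    obs_g <- obs
    obs_g[4] <- g
    post <- genotype_probabilities(trio, obs_g, q, method = "exact")
    h_cond <- h_cond + p_c2[g + 1] * entropy(post["S", 1, ])
  }
  expect_lte(h_cond, h_base + 1e-12)
})

test_that("Mendelian inconsistencies are reported with the trio", {
  trio <- build_pedigree(ped_df(c("S", "D", "C"), c("0", "0", "S"),
                                c("0", "0", "D"), c("M", "F", "F")))
  expect_error(genotype_probabilities(trio, c(0L, 0L, 2L), 0.1,
                                      method = "exact"),
               "Mendelian inconsistency.*S.*D.*C")
  expect_error(genotype_probabilities(trio, c(0L, 0L, 2L), 0.1,
                                      method = "loopy"),
               "Mendelian inconsistency.*S.*D.*C")
})

test_that("survivor conditioning zeroes aa for ungenotyped animals", {
  trio <- build_pedigree(ped_df(c("S", "D", "C"), c("0", "0", "S"),
                                c("0", "0", "D"), c("M", "F", "F")))
  pr <- genotype_probabilities(trio, c(1L, 1L, NA), 0.1, method = "exact",
                               condition_alive = TRUE)
  expect_equal(unname(pr["C", 1, ]), c(1 / 3, 2 / 3, 0))
})
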