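# a 2-sire x 6-dam instance with one carrier sire and carrier dams; a
# zero-mortality assignment exists (carriers can be paired with non-carriers)
small_instance <- function(w_a = 0, w_g = 0, n_matings = 4) {
  make_context(
    n_s = 2, n_d = 6,
    m_s = c(2, 1), m_d = c(1.5, 1.2, 1.0, 0.8, 0.5, 0.1),
    geno_s = rbind(c(1L, 0L), c(0L, 0L)),
    geno_d = rbind(c(1L, 0L), c(1L, 0L), c(0L, 0L), c(0L, 0L),
                   c(0L, 1L), c(0L, 0L)),
    q = c(0.1, 0.05), n_matings = n_matings, max_per_sire = 3,
    w_a = w_a, w_g = w_g)
}

test_that("evaluate_matings computes the penalized objective components", {
  ctx <- small_instance()
  ev <- evaluate_matings(ctx, sidx = c(1, 1, 2, 2), didx = c(1, 2, 3, 4))
  # with w_a = w_g = 0 the objective is the mean progeny index
  expect_equal(ev$objective, ev$mean_index)
  expect_equal(ev$mean_index, (2 + 2 + 1 + 1 + 1.5 + 1.2 + 1 + 0.8) / 8)
  # infeasible lists are rejected
  expect_error(evaluate_matings(ctx, c(1, 1, 1, 1), c(1, 2, 3, 4)),
               "infeasible")
  expect_error(evaluate_matings(ctx, c(1, 1, 2, 2), c(1, 1, 3, 4)),
               "infeasible")
  # direct arithmetic: mean index 100, lethal_g penalty w_g * 200 * lG
  ctx2 <- make_context(1, 1, 100, 100, rbind(1L), rbind(1L), q = 0.1,
                       n_matings = 1, max_per_sire = 1, w_g = 1)
  ev2 <- evaluate_matings(ctx2, 1, 1)
  expect_equal(ev2$lethalG, 0.25)
  expect_equal(ev2$objective, 100 - 1 * 200 * 0.25)
})

test_that("a clean population makes all weightings equivalent", {
  g0 <- matrix(0L, 8, 2)
  for (w in c(0, 1, 100)) {
    ctx <- make_context(2, 6, c(2, 1), c(1.5, 1.2, 1, 0.8, 0.5, 0.1),
                        g0[1:2, ], g0[3:8, ], q = c(0.1, 0.05),
                        n_matings = 4, max_per_sire = 3, w_g = w)
    ev <- evaluate_matings(ctx, c(1, 1, 2, 2), c(1, 2, 3, 4))
    expect_equal(ev$objective, ev$mean_index)
  }
})

test_that("the evolutionary search finds the enumerated optimum", {
  for (inst in 1:4) {
    w_g <- c(0, 0, 1, 10)[inst]
    w_a <- c(0, 0.5, 0, 0)[inst]
    ctx <- small_instance(w_a = w_a, w_g = w_g)
    best <- enumerate_best_list(ctx)
    sol <- ea_optimize(ctx, seed = inst, pop = 32, max_gen = 200,
                       stall_gen = 50)
    expect_equal(sol$eval$penalized, best$eval$penalized, tolerance = 1e-10)
  }
  # determinism
  ctx <- small_instance(w_g = 1)
  s1 <- ea_optimize(ctx, seed = 42, pop = 24, max_gen = 100, stall_gen = 30)
  s2 <- ea_optimize(ctx, seed = 42, pop = 24, max_gen = 100, stall_gen = 30)
  expect_identical(s1$sidx, s2$sidx)
  expect_identical(s1$didx, s2$didx)
})

test_that("elitism makes the best objective non-decreasing", {
  ctx <- small_instance(w_g = 1)
  sol <- ea_optimize(ctx, seed = 3, pop = 16, max_gen = 120, stall_gen = 120)
  expect_true(all(diff(sol$trace) >= 0))
})

test_that("returned lists always satisfy the feasibility invariants", {
  set.seed(77)
  for (rep in 1:6) {
    n_s <- sample(2:4, 1)
    n_d <- sample(5:8, 1)
    N <- sample(3:min(6, n_d), 1)
    cap <- sample(2:4, 1)
    if (N > n_s * cap) next
    L <- 2
    ctx <- make_context(
      n_s, n_d, stats::rnorm(n_s), stats::rnorm(n_d),
      matrix(stats::rbinom(n_s * L, 1, 0.3), n_s, L),
      matrix(stats::rbinom(n_d * L, 1, 0.3), n_d, L),
      q = c(0.1, 0.1), n_matings = N, max_per_sire = cap,
      w_g = stats::runif(1, 0, 2))
    sol <- ea_optimize(ctx, seed = rep, pop = 16, max_gen = 60,
                       stall_gen = 20)
    expect_false(anyDuplicated(sol$didx) > 0)
    expect_true(all(tabulate(sol$sidx, n_s) <= cap))
    expect_length(sol$sidx, N)
  }
})

test_that("a heavy LethalG weighting finds a zero-mortality assignment", {
  ctx <- small_instance(w_g = 100)
  sol <- ea_optimize(ctx, seed = 9, pop = 32, max_gen = 200, stall_gen = 60)
  expect_equal(sol$eval$lethalG, 0)
})

test_that("frontier endpoints and angles behave as the axes require", {
  # two unrelated sire families, one clearly better: the max-index endpoint
  # uses only the top family; the min-coancestry endpoint spreads usage
  ped <- build_pedigree(ped_df(
    c("FS1", "FD1", "FS2", "FD2",
      "S1", "S2", "S3", "S4", paste0("D", 1:6)),
    c(rep("0", 4), "FS1", "FS1", "FS2", "FS2", rep("0", 6)),
    c(rep("0", 4), "FD1", "FD1", "FD2", "FD2", rep("0", 6)),
    c("M", "F", "M", "F", rep("M", 4), rep("F", 6)),
    c(rep("ancestor", 4), rep("candidate", 10))))
  kin <- kinship_matrix(ped)
  m <- stats::setNames(
    c(0, 0, 0, 0, 5, 5, 1, 1, rep(1, 6)),
    c("FS1", "FD1", "FS2", "FD2", "S1", "S2", "S3", "S4", paste0("D", 1:6)))
  m <- m[ped$id]
  geno <- matrix(0L, nrow(ped), 1, dimnames = list(ped$id, "L1"))
  probs <- genotype_point_probs(geno)
  ctx <- mating_context(ped, kin, m, probs, 0.1, n_matings = 4,
                        max_per_sire = 2)
  fr <- frontier_endpoints(ctx, seed = 1, pop = 32, max_gen = 150,
                           stall_gen = 40)
  top_sires <- unique(ctx$sires[fr$max_index$sidx])
  expect_true(all(top_sires %in% c("S1", "S2")))
  minc_sires <- unique(ctx$sires[fr$min_coancestry$sidx])
  expect_equal(sort(minc_sires), c("S1", "S2", "S3", "S4"))
  expect_lt(fr$min_coancestry$eval$coancestry,
            fr$max_index$eval$coancestry)
  # angle endpoints
  expect_equal(frontier_angle(fr, fr$max_index$eval), 0)
  expect_equal(frontier_angle(fr, fr$min_coancestry$eval), 90)
  # translation invariance of the endpoint solutions
  m2 <- m + 100
  ctx2 <- mating_context(ped, kin, m2, probs, 0.1, n_matings = 4,
                         max_per_sire = 2)
  fr2 <- frontier_endpoints(ctx2, seed = 1, pop = 32, max_gen = 150,
                            stall_gen = 40)
  expect_identical(sort(unique(ctx2$sires[fr2$max_index$sidx])),
                   sort(top_sires))
})

test_that("solve_at_degrees hits the target-angle endpoints", {
  ctx <- small_instance()
  s0 <- solve_at_degrees(ctx, theta = 0, seed = 5, pop = 24, max_gen = 120,
                         stall_gen = 40)
  expect_equal(s0$angle, 0, tolerance = 1e-9)
  expect_true(s0$converged)
  # theta = 0 is the exhaustive index optimum
  best <- enumerate_best_list(ctx)
  expect_equal(s0$eval$mean_index, best$eval$mean_index, tolerance = 1e-10)
  s90 <- solve_at_degrees(ctx, theta = 90, seed = 5, pop = 24, max_gen = 120,
                          stall_gen = 40)
  expect_equal(s90$angle, 90, tolerance = 1e-6)
  expect_lte(s90$eval$coancestry, s0$eval$coancestry + 1e-12)
})
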