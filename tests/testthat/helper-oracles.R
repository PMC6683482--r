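# Independent oracles and fixture builders used across the suite.
# Every oracle is a brute-force computation that shares no code path with
# the package implementation it checks.

round_cents_for_test <- function(x) round(x, 2)

ped_df <- function(id, sire, dam, sex, role = "ancestor") {
  data.frame(id = id, sire = sire, dam = dam, sex = sex, role = role,
             stringsAsFactors = FALSE)
}

# A random small pedigree (possibly looped): founders first, then animals
# whose parents are drawn from earlier animals (or unknown with prob 0.2).
random_small_pedigree <- function(n, seed, p_unknown = 0.2) {
  set.seed(seed)
  sex <- c("M", "F", sample(c("M", "F"), n - 2, replace = TRUE))
  sire <- dam <- rep("0", n)
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) && stats::runif(1) > p_unknown)
      sire[i] <- paste0("X", males[sample.int(length(males), 1)])
    if (length(females) && stats::runif(1) > p_unknown)
      dam[i] <- paste0("X", females[sample.int(length(females), 1)])
  }
  build_pedigree(ped_df(paste0("X", 1:n), sire, dam, sex))
}

# Exact kinship by exhaustive gamete enumeration: label founder alleles
# uniquely, enumerate all 4^(n_nonfounders) equally likely segregation
# outcomes, and average the probability that random alleles drawn from two
# animals are identical by descent. Feasible for <= ~7 non-founders.
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  nonf <- which(!(is.na(ped$sire_row) & is.na(ped$dam_row)))
  stopifnot(length(nonf) <= 7)
  # allele ids: founders (and unknown parent sides) get fresh labels
  a1 <- a2 <- integer(n)
  next_allele <- 0L
  fresh <- function() {
    next_allele <<- next_allele + 1L
    next_allele
  }
  for (i in seq_len(n)) {
    if (is.na(ped$sire_row[i]) && is.na(ped$dam_row[i])) {
      a1[i] <- fresh()
      a2[i] <- fresh()
    }
  }
  # unknown single parents contribute a fresh allele per animal
  K <- matrix(0, n, n)
  n_out <- 4^length(nonf)
  for (code in seq_len(n_out) - 1L) {
    b1 <- a1
    b2 <- a2
    c_rem <- code
    extra <- next_allele
    for (i in nonf) {
      pick <- c_rem %% 4L          # 2 bits: gamete choice from sire and dam
      c_rem <- c_rem %/% 4L
      s <- ped$sire_row[i]
      d <- ped$dam_row[i]
      b1[i] <- if (is.na(s)) {
        extra <- extra + 1L
        extra
      } else if (pick %% 2L == 0L) b1[s] else b2[s]
      b2[i] <- if (is.na(d)) {
        extra <- extra + 1L
        extra
      } else if (pick %/% 2L == 0L) b1[d] else b2[d]
    }
    for (i in seq_len(n)) for (j in i:n) {
      p <- ((b1[i] == b1[j]) + (b1[i] == b2[j]) +
            (b2[i] == b1[j]) + (b2[i] == b2[j])) / 4
      K[i, j] <- K[i, j] + p
      if (j > i) K[j, i] <- K[j, i] + p
    }
  }
  K / n_out
}

# Exhaustive genotype posterior: sum over all 3^n genotype configurations of
# founder HWE priors x Mendelian transmission x evidence.
oracle_genotype_posterior <- function(ped, obs, q, condition_alive = FALSE) {
  n <- nrow(ped)
  stopifnot(n <= 12)
  n_cfg <- 3^n
  gt <- function(i) ((seq_len(n_cfg) - 1L) %/% 3^(i - 1L)) %% 3L + 1L
  prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  tr <- function(gc, gs, gd) {
    t_of <- c(0, 0.5, 1)
    ts <- t_of[gs]
    td <- t_of[gd]
    paa <- ts * td
    pAa <- ts * (1 - td) + (1 - ts) * td
    cbind(1 - pAa - paa, pAa, paa)[cbind(seq_along(gc), gc)]
  }
  w <- rep(1, n_cfg)
  for (i in seq_len(n)) {
    gi <- gt(i)
    s <- ped$sire_row[i]
    d <- ped$dam_row[i]
    if (is.na(s) && is.na(d)) {
      w <- w * prior[gi]
    } else if (!is.na(s) && !is.na(d)) {
      w <- w * tr(gi, gt(s), gt(d))
    } else {
      # marginalize the unknown parent over HWE
      kp <- gt(if (is.na(s)) d else s)
      wsum <- 0
      for (gu in 1:3) {
        wsum <- wsum + prior[gu] *
          (if (is.na(s)) tr(gi, rep(gu, n_cfg), kp)
           else tr(gi, kp, rep(gu, n_cfg)))
      }
      w <- w * wsum
    }
    if (!is.na(obs[i])) w <- w * (gi == obs[i] + 1L)
    if (condition_alive && is.na(obs[i])) w <- w * (gi != 3L)
  }
  z <- sum(w)
  if (z <= 0) stop("oracle: inconsistent evidence")
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    gi <- gt(i)
    for (g in 1:3) out[i, g] <- sum(w[gi == g]) / z
  }
  out
}

# Brute-force mating mortality: enumerate every multi-locus offspring
# genotype vector and add up the probability of those with >= 1 aa locus.
oracle_pair_mortality <- function(ps, pd) {
  if (is.null(dim(ps))) ps <- matrix(ps, ncol = 3)
  if (is.null(dim(pd))) pd <- matrix(pd, ncol = 3)
  L <- nrow(ps)
  stopifnot(L <= 5)
  t_of <- c(0, 0.5, 1)
  off <- matrix(0, L, 3)   # per-locus offspring genotype distribution
  for (l in seq_len(L)) {
    for (gs in 1:3) for (gd in 1:3) {
      ts <- t_of[gs]
      td <- t_of[gd]
      p <- ps[l, gs] * pd[l, gd]
      off[l, 1] <- off[l, 1] + p * (1 - ts) * (1 - td)
      off[l, 2] <- off[l, 2] + p * (ts * (1 - td) + (1 - ts) * td)
      off[l, 3] <- off[l, 3] + p * ts * td
    }
  }
  cfgs <- expand.grid(rep(list(1:3), L))
  dead <- 0
  for (r in seq_len(nrow(cfgs))) {
    g <- as.integer(cfgs[r, ])
    p <- prod(off[cbind(seq_len(L), g)])
    if (any(g == 3L)) dead <- dead + p
  }
  dead
}

# All feasible mating lists of a small instance (dams distinct, sire caps),
# scored with the package evaluator; returns the best penalized objective.
enumerate_best_list <- function(ctx, lambda = 0) {
  N <- ctx$n_matings
  dam_sets <- utils::combn(ctx$n_d, N)
  n_assign <- ctx$n_s^N
  best <- -Inf
  best_list <- NULL
  for (c_i in seq_len(ncol(dam_sets))) {
    didx <- dam_sets[, c_i]
    for (a in seq_len(n_assign) - 1L) {
      sidx <- integer(N)
      rem <- a
      for (k in seq_len(N)) {
        sidx[k] <- rem %% ctx$n_s + 1L
        rem <- rem %/% ctx$n_s
      }
      if (any(tabulate(sidx, ctx$n_s) > ctx$max_per_sire)) next
      ev <- evaluate_matings(ctx, sidx, didx, lambda)
      if (ev$penalized > best) {
        best <- ev$penalized
        best_list <- list(sidx = sidx, didx = didx, eval = ev)
      }
    }
  }
  best_list
}

# A small fully specified mating context built from explicit inputs.
make_context <- function(n_s, n_d, m_s, m_d, geno_s, geno_d, q,
                         n_matings, max_per_sire, ...) {
  ids_s <- paste0("S", seq_len(n_s))
  ids_d <- paste0("D", seq_len(n_d))
  ped <- build_pedigree(ped_df(
    c(ids_s, ids_d), "0", "0",
    c(rep("M", n_s), rep("F", n_d)), "candidate"))
  kin <- kinship_matrix(ped)
  m <- stats::setNames(c(m_s, m_d), c(ids_s, ids_d))
  geno <- rbind(geno_s, geno_d)
  rownames(geno) <- c(ids_s, ids_d)
  colnames(geno) <- paste0("L", seq_len(ncol(geno)))
  probs <- genotype_point_probs(geno)
  mating_context(ped, kin, m, probs, q, n_matings = n_matings,
                 max_per_sire = max_per_sire, ...)
}
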