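# Genotype states are coded 1 = AA, 2 = Aa, 3 = aa (a = LOF allele).
# Observed genotypes use the 0/1/2 allele-count coding of lof_genotypes.

# P(gamete carries a | parent genotype)
.transmit <- c(0, 0.5, 1)

# Mendelian transmission array TR[child, sire, dam]
mendel_array <- function() {
  TR <- array(0, c(3, 3, 3))
  for (s in 1:3) for (d in 1:3) {
    ts <- .transmit[s]
    td <- .transmit[d]
    TR[1, s, d] <- (1 - ts) * (1 - td)
    TR[2, s, d] <- ts * (1 - td) + (1 - ts) * td
    TR[3, s, d] <- ts * td
  }
  TR
}

hwe_prior <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Nested random genotyping scheme
#'
#' Draws one random permutation of the herd and defines the genotyped subset
#' at tier `t` percent as the first `round(t/100 * n)` animals of that
#' permutation, so subsets are nested: an animal genotyped at one tier stays
#' genotyped at every higher tier, and the lowest tier is a uniform random
#' sample of the herd (both sexes).
#'
#' @param ped a `lof_pedigree`.
#' @param tiers percentages, ascending, in `[0, 100]`.
#' @param seed integer seed.
#' @return class `lof_scheme`: list with `ids` (the permutation) and `sets`,
#'   a named list (one element per tier) of logical vectors over `ped$id`.
#' @export
assign_genotyping <- function(ped, tiers = seq(0, 100, 10), seed = 1) {
  stopifnot(!is.unsorted(tiers), all(tiers >= 0 & tiers <= 100))
  n <- nrow(ped)
  with_seed(seed, {
    perm <- sample(ped$id)
    sets <- lapply(tiers, function(t) {
      k <- round(t / 100 * n)
      stats::setNames(ped$id %in% perm[seq_len(k)], ped$id)
    })
    names(sets) <- as.character(tiers)
    structure(list(ids = perm, tiers = tiers, sets = sets),
              class = "lof_scheme")
  })
}

#' Mask true genotypes by a genotyping scheme
#'
#' @param geno a `lof_genotypes` matrix (0/1/2).
#' @param genotyped logical vector over the rows of `geno` (e.g. one element
#'   of `scheme$sets`).
#' @return matrix like `geno` with `NA` for ungenotyped animals.
#' @export
mask_genotypes <- function(geno, genotyped) {
  out <- unclass(geno)
  out[!genotyped[rownames(geno)], ] <- NA_integer_
  out
}

# ---- exact inference: variable elimination --------------------------------

# factors are lists(vars = integer ids, tab = array of dim rep(3, k))
f_expand <- function(f, vars) {
  k <- length(vars)
  if (length(f$vars) == 0L) return(array(as.numeric(f$tab), rep(3L, k)))
  grid <- as.matrix(expand.grid(rep(list(1:3), k)))
  idx <- grid[, match(f$vars, vars), drop = FALSE]
  array(f$tab[idx], rep(3L, k))
}

f_mult <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  if (length(vars) > 14L)
    stop("factor too large for exact elimination; use method = 'loopy'")
  list(vars = vars, tab = f_expand(f1, vars) * f_expand(f2, vars))
}

f_marg <- function(f, v) {
  p <- match(v, f$vars)
  keep <- seq_along(f$vars)[-p]
  if (!length(keep))
    return(list(vars = integer(0), tab = sum(f$tab)))
  tab <- apply(f$tab, keep, sum)
  list(vars = f$vars[keep], tab = array(tab, rep(3L, length(keep))))
}

# Eliminate all variables except `query` (greedy min-size order).
ve_marginal <- function(factors, query, n_vars) {
  todo <- setdiff(seq_len(n_vars), query)
  for (rep_i in seq_along(todo)) {
    # pick the variable whose elimination gives the smallest joint scope
    scopes <- lapply(todo, function(v) {
      unique(unlist(lapply(factors, function(f) if (v %in% f$vars) f$vars)))
    })
    sizes <- vapply(scopes, length, 1L)
    v <- todo[which.min(sizes)]
    has_v <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (any(has_v)) {
      fv <- Reduce(f_mult, factors[has_v])
      factors <- c(factors[!has_v], list(f_marg(fv, v)))
    }
    todo <- setdiff(todo, v)
  }
  out <- Reduce(f_mult, factors)
  if (length(out$vars) == 0L) return(rep(NA_real_, 3))
  stopifnot(identical(out$vars, query))
  drop(out$tab)
}

# ---- shared model construction --------------------------------------------

# Nuclear families: children grouped by (sire, dam) when both parents are
# known; a child with one unknown parent forms its own family (each unknown
# parent is a distinct unrelated founder, integrated over HWE).
pedigree_families <- function(ped) {
  founder <- is.na(ped$sire_row) & is.na(ped$dam_row)
  kids <- which(!founder)
  key <- ifelse(is.na(ped$sire_row[kids]) | is.na(ped$dam_row[kids]),
                paste0("solo", kids),
                paste0(ped$sire_row[kids], "_", ped$dam_row[kids]))
  fam_groups <- split(kids, key)
  unname(lapply(fam_groups, function(ch) {
    list(s = ped$sire_row[ch[1L]], d = ped$dam_row[ch[1L]], children = ch)
  }))
}

# Build unary potentials and family structure for one locus.
locus_model <- function(ped, obs, q, condition_alive = FALSE) {
  n <- nrow(ped)
  prior <- hwe_prior(q)
  psi <- matrix(1, 3, n)
  founder <- is.na(ped$sire_row) & is.na(ped$dam_row)
  psi[, founder] <- prior
  if (condition_alive) psi[3, is.na(obs)] <- 0
  for (i in which(!is.na(obs))) {
    e <- numeric(3)
    e[obs[i] + 1L] <- 1
    psi[, i] <- psi[, i] * e
  }
  list(n = n, psi = psi, prior = prior, families = pedigree_families(ped))
}

mendelian_error <- function(ped, fam, locus = NULL) {
  nm <- function(i) if (is.na(i)) "<unknown>" else ped$id[i]
  stop("Mendelian inconsistency", if (!is.null(locus)) paste0(" at locus ", locus),
       ": family sire=", nm(fam$s), " dam=", nm(fam$d),
       " children=", paste(ped$id[fam$children], collapse = ","))
}

# quick local feasibility check used to name an offending trio
check_families <- function(ped, model, locus = NULL) {
  TR <- mendel_array()
  for (fam in model$families) {
    ms <- if (is.na(fam$s)) model$prior else model$psi[, fam$s]
    md <- if (is.na(fam$d)) model$prior else model$psi[, fam$d]
    W <- outer(ms > 0, md > 0)
    for (ch in fam$children) {
      z <- apply(TR * model$psi[, ch], c(2, 3), sum)
      W <- W & (z > 0)
    }
    if (!any(W)) mendelian_error(ped, fam, locus)
  }
  invisible(TRUE)
}

exact_locus_probs <- function(ped, model, locus = NULL) {
  TR <- mendel_array()
  factors <- lapply(seq_len(model$n), function(i)
    list(vars = i, tab = model$psi[, i]))
  for (fam in model$families) {
    for (ch in fam$children) {
      if (!is.na(fam$s) && !is.na(fam$d)) {
        factors <- c(factors, list(list(
          vars = c(ch, fam$s, fam$d), tab = aperm(TR, c(1, 2, 3)))))
      } else {
        # duo[c, p] = sum over the unknown parent of HWE prior * TR
        p <- if (is.na(fam$s)) fam$d else fam$s
        duo <- if (is.na(fam$s)) {
          w <- array(rep(rep(model$prior, each = 3), 3), c(3, 3, 3))
          apply(TR * w, c(1, 3), sum)
        } else {
          w <- array(rep(model$prior, each = 9), c(3, 3, 3))
          apply(TR * w, c(1, 2), sum)
        }
        factors <- c(factors, list(list(vars = c(ch, p), tab = duo)))
      }
    }
  }
  out <- matrix(NA_real_, model$n, 3)
  for (i in seq_len(model$n)) {
    m <- ve_marginal(factors, i, model$n)
    s <- sum(m)
    if (!is.finite(s) || s <= 0) {
      check_families(ped, model, locus)
      stop("Mendelian inconsistency",
           if (!is.null(locus)) paste0(" at locus ", locus))
    }
    out[i, ] <- m / s
  }
  out
}

# ---- loopy belief propagation (iterative peeling) -------------------------

# Damped iterative peeling over all loci simultaneously. The factor-graph
# structure (nuclear families) is shared across loci, so messages are stored
# as 3 x L matrices and every update is vectorized over loci. Exact on
# loop-free pedigrees; approximate on looped ones.
#
# observed: n x L matrix of 0/1/2/NA; q: per-locus allele frequency.
# Returns an n x L x 3 array of posteriors.
loopy_all_probs <- function(ped, observed, q, loci, tol = 1e-8,
                            max_iter = 500, damping = 0.5,
                            condition_alive = FALSE) {
  TRm <- matrix(mendel_array(), 3, 9)  # rows = child, cols = (gs, gd) pairs
  n <- nrow(ped)
  L <- ncol(observed)
  prior <- vapply(q, hwe_prior, numeric(3))      # 3 x L
  founder <- is.na(ped$sire_row) & is.na(ped$dam_row)

  # unary potentials psi[[i]]: 3 x L (evidence x founder prior)
  psi <- vector("list", n)
  ones <- matrix(1, 3, L)
  for (i in seq_len(n)) {
    p <- if (founder[i]) prior else ones
    obs_i <- observed[i, ]
    if (condition_alive && anyNA(obs_i)) {
      p <- p + 0            # force a copy before modification
      p[3, is.na(obs_i)] <- 0
    }
    seen <- which(!is.na(obs_i))
    if (length(seen)) {
      e <- matrix(1, 3, L)
      e[, seen] <- 0
      e[cbind(obs_i[seen] + 1L, seen)] <- 1
      p <- p * e
    }
    psi[[i]] <- p
  }

  fams <- pedigree_families(ped)
  nf <- length(fams)

  # upfront family-local consistency check (e.g. an aa child of an AA
  # parent), naming the offending trio; damped messages would otherwise
  # smooth a hard contradiction over without ever producing an exact zero
  idx_gs0 <- rep(1:3, 3)
  idx_gd0 <- rep(1:3, each = 3)
  for (fam in fams) {
    ms <- if (is.na(fam$s)) prior else psi[[fam$s]]
    md <- if (is.na(fam$d)) prior else psi[[fam$d]]
    W <- (ms[idx_gs0, , drop = FALSE] > 0) & (md[idx_gd0, , drop = FALSE] > 0)
    for (ch in fam$children)
      W <- W & (crossprod(matrix(TRm > 0, 3, 9), psi[[ch]] > 0) > 0)
    bad <- which(colSums(W) == 0)
    if (length(bad)) mendelian_error(ped, fam, loci[bad[1L]])
  }

  # single-locus fallback used to name an offending family on inconsistency
  inconsistent <- function(bad_locus, fam = NULL) {
    model <- locus_model(ped, observed[, bad_locus], q[bad_locus],
                         condition_alive)
    check_families(ped, model, loci[bad_locus])
    if (!is.null(fam)) mendelian_error(ped, fam, loci[bad_locus])
    stop("Mendelian inconsistency at locus ", loci[bad_locus])
  }
  normalize <- function(raw, fam = NULL) {
    s <- colSums(raw)
    bad <- which(!is.finite(s) | s <= 0)
    if (length(bad)) inconsistent(bad[1L], fam)
    raw * rep(1 / s, each = 3L)
  }

  if (nf == 0L) {
    out <- array(NA_real_, c(n, L, 3))
    for (i in seq_len(n)) out[i, , ] <- t(normalize(psi[[i]]))
    return(out)
  }

  # incidence: per animal, 2-row matrix of (family, message column);
  # columns per family: 1 = sire, 2 = dam, 2 + j = j-th child
  roles <- vector("list", n)
  for (k in seq_len(nf)) {
    fam <- fams[[k]]
    if (!is.na(fam$s)) roles[[fam$s]] <- cbind(roles[[fam$s]], c(k, 1L))
    if (!is.na(fam$d)) roles[[fam$d]] <- cbind(roles[[fam$d]], c(k, 2L))
    for (j in seq_along(fam$children))
      roles[[fam$children[j]]] <-
        cbind(roles[[fam$children[j]]], c(k, 2L + j))
  }

  # messages: per family, an array 3 x (2 + kk) x L
  third <- matrix(1 / 3, 3, L)
  m_f2v <- lapply(fams, function(f) {
    kk <- length(f$children)
    array(1 / 3, c(3, 2 + kk, L))
  })
  m_v2f <- lapply(fams, function(f) {
    kk <- length(f$children)
    a <- array(1 / 3, c(3, 2 + kk, L))
    if (is.na(f$s)) a[, 1, ] <- prior
    if (is.na(f$d)) a[, 2, ] <- prior
    a
  })
  slice <- function(a, col) matrix(a[, col, ], 3)   # 3 x L view

  idx_gs <- rep(1:3, 3)          # row of the 9-vector = gs + 3 (gd - 1)
  idx_gd <- rep(1:3, each = 3)

  for (iter in seq_len(max_iter)) {
    # variable -> factor: leave-one-out products via prefix/suffix
    for (i in seq_len(n)) {
      rl <- roles[[i]]
      if (is.null(rl)) next
      deg <- ncol(rl)
      inc <- vector("list", deg)
      for (j in seq_len(deg)) inc[[j]] <- slice(m_f2v[[rl[1L, j]]], rl[2L, j])
      pre <- psi[[i]]
      prefix <- vector("list", deg)
      for (j in seq_len(deg)) {
        prefix[[j]] <- pre
        pre <- pre * inc[[j]]
      }
      suf <- 1
      for (j in rev(seq_len(deg))) {
        msg <- prefix[[j]] * suf
        s <- colSums(msg)
        s[s <= 0] <- 1      # a dead locus surfaces in the factor update
        msg <- msg * rep(1 / s, each = 3L)
        k <- rl[1L, j]
        col <- rl[2L, j]
        m_v2f[[k]][, col, ] <- damping * slice(m_v2f[[k]], col) +
          (1 - damping) * msg
        suf <- suf * inc[[j]]
      }
    }
    # factor -> variable
    delta <- 0
    for (k in seq_len(nf)) {
      fam <- fams[[k]]
      kk <- length(fam$children)
      ms <- slice(m_v2f[[k]], 1)
      md <- slice(m_v2f[[k]], 2)
      # Z[[j]]: 9 x L, sum over the child's genotype of TR * message
      Z <- vector("list", kk)
      for (j in seq_len(kk))
        Z[[j]] <- crossprod(TRm, slice(m_v2f[[k]], 2L + j))
      pre <- 1
      prefix <- vector("list", kk)
      for (j in seq_len(kk)) {
        prefix[[j]] <- pre
        pre <- pre * Z[[j]]
      }
      Zall <- pre                      # 9 x L (or scalar 1 when kk = 0)
      if (kk == 0L) Zall <- matrix(1, 9, L)
      new <- m_f2v[[k]]
      if (!is.na(fam$s)) {
        tmp <- Zall * md[idx_gd, , drop = FALSE]
        raw <- tmp[1:3, , drop = FALSE] + tmp[4:6, , drop = FALSE] +
               tmp[7:9, , drop = FALSE]
        new[, 1, ] <- damping * slice(m_f2v[[k]], 1) +
          (1 - damping) * normalize(raw, fam)
      }
      if (!is.na(fam$d)) {
        tmp <- Zall * ms[idx_gs, , drop = FALSE]
        raw <- tmp[c(1, 4, 7), , drop = FALSE] +
               tmp[c(2, 5, 8), , drop = FALSE] +
               tmp[c(3, 6, 9), , drop = FALSE]
        new[, 2, ] <- damping * slice(m_f2v[[k]], 2) +
          (1 - damping) * normalize(raw, fam)
      }
      W <- ms[idx_gs, , drop = FALSE] * md[idx_gd, , drop = FALSE]
      suf <- 1
      for (j in rev(seq_len(kk))) {
        Zexcl <- prefix[[j]] * suf
        if (kk == 1L) Zexcl <- matrix(1, 9, L)
        raw <- TRm %*% (Zexcl * W)
        new[, 2L + j, ] <- damping * slice(m_f2v[[k]], 2L + j) +
          (1 - damping) * normalize(raw, fam)
        suf <- suf * Z[[j]]
      }
      delta <- max(delta, max(abs(new - m_f2v[[k]])))
      m_f2v[[k]] <- new
    }
    if (delta < tol && iter > 3L) break
  }

  out <- array(NA_real_, c(n, L, 3))
  for (i in seq_len(n)) {
    b <- psi[[i]]
    rl <- roles[[i]]
    if (!is.null(rl)) {
      for (j in seq_len(ncol(rl)))
        b <- b * slice(m_f2v[[rl[1L, j]]], rl[2L, j])
    }
    s <- colSums(b)
    bad <- which(!is.finite(s) | s <= 0)
    if (length(bad)) inconsistent(bad[1L])
    out[i, , ] <- t(b * rep(1 / s, each = 3L))
  }
  out
}

#' Genotype probabilities by segregation analysis
#'
#' Computes, per locus, the posterior genotype distribution
#' `(P_AA, P_Aa, P_aa)` of every animal given the observed genotypes of the
#' genotyped animals, Mendelian transmission through the pedigree, and a
#' Hardy-Weinberg founder prior at the panel allele frequency. Genotyped
#' animals get a unit mass on their observed genotype. Inference is exact
#' (variable elimination, loops included) when `method = "exact"`, and uses
#' damped iterative peeling (loopy belief propagation over nuclear-family
#' factors, exact on loop-free pedigrees) when `method = "loopy"`;
#' `method = "auto"` picks exact for pedigrees of at most 25 animals.
#'
#' By default posteriors are not conditioned on ungenotyped animals being
#' alive (hence possibly `aa`); set `condition_alive = TRUE` to add that
#' conditioning.
#'
#' @param ped a `lof_pedigree`.
#' @param observed matrix animals x loci of observed allele counts (0/1/2,
#'   `NA` = ungenotyped), e.g. from [mask_genotypes()]; or a vector for a
#'   single locus.
#' @param q LOF allele frequency per locus (recycled).
#' @param method `"auto"`, `"exact"` or `"loopy"`.
#' @param tol,max_iter,damping iterative-peeling controls.
#' @param condition_alive condition ungenotyped animals on not being `aa`.
#' @return array `[animal, locus, genotype]` with genotype slices
#'   `pAA`, `pAa`, `paa`; class `lof_genoprobs`. Triples sum to 1.
#' @export
genotype_probabilities <- function(ped, observed, q,
                                   method = c("auto", "exact", "loopy"),
                                   tol = 1e-8, max_iter = 500, damping = 0.5,
                                   condition_alive = FALSE) {
  method <- match.arg(method)
  if (is.null(dim(observed))) observed <- matrix(observed, ncol = 1)
  n <- nrow(ped)
  stopifnot(nrow(observed) == n)
  L <- ncol(observed)
  q <- rep_len(q, L)
  if (method == "auto") method <- if (n <= 25L) "exact" else "loopy"
  loci <- colnames(observed) %||% sprintf("L%03d", seq_len(L))
  if (method == "exact") {
    out <- array(NA_real_, c(n, L, 3),
                 dimnames = list(ped$id, loci, c("pAA", "pAa", "paa")))
    for (l in seq_len(L)) {
      model <- locus_model(ped, observed[, l], q[l], condition_alive)
      out[, l, ] <- exact_locus_probs(ped, model, loci[l])
    }
  } else {
    out <- loopy_all_probs(ped, observed, q, loci, tol, max_iter, damping,
                           condition_alive)
    dimnames(out) <- list(ped$id, loci, c("pAA", "pAa", "paa"))
  }
  class(out) <- "lof_genoprobs"
  out
}

#' Point-mass genotype probabilities from known genotypes
#'
#' @param geno a complete `lof_genotypes` matrix (0/1/2, no `NA`).
#' @return a `lof_genoprobs` array of 0/1 point masses.
#' @export
genotype_point_probs <- function(geno) {
  stopifnot(!anyNA(geno))
  n <- nrow(geno)
  L <- ncol(geno)
  out <- array(0, c(n, L, 3),
               dimnames = list(rownames(geno), colnames(geno),
                               c("pAA", "pAa", "paa")))
  for (g in 0:2) out[, , g + 1L][unclass(geno) == g] <- 1
  class(out) <- "lof_genoprobs"
  out
}

#' Write the per-locus genotype-probability CSV
#'
#' Long format `id,locus,pAA,pAa,paa`.
#' @param probs a `lof_genoprobs` array.
#' @param file path.
#' @export
write_genoprobs <- function(probs, file) {
  ids <- dimnames(probs)[[1]]
  loci <- dimnames(probs)[[2]]
  long <- data.frame(
    id = rep(ids, times = length(loci)),
    locus = rep(loci, each = length(ids)),
    pAA = as.vector(probs[, , 1]),
    pAa = as.vector(probs[, , 2]),
    paa = as.vector(probs[, , 3])
  )
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
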