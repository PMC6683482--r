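#' Kosambi map function
#'
#' Converts a map distance in Morgans to a recombination fraction:
#' `r(d) = tanh(2 d) / 2`, so `r(0) = 0` and `r -> 0.5` as `d -> Inf`.
#'
#' @param d map distance in Morgans (non-negative).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
kosambi <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(2 * d) / 2
}

#' Lay out a locus panel on a genome map
#'
#' Places each locus of a panel at a uniform random position on one of
#' `n_chromosomes` chromosomes of a genome of `genome_gb` gigabases,
#' converting physical to map distance at `cm_per_mb` centimorgans per
#' megabase (default 1, i.e. 3 Gb -> 30 Morgans total map). Loci are returned
#' sorted by chromosome and position; recombination fractions between
#' adjacent loci use the Kosambi function, and loci on different chromosomes
#' segregate independently.
#'
#' @param panel a `lof_panel` (or anything with a `locus` column).
#' @param n_chromosomes number of chromosomes (bovine default 29).
#' @param genome_gb genome size in Gb (default 3).
#' @param cm_per_mb map expansion (default 1 cM/Mb).
#' @param seed integer seed.
#' @return data frame `locus`, `chrom`, `pos_m` (position in Morgans),
#'   `r_prev` (recombination fraction to the previous locus in map order; 0.5
#'   across chromosome boundaries, NA for the first locus); class `lof_map`
#'   with attribute `mu` slot left to the caller.
#' @export
genome_map <- function(panel, n_chromosomes = 29, genome_gb = 3,
                       cm_per_mb = 1, seed = 1) {
  loci <- panel$locus
  n <- length(loci)
  chr_len_m <- genome_gb * 1000 / n_chromosomes * cm_per_mb / 100
  with_seed(seed, {
    chrom <- sample.int(n_chromosomes, n, replace = TRUE)
    pos <- stats::runif(n, 0, chr_len_m)
    ord <- order(chrom, pos)
    out <- data.frame(locus = loci[ord], chrom = chrom[ord], pos_m = pos[ord],
                      stringsAsFactors = FALSE)
    d <- diff(out$pos_m)
    same <- diff(out$chrom) == 0L
    out$r_prev <- c(NA, ifelse(same, kosambi(pmax(d, 0)), 0.5))
    class(out) <- c("lof_map", "data.frame")
    out
  })
}

# Draw one gamete per row: recombination pattern along the ordered loci.
# H1, H2: n x L haplotype matrices (0/1). Returns an n x L matrix.
make_gametes <- function(H1, H2, r_prev) {
  n <- nrow(H1)
  L <- ncol(H1)
  S <- matrix(0L, n, L)
  S[, 1L] <- stats::rbinom(n, 1L, 0.5)
  if (L > 1L) {
    for (k in 2:L) {
      sw <- stats::rbinom(n, 1L, r_prev[k])
      S[, k] <- (S[, k - 1L] + sw) %% 2L
    }
  }
  H1 * (1L - S) + H2 * S
}

#' Founder haplotype pool via random-mating burn-in
#'
#' Simulates a random-union-of-gametes population of `n_pop` individuals for
#' `n_generations` generations over the panel loci, with recombination per
#' the Kosambi map, per-site mutation at rate `mu`, and removal of lethal
#' homozygotes (`aa`) each generation (offspring drawn `aa` at any locus are
#' redrawn). Terminal allele frequencies are pinned back to the panel targets
#' (within machine counting, i.e. well inside +/- 0.01) by resampling allele
#' copies without creating `aa` genotypes, since drift would otherwise move
#' the panel off its published frequencies; whether pinning changed anything
#' is recorded in the `drift_corrected` attribute.
#'
#' `n_generations = 0` skips the burn-in and draws the pool directly from
#' Hardy-Weinberg at the panel frequencies (then rejects and pins the same
#' way), which is distributionally equivalent for unlinked downstream use.
#'
#' @param panel a `lof_panel`.
#' @param map a `lof_map` over the same loci (ignored when
#'   `n_generations = 0`).
#' @param n_pop pool size (>= 50).
#' @param n_generations burn-in length (study value 1000).
#' @param mu per-site per-generation mutation rate (study value 2.2e-9).
#' @param seed integer seed.
#' @return list with haplotype matrices `H1`, `H2` (`n_pop` x L, 0 = wild
#'   type, 1 = LOF), `loci`, `freq` (realized = target frequencies), class
#'   `lof_founder_pool`.
#' @export
burn_in_founders <- function(panel, map = NULL, n_pop = 500,
                             n_generations = 1000, mu = 2.2e-9, seed = 1) {
  stopifnot(n_pop >= 50)
  q <- panel$freq
  loci <- panel$locus
  L <- length(q)
  if (n_generations > 0) {
    if (is.null(map)) stop("a genome map is required for a burn-in")
    ord <- match(map$locus, loci)
    if (anyNA(ord)) stop("map does not cover the panel loci")
    q_ord <- q[ord]
  } else {
    ord <- seq_len(L)
    q_ord <- q
  }

  with_seed(seed, {
    H1 <- matrix(stats::rbinom(n_pop * L, 1L, rep(q_ord, each = n_pop)),
                 n_pop, L)
    H2 <- matrix(stats::rbinom(n_pop * L, 1L, rep(q_ord, each = n_pop)),
                 n_pop, L)
    fix_aa <- function(H1, H2) {
      bad <- which(rowSums(H1 * H2) > 0)
      tries <- 0L
      while (length(bad)) {
        H1[bad, ] <- matrix(
          stats::rbinom(length(bad) * L, 1L, rep(q_ord, each = length(bad))),
          length(bad), L)
        bad <- bad[rowSums(H1[bad, , drop = FALSE] *
                           H2[bad, , drop = FALSE]) > 0]
        tries <- tries + 1L
        if (tries > 1000L) stop("could not draw an aa-free pool")
      }
      list(H1 = H1, H2 = H2)
    }
    hh <- fix_aa(H1, H2)
    H1 <- hh$H1
    H2 <- hh$H2

    if (n_generations > 0) {
      r_prev <- map$r_prev
      for (g in seq_len(n_generations)) {
        p1 <- sample.int(n_pop, n_pop, replace = TRUE)
        p2 <- sample.int(n_pop, n_pop, replace = TRUE)
        G1 <- make_gametes(H1[p1, , drop = FALSE], H2[p1, , drop = FALSE],
                           r_prev)
        G2 <- make_gametes(H1[p2, , drop = FALSE], H2[p2, , drop = FALSE],
                           r_prev)
        # mutation: expected count mu * 2 n L per generation
        n_mut <- stats::rpois(1L, mu * 2 * n_pop * L)
        if (n_mut > 0) {
          for (m in seq_len(n_mut)) {
            i <- sample.int(n_pop, 1L)
            j <- sample.int(L, 1L)
            if (stats::runif(1) < 0.5) G1[i, j] <- 1L - G1[i, j]
            else G2[i, j] <- 1L - G2[i, j]
          }
        }
        # lethal rejection: redraw aa offspring from new random parents
        bad <- which(rowSums(G1 * G2) > 0)
        tries <- 0L
        while (length(bad)) {
          b1 <- sample.int(n_pop, length(bad), replace = TRUE)
          b2 <- sample.int(n_pop, length(bad), replace = TRUE)
          G1[bad, ] <- make_gametes(H1[b1, , drop = FALSE],
                                    H2[b1, , drop = FALSE], r_prev)
          G2[bad, ] <- make_gametes(H1[b2, , drop = FALSE],
                                    H2[b2, , drop = FALSE], r_prev)
          bad <- bad[rowSums(G1[bad, , drop = FALSE] *
                             G2[bad, , drop = FALSE]) > 0]
          tries <- tries + 1L
          if (tries > 1000L) stop("lethal rejection failed during burn-in")
        }
        H1 <- G1
        H2 <- G2
      }
    }

    # pin frequencies back to panel targets without creating aa genotypes
    corrected <- FALSE
    for (j in seq_len(L)) {
      target <- as.integer(round(2 * n_pop * q_ord[j]))
      cur <- sum(H1[, j]) + sum(H2[, j])
      if (cur == target) next
      corrected <- TRUE
      if (cur > target) {
        carriers1 <- which(H1[, j] == 1L)
        carriers2 <- which(H2[, j] == 1L)
        slots <- c(carriers1, n_pop + carriers2)
        drop <- sample(slots, cur - target)
        H1[drop[drop <= n_pop], j] <- 0L
        H2[drop[drop > n_pop] - n_pop, j] <- 0L
      } else {
        free <- which(H1[, j] == 0L & H2[, j] == 0L)  # only these stay aa-free
        if (length(free) < target - cur)
          stop("cannot restore allele frequency at locus ", loci[ord[j]],
               " without creating aa genotypes")
        add <- if (length(free) == 1L) free else sample(free, target - cur)
        H1[add, j] <- 1L
      }
    }

    # return in panel locus order
    back <- match(loci, loci[ord])
    pool <- list(H1 = H1[, back, drop = FALSE], H2 = H2[, back, drop = FALSE],
                 loci = loci, freq = q)
    attr(pool, "drift_corrected") <- corrected
    class(pool) <- "lof_founder_pool"
    pool
  })
}

#' Drop genotypes through a pedigree with lethal-homozygote rejection
#'
#' Founders (animals with two unknown parents) receive the two haplotypes of
#' a random pool individual (which preserves the pool's non-`aa` guarantee
#' and any burn-in linkage disequilibrium). Every other animal receives one
#' gamete from each parent, a random pool gamete standing in for an unknown
#' parent. In the default `"unlinked"` mode each locus segregates
#' independently; in `"linked"` mode gametes recombine per the map. Any
#' animal drawn `aa` at one or more loci is redrawn (bounded retries): the
#' pedigree records survivors only, so lethal homozygotes are never emitted.
#'
#' @param ped a `lof_pedigree`.
#' @param pool a [burn_in_founders()] pool.
#' @param mode `"unlinked"` (default) or `"linked"`.
#' @param map a `lof_map`; required for `mode = "linked"`.
#' @param seed integer seed.
#' @param max_retries redraw budget per animal.
#' @return integer matrix animals x loci with entries 0 (`AA`), 1 (`Aa`);
#'   (2 = `aa` never survives); rownames = animal ids, colnames = loci;
#'   class `lof_genotypes`, with phased haplotypes in attributes `H1`, `H2`.
#' @export
drop_genotypes <- function(ped, pool, mode = c("unlinked", "linked"),
                           map = NULL, seed = 1, max_retries = 10000) {
  mode <- match.arg(mode)
  if (mode == "linked" && is.null(map))
    stop("linked mode needs a genome map")
  n <- nrow(ped)
  L <- length(pool$loci)
  n_pool <- nrow(pool$H1)
  if (mode == "linked") {
    ord <- match(map$locus, pool$loci)
    r_prev <- map$r_prev
  } else {
    ord <- seq_len(L)
  }
  P1 <- pool$H1[, ord, drop = FALSE]
  P2 <- pool$H2[, ord, drop = FALSE]

  with_seed(seed, {
    H1 <- matrix(0L, n, L)  # paternal gamete
    H2 <- matrix(0L, n, L)  # maternal gamete
    gamete_of <- function(i) {
      # a gamete from animal row i (or from a random pool animal if i is NA)
      if (is.na(i)) {
        k <- sample.int(n_pool, 1L)
        a <- P1[k, ]
        b <- P2[k, ]
      } else {
        a <- H1[i, ]
        b <- H2[i, ]
      }
      if (mode == "unlinked") {
        pick <- stats::rbinom(L, 1L, 0.5)
        a * (1L - pick) + b * pick
      } else {
        drop(make_gametes(matrix(a, 1L), matrix(b, 1L), r_prev))
      }
    }
    for (a in seq_len(n)) {
      si <- ped$sire_row[a]
      di <- ped$dam_row[a]
      if (is.na(si) && is.na(di)) {
        k <- sample.int(n_pool, 1L)
        H1[a, ] <- P1[k, ]
        H2[a, ] <- P2[k, ]
        next
      }
      for (try in seq_len(max_retries)) {
        g1 <- gamete_of(si)
        g2 <- gamete_of(di)
        if (!any(g1 & g2)) break
        if (try == max_retries)
          stop("lethal rejection failed for animal ", ped$id[a])
      }
      H1[a, ] <- g1
      H2[a, ] <- g2
    }
    geno <- H1 + H2
    back <- match(pool$loci, pool$loci[ord])
    geno <- geno[, back, drop = FALSE]
    dimnames(geno) <- list(ped$id, pool$loci)
    structure(geno, H1 = H1[, back, drop = FALSE],
              H2 = H2[, back, drop = FALSE], class = "lof_genotypes")
  })
}

#' Write / read the genotype CSV dialect
#'
#' Long format `id,locus,genotype` with genotype in `AA`/`Aa`/`aa`.
#' @param geno a `lof_genotypes` matrix (entries 0/1/2).
#' @param file path.
#' @export
write_genotypes <- function(geno, file) {
  long <- data.frame(
    id = rep(rownames(geno), times = ncol(geno)),
    locus = rep(colnames(geno), each = nrow(geno)),
    genotype = c("AA", "Aa", "aa")[as.vector(geno) + 1L]
  )
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write / read a founder haplotype pool as plain text
#'
#' Long CSV `indiv,locus,h1,h2` with alleles 0 (wild type) / 1 (LOF), plus a
#' `freq` column repeated per locus, so a burn-in pool can be cached and
#' reused across replicates without any binary format.
#' @param pool a [burn_in_founders()] pool.
#' @param file path.
#' @export
write_founder_pool <- function(pool, file) {
  n <- nrow(pool$H1)
  L <- length(pool$loci)
  long <- data.frame(
    indiv = rep(seq_len(n), times = L),
    locus = rep(pool$loci, each = n),
    h1 = as.vector(pool$H1),
    h2 = as.vector(pool$H2),
    freq = rep(pool$freq, each = n)
  )
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_founder_pool
#' @export
read_founder_pool <- function(file) {
  long <- utils::read.csv(file)
  loci <- unique(long$locus)
  n <- max(long$indiv)
  pool <- list(
    H1 = matrix(long$h1, n, length(loci)),
    H2 = matrix(long$h2, n, length(loci)),
    loci = loci,
    freq = long$freq[match(loci, long$locus)]
  )
  class(pool) <- "lof_founder_pool"
  pool
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(file) {
  long <- utils::read.csv(file, colClasses = "character")
  ids <- unique(long$id)
  loci <- unique(long$locus)
  geno <- matrix(NA_integer_, length(ids), length(loci),
                 dimnames = list(ids, loci))
  geno[cbind(long$id, long$locus)] <-
    match(long$genotype, c("AA", "Aa", "aa")) - 1L
  class(geno) <- "lof_genotypes"
  geno
}
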