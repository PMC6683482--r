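#' Trait model: heritabilities, genetic correlations, scales
#'
#' Container for the genetic parameters of the seven recorded maternal traits:
#' heifer pregnancy (HP), calving ease direct (CED), calving ease maternal
#' (CEM), weaning weight direct (WWD), weaning weight maternal/milk (WWM),
#' back fat thickness (FT) and stayability (STAY). Defaults are the published
#' Angus/British-breed estimates used throughout the package: heritabilities
#' on the diagonal and the sparse genetic-correlation structure off it
#' (HP-WWD 0.29, CED-CEM -0.30, CED-WWD -0.16, CEM-STAY 0.25, WWD-WWM -0.17,
#' WWD-FT 0.10, WWM-STAY -0.15, FT-STAY 0.53; all other pairs 0).
#'
#' Phenotypic SDs are unitless 1 by default (the source population's scales
#' are not published), so EPDs and index values are on a synthetic dollar-like
#' scale.
#'
#' @param h2 named vector of heritabilities.
#' @param r_g genetic correlation matrix (unit diagonal, symmetric).
#' @param sd_p named vector of phenotypic standard deviations.
#' @return an object of class `lof_trait_model` with elements `traits`, `h2`,
#'   `r_g`, `sd_p`, and `G` (the genetic covariance matrix
#'   `G = D r_g D`, `D = diag(sqrt(h2) * sd_p)`), repaired to the nearest
#'   positive semidefinite matrix if needed (repair recorded in the
#'   `psd_repaired` element).
#' @export
trait_model <- function(h2 = NULL, r_g = NULL, sd_p = NULL) {
  traits <- c("HP", "CED", "CEM", "WWD", "WWM", "FT", "STAY")
  if (is.null(h2))
    h2 <- c(HP = 0.21, CED = 0.20, CEM = 0.10, WWD = 0.20, WWM = 0.14,
            FT = 0.40, STAY = 0.15)
  if (is.null(r_g)) {
    r_g <- diag(length(traits))
    dimnames(r_g) <- list(traits, traits)
    set_r <- function(a, b, v) {
      r_g[a, b] <<- v
      r_g[b, a] <<- v
    }
    set_r("HP", "WWD", 0.29)
    set_r("CED", "CEM", -0.30)
    set_r("CED", "WWD", -0.16)
    set_r("CEM", "STAY", 0.25)
    set_r("WWD", "WWM", -0.17)
    set_r("WWD", "FT", 0.10)
    set_r("WWM", "STAY", -0.15)
    set_r("FT", "STAY", 0.53)
  }
  if (is.null(sd_p)) sd_p <- stats::setNames(rep(1, length(traits)), traits)
  traits <- names(h2)
  stopifnot(
    all(h2 >= 0 & h2 <= 1),
    identical(rownames(r_g), traits), identical(colnames(r_g), traits),
    isTRUE(all.equal(r_g, t(r_g))), all(abs(diag(r_g) - 1) < 1e-12),
    all(r_g >= -1 & r_g <= 1),
    identical(names(sd_p), traits), all(sd_p > 0)
  )
  D <- diag(sqrt(h2) * sd_p, nrow = length(traits))
  G <- D %*% r_g %*% D
  dimnames(G) <- list(traits, traits)
  repaired <- FALSE
  ev <- eigen(G, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    # clip negative eigenvalues: nearest-PSD repair (logged in the object)
    vals <- pmax(ev$values, 0)
    G <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    dimnames(G) <- list(traits, traits)
    repaired <- TRUE
  }
  structure(
    list(traits = traits, h2 = h2, r_g = r_g, sd_p = sd_p, G = G,
         psd_repaired = repaired),
    class = "lof_trait_model"
  )
}

#' Generate a synthetic multi-generation herd pedigree
#'
#' Builds an overlapping-generation pedigree shaped like a seedstock herd:
#' `n_ancestors` animals spread over `n_generations` ancestor cohorts
#' (cohort 1 = founders with unknown parents; later cohorts draw a sire and a
#' dam from earlier cohorts, most recent cohorts preferred), plus a youngest
#' cohort of `n_male_cand` male and `n_female_cand` female selection
#' candidates whose parents are ancestors. Dams are limited to 8 and sires to
#' 50 offspring per cohort, so counts that cannot be produced under those
#' limits are an error.
#'
#' @param n_ancestors,n_male_cand,n_female_cand cohort sizes; the study shape
#'   is 546 ancestors, 85 male and 169 female candidates.
#' @param n_generations number of ancestor cohorts (>= 2).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a `lof_pedigree` with `n_ancestors + n_male_cand + n_female_cand`
#'   animals.
#' @export
generate_pedigree <- function(n_ancestors = 546, n_male_cand = 85,
                              n_female_cand = 169, n_generations = 4,
                              seed = 1) {
  stopifnot(n_ancestors >= 2, n_male_cand >= 1, n_female_cand >= 1,
            n_generations >= 2)
  max_dam <- 8L
  max_sire <- 50L
  # every ancestor cohort needs at least 2 animals (one of each sex can then
  # be guaranteed), so small herds get fewer cohorts than requested
  n_generations <- max(1L, min(n_generations, n_ancestors %/% 2L))
  with_seed(seed, {
    sizes <- rep(n_ancestors %/% n_generations, n_generations)
    extra <- n_ancestors %% n_generations
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

    id <- sprintf("A%04d", seq_len(n_ancestors))
    sex <- character(n_ancestors)
    sire <- rep(NA_character_, n_ancestors)
    dam <- rep(NA_character_, n_ancestors)
    cohort <- rep(seq_len(n_generations), sizes)

    for (g in seq_len(n_generations)) {
      rows <- which(cohort == g)
      # balanced sexes, at least one of each per cohort
      sx <- rep(c("M", "F"), length.out = length(rows))
      sex[rows] <- sample(sx)
      if (g == 1L) next
      males <- which(cohort < g & sex == "M")
      females <- which(cohort < g & sex == "F")
      if (!length(males) || !length(females))
        stop("cohort ", g, " has no available sires or dams")
      if (length(rows) > length(females) * max_dam ||
          length(rows) > length(males) * max_sire)
        stop("infeasible counts: cohort ", g,
             " exceeds parental capacity under mating limits")
      w_m <- 2^(cohort[males])   # prefer recent cohorts as parents
      w_f <- 2^(cohort[females])
      sire[rows] <- id[sample_capped(males, length(rows), w_m, max_sire)]
      dam[rows] <- id[sample_capped(females, length(rows), w_f, max_dam)]
    }

    n_cand <- n_male_cand + n_female_cand
    cid <- c(sprintf("CM%03d", seq_len(n_male_cand)),
             sprintf("CF%03d", seq_len(n_female_cand)))
    csex <- c(rep("M", n_male_cand), rep("F", n_female_cand))
    males <- which(sex == "M")
    females <- which(sex == "F")
    if (n_cand > length(females) * max_dam || n_cand > length(males) * max_sire)
      stop("infeasible counts: candidate cohort exceeds parental capacity")
    csire <- id[sample_capped(males, n_cand, 2^cohort[males], max_sire)]
    cdam <- id[sample_capped(females, n_cand, 2^cohort[females], max_dam)]

    build_pedigree(data.frame(
      id = c(id, cid),
      sire = c(sire, csire),
      dam = c(dam, cdam),
      sex = c(sex, csex),
      role = c(rep("ancestor", n_ancestors), rep("candidate", n_cand))
    ))
  })
}

# Sample n parents from `pool` (row indices) with weights w, each used at
# most `cap` times.
sample_capped <- function(pool, n, w, cap) {
  out <- integer(n)
  left <- rep(cap, length(pool))
  for (k in seq_len(n)) {
    ok <- left > 0L
    pick <- if (sum(ok) == 1L) which(ok) else
      sample(which(ok), 1L, prob = w[ok])
    out[k] <- pool[pick]
    left[pick] <- left[pick] - 1L
  }
  out
}

#' Simulate EPDs for every animal in a pedigree
#'
#' EPDs (expected progeny differences, half the breeding value) are drawn
#' multivariate normal with mean `mu` and covariance `G / 4`, where `G` is the
#' trait model's genetic covariance: a parent-average accuracy proxy (this
#' scaling is a modeling choice of this package, not an estimate). A
#' configurable fraction of animals receives breed-average (mean) EPDs,
#' emulating animals without reported records.
#'
#' @param ped a `lof_pedigree`.
#' @param model a [trait_model()].
#' @param seed integer seed.
#' @param missing_fraction fraction of animals whose EPDs are replaced by the
#'   trait means (breed average), in `[0, 1]`.
#' @param mu named vector of trait means (default 0).
#' @return data frame with column `id` then one column per trait; class
#'   `lof_epds`.
#' @export
generate_epds <- function(ped, model = trait_model(), seed = 1,
                          missing_fraction = 0, mu = NULL) {
  stopifnot(inherits(model, "lof_trait_model"),
            missing_fraction >= 0, missing_fraction <= 1)
  traits <- model$traits
  if (is.null(mu)) mu <- stats::setNames(rep(0, length(traits)), traits)
  n <- nrow(ped)
  Sigma <- model$G / 4
  with_seed(seed, {
    X <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    if (missing_fraction > 0) {
      n_miss <- round(missing_fraction * n)
      miss <- sample.int(n, n_miss)
      X[miss, ] <- matrix(mu, nrow = n_miss, ncol = length(traits),
                          byrow = TRUE)
    }
    out <- data.frame(id = ped$id, X, stringsAsFactors = FALSE)
    names(out) <- c("id", traits)
    class(out) <- c("lof_epds", "data.frame")
    out
  })
}

# Summary statistics of the three published LOF panels:
# scenario, locus count, mean, SD, min, max of the minor-allele frequency.
panel_table <- function() {
  data.frame(
    scenario = c("A", "B", "C"),
    n_loci = c(7L, 76L, 50L),
    mean = c(0.0847, 0.0112, 0.0488),
    sd = c(0.0151, 0.0125, 0.0307),
    min = c(0.0527, 0.0004, 0.0044),
    max = c(0.1001, 0.0695, 0.1436)
  )
}

#' Generate a LOF locus panel for one of the three study scenarios
#'
#' Scenario A: 7 loci with high-frequency LOF alleles (mean 0.0847, range
#' 0.0527-0.1001); scenario B: 76 low-frequency loci (mean 0.0112, range
#' 0.0004-0.0695, i.e. below the 0.07 cut-off); scenario C: 50 mixed-frequency
#' loci (mean 0.0488, range 0.0044-0.1436). One locus is pinned at the range
#' minimum and one at the maximum; the rest are drawn from a
#' moment-matched beta (A) or gamma (B, C) distribution and then shifted so
#' the panel mean lands within 0.005 of the published mean while all
#' frequencies stay inside the published range.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param seed integer seed; deterministic given the seed.
#' @return data frame `locus`, `freq` with attribute `scenario`; class
#'   `lof_panel`.
#' @export
generate_locus_panel <- function(scenario = c("A", "B", "C"), seed = 1) {
  scenario <- match.arg(scenario)
  tab <- panel_table()
  p <- tab[tab$scenario == scenario, ]
  with_seed(seed, {
    n <- p$n_loci
    lo <- p$min
    hi <- p$max
    n_free <- n - 2L
    if (scenario == "A") {
      # beta on [lo, hi], moments matched to the published mean/SD
      m <- (p$mean - lo) / (hi - lo)
      v <- (p$sd / (hi - lo))^2
      k <- m * (1 - m) / v - 1
      q_free <- lo + (hi - lo) * stats::rbeta(n_free, m * k, (1 - m) * k)
    } else {
      # gamma offsets above lo (heavily right-skewed panels)
      m_off <- p$mean - lo
      shape <- (m_off / p$sd)^2
      q_free <- lo + stats::rgamma(n_free, shape = shape,
                                   scale = p$sd^2 / m_off)
      q_free <- pmin(q_free, hi)
    }
    q <- c(lo, q_free, hi)
    # pin the panel mean within +/- 0.005 by shifting the free loci
    for (it in 1:50) {
      gap <- p$mean - mean(q)
      if (abs(gap) <= 0.0045) break
      free <- seq(2L, n - 1L)
      q[free] <- pmin(pmax(q[free] + gap * n / length(free), lo), hi)
    }
    out <- data.frame(locus = sprintf("L%03d", seq_len(n)), freq = q,
                      stringsAsFactors = FALSE)
    attr(out, "scenario") <- scenario
    class(out) <- c("lof_panel", "data.frame")
    out
  })
}

#' Write the synthetic-data CSV artifacts
#'
#' @param epds a `lof_epds` data frame.
#' @param panel a `lof_panel` data frame.
#' @param file output path.
#' @export
write_epds <- function(epds, file) {
  utils::write.csv(as.data.frame(epds), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_epds
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(as.data.frame(panel), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
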