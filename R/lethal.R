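# Lethality metrics: probability that progeny (LethalG) or grandprogeny
# (LethalA) die from homozygosity at any LOF locus, and the sire genetic
# load score (GLS). Loci combine as a union of independent per-locus deaths:
# 1 - prod(1 - p_l), so all metrics stay probabilities.

# slice k of an [n, L, 3] array as an n x L matrix (robust to L = 1)
slice3 <- function(a, k) {
  matrix(a[, , k], nrow = dim(a)[1], ncol = dim(a)[2],
         dimnames = dimnames(a)[1:2])
}

# P(transmit a) per animal x locus from a lof_genoprobs array
transmission_matrix <- function(probs) {
  slice3(probs, 2) / 2 + slice3(probs, 3)
}

#' Probability that a mating's progeny dies from a LOF locus
#'
#' Per locus, the death probability is the chance the offspring is `aa`:
#' `p_l = t_s t_d` where `t = P(transmit a) = P_Aa / 2 + P_aa` for each
#' parent (equivalently the sum over parental genotype pairs of their
#' probabilities times the Mendelian `aa` chance). Loci combine as
#' `1 - prod_l (1 - p_l)`.
#'
#' @param probs_sire,probs_dam genotype-probability triples for the two
#'   parents: vectors of length 3, or `loci x 3` matrices.
#' @return the mortality probability of the mating.
#' @export
pair_mortality <- function(probs_sire, probs_dam) {
  if (is.null(dim(probs_sire))) probs_sire <- matrix(probs_sire, ncol = 3)
  if (is.null(dim(probs_dam))) probs_dam <- matrix(probs_dam, ncol = 3)
  ts <- probs_sire[, 2] / 2 + probs_sire[, 3]
  td <- probs_dam[, 2] / 2 + probs_dam[, 3]
  1 - prod(1 - ts * td)
}

# internal: per-mating mortality vector, vectorized over the list
mating_mortality <- function(matings, probs) {
  Tm <- transmission_matrix(probs)
  ts <- Tm[as.character(matings$sire), , drop = FALSE]
  td <- Tm[as.character(matings$dam), , drop = FALSE]
  1 - exp(rowSums(log1p(-ts * td)))
}

#' LethalG: expected progeny mortality of a mating list
#'
#' Mean of [pair_mortality()] over the list. `100 * lethal_g` is the
#' predicted number of affected (`aa`) calves per 100 matings.
#'
#' @param matings data frame with columns `sire`, `dam`.
#' @param probs a `lof_genoprobs` array covering all parents.
#' @return probability of mortality in progeny.
#' @export
lethal_g <- function(matings, probs) {
  if (nrow(matings) == 0L) stop("empty mating list")
  mean(mating_mortality(matings, probs))
}

#' LethalA: expected grandprogeny mortality under random mating of progeny
#'
#' For each mating and locus, the progeny genotype distribution is derived
#' from the parental genotype probabilities and (by default) conditioned on
#' the progeny surviving (not `aa`); `t_l` is the probability that this
#' progeny transmits the LOF allele. The cohort transmission frequency
#' `tbar_l` is the mean of `t_l` over the list, and a random mate contributes
#' the allele at the current candidate frequency `q_l`, so
#' `lethal_a = 1 - prod_l (1 - tbar_l q_l)`. The value depends only on which
#' parents are used and how often, not on the pairings (up to
#' survivor-conditioning effects).
#'
#' @param matings data frame with columns `sire`, `dam`.
#' @param probs a `lof_genoprobs` array covering all parents.
#' @param q per-locus allele frequency: with `freq = "panel"` the supplied
#'   panel frequencies; with `freq = "empirical"` (default) recomputed as the
#'   mean allele dosage of the `candidates` under `probs`.
#' @param candidates ids over which empirical frequencies are computed
#'   (default: all animals in `probs`).
#' @param survivor_condition condition the progeny distribution on survival
#'   (default TRUE: dead progeny cannot breed).
#' @param freq `"empirical"` or `"panel"`.
#' @return probability of mortality in grandprogeny.
#' @export
lethal_a <- function(matings, probs, q, candidates = NULL,
                     survivor_condition = TRUE,
                     freq = c("empirical", "panel")) {
  if (nrow(matings) == 0L) stop("empty mating list")
  freq <- match.arg(freq)
  if (freq == "empirical") {
    Tm <- transmission_matrix(probs)   # allele dosage/2 = pAa/2 + paa
    if (!is.null(candidates)) Tm <- Tm[candidates, , drop = FALSE]
    q <- colMeans(Tm)
  }
  Tm <- transmission_matrix(probs)
  ts <- Tm[as.character(matings$sire), , drop = FALSE]
  td <- Tm[as.character(matings$dam), , drop = FALSE]
  p_aa <- ts * td
  p_Aa <- ts * (1 - td) + (1 - ts) * td
  t_prog <- if (survivor_condition) {
    (p_Aa / 2) / pmax(1 - p_aa, .Machine$double.eps)
  } else {
    p_Aa / 2 + p_aa
  }
  tbar <- colMeans(t_prog)
  1 - prod(1 - tbar * q)
}

#' Genetic load score (GLS) of the sires of a mating list
#'
#' For each sire, the squared minor-allele frequency `q_l^2` is summed over
#' the loci at which the sire is (probabilistically) heterozygous, weighted
#' by the number of matings `n_s` allocated to him, and divided by the number
#' of matings: `GLS = sum_s n_s (sum_l P(Aa)_{s,l} q_l^2) / N`. With point
#' genotypes `P(Aa)` is 0 or 1.
#'
#' @param matings data frame with a `sire` column (`N` rows).
#' @param probs a `lof_genoprobs` array (point masses for known genotypes).
#' @param q per-locus panel allele frequencies.
#' @return the genetic load score.
#' @export
genetic_load_score <- function(matings, probs, q) {
  if (nrow(matings) == 0L) return(0)
  pAa <- slice3(probs, 2)
  load <- drop(pAa %*% q^2)   # per-animal carrier load
  sum(load[as.character(matings$sire)]) / nrow(matings)
}

#' Full lethality report for a mating list
#'
#' @inheritParams lethal_a
#' @param q_panel panel frequencies (used for GLS and, when
#'   `freq = "panel"`, for LethalA).
#' @return list with `lethalG`, `lethalA`, `gls`.
#' @export
lethal_report <- function(matings, probs, q_panel, candidates = NULL,
                          survivor_condition = TRUE,
                          freq = c("empirical", "panel")) {
  list(
    lethalG = lethal_g(matings, probs),
    lethalA = lethal_a(matings, probs, q_panel, candidates,
                       survivor_condition, freq),
    gls = genetic_load_score(matings, probs, q_panel)
  )
}
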