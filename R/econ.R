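#' Economic configuration
#'
#' @param c_dead opportunity cost of one homozygous lethal (`aa`) conception,
#'   dollars (study value 200).
#' @param c_test cost of one genotype test, dollars (study value 30).
#' @return class `lof_econ_config`.
#' @export
econ_config <- function(c_dead = 200, c_test = 30) {
  stopifnot(c_dead >= 0, c_test >= 0)
  structure(list(c_dead = c_dead, c_test = c_test),
            class = "lof_econ_config")
}

# Tests purchased at a genotyping tier, on the per-100-matings accounting
# basis: pct percent of the herd genotyped costs pct tests per 100 matings
# (10% -> 10 tests, 100% -> 100 tests).
n_tests <- function(pct) pct

#' Profit per mating
#'
#' `$P = $M - c_dead * LethalG`: the mean progeny index minus the expected
#' embryonic-mortality cost. Reported rounded to cents (half-up); pass
#' `round = FALSE` for the unrounded value.
#'
#' @param mean_m mean progeny index (`$M`) of the mating list, dollars.
#' @param lethalG expected progeny mortality probability, in `[0, 1]`.
#' @param cfg an [econ_config()].
#' @param round round to cents for reporting.
#' @return dollars per mating.
#' @export
profit_per_mating <- function(mean_m, lethalG, cfg = econ_config(),
                              round = TRUE) {
  stopifnot(all(lethalG >= 0 & lethalG <= 1))
  p <- mean_m - cfg$c_dead * lethalG
  if (round) round_cents(p) else p
}

#' Total herd loss from affected calves
#'
#' @param affected_per_100 predicted number of `aa` conceptions per 100
#'   matings (may be fractional).
#' @param cfg an [econ_config()].
#' @return dollars lost per 100 matings.
#' @export
total_loss <- function(affected_per_100, cfg = econ_config()) {
  stopifnot(all(affected_per_100 >= 0))
  affected_per_100 * cfg$c_dead
}

#' Savings from genotyping, before test costs
#'
#' The reduction in affected calves relative to the ungenotyped base run,
#' valued at `c_dead` per calf: `(base - at_tier) * c_dead` per 100 matings.
#'
#' @param base_affected affected calves per 100 matings at 0% genotyping.
#' @param affected_at_tier affected calves per 100 matings at the tier.
#' @param cfg an [econ_config()].
#' @return dollars saved per 100 matings (negative if mortality rose).
#' @export
savings <- function(base_affected, affected_at_tier, cfg = econ_config()) {
  (base_affected - affected_at_tier) * cfg$c_dead
}

#' Net profit of a genotyping tier
#'
#' Savings minus genotyping costs: `savings - c_test * n_tests(pct)` with
#' `n_tests(pct) = pct` on the per-100-matings accounting basis.
#'
#' @param savings dollars saved before genotyping costs.
#' @param pct percentage of the herd genotyped, in `[0, 100]`.
#' @param cfg an [econ_config()].
#' @return dollars per 100 matings.
#' @export
net_profit <- function(savings, pct, cfg = econ_config()) {
  stopifnot(all(pct >= 0 & pct <= 100))
  savings - cfg$c_test * n_tests(pct)
}

#' Breakeven genotyping cost
#'
#' The test price at which genotyping costs exactly offset the savings:
#' `savings / n_tests(pct)`.
#'
#' @param savings dollars saved before genotyping costs.
#' @param pct percentage of the herd genotyped (> 0).
#' @param cfg an [econ_config()] (unused; kept for interface symmetry).
#' @return dollars per test.
#' @export
breakeven <- function(savings, pct, cfg = econ_config()) {
  if (any(pct <= 0)) stop("breakeven is undefined at 0% genotyping")
  savings / n_tests(pct)
}
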