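#' Maternal selection index specification
#'
#' The maternal breeding objective comprises HP, CED, CEM, WWD, WWM and STAY;
#' the selection criteria (the EPDs actually entering the index) are HP, CED,
#' CEM, WWD, WWM and FT. Economic weights default to 1 per objective trait
#' (the source population's weights are not published, so the index is on a
#' synthetic dollar scale).
#'
#' @param objective character vector of objective trait names.
#' @param criteria character vector of criterion trait names.
#' @param weights economic weights `v`, one per objective trait.
#' @return class `lof_index_spec`.
#' @export
index_spec <- function(objective = c("HP", "CED", "CEM", "WWD", "WWM", "STAY"),
                       criteria = c("HP", "CED", "CEM", "WWD", "WWM", "FT"),
                       weights = rep(1, length(objective))) {
  stopifnot(length(weights) == length(objective))
  structure(list(objective = objective, criteria = criteria,
                 weights = stats::setNames(weights, objective)),
            class = "lof_index_spec")
}

#' Index coefficients by selection-index theory
#'
#' Solves `G_cc b = G_co v` where `G_cc` is the genetic covariance among the
#' criterion traits, `G_co` the genetic covariance between criteria and
#' objective traits, and `v` the economic weights, giving the weights `b`
#' applied to the criterion EPDs.
#'
#' @param model a [trait_model()].
#' @param spec an [index_spec()].
#' @return named numeric vector `b` over the criteria.
#' @export
index_coefficients <- function(model = trait_model(), spec = index_spec()) {
  stopifnot(all(spec$criteria %in% model$traits),
            all(spec$objective %in% model$traits))
  Gcc <- model$G[spec$criteria, spec$criteria, drop = FALSE]
  Gco <- model$G[spec$criteria, spec$objective, drop = FALSE]
  if (rcond(Gcc) < 1e-12) stop("singular criterion covariance matrix")
  b <- solve(Gcc, Gco %*% spec$weights)
  stats::setNames(drop(b), spec$criteria)
}

#' Index value ($M) of each animal
#'
#' `$M = b . EPD` over the criterion traits.
#'
#' @param epds a `lof_epds` data frame (or any data frame with `id` and the
#'   criterion columns).
#' @param b coefficients from [index_coefficients()].
#' @return named numeric vector of `$M` values (names = animal ids).
#' @export
animal_index <- function(epds, b) {
  crit <- names(b)
  if (!all(crit %in% names(epds)))
    stop("EPDs are missing criterion trait(s): ",
         paste(setdiff(crit, names(epds)), collapse = ", "))
  m <- as.matrix(epds[crit]) %*% b
  stats::setNames(drop(m), epds$id)
}

#' Progeny index of a mating
#'
#' The expected index of the progeny is the mid-parent average
#' `($M_sire + $M_dam) / 2`, the unique choice consistent with additive EPDs.
#'
#' @param m_sire,m_dam parental `$M` values (vectorized).
#' @return numeric vector of progeny `$M`.
#' @export
progeny_index <- function(m_sire, m_dam) {
  (m_sire + m_dam) / 2
}

#' Write per-animal index values as CSV (`id,M`)
#'
#' @param m named vector from [animal_index()].
#' @param file path.
#' @export
write_index_values <- function(m, file) {
  utils::write.csv(data.frame(id = names(m), M = unname(m)), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Mating-weighted mean sire index ($MB)
#'
#' `$MB = sum_s n_s $M_s / sum_s n_s` over the sires `s` of a mating list,
#' with `n_s` matings allocated to sire `s`.
#'
#' @param matings data frame with a `sire` column.
#' @param m named vector of `$M` values covering all sires used.
#' @return the `$MB` value.
#' @export
mb_value <- function(matings, m) {
  if (nrow(matings) == 0L) stop("empty mating list")
  s <- as.character(matings$sire)
  if (!all(s %in% names(m))) stop("sire(s) without an index value")
  mean(m[s])
}
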