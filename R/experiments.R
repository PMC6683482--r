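#' Study configuration
#'
#' Full factorial study layout: scenarios (LOF panels) x breeding strategies
#' x penalty weightings x genotyping tiers x replicates. Strategy 1 weights
#' LethalA (selection against carrier parents); strategy 2 weights LethalG
#' (mate allocation against affected offspring); the configured weighting is
#' applied to the strategy's criterion and the other weight is 0. The
#' pedigree, EPDs and panel are fixed per scenario; replicates differ only in
#' the random sampling of true genotypes (and the genotyping subsets drawn
#' from them).
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param weightings penalty weighting grid (study grid
#'   `0, 0.001, 0.01, 0.1, 1, 10, 100`).
#' @param tiers genotyping percentages (study grid 0-100 by 10).
#' @param n_replicates replicates per cell (study value 100).
#' @param n_matings,max_per_sire,theta mate-selection constraints (study:
#'   100 matings, 50 per sire, 25 degrees).
#' @param n_ancestors,n_male_cand,n_female_cand,n_generations herd shape.
#' @param econ an [econ_config()].
#' @param burnin_generations,burnin_pop founder burn-in controls.
#' @param ea list of evolutionary-search controls
#'   (`pop`, `max_gen`, `stall_gen`, `stall_tol`).
#' @param reuse_lambda calibrate the coancestry penalty multiplier once per
#'   scenario (at the base run's target angle) and reuse it across cells
#'   (default TRUE), instead of re-running the bisection in every cell.
#' @param missing_epd_fraction fraction of animals with breed-average EPDs.
#' @param master_seed master seed; all stage seeds are derived substreams.
#' @return class `lof_study_config`.
#' @export
study_config <- function(scenario = "A",
                         weightings = c(0, 0.001, 0.01, 0.1, 1, 10, 100),
                         tiers = seq(0, 100, 10),
                         n_replicates = 100,
                         n_matings = 100, max_per_sire = 50, theta = 25,
                         n_ancestors = 546, n_male_cand = 85,
                         n_female_cand = 169, n_generations = 4,
                         econ = econ_config(),
                         burnin_generations = 1000, burnin_pop = 500,
                         ea = list(pop = 64, max_gen = 2000, stall_gen = 100,
                                   stall_tol = 1e-6),
                         reuse_lambda = TRUE,
                         missing_epd_fraction = 0.1,
                         master_seed = 1) {
  stopifnot(scenario %in% c("A", "B", "C"))
  structure(list(
    scenario = scenario, weightings = weightings, tiers = tiers,
    n_replicates = n_replicates, n_matings = n_matings,
    max_per_sire = max_per_sire, theta = theta,
    n_ancestors = n_ancestors, n_male_cand = n_male_cand,
    n_female_cand = n_female_cand, n_generations = n_generations,
    econ = econ, burnin_generations = burnin_generations,
    burnin_pop = burnin_pop, ea = ea, reuse_lambda = reuse_lambda,
    missing_epd_fraction = missing_epd_fraction,
    master_seed = master_seed
  ), class = "lof_study_config")
}

#' Build the fixed per-scenario study context
#'
#' Generates the pedigree, kinship matrix, EPDs, index values, locus panel,
#' genome map and founder haplotype pool that stay fixed across replicates of
#' a scenario, and calibrates the coancestry penalty multiplier at the target
#' angle (on true-genotype point masses of replicate 1) when
#' `cfg$reuse_lambda` is TRUE.
#'
#' @param cfg a [study_config()].
#' @return class `lof_study_context`.
#' @export
build_study_context <- function(cfg) {
  seed <- cfg$master_seed
  ped <- generate_pedigree(cfg$n_ancestors, cfg$n_male_cand,
                           cfg$n_female_cand, cfg$n_generations,
                           seed = derive_seed(seed, "pedigree"))
  kin <- kinship_matrix(ped)
  model <- trait_model()
  epds <- generate_epds(ped, model, seed = derive_seed(seed, "epd"),
                        missing_fraction = cfg$missing_epd_fraction)
  b <- index_coefficients(model, index_spec())
  m <- animal_index(epds, b)
  panel <- generate_locus_panel(cfg$scenario,
                                seed = derive_seed(seed, "panel"))
  map <- genome_map(panel, seed = derive_seed(seed, "map"))
  pool <- burn_in_founders(panel, map, n_pop = cfg$burnin_pop,
                           n_generations = cfg$burnin_generations,
                           seed = derive_seed(seed, "burnin"))
  ctx <- structure(list(
    cfg = cfg, ped = ped, kin = kin, model = model, epds = epds, b = b,
    m = m, panel = panel, map = map, pool = pool, lambda = NULL
  ), class = "lof_study_context")
  if (isTRUE(cfg$reuse_lambda)) {
    geno <- replicate_genotypes(ctx, 1L)
    probs <- genotype_point_probs(geno)
    mctx <- mating_context(ped, kin, m, probs, panel$freq,
                           n_matings = cfg$n_matings,
                           max_per_sire = cfg$max_per_sire,
                           c_dead = cfg$econ$c_dead)
    sol <- solve_at_degrees(mctx, theta = cfg$theta,
                            seed = derive_seed(seed, "calibrate"),
                            pop = cfg$ea$pop, max_gen = cfg$ea$max_gen,
                            stall_gen = cfg$ea$stall_gen,
                            stall_tol = cfg$ea$stall_tol)
    ctx$lambda <- sol$lambda
    ctx$frontier <- sol$frontier
  }
  ctx
}

#' True genotypes of one replicate
#'
#' @param ctx a [build_study_context()] result.
#' @param replicate replicate number.
#' @return a `lof_genotypes` matrix.
#' @export
replicate_genotypes <- function(ctx, replicate) {
  drop_genotypes(ctx$ped, ctx$pool,
                 seed = derive_seed(ctx$cfg$master_seed, "drop", replicate))
}

#' Run one study cell
#'
#' One (weighting, tier, replicate) combination for the context's scenario
#' and a strategy. True genotypes are sampled for the replicate; the tier's
#' nested random subset is genotyped; ungenotyped animals get segregation-
#' analysis probabilities, and the optimizer sees only those inferred
#' probabilities. Realized outcomes (lethalG, affected calves, `$P`, GLS) are
#' then scored on the true genotypes: decisions use inference, outcomes use
#' truth.
#'
#' @param ctx a [build_study_context()] result.
#' @param strategy 1 (weight on LethalA) or 2 (weight on LethalG).
#' @param weighting penalty weighting for the strategy's criterion.
#' @param tier percentage of the herd genotyped.
#' @param replicate replicate number (drives the genotype sampling).
#' @param geno optional precomputed true genotypes for this replicate.
#' @return one-row data frame (EconReport row).
#' @export
run_cell <- function(ctx, strategy, weighting, tier, replicate = 1L,
                     geno = NULL) {
  cfg <- ctx$cfg
  stopifnot(strategy %in% c(1L, 2L))
  if (is.null(geno)) geno <- replicate_genotypes(ctx, replicate)
  q <- ctx$panel$freq

  if (tier >= 100) {
    probs <- genotype_point_probs(geno)
  } else {
    scheme <- assign_genotyping(
      ctx$ped, tiers = tier,
      seed = derive_seed(cfg$master_seed, "scheme", replicate))
    observed <- mask_genotypes(geno, scheme$sets[[1L]])
    probs <- if (tier <= 0)
      genotype_probabilities(ctx$ped,
                             matrix(NA_integer_, nrow(geno), ncol(geno),
                                    dimnames = dimnames(geno)),
                             q, method = "loopy")
    else genotype_probabilities(ctx$ped, observed, q, method = "loopy")
  }

  mctx <- mating_context(
    ctx$ped, ctx$kin, ctx$m, probs, q,
    n_matings = cfg$n_matings, max_per_sire = cfg$max_per_sire,
    w_a = if (strategy == 1L) weighting else 0,
    w_g = if (strategy == 2L) weighting else 0,
    c_dead = cfg$econ$c_dead)

  ea_seed <- derive_seed(cfg$master_seed, "ea", strategy,
                         round(weighting * 1000), tier, replicate)
  if (!is.null(ctx$lambda)) {
    sol <- ea_optimize(mctx, lambda = ctx$lambda, seed = ea_seed,
                       pop = cfg$ea$pop, max_gen = cfg$ea$max_gen,
                       stall_gen = cfg$ea$stall_gen,
                       stall_tol = cfg$ea$stall_tol)
    matings <- data.frame(mating_no = seq_len(cfg$n_matings),
                          sire = mctx$sires[sol$sidx],
                          dam = mctx$dams[sol$didx],
                          stringsAsFactors = FALSE)
    eval <- sol$eval
    angle <- if (!is.null(ctx$frontier))
      frontier_angle(ctx$frontier, eval) else NA_real_
  } else {
    sol <- solve_at_degrees(mctx, theta = cfg$theta, seed = ea_seed,
                            pop = cfg$ea$pop, max_gen = cfg$ea$max_gen,
                            stall_gen = cfg$ea$stall_gen,
                            stall_tol = cfg$ea$stall_tol)
    matings <- sol$matings
    eval <- sol$eval
    angle <- sol$angle
  }

  # realized outcomes on true genotypes
  true_probs <- genotype_point_probs(geno)
  realized <- lethal_report(matings, true_probs, q,
                            candidates = c(mctx$sires, mctx$dams))
  p_dollars <- profit_per_mating(eval$mean_index, realized$lethalG, cfg$econ,
                                 round = FALSE)
  data.frame(
    scenario = cfg$scenario, strategy = strategy, weighting = weighting,
    pct_genotyped = tier, replicate = replicate,
    meanM = eval$mean_index,
    MB = mb_value(matings, ctx$m),
    coancestry = eval$coancestry, angle = angle,
    lethalA_inferred = eval$lethalA, lethalG_inferred = eval$lethalG,
    lethalA = realized$lethalA, lethalG = realized$lethalG,
    gls = realized$gls,
    P = p_dollars,
    affected_per_100 = 100 * realized$lethalG,
    stringsAsFactors = FALSE
  )
}

#' Run the full factorial sweep of a study
#'
#' Full factorial over weightings x tiers x replicates for both strategies
#' (or a chosen subset), returning the long-format cell table plus per-cell
#' means and standard errors over replicates and the profit-maximizing
#' weighting per strategy. Re-running with the same master seed reproduces
#' the table exactly.
#'
#' @param cfg a [study_config()].
#' @param strategies subset of `c(1, 2)`.
#' @param ctx optionally a prebuilt [build_study_context()].
#' @param progress print per-cell progress to stderr.
#' @return class `lof_study_result`: list with `cells` (long table),
#'   `summary` (means and SEs per scenario/strategy/weighting/tier),
#'   `optimal_weighting` (argmax of mean `$P`; ties go to the smaller
#'   weighting), and `context`.
#' @export
sweep_study <- function(cfg, strategies = c(1L, 2L), ctx = NULL,
                        progress = FALSE) {
  if (is.null(ctx)) ctx <- build_study_context(cfg)
  rows <- list()
  for (r in seq_len(cfg$n_replicates)) {
    geno <- replicate_genotypes(ctx, r)
    for (strategy in strategies) {
      for (w in cfg$weightings) {
        for (tier in cfg$tiers) {
          if (progress)
            message(sprintf("scenario %s strategy %d w=%g tier=%d rep=%d",
                            cfg$scenario, strategy, w, tier, r))
          rows[[length(rows) + 1L]] <-
            run_cell(ctx, strategy, w, tier, r, geno = geno)
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cells[c("meanM", "MB", "lethalA", "lethalG", "gls", "P",
            "affected_per_100")],
    by = cells[c("scenario", "strategy", "weighting", "pct_genotyped")],
    FUN = mean)
  se <- stats::aggregate(
    cells[c("P", "affected_per_100")],
    by = cells[c("scenario", "strategy", "weighting", "pct_genotyped")],
    FUN = function(x) stats::sd(x) / sqrt(length(x)))
  names(se)[names(se) == "P"] <- "P_se"
  names(se)[names(se) == "affected_per_100"] <- "affected_se"
  summary <- merge(summary, se,
                   by = c("scenario", "strategy", "weighting",
                          "pct_genotyped"))
  optimal <- do.call(rbind, lapply(split(
    summary, summary[c("scenario", "strategy", "pct_genotyped")],
    drop = TRUE), function(d) {
      d <- d[order(d$weighting), ]
      d[which.max(d$P), c("scenario", "strategy", "pct_genotyped",
                          "weighting", "P")]
    }))
  rownames(optimal) <- NULL
  structure(list(cells = cells, summary = summary,
                 optimal_weighting = optimal, context = ctx),
            class = "lof_study_result")
}

#' Economic table for one strategy of a study result
#'
#' Derives, per genotyping tier, the savings relative to the base (0%) run,
#' the net profit at the configured test cost, and the breakeven test value,
#' from the mean affected-calf counts of a [sweep_study()] result evaluated
#' at one weighting per strategy.
#'
#' @param result a `lof_study_result`.
#' @param strategy 1 or 2.
#' @param weighting the weighting whose tier curve to tabulate (default: the
#'   profit-maximizing weighting at full genotyping).
#' @param base_affected affected calves per 100 matings of the base run
#'   (default: the weighting-0 tier-0 mean of the result).
#' @return data frame `pct_genotyped, affected_per_100, P, savings,
#'   net_profit, breakeven`.
#' @export
econ_table <- function(result, strategy, weighting = NULL,
                       base_affected = NULL) {
  cfg <- result$context$cfg
  s <- result$summary
  s <- s[s$strategy == strategy, ]
  if (is.null(weighting)) {
    opt <- result$optimal_weighting
    opt <- opt[opt$strategy == strategy &
               opt$pct_genotyped == max(opt$pct_genotyped), ]
    weighting <- opt$weighting[1L]
  }
  if (is.null(base_affected)) {
    b <- result$summary
    b <- b[b$strategy == strategy & b$weighting == min(b$weighting) &
           b$pct_genotyped == min(b$pct_genotyped), ]
    base_affected <- b$affected_per_100[1L]
  }
  s <- s[s$weighting == weighting, ]
  s <- s[order(s$pct_genotyped), ]
  sv <- savings(base_affected, s$affected_per_100, cfg$econ)
  data.frame(
    pct_genotyped = s$pct_genotyped,
    affected_per_100 = s$affected_per_100,
    P = round_cents(s$P),
    savings = round_cents(sv),
    net_profit = round_cents(net_profit(sv, s$pct_genotyped, cfg$econ)),
    breakeven = ifelse(s$pct_genotyped > 0,
                       round_cents(sv / n_tests(s$pct_genotyped)), NA_real_)
  )
}

#' Write a study result's cell table
#'
#' @param result a `lof_study_result`.
#' @param file path.
#' @export
write_study_cells <- function(result, file) {
  utils::write.csv(result$cells, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
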