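#' Context for mate-selection optimization
#'
#' Bundles everything the optimizer needs to score a mating list: candidate
#' index values, the kinship matrix, genotype probabilities for the lethality
#' criteria, and the run constraints. Sires are the male candidates, dams the
#' female candidates; every dam can be used at most once and no sire more
#' than `max_per_sire` times.
#'
#' @param ped a `lof_pedigree` (candidates are taken from it).
#' @param kin kinship matrix over the pedigree.
#' @param m named vector of `$M` index values covering the candidates.
#' @param probs `lof_genoprobs` used for mate-selection decisions (inferred
#'   probabilities at the current genotyping tier, or point masses).
#' @param q_panel per-locus panel allele frequencies.
#' @param n_matings number of matings (study value 100).
#' @param max_per_sire sire usage limit (study value 50).
#' @param w_a,w_g penalty weightings on LethalA and LethalG.
#' @param c_dead cost of one `aa` conception in index dollars (study value
#'   200); converts the lethality probabilities into objective dollars so
#'   that the weighting grid is dimensionless.
#' @param survivor_condition,freq passed to [lethal_a()].
#' @return class `lof_mating_context`.
#' @export
mating_context <- function(ped, kin, m, probs, q_panel, n_matings = 100,
                           max_per_sire = 50, w_a = 0, w_g = 0, c_dead = 200,
                           survivor_condition = TRUE,
                           freq = c("empirical", "panel")) {
  freq <- match.arg(freq)
  sires <- ped$id[ped$role == "candidate" & ped$sex == "M"]
  dams <- ped$id[ped$role == "candidate" & ped$sex == "F"]
  if (n_matings > length(dams))
    stop("more matings than dams: no feasible mating list")
  if (n_matings > length(sires) * max_per_sire)
    stop("more matings than total sire capacity: no feasible mating list")
  cand <- c(sires, dams)
  stopifnot(all(cand %in% names(m)), all(cand %in% rownames(kin)),
            all(cand %in% dimnames(probs)[[1]]))
  Tm <- transmission_matrix(probs)
  q_used <- if (freq == "empirical") colMeans(Tm[cand, , drop = FALSE])
            else q_panel
  pAa <- slice3(probs, 2)
  structure(list(
    sires = sires, dams = dams,
    n_matings = as.integer(n_matings), max_per_sire = as.integer(max_per_sire),
    w_a = w_a, w_g = w_g, c_dead = c_dead,
    survivor_condition = survivor_condition, freq = freq,
    m_sire = unname(m[sires]), m_dam = unname(m[dams]),
    K = kin[cand, cand], n_s = length(sires), n_d = length(dams),
    Ts = Tm[sires, , drop = FALSE], Td = Tm[dams, , drop = FALSE],
    load_sire = drop(pAa[sires, , drop = FALSE] %*% q_panel^2),
    q_panel = q_panel, q_used = q_used
  ), class = "lof_mating_context")
}

#' Score a mating list
#'
#' Computes the components of the penalized objective:
#' mean progeny index, parental coancestry (contributions scaled to 1/2 per
#' sex), LethalA, LethalG, GLS, and
#' `objective = mean index - c_dead (w_a LethalA + w_g LethalG)`;
#' `penalized = objective - lambda * coancestry` is what the evolutionary
#' search maximizes at a given coancestry penalty multiplier.
#'
#' @param ctx a [mating_context()].
#' @param sidx,didx integer vectors (length `n_matings`): positions of each
#'   mating's sire in `ctx$sires` and dam in `ctx$dams`.
#' @param lambda coancestry penalty multiplier (index dollars per unit
#'   coancestry).
#' @return list of components.
#' @export
evaluate_matings <- function(ctx, sidx, didx, lambda = 0) {
  N <- ctx$n_matings
  stopifnot(length(sidx) == N, length(didx) == N)
  if (anyDuplicated(didx) || any(tabulate(sidx, ctx$n_s) > ctx$max_per_sire))
    stop("infeasible mating list")
  mean_index <- (sum(ctx$m_sire[sidx]) + sum(ctx$m_dam[didx])) / (2 * N)

  cnt <- c(tabulate(sidx, ctx$n_s), tabulate(didx, ctx$n_d))
  u <- which(cnt > 0L)
  x <- cnt[u] / (2 * N)
  coan <- drop(x %*% ctx$K[u, u, drop = FALSE] %*% x)

  ts <- ctx$Ts[sidx, , drop = FALSE]
  td <- ctx$Td[didx, , drop = FALSE]
  p_aa <- ts * td
  lG <- mean(1 - exp(rowSums(log1p(-p_aa))))
  p_Aa <- ts * (1 - td) + (1 - ts) * td
  t_prog <- if (ctx$survivor_condition)
    (p_Aa / 2) / pmax(1 - p_aa, .Machine$double.eps)
  else p_Aa / 2 + p_aa
  lA <- 1 - prod(1 - colMeans(t_prog) * ctx$q_used)
  gls <- sum(ctx$load_sire[sidx]) / N

  obj <- mean_index - ctx$c_dead * (ctx$w_a * lA + ctx$w_g * lG)
  list(mean_index = mean_index, coancestry = coan, lethalA = lA,
       lethalG = lG, gls = gls, objective = obj,
       penalized = obj - lambda * coan)
}

# ---- feasible-list construction and repair ---------------------------------

random_list <- function(ctx) {
  N <- ctx$n_matings
  didx <- sample.int(ctx$n_d, N)
  sidx <- integer(N)
  left <- rep(ctx$max_per_sire, ctx$n_s)
  for (k in seq_len(N)) {
    ok <- which(left > 0L)
    pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
    sidx[k] <- pick
    left[pick] <- left[pick] - 1L
  }
  list(sidx = sidx, didx = didx)
}

truncation_list <- function(ctx) {
  N <- ctx$n_matings
  didx <- order(ctx$m_dam, decreasing = TRUE)[seq_len(N)]
  s_ord <- order(ctx$m_sire, decreasing = TRUE)
  counts <- integer(ctx$n_s)
  need <- N
  for (s in s_ord) {
    take <- min(ctx$max_per_sire, need)
    counts[s] <- take
    need <- need - take
    if (need == 0L) break
  }
  list(sidx = rep(seq_len(ctx$n_s), counts), didx = didx)
}

even_list <- function(ctx) {
  N <- ctx$n_matings
  sidx <- rep(seq_len(ctx$n_s), length.out = N)
  didx <- seq_len(ctx$n_d)[seq_len(N)]
  list(sidx = sidx, didx = didx)
}

repair_list <- function(ctx, sidx, didx) {
  N <- ctx$n_matings
  # dams: replace duplicates with unused dams
  dup <- which(duplicated(didx))
  if (length(dup)) {
    unused <- setdiff(seq_len(ctx$n_d), didx)
    didx[dup] <- if (length(unused) == 1L) unused[seq_along(dup)]
                 else sample(unused, length(dup))
  }
  # sires: move excess matings to sires with remaining capacity
  cnt <- tabulate(sidx, ctx$n_s)
  over <- which(cnt > ctx$max_per_sire)
  for (s in over) {
    slots <- which(sidx == s)
    excess <- slots[seq_len(cnt[s] - ctx$max_per_sire)]
    for (k in excess) {
      cnt <- tabulate(sidx, ctx$n_s)
      ok <- which(cnt < ctx$max_per_sire)
      sidx[k] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
  }
  list(sidx = sidx, didx = didx)
}

mutate_list <- function(ctx, ind) {
  N <- ctx$n_matings
  n_ops <- sample.int(3L, 1L)
  for (o in seq_len(n_ops)) {
    op <- sample.int(4L, 1L)
    if (op == 1L) {             # reassign one mating's sire
      k <- sample.int(N, 1L)
      cnt <- tabulate(ind$sidx, ctx$n_s)
      cnt[ind$sidx[k]] <- cnt[ind$sidx[k]] - 1L
      ok <- which(cnt < ctx$max_per_sire)
      ind$sidx[k] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    } else if (op == 2L && N >= 2L) {  # swap two dams between matings
      kk <- sample.int(N, 2L)
      ind$didx[kk] <- ind$didx[rev(kk)]
    } else if (op == 3L) {      # bring in an unused dam
      unused <- setdiff(seq_len(ctx$n_d), ind$didx)
      if (length(unused)) {
        k <- sample.int(N, 1L)
        ind$didx[k] <- if (length(unused) == 1L) unused
                       else sample(unused, 1L)
      }
    } else if (N >= 2L) {       # swap two sires between matings
      kk <- sample.int(N, 2L)
      ind$sidx[kk] <- ind$sidx[rev(kk)]
    }
  }
  ind
}

crossover_list <- function(ctx, a, b) {
  take <- stats::runif(ctx$n_matings) < 0.5
  repair_list(ctx, ifelse(take, a$sidx, b$sidx), ifelse(take, a$didx, b$didx))
}

#' Evolutionary search over feasible mating lists
#'
#' Population-based search maximizing the penalized objective of
#' [evaluate_matings()]. Individuals are feasible mating lists; operators are
#' uniform crossover on the pair assignments with greedy repair to
#' feasibility, plus mutations that move a mating between sires, swap dams or
#' sires between matings, or bring in an unused dam. Elitism guarantees the
#' best objective is non-decreasing over generations. The search stops at the
#' generation cap or when the best objective has improved by less than
#' `stall_tol` over `stall_gen` generations. Deterministic given `seed`.
#'
#' @param ctx a [mating_context()].
#' @param lambda coancestry penalty multiplier.
#' @param pop,max_gen,stall_gen,stall_tol EA hyperparameters.
#' @param seed integer seed.
#' @param init optional list of starting individuals (`list(sidx, didx)`),
#'   e.g. warm starts; the truncation and even-usage heuristics plus random
#'   lists complete the population.
#' @param objective one of `"penalized"` (default), `"index"`,
#'   `"min_coancestry"` - the latter two are used to locate the frontier
#'   endpoints.
#' @return list with `sidx`, `didx`, `eval` (component list), `generations`,
#'   `trace` (best objective per generation).
#' @export
ea_optimize <- function(ctx, lambda = 0, pop = 64, max_gen = 2000,
                        stall_gen = 100, stall_tol = 1e-6, seed = 1,
                        init = NULL, objective = c("penalized", "index",
                                                   "min_coancestry")) {
  objective <- match.arg(objective)
  score_of <- function(ev) switch(objective,
    penalized = ev$penalized,
    index = ev$mean_index,
    min_coancestry = -ev$coancestry)
  with_seed(seed, {
    inds <- list(truncation_list(ctx), even_list(ctx))
    if (!is.null(init)) inds <- c(init, inds)
    while (length(inds) < pop) inds <- c(inds, list(random_list(ctx)))
    inds <- inds[seq_len(pop)]
    evals <- lapply(inds, function(i) evaluate_matings(ctx, i$sidx, i$didx,
                                                       lambda))
    scores <- vapply(evals, score_of, 0)
    best_i <- which.max(scores)
    best <- list(ind = inds[[best_i]], eval = evals[[best_i]],
                 score = scores[best_i])
    trace <- numeric(0)
    stall_ref <- best$score
    stall_at <- 0L
    gen <- 0L
    for (gen in seq_len(max_gen)) {
      new_inds <- vector("list", pop)
      new_inds[[1L]] <- best$ind                   # elitism
      for (k in 2:pop) {
        pick <- function() {
          tt <- sample.int(pop, min(3L, pop))
          inds[[tt[which.max(scores[tt])]]]
        }
        child <- if (stats::runif(1) < 0.7) crossover_list(ctx, pick(), pick())
                 else pick()
        new_inds[[k]] <- mutate_list(ctx, child)
      }
      inds <- new_inds
      evals <- lapply(inds, function(i) evaluate_matings(ctx, i$sidx, i$didx,
                                                         lambda))
      scores <- vapply(evals, score_of, 0)
      gen_best <- which.max(scores)
      if (scores[gen_best] > best$score) {
        best <- list(ind = inds[[gen_best]], eval = evals[[gen_best]],
                     score = scores[gen_best])
      }
      trace <- c(trace, best$score)
      if (best$score > stall_ref + stall_tol) {
        stall_ref <- best$score
        stall_at <- gen
      } else if (gen - stall_at >= stall_gen) break
    }
    list(sidx = best$ind$sidx, didx = best$ind$didx, eval = best$eval,
         generations = gen, trace = trace)
  })
}

#' Frontier endpoints: maximum index and minimum coancestry
#'
#' The maximum-index endpoint is the truncation-selection solution (top dams
#' by `$M`, sire capacity filled in `$M` order), which is exactly optimal for
#' the index axis. The minimum-coancestry endpoint is found by the
#' evolutionary search minimizing `x'Kx`. Axes are normalized to `[0, 1]`
#' between the endpoints; the achieved compromise angle of a solution is
#' `atan2(normalized coancestry reduction, normalized index gain)`, measured
#' from the index axis: 0 degrees at the maximum-index endpoint, 90 degrees
#' at minimum coancestry.
#'
#' @inheritParams ea_optimize
#' @param ... passed to [ea_optimize()] for the minimum-coancestry search.
#' @return class `lof_frontier`: list with `max_index` and `min_coancestry`
#'   endpoint solutions and the axis ranges.
#' @export
frontier_endpoints <- function(ctx, seed = 1, ...) {
  tr <- truncation_list(ctx)
  max_i <- list(sidx = tr$sidx, didx = tr$didx,
                eval = evaluate_matings(ctx, tr$sidx, tr$didx))
  min_c <- ea_optimize(ctx, lambda = 0, seed = derive_seed(seed, "minco"),
                       objective = "min_coancestry", ...)
  structure(list(
    max_index = max_i, min_coancestry = min_c,
    index_range = c(min_c$eval$mean_index, max_i$eval$mean_index),
    coan_range = c(min_c$eval$coancestry, max_i$eval$coancestry)
  ), class = "lof_frontier")
}

#' @rdname frontier_endpoints
#' @param frontier a `lof_frontier`.
#' @param eval an [evaluate_matings()] result.
#' @return `frontier_angle()`: the achieved angle in degrees, in `[0, 90]`.
#' @export
frontier_angle <- function(frontier, eval) {
  gI <- diff(frontier$index_range)
  gC <- diff(frontier$coan_range)
  if (gI <= 1e-12 && gC <= 1e-12) return(0)   # degenerate frontier
  gain <- if (gI <= 1e-12) 1 else
    (eval$mean_index - frontier$index_range[1]) / gI
  red <- if (gC <= 1e-12) 1 else
    (frontier$coan_range[2] - eval$coancestry) / gC
  gain <- min(max(gain, 0), 1)
  red <- min(max(red, 0), 1)
  atan2(red, gain) * 180 / pi
}

#' Optimize matings at a target compromise angle
#'
#' Outer loop around [ea_optimize()]: adjusts the coancestry penalty
#' multiplier `lambda` by bisection until the achieved angle on the
#' normalized index-coancestry frontier is within `tol_deg` of the target
#' (study value 25 degrees), warm-starting each inner search with the best
#' list found so far. If the target cannot be reached (e.g. the frontier is
#' exhausted, or heavy lethality weightings dominate the index axis) the best
#' achieved solution is returned with `converged = FALSE`.
#'
#' @inheritParams ea_optimize
#' @param theta target angle in degrees, 0 = maximum index response,
#'   90 = minimum parental coancestry.
#' @param tol_deg acceptable deviation from `theta`.
#' @param max_outer bisection iteration cap.
#' @param frontier optionally a precomputed [frontier_endpoints()] result.
#' @param ... passed to [ea_optimize()].
#' @return list: `matings` (data frame `mating_no,sire,dam`), `sidx`, `didx`,
#'   `eval`, `angle`, `lambda`, `converged`, `frontier`, and `report`, a
#'   plain list (objective components, achieved degrees, generations, seed,
#'   warnings) suitable for JSON serialization.
#' @export
solve_at_degrees <- function(ctx, theta = 25, tol_deg = 1, max_outer = 12,
                             seed = 1, frontier = NULL, ...) {
  stopifnot(theta >= 0, theta <= 90)
  if (is.null(frontier)) frontier <- frontier_endpoints(ctx, seed = seed, ...)
  finish <- function(sol, lambda, converged) {
    ang <- frontier_angle(frontier, sol$eval)
    matings <- data.frame(
      mating_no = seq_len(ctx$n_matings),
      sire = ctx$sires[sol$sidx], dam = ctx$dams[sol$didx],
      stringsAsFactors = FALSE)
    list(matings = matings, sidx = sol$sidx, didx = sol$didx, eval = sol$eval,
         angle = ang, lambda = lambda, converged = converged,
         frontier = frontier,
         report = c(sol$eval, list(angle = ang, lambda = lambda,
                                   converged = converged, theta = theta,
                                   seed = seed,
                                   generations = sol$generations %||% 0L,
                                   contribution_convention =
                                     "x_i = n_i/(2N), each sex sums to 1/2")))
  }

  gI <- diff(frontier$index_range)
  gC <- diff(frontier$coan_range)
  degenerate <- gI <= 1e-12 && gC <= 1e-12
  run <- function(lambda, it, warm) {
    ea_optimize(ctx, lambda = lambda,
                seed = derive_seed(seed, "ea", it), init = warm, ...)
  }
  base <- run(0, 0L, NULL)
  if (theta <= tol_deg / 2 || degenerate)
    return(finish(base, 0, TRUE))
  warm <- list(list(sidx = base$sidx, didx = base$didx))
  if (theta >= 90 - tol_deg / 2) {
    mc <- frontier$min_coancestry
    return(finish(mc, Inf, TRUE))
  }
  angle_of <- function(sol) frontier_angle(frontier, sol$eval)
  lam_unit <- gI / max(gC, 1e-12)
  lo <- 0
  lo_sol <- base
  hi <- lam_unit
  hi_sol <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    hi_sol <- run(hi, it, warm)
    warm <- c(warm, list(list(sidx = hi_sol$sidx, didx = hi_sol$didx)))
    if (angle_of(hi_sol) >= theta || hi > lam_unit * 2^16 || it >= max_outer)
      break
    lo <- hi
    lo_sol <- hi_sol
    hi <- hi * 4
  }
  best <- if (abs(angle_of(hi_sol) - theta) < abs(angle_of(lo_sol) - theta))
    list(sol = hi_sol, lambda = hi) else list(sol = lo_sol, lambda = lo)
  while (it < max_outer) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    sol <- run(mid, it, warm)
    warm <- c(warm[seq_len(min(length(warm), 3L))],
              list(list(sidx = sol$sidx, didx = sol$didx)))
    ang <- angle_of(sol)
    if (abs(ang - theta) < abs(angle_of(best$sol) - theta))
      best <- list(sol = sol, lambda = mid)
    if (abs(ang - theta) <= tol_deg) break
    if (ang < theta) lo <- mid else hi <- mid
  }
  finish(best$sol, best$lambda,
         abs(angle_of(best$sol) - theta) <= tol_deg)
}

#' Write a mating list CSV (`mating_no,sire,dam`)
#'
#' @param matings the `matings` data frame of a [solve_at_degrees()] result.
#' @param file path.
#' @export
write_matings <- function(matings, file) {
  utils::write.csv(matings, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the solver report of a [solve_at_degrees()] result as JSON
#'
#' Objective components, achieved degrees, the coancestry penalty, seed,
#' generations and the contribution convention. Uses jsonlite when available
#' and falls back to a minimal flat-JSON writer otherwise.
#'
#' @param solution a [solve_at_degrees()] result.
#' @param file path.
#' @export
write_solver_report <- function(solution, file) {
  rep <- solution$report
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
  } else {
    enc <- vapply(rep, function(x) {
      if (is.character(x)) paste0("\"", x, "\"")
      else if (is.logical(x)) tolower(as.character(x))
      else format(x, digits = 15)
    }, "")
    writeLines(paste0("{", paste0("\"", names(rep), "\":", enc,
                                  collapse = ","), "}"), file)
  }
  invisible(file)
}
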