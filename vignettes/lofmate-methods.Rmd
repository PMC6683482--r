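---
title: "Managing recessive lethal alleles by mate selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing recessive lethal alleles by mate selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofmate)
```

## The problem

Recessive loss-of-function (LOF) alleles at essential loci kill homozygous
(`aa`) embryos. In a beef herd they silently tax fertility: a carrier (`Aa`)
bull mated to carrier cows at the same locus loses a quarter of those
conceptions. Once carrier status is observable (by genotyping, or
probabilistically by segregation analysis through the pedigree), a breeder
can respond in two ways:

* **Strategy 1 — select against carriers.** Penalize the use of carrier
  parents regardless of their mates. This reduces the long-run frequency of
  the alleles but discards genetically superior carriers.
* **Strategy 2 — mate allocation against affected offspring.** Keep carriers
  in service but never mate two carriers of the same locus. This eliminates
  short-term losses at almost no cost in genetic merit, but does not purge
  the alleles.

`lofmate` implements a single-generation, single-herd simulation of both
strategies: a synthetic herd, gene dropping of LOF genotypes, genotype
probabilities for ungenotyped animals, an evolutionary mate-selection
optimizer, and the economics of partial herd genotyping.

## Herd and trait model

The synthetic herd mirrors a seedstock Angus herd of 546 ancestors, 85 male
and 169 female selection candidates (the shape used throughout; all counts
are arguments of `generate_pedigree()`). Ancestors are spread over a small
number of overlapping cohorts with per-sire and per-dam usage limits;
candidates form the youngest cohort.

EPDs (expected progeny differences; half the breeding value) are drawn
multivariate normal for seven maternal traits — heifer pregnancy (HP),
calving ease direct (CED) and maternal (CEM), weaning weight direct (WWD)
and maternal (WWM), back fat (FT) and stayability (STAY) — using published
heritabilities and the sparse genetic-correlation structure coded in
`trait_model()`. Two deliberate modeling choices:

* **EPD covariance is a quarter of the genetic covariance.** EPDs are
  parent-average predictions; a quarter of the additive variance is a
  reasonable proxy for the variance of such predictions. This is a choice of
  this package, not an estimate from data.
* **Phenotypic SDs and economic weights default to 1.** The source
  population's scales and index weights are not public, so the maternal
  index `$M` produced by `index_coefficients()`/`animal_index()` is on a
  unitless "synthetic dollar" scale. All dollar outputs are therefore
  comparable within a simulation, never against a published dollar figure.
  Both are configuration parameters, so a user with real parameters can
  supply them.

The index solves the standard selection-index equations `G_cc b = G_co v`
with objective traits (HP, CED, CEM, WWD, WWM, STAY) and criterion traits
(HP, CED, CEM, WWD, WWM, FT). The genetic load score (GLS) is not a trait —
it has zero heritability and no correlations — so it never enters the index
solve; it is computed directly from sire carrier status (see below).

## LOF panels and gene dropping

Three locus panels reproduce the published scenario summaries: A, 7
high-frequency loci (mean allele frequency 0.0847, range 0.0527–0.1001); B,
76 low-frequency loci (0.0112, 0.0004–0.0695, i.e. under a 0.07 cut-off);
C, 50 mixed loci (0.0488, 0.0044–0.1436). `generate_locus_panel()` pins the
range endpoints, draws the rest from a moment-matched beta (A) or gamma
(B, C), and shifts the draw so the panel mean is within 0.005 of the target.

Founder genotypes come from `burn_in_founders()`: a random-mating population
iterated (by default 1000 generations) over a 29-chromosome, 3-Gb genome at
1 cM/Mb with Kosambi recombination (`r(d) = tanh(2d)/2`), mutation at
2.2e-9 per site per generation, and removal of `aa` individuals each
generation. Because the contract is the published panel frequencies, not
drifted ones, terminal frequencies are pinned back to the targets by
resampling allele copies without creating `aa` genotypes. With
`n_generations = 0` the pool is drawn directly from Hardy–Weinberg — the
same distribution for unlinked downstream use, and the scaled-down option
used in fast tests.

`drop_genotypes()` transmits alleles down the pedigree by Mendelian
sampling. Any offspring drawn `aa` at one or more loci is redrawn — the
pedigree records survivors, so the conditional genotype ratios apply (e.g.
`Aa` with probability 2/3 from an `Aa x Aa` mating). The default drop treats
loci as unlinked: the panels place at most 76 loci on 29 chromosomes, and
single-locus lethality accounting is insensitive to linkage, while the
burn-in retains it where it matters for the founder pool. A `"linked"` mode
is available.

## Genotype probabilities (segregation analysis)

`genotype_probabilities()` computes per-locus posteriors
`(P_AA, P_Aa, P_aa)` for every animal given the genotyped subset, Mendelian
transmission and a Hardy–Weinberg founder prior at the panel frequency.
Two engines share one model:

* **Exact variable elimination** (used automatically up to 25 animals, and
  in all oracle tests): correct on arbitrary, including looped, pedigrees.
* **Damped iterative peeling** (loopy belief propagation over
  nuclear-family factors, damping 0.5, tolerance 1e-8, iteration cap 500):
  exact on loop-free pedigrees, a close approximation on looped livestock
  pedigrees, and linear-time in herd size. Messages are vectorized across
  loci, which makes an 800-animal, 76-locus herd practical in R.

Hard Mendelian contradictions are reported naming the offending family.
Posteriors are *not* conditioned on ungenotyped animals being alive (hence
not `aa`) by default, matching standard segregation-analysis output; the
conditioning is available as `condition_alive = TRUE`.

Nested genotyping subsets (`assign_genotyping()`) model partial herd
genotyping: one permutation of the herd defines every tier, so animals
genotyped at 10% stay genotyped at 20% and beyond.

## Lethality metrics

For parents with per-locus transmission probabilities
`t = P_Aa/2 + P_aa`:

* **LethalG** (short-term): probability a progeny dies,
  `1 - prod_l (1 - t_s t_d)` per mating, averaged over the list.
  `100 x LethalG` is the predicted number of affected calves per 100
  matings.
* **LethalA** (long-term): probability a grandprogeny dies under random
  mating of the surviving progeny at current candidate allele frequencies:
  the mean progeny transmission frequency per locus times `q_l`, combined
  across loci the same way. The progeny distribution is survivor-conditioned
  by default (dead progeny cannot breed); candidate frequencies are
  recomputed from the candidates' genotype probabilities (`freq =
  "empirical"`), with the raw panel frequency available as an option. Both
  flags exist because the original definitions leave these points open.
* **GLS**: mating-weighted sire carrier load,
  `sum_s n_s (sum_l P(Aa)_{s,l} q_l^2) / N`.

Multi-locus combination is always the complement of a product — a union of
independent per-locus death events — so every metric stays a probability.

## Mate selection

A mating list is 100 sire–dam pairs (N configurable): every dam at most once
(the dam pool is larger than the list), no sire above 50 matings. The
optimizer maximizes

```
mean progeny index - c_dead * (w_A LethalA + w_G LethalG) - lambda * coancestry
```

where `c_dead` ($200 per `aa` conception) converts mortality probabilities
into index dollars so the dimensionless weighting grid
`0, 0.001, 0.01, 0.1, 1, 10, 100` is meaningful, and progeny index is the
mid-parent `$M` (the unique choice consistent with additive EPDs). Parental
coancestry is `x'Kx` with contributions `x_i = n_i / 2N` (each sex sums to
1/2, so one unrelated pair gives 0.25; self-kinship diagonal terms
included — both conventions are recorded in the solver report because the
reference tool does not document its normalization).

The inner search (`ea_optimize()`) is a seeded evolutionary algorithm:
population 64, uniform crossover on pair assignments with greedy repair,
mutations that move a mating between sires, swap dams or sires, or bring in
an unused dam, tournament selection and one-elite survival, stopping at
2000 generations or after 100 generations without 1e-6 improvement. The
reference optimizer's internals are proprietary; what this package promises
instead is the contract the tests enforce: feasibility of every returned
list, monotone best objective, seeded determinism, and agreement with
exhaustive enumeration on small instances.

The gain–diversity compromise is a target angle on the normalized frontier
between the maximum-index solution (truncation selection, which is exactly
optimal for that axis) and the minimum-coancestry solution (found by the
same search): 0 degrees is maximum index response, 90 degrees minimum
coancestry, and the study runs at 25 degrees. `solve_at_degrees()` bisects
the coancestry penalty `lambda` until the achieved angle is within 1 degree
of the target, warm-starting each inner search. Two honest caveats: on
small instances contribution granularity makes some angles unattainable
(the best achieved solution is returned with `converged = FALSE`), and
under very heavy lethality weightings the index axis itself is sacrificed,
so the 25-degree target may sit off the reachable frontier. Whether the
reference tool normalizes its axes the same way is not documented; this
package's convention is fixed and recorded in the solver report.

## Study driver and economics

`run_cell()` runs one (strategy, weighting, tier, replicate) combination.
The decisions/outcomes split is central: the optimizer sees only the
genotype probabilities available at the genotyping tier, while realized
outcomes (LethalG, affected calves, `$P`, GLS) are scored on the true
genotypes. This is the only reading under which partial genotyping can
change outcomes at all. Per scenario, the pedigree, EPDs and panel are
fixed; replicates resample true genotypes (and with them the genotyping
subsets). All randomness derives from a master seed through named
substreams (`derive_seed()`), so a sweep reproduces byte-identically.

To keep sweeps tractable the coancestry penalty `lambda` is calibrated once
per scenario (at the target angle, on full-information replicate 1, with
zero lethality weighting) and reused across cells; re-running the bisection
in every cell is available by setting `reuse_lambda = FALSE`.

Economics (per 100 matings): `$P = $M - 200 x LethalG`; total loss =
affected x $200; savings at a genotyping tier = (base affected - tier
affected) x $200; net profit = savings - $30 x tests; breakeven = savings /
tests. The test count at a tier is `pct` tests per 100 matings (10% -> 10
tests), the basis consistent with the published tables. Reported dollars
are rounded half-up to cents; internal values are never rounded.

## Problem sizes in tests and the acceptance script

The test suite and `scripts/acceptance.R` choose sizes that keep a complete
run in minutes while leaving every mechanism exercised at full fidelity:
exact-inference oracles run on pedigrees of 4–12 animals (where exhaustive
enumeration over all 3^n genotype configurations is feasible); Monte-Carlo
Mendelian checks use 100,000 offspring; the strategy comparison runs 20
replicates of a 96-animal herd with 16 matings on the mixed-frequency
panel; and the acceptance script runs the full 800-animal herd shape with
100 matings, the 1000-generation burn-in, and 5 replicates for the strategy
comparison. These are the package's own default study sizes for a desk-scale
reproduction; all of them are configuration, not constants.

## What the synthetic data does and does not show

The generator reproduces the herd's *shape* (pedigree size and structure,
EPD covariance structure, panel frequency summaries), not the private
herd's genealogy, EPD scales or economic weights. Consequences:

* Qualitative results — strategy 2 dominating strategy 1 under full
  information, savings saturating with the percentage genotyped, breakeven
  values falling as more of the herd is genotyped — are reproduced and
  tested.
* Published dollar magnitudes that depend on the real index scale ($MB of
  141.03, $P of 113.17, and so on) are *not* reproducible from synthetic
  data and are never asserted. The economic identities connecting printed
  quantities (loss, savings, net profit, breakeven) are reproduced exactly
  from printed inputs, because they are scale-free arithmetic.
* Single generation only: LethalA is computed and optimized, but its
  long-run payoff (allele purging) is outside a one-generation study by
  construction.

## Numerical notes and known limitations

* Iterative peeling is approximate on looped pedigrees (inbreeding loops,
  shared grandparents); the exact engine bounds the error in tests
  (total-variation distance under 1e-6 where enumeration is feasible).
  Loop-heavy pedigrees with strong evidence are the worst case.
* The peeling consistency check is family-local: it names the trio for any
  direct parent–offspring contradiction; a contradiction visible only
  through a longer chain of inference is detected by the exact engine, not
  the loopy one.
* A pointwise "more genotyping never increases posterior entropy" claim is
  false in general (a surprising genotype can raise uncertainty elsewhere);
  the true and tested property is that *expected* posterior entropy cannot
  increase.
* The evolutionary search is stochastic; only seeded determinism and
  small-instance optimality are guaranteed. Published-scale instances (254
  candidates) use the default budgets, which converge well before the
  generation cap in practice.
* Frequency pinning after burn-in means the panels are exact by
  construction; drift during the pedigree drop is real and downward
  (rejection removes `a` alleles), which the tests assert.
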