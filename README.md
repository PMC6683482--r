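# lofmate

Mate selection and genotyping economics for recessive lethal alleles in a
beef herd.

Recessive loss-of-function (LOF) alleles at essential loci kill homozygous
(`aa`) embryos, silently taxing herd fertility. Given the carrier status of
selection candidates — observed by genotyping, or inferred by segregation
analysis for the rest of the herd — a breeder can either select against
carrier parents (strategy 1) or keep carriers and allocate mates so that no
two carriers of the same locus are paired (strategy 2). `lofmate` is a
single-generation simulation toolkit for comparing the two strategies and
for asking how much of a herd is worth genotyping at a given test price.

The package implements the whole pipeline in plain R:

* **Pedigree and kinship** — tabular kinship/coancestry, progeny inbreeding,
  parental coancestry `x'Kx` of a mating list with contributions scaled to
  1/2 per sex (`build_pedigree()`, `kinship_matrix()`,
  `parental_coancestry()`).
* **Synthetic herd** — a 546-ancestor / 85-sire / 169-dam candidate herd
  shape, EPDs drawn from published maternal-trait heritabilities and genetic
  correlations, and LOF locus panels matching three published scenarios:
  7 high-frequency, 76 low-frequency, or 50 mixed-frequency loci
  (`generate_pedigree()`, `generate_epds()`, `generate_locus_panel()`).
* **Gene dropping** — founder haplotypes from a 1000-generation burn-in
  (29 chromosomes, 3 Gb, Kosambi map, mutation 2.2e-9) pinned to the panel
  frequencies, then Mendelian transmission with lethal-homozygote rejection:
  no live animal is ever `aa` (`burn_in_founders()`, `drop_genotypes()`).
* **Segregation analysis** — per-locus genotype probabilities
  `(P_AA, P_Aa, P_aa)` for ungenotyped animals: exact variable elimination
  on small pedigrees, damped iterative peeling on herd-scale ones
  (`genotype_probabilities()`, `assign_genotyping()`).
* **Selection index** — maternal index `$M` from selection-index theory
  (`index_coefficients()`, `animal_index()`), mid-parent progeny index,
  mating-weighted sire mean `$MB`.
* **Lethality metrics** — LethalG (expected progeny mortality of the list),
  LethalA (grandprogeny mortality under random mating of survivors), and
  the sire genetic load score GLS = mating-weighted
  `sum(P(Aa) * q^2) / N` (`lethal_g()`, `lethal_a()`,
  `genetic_load_score()`).
* **Mate-selection optimizer** — a seeded evolutionary algorithm over
  feasible mating lists (100 matings, max 50 per sire, each dam once)
  maximizing progeny index minus weighted lethality penalties, constrained
  to a target angle (25 degrees) on the normalized index-vs-coancestry
  frontier (`ea_optimize()`, `solve_at_degrees()`).
* **Economics** — `$P = $M - 200 x LethalG`, genotyping savings, net profit
  at $30/test and breakeven test value per genotyping tier
  (`profit_per_mating()`, `savings()`, `net_profit()`, `breakeven()`), and
  the full factorial study driver (`study_config()`, `run_cell()`,
  `sweep_study()`, `econ_table()`).

EPD scales and index weights of the original (private) herd are not public,
so `$M` is on a synthetic dollar scale: within-run comparisons and the
scale-free economic identities are meaningful, published dollar magnitudes
are not reproduced. See `vignettes/lofmate-methods.Rmd` for the models,
conventions and limitations.

## Worked example

A miniature herd, full genotyping, strategy 2 (mate allocation against
affected offspring) with weighting 1:

```r
library(lofmate)

cfg <- study_config(
  scenario = "A",                      # 7 high-frequency LOF loci
  n_ancestors = 20, n_male_cand = 5, n_female_cand = 10,
  n_matings = 6, max_per_sire = 3,
  burnin_generations = 0, burnin_pop = 60,
  ea = list(pop = 16, max_gen = 80, stall_gen = 25, stall_tol = 1e-6),
  missing_epd_fraction = 0, master_seed = 11)
ctx <- build_study_context(cfg)

base <- run_cell(ctx, strategy = 2, weighting = 0, tier = 0, replicate = 1)
full <- run_cell(ctx, strategy = 2, weighting = 1, tier = 100, replicate = 1)

base[c("meanM", "lethalG", "affected_per_100", "P")]
#>       meanM   lethalG affected_per_100         P
#> 1 0.4974674 0.1979167         19.79167 -39.08587
full[c("meanM", "lethalG", "affected_per_100", "P")]
#>       meanM lethalG affected_per_100         P
#> 1 0.4567815       0                0 0.4567815
```

Reading the output: with no genotype information the optimizer pairs
carriers of the same locus often enough to lose 19.8 calves per 100 matings
(this miniature herd concentrates matings on very few sires, so carrier
sires are costly), which at $200 per loss wipes out the synthetic-scale
index gain — profit per mating `P = meanM - 200 * lethalG` is deeply
negative. With every candidate genotyped and a weighting of 1 on LethalG,
mate allocation removes all expected losses at a tiny index cost (`meanM`
0.497 to 0.457), so `P` rises to essentially the index itself. `sweep_study()` runs the full weighting-grid x
genotyping-tier x replicate factorial and `econ_table()` turns it into the
savings / net-profit / breakeven accounting.

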