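# hlamatchr

Population-genetic modeling of unrelated-donor searches in HLA-typed
stem-cell donor registries. The package is aimed at transplant
immunogenetics and registry-modeling work: it estimates multi-locus HLA
haplotype frequencies from unphased genotype tables, computes
Hardy-Weinberg match probabilities at the clinical 8/8, 7/8, 6/6 and 5/6
stringencies, and quantifies how *eliminating one HLA locus from matching
consideration* changes a patient's chance of finding a matched donor in a
multi-population registry of given effective size.

## The model

Registry typing gives unphased genotypes (per-locus unordered allele
pairs). With haplotype frequencies $f(h)$ and Hardy-Weinberg equilibrium,
a genotype $g$ has probability
$P(g) = \sum_{\{h_1,h_2\} \vdash g} (2-\delta_{h_1 h_2}) f(h_1) f(h_2)$,
and `em_estimate()` recovers $f$ from unphased data by
expectation-maximization over the phase decompositions. Removing a locus
from the matching requirement is marginalization: `marginalize()` sums the
four-locus table over that locus. A patient from population $p$ finds at
least one donor within mismatch budget $b$ with probability

```math
P_{\mathrm{match}} = \sum_g P_p(g) \Big[ 1 - \prod_k \big(1 - q_k(g)\big)^{N_k} \Big],
```

where $q_k(g)$ is the chance a random population-$k$ donor is within $b$
allele mismatches of $g$ on the considered loci, and
$N_k = \mathrm{donors}_k \times \mathrm{availability}_k$ is the effective
population size. Everything is exact at desk scale (a seeded Monte Carlo
mode covers large supports), and every component is validated against an
independent oracle: gamete counting, simplex grid search, brute-force pair
enumeration, and donor-by-donor registry simulation. See the methods
vignette (`vignettes/match-likelihood-model.Rmd`) for the full account.

Because real registry haplotype tables are proprietary, the package ships
a synthetic-registry generator with known ground truth
(`generate_population_tables()`, `minority_scenario()`) that reproduces
the structural features the model consumes: haplotype-level linkage
disequilibrium, population-specific spectra, a poorly represented minority
population, and availability-discounted donor counts.

## Worked example

```r
library(hlamatchr)

sc <- minority_scenario(seed = sub_seed(1, 1))   # packaged two-population registry
print(sc$registry)
#> HLA donor registry: 2 population(s), loci A/B/C/DRB1
#>   majority         20000 donors x availability 0.60 =    12000.0 effective; 40 haplotypes
#>   minority          1500 donors x availability 0.30 =       450.0 effective; 60 haplotypes

g <- sample_genotypes(sc$truth$tables$minority, 3000, seed = 42)  # typed cohort
fit <- em_estimate(g)                                             # phase-resolving EM
print(fit)
#> EM haplotype frequency fit: n = 3000 genotypes, 59 haplotypes retained
#>   log-likelihood -19156.341539 after 52 iteration(s); converged: TRUE; init: uniform
tv_distance(sc$truth$tables$minority, prune_freq_table(fit$table, 1e-4))
#> [1] 0.03030402

registry_match_likelihood(sc$registry, "minority", "8/8")
#> Match likelihood [minority, 8/8]: 0.564859 (exact)
registry_match_likelihood(sc$registry, "minority", "6/6:A")
#> Match likelihood [minority, 6/6:A]: 0.583043 (exact)
registry_match_likelihood(sc$registry, "minority", "5/6:A")
#> Match likelihood [minority, 5/6:A]: 0.904393 (exact)
registry_match_likelihood(sc$registry, "majority", "8/8")
#> Match likelihood [majority, 8/8]: 0.993182 (exact)
```

The minority patient's chance of an 8/8-matched donor is 0.56 against 0.99
for the majority population; dropping HLA-A from consideration lifts it by
1.8 percentage points at zero mismatches and to 0.90 at the 5/6 criterion.
The end-to-end driver

```r
res <- run_locus_elimination_study(seed = 1, out_dir = "results/locus_elimination")
```

simulates the registry, re-estimates frequencies from a typed cohort,
computes the full locus-drop report from the *estimated* tables, checks
the model's directional properties (6/6 ≥ 8/8, 5/6 ≥ 6/6 and ≥ 7/8,
minority below majority, strictly positive gains), and writes TSV reports
plus metadata. The numbered scripts under `analysis/` run the same
pipeline as a narrated four-stage workflow (simulate → estimate →
baseline likelihoods → locus elimination).

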