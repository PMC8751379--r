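# netprio

Network-based inference of disease risk genes from GWAS loci, and
network-proximity screening of repurposable drugs against the inferred
risk-gene module.

`netprio` is for computational biologists who have (i) a set of GWAS index
SNPs for a complex disease, (ii) a human protein–protein interactome as an
edge list, and (iii) a drug–target table, and who want to go from loci to a
ranked list of repurposing candidates with permutation-based significance
at every step.

## Method in brief

**Step 1 — risk genes.** Each locus contributes the ≤ 20 genes whose TSS
falls in the 2-Mb window centred on its index SNP. One gene per locus is
chosen by Bayesian model selection: for candidate *X<sub>L</sub>* and the
currently selected genes *X<sub>−L</sub>* at the other loci,

&nbsp;&nbsp;&nbsp;&nbsp;P(M₁|X₋L, N) / P(M₀|X₋L, N) = [P(M₁)/P(M₀)] · BF(X_L),

where the Bayes factor is the summed random-walk-with-restart (RWR)
reachability from the candidate to *X<sub>−L</sub>* on the interactome
(q<sub>t+1</sub> = (1−r) W q<sub>t</sub> + r s, r = 0.3, halting at
|Δq|² < 10⁻⁶). A Gibbs sampler sweeps the loci until the sampling
frequencies stabilize (Σ of squared frequency differences < 10⁻⁴). The
top-frequency gene per locus is a risk gene; never-selected candidates
form the local background gene (LBG) control set. Whether the risk genes
clump into a disease module is tested by comparing their largest connected
component against degree-preserving random gene sets.

**Step 2 — drugs.** Each drug's target set *B* is scored against the
risk-gene module *A* by the closest network proximity

&nbsp;&nbsp;&nbsp;&nbsp;⟨d<sub>AB</sub>⟩ = (Σ<sub>a∈A</sub> min<sub>b∈B</sub> d(a,b) + Σ<sub>b∈B</sub> min<sub>a∈A</sub> d(a,b)) / (‖A‖+‖B‖),

standardized to a z-score against 1000 degree-preserving permutations of
both sets; drugs with z < −1.5 are flagged as repurposing candidates.

A synthetic-benchmark module generates interactomes with planted dense
modules, GWAS loci with known true genes, and proximal/distal drug sets,
so the whole pipeline is testable against ground truth with no downloads.
See `vignette("network-prioritization")` for the full model, parameter and
design discussion.

## Worked example

On the default synthetic benchmark (500-node interactome, 20-gene planted
module at density 0.3, 20 loci × 5 candidates, 5 proximal + 45 distal
drugs):

```r
library(netprio)
spec <- benchmark_spec()                     # seeded: fully reproducible
sim  <- simulate_interactome_with_module(spec)
gwas <- simulate_gwas_benchmark(sim$net, sim$planted, spec)

tm   <- build_transition_matrix(sim$net)
cands <- unique(unlist(lapply(gwas$locus_table, `[[`, "candidates")))
W    <- rwr_proximity_matrix(tm, restrict_rows = cands)
post <- gibbs_sample(gwas$locus_table, W, gibbs_config(rng_seed = 7))
post
#> Posterior table: 20 loci, 349 rounds, converged: TRUE
#>   top-candidate frequency: min 0.24, median 0.30, max 0.36

risk <- select_risk_genes(post, gwas$locus_table)
risk
#> Risk gene set: 20 risk genes from 20 loci, 80 background genes
sum(risk$per_locus_choice[names(gwas$truth)] == gwas$truth)
#> [1] 19                                     # 19/20 planted genes recovered

module_significance(sim$net, risk$risk_genes, n_perm = 1000, rng_seed = 8)
#> Disease-module significance (degree-preserving permutation)
#>   observed LCC: 20 of 20 genes (50 internal edges)
#>   null LCC: mean 7.20 (range 1-17), 1000 permutations
#>   one-sided P = 0.000999

drugs <- simulate_drug_target_network(sim$net, sim$planted, spec)
rk <- screen_drugs(sim$net, risk$risk_genes, drugs$drug_targets,
                   n_perm = 200, rng_seed = 9)
head(rk[c("drug_id", "n_targets", "d", "null_mean", "z", "selected")], 6)
#>        drug_id n_targets    d null_mean     z selected
#> 1 drug_prox_05         3 1.26      2.12 -4.84     TRUE
#> 2 drug_prox_01         3 1.00      1.88 -4.46     TRUE
#> 3 drug_prox_04         3 1.22      2.03 -4.42     TRUE
#> 4 drug_prox_02         3 1.17      1.88 -3.78     TRUE
#> 5 drug_prox_03         3 1.30      1.90 -2.95     TRUE
#> 6 drug_dist_21         3 2.96      2.46  2.67    FALSE
```

Reading the output: the sampler converged under the 10⁻⁴ halting rule in
349 rounds and its per-locus top choice recovers 19 of the 20 planted
genes; the selected risk genes form a single 20-gene connected module that
no degree-matched random set approached (P ≈ 0.001); and all five planted
proximal drugs — and no distal drug — clear the z < −1.5 selection cutoff.

The same chain runs from files via `run_screen()` (see
`?run_screen`) or the thin CLI wrapper in `inst/cli/netprio.R`, which
writes `risk_genes.tsv`, `posterior.tsv`, `module_significance.json`,
`drug_ranking.tsv` and a `manifest.json` of every parameter, seed and
input digest.

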