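# admixped

Admixture proportions of **parents, grandparents and
great-grandparents**, inferred from the genome of a single phased
diploid individual.

Standard ancestry estimators (the STRUCTURE/ADMIXTURE model family)
return one admixture proportion per individual, silently assuming
both parents share it. In recently admixed populations they usually
do not, and the information to tell them apart is present in a single
genome: the *length distribution of admixture tracts* reflects how
ancestry was packaged in the recent pedigree. `admixped` models the
K most recent generations of the pedigree explicitly and estimates a
separate admixture proportion for every ancestor at generation K —
useful for individuals exploring family history from their own
genotypes (including adoptees), and for studies of assortative mating
where parents cannot be sampled.

## The model in brief

The hidden state at SNP i is an *ancestral configuration*
AC<sub>i</sub> = (P, C, R):

* P — one phase bit (haplotype-to-pedigree-half assignment; flips at
  the known phase-switch error rate p<sub>p</sub> per bp),
* C — one ancestry bit per generation-K founder (population A or B at
  this site; founder j's ancestry is a Markov chain with per-bp
  switch rates P<sup>j</sup><sub>A→B</sub>, P<sup>j</sup><sub>B→A</sub>),
* R — one bit per meiosis in the pedigree (the Lander–Green
  inheritance arrows; flip with the map recombination fraction).

That is 2<sup>K+1</sup>−1 bits, i.e. N = 8 / 128 / 32768 states for
K = 1 / 2 / 3. Emissions read, per haplotype, the source-population
frequency of the observed allele for the founder the arrows route it
to. Since every bit transitions independently, the transition matrix
is a Kronecker product of 2×2 kernels and the forward update costs
O(N log N) per site (divide-and-conquer, implemented in C++) instead
of O(N²).

The 2<sup>K+1</sup> switch rates are estimated by maximum likelihood
(L-BFGS on logit-transformed box-bounded rates, central
finite-difference gradients, multi-start), and each founder's
admixture proportion is the stationary law of its ancestry chain:

m<sub>0</sub><sup>j</sup> =
P<sup>j</sup><sub>B→A</sub> /
(P<sup>j</sup><sub>A→B</sub> + P<sup>j</sup><sub>B→A</sub>).

Accuracy is always reported as *best-match* mean absolute error:
estimated ancestors are unlabeled up to sibling swaps at each
pedigree node, so the error is minimized over the 2/8/128
pedigree-consistent rotations.

## Worked example

Simulate an admixed population (two source populations split t = 0.6
coalescent units ago, single admixture pulse g = 10 generations ago,
22 chromosomes totalling 100 Mb), prune uninformative SNPs, and infer
the two parental admixture proportions of one sampled individual:

```r
library(admixped)

cfg <- sim_config(n_h = 200, L = 1e8, t = 0.6, g = 10, n_i = 1, seed = 7)
sim <- simulate_admixture(cfg)
#> <admix_sim> 196158 sites on 22 chromosomes, 1 sampled individuals (g = 10)

pruned <- frequency_prune(sim$sites, sim$genomes, d_f = 0.5)
pruned$report
#> <prune_report> frequency (threshold 0.5): 196158 -> 53109 sites

fit <- fit_ml(pruned$genomes[[1]], pruned$sites, K = 1,
              options = fit_options(seed = 7))
fit
#> <fit_result> K = 1, loglik = -34871.504 (converged, 810 evaluations)
#>   m0_hat (population A): 0.656 0.431

truth <- sim$truth[[1]]$generations[[1]]$proportions
round(truth, 3)
#> [1] 0.572 0.523
best_match_error(truth, fit$m0_hat, K = 1)$error
#> [1] 0.08811599
```

The two parents' population-A fractions (truth 0.572 and 0.523) are
recovered as 0.656 and 0.431: the individual's *average* ancestry is
estimated well and the parent asymmetry is resolved up to the
sampling noise of one transmitted gamete per parent (at 100 Mb ≈ 1
Morgan this noise floor is ≈ 0.06; see the methods vignette).

## Command line

```sh
Rscript -e 'quit(status = admixped::cli())' simulate \
    --out-prefix sim --L 2e7 --n-h 200 --n-c 3 --n-i 2 --seed 1
Rscript -e 'quit(status = admixped::cli())' infer \
    --vcf sim.vcf --freqs sim.freqs.tsv --map sim.map.tsv \
    --generation 1 --df 0.5 --seed 1 --out fit.json
Rscript -e 'quit(status = admixped::cli())' evaluate \
    --truth sim.truth.json --fit fit.json --generation 1 --out err.json
```

`infer` accepts any phased biallelic VCF plus a frequency TSV
(`chrom pos allele freqA freqB`, frequencies of the VCF ALT allele in
the two source populations) and a HapMap-style genetic map
(`chrom pos rate cM`). Unphased or multiallelic records are rejected
with line numbers. `--generation` is 1, 2 or 3; `--phase-error-rate`
enables the phase-switch model and (by default) the phase-cleanup
preprocessing.

## Layout

* `R/`, `src/` — state space, HMM + divide-and-conquer forward pass
  (C++), ML fitting, preprocessing, Wright–Fisher simulator with
  tract tracking, best-match evaluation, file I/O, CLI.
* `vignettes/ancestor-admixture.Rmd` — the model, its assumptions,
  numerical choices, what the simulator does and does not emulate,
  and the information limits of scaled-down experiments.
* `tests/testthat/` — unit + property tests per module, and
  `test-acceptance.R` (exact oracles and scaled-down recovery
  experiments).
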