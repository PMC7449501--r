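---
title: "Inferring ancestor admixture proportions from a single phased genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestor admixture proportions from a single phased genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixped)
```

## The problem

Standard admixture estimators (STRUCTURE-family models) report one
admixture proportion per individual, implicitly assuming both parents
share it. For recently admixed individuals this is rarely true, and
the difference is informative: the genome of a child of a European and
a West-African parent and the genome of a child of two 50:50 admixed
parents have the same *average* ancestry but very different *tract
structure*. A fixed-difference site makes the point exactly: under an
A×B mating the heterozygote probability is 1; under two 50:50 admixed
parents it is 0.5.

`admixped` exploits tract structure to decompose a single phased
diploid genome into admixture proportions of each ancestor at
generation K above the focal individual: parents (K = 1),
grandparents (K = 2) or great-grandparents (K = 3), using only the
genome of the focal individual, per-SNP allele frequencies in the two
source populations, and a genetic map.

## The model

### Ancestral configurations

The hidden state at SNP i is the *ancestral configuration*
AC = (P, C, R):

* **P** (1 bit) — the phase arrow. Haplotype assignments can be
  swapped by phasing errors; P records which half of the pedigree
  haplotype 1 currently traces to. P flips at the known per-bp
  phase-switch error rate `pp`.
* **C** (2^K bits) — the population of origin (A or B) of each
  generation-K founder *at this site*. Founders are themselves
  admixed: each founder j's ancestry follows a two-state Markov chain
  along the genome with per-bp switch rates `rateAB[j]`, `rateBA[j]`.
* **R** (2^K − 2 bits) — the recombination arrows of the meioses
  inside the K-generation pedigree (the Lander–Green inheritance
  vector restricted to the modeled generations). Each bit flips
  between adjacent SNPs with the map-derived recombination
  probability.

The state has 2^(K+1) − 1 bits, so the chain has 8, 128 or 32768
states for K = 1, 2, 3. Every bit moves independently, and emissions
read, for each haplotype, the frequency of the observed allele in the
population of the founder that the (P, R) arrows route it to.

Each diploid founder is represented by one "average" haplotype; the
reported proportion of a founder is the stationary proportion of its
ancestry chain, `m0 = rateBA / (rateAB + rateBA)`. By the invariance
principle of maximum likelihood, proportions computed from ML rates
are ML estimates themselves.

### Fast forward pass

Because bits transition independently, the transition matrix is a
Kronecker product of 2×2 kernels. The forward update `T %*% v` is
computed by peeling one bit per level — `N log2(N)` multiply-adds
instead of `N^2` — which is what makes K = 3 (2^30 dense entries per
site) tractable. The state vector is rescaled at every site and log
normalizers accumulated, so likelihoods of genome-scale inputs do not
underflow. Chromosomes are independent chains whose log-likelihoods
add.

### Numerical and design choices

These points are where the design was genuinely open; the choices are
recorded here because they affect reproduction:

* **Bit layout.** Packed index = [P | C left-to-right | R level by
  level, left to right], most significant bit first. `P = 0` routes
  haplotype 1 to the left pedigree half; an R bit 0 picks the left
  child. This makes the divide-and-conquer bipartition equal to
  splitting on the top unpeeled bit.
* **Clamping.** One-step switch probabilities are linear, `d × rate`.
  After pruning, inter-site gaps can make `d × rate` exceed 1; switch
  probabilities are clamped at 0.5, the maximally uninformative value
  for a binary chain.
* **Initial distribution.** The chain's site-1 law: P and R uniform,
  each C bit at its stationary proportion `m0[j]` — the only choice
  consistent with interpreting `m0` as a long-run ancestry fraction.
* **Recombination probabilities.** `rec_prob` between adjacent
  retained SNPs is the genetic distance in Morgans (1 cM = 0.01),
  clamped at 0.5, recomputed across removed sites after pruning.
* **Rate box and transform.** Switch rates live in
  [1e-10, 1e-4] per bp: the expected ancestry-switch rate is of order
  g·ρ ≈ 1e-7 for recent admixture, and the box spans ±3 orders of
  magnitude around it. The optimizer works on a logit transform of
  the *log*-position of the rate inside the box (rates vary over
  orders of magnitude, so a linear-scale logit would be badly
  conditioned). The transformed parameters are additionally boxed to
  [−12, 12]: beyond that the logistic saturates, finite-difference
  gradients vanish, and L-BFGS freezes parameters at the box edge —
  an optimization failure mode we observed, not a theoretical nicety.
* **Optimization.** L-BFGS-B with central finite differences (step
  1e-4 on the transformed scale), relative-improvement tolerance
  1e-7, gradient tolerance 1e-5, max 500 iterations, multi-start.
  The first start is a *jittered centered start* (all `m0` near 0.5,
  total switch rate near 1e-7). The exactly symmetric point is a
  fixed point of the gradient flow — founders are exchangeable, so
  from an exactly symmetric start the optimizer can never break
  symmetry — hence the jitter. Remaining starts draw `m0` uniform on
  (0.1, 0.9) and total rates log-uniform over the box. The reported
  fit is the best restart; mirrored optima (pedigree halves swapped)
  are equivalent and handled by best-match scoring at evaluation
  time.

## Preprocessing

* **Frequency pruning** (default, threshold `d_f = 0.5`) removes
  sites with `|freqA − freqB| < d_f`, keeping the most
  ancestry-informative SNPs — measured to work slightly better than
  LD pruning for this model, and also shrinking the site count.
* **LD pruning** is provided as the PLINK-style alternative: windowed
  greedy thinning (defaults 50 SNPs / step 5 / r² > 0.1), dropping
  the later SNP of each offending pair.
* **Phase-switch cleanup.** A phase error inside two long
  opposite-ancestry tracts leaves a signature: both haplotypes switch
  ancestry at the same position in opposite directions. Each
  haplotype's ancestry is decoded with a rough two-state Viterbi HMM;
  opposite-direction switch pairs closer than `min_tract` (default
  1e5 bp ≈ 0.1 cM) are treated as phasing artifacts and the
  downstream phase is flipped. Genotypes are never altered. Since
  `pp` is a known input, the expected number of switch points is
  `pp × L`; each corrected event removes one, so the rate passed to
  inference is `reduced_pp = pp × (pp·L − corrected)/(pp·L)`, floored
  at `pp/10`.

## The synthetic-data generator

The generator reproduces the standard simulation design for this
class of methods: two populations that diverged `t` (coalescent
units) ago, merged `g = 10` generations ago into an admixed
population evolved under a diploid Wright–Fisher model with
recombination, 22 equal chromosomes, `Ne = 10000`, μ = ρ = 1e-8.

* **Founder panels.** Instead of a coalescent engine, sites are drawn
  at the neutral density `4·Ne·μ·L·H(n_h−1)` with ancestral
  frequencies uniform and population frequencies from a
  Balding–Nichols law with `F = 1 − exp(−t)`; panel haplotypes are
  site-independent Bernoulli draws. This reproduces the
  frequency-divergence structure the HMM consumes (realized Hudson
  F_ST tracks F) at desk speed with no external downloads. It does
  **not** reproduce within-population background LD — so a green test
  here says nothing about robustness to background LD, which is
  exactly what frequency pruning is for on real data.
* **Wright–Fisher phase.** Every haplotype is carried as a mosaic of
  founder tracts; children draw two distinct parents uniformly, and
  each gamete is a crossover mosaic with breakpoints Poisson on a
  hotspot-like map (piecewise-constant rates, log-normal multipliers
  with mean 1). Tracts — hence every ancestor's true admixture
  proportion — are known exactly; the truth record stores them for
  the last three generations of each sampled individual's pedigree.
* **Phase errors** are injected as a Poisson process of switch points
  at rate `pp` per bp; between switch points the haplotype labels
  swap, leaving genotypes untouched.

## Evaluation

Estimated ancestors are unlabeled up to sibling swaps at each
internal pedigree node, so accuracy is the mean absolute error
minimized over the 2^(2^K − 1) pedigree-consistent rotations (2, 8,
128 for K = 1, 2, 3), averaged over individuals. A calibrated naive
baseline guesses each ancestor by drawing from the empirical
distribution of individual proportions in the simulated population.

## What the scaled-down experiments can and cannot show

The package's acceptance experiments run at L = 1e8 bp (≈ 1.06
Morgans total with ρ = 1e-8) with 200 founder haplotypes — 1/30 of
the genome the full-scale design uses. This changes what is
achievable *in principle*, not just statistically convenient:

* A parent's proportion is only observed through the single gamete it
  transmitted. With ~1 Morgan of genome in 22 almost-never-
  recombining chromosomes, the transmitted mosaic is a coarse sample
  of the parent's genome. An oracle that knows the child's tract
  structure perfectly still makes a mean error of ≈ 0.055 (t = 0.2)
  to ≈ 0.062 (t = 0.6) against the parents' true proportions at this
  scale (both floors are recomputed by the acceptance suite from the
  simulator's per-gamete truth). Parental accuracy criteria much
  below that floor cannot be met by any method at this genome
  length.
* Grandparents are observed through a quarter of the genome each, and
  the K = 2 likelihood becomes nearly flat: configurations with
  per-ancestor errors differing by 0.3 can sit within ~1 log unit.
  ML estimates then swing to the rate-box corners; this is a genuine
  property of the model at this scale (the full-scale design reports
  ≈ 7.4% error using 30× more genome).
* Orderings whose full-scale effect size is a few percentage points
  (error decreasing in g; cleanup benefit at pp = 2e-5) are compared
  with paired designs (same seed, one knob changed) to strip founder-
  panel noise, but remain near the resolution limit at this scale.

## Limitations

Two source populations only; a single admixture pulse; `pp` is a
known input, not estimated; `g` does not enter the two-stage model at
all (the likelihood depends only on founder ancestry-switch rates);
tract lengths are implicitly exponential within each founder (the
Markov assumption), which is known to be only an approximation to the
true tract-length distribution; identifiability degrades rapidly with
K, and nothing beyond K = 3 is supported.
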