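---
title: "Simulating population structure and its biases in LD-based historical Ne estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating population structure and its biases in LD-based historical Ne estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldnesim)
```

## The problem

Linkage-disequilibrium (LD) methods estimate the recent historical
effective population size $N_e$ from a single contemporary sample: the
expected squared correlation between alleles at two loci separated by a
recombination distance of $c$ Morgan reflects the effective size roughly
$t = 1/(2c)$ generations before present. Tools built on this signal (GONE
is the best-known) assume a closed, panmictic population. Real cohorts are
rarely that: they are admixed, subdivided with migration, connected to
larger source populations, or carry chromosomal inversions that suppress
recombination in heterozygotes. Each of these violations reshapes LD and
therefore distorts the inferred $N_e$ trajectory, typically as a spurious
decline — sometimes a drastic recent collapse, sometimes a steady slide.

`ldnesim` provides, in one tested package, (i) a forward-in-time
Wright–Fisher simulator able to generate all four kinds of structure,
(ii) a transparent moment-based LD estimator of the $N_e$ trajectory,
(iii) the expected-$N_{eVk}$ baselines the estimates should be compared
with, and (iv) the two remedies that remove the artifacts: restricting
estimation to one inferred group after a PCA screen, and masking the
inverted genomic region.

## The simulation model

The simulator is a discrete-generation diploid Wright–Fisher model with
random mating, implemented in C++ for speed and driven entirely from R.
Each haplotype is a sorted list of derived-allele positions on a uniform
genetic map (default 1 cM/Mb, i.e. $10^{-8}$ Morgan/bp). Per meiosis the
crossover count is Poisson with mean equal to the map length, crossover
positions are uniform, and new mutations arise at rate $\mu L$ per gamete
at uniform positions (infinite-sites in practice: collisions within a
gamete are resampled, and the chance that a new mutation lands on a
segregating position is negligible at the default rates). Only neutral
mutations are modelled, except for the inversion polymorphism below.

Reproduction is parent-centric ("backward migration"): each offspring of
deme $i$ first chooses a parental deme — with probability $m$ a uniformly
chosen other deme in the reciprocal/island model, or the source deme in
the source–sink model, where the source itself never receives migrants —
then two *distinct* parents from that deme with probability proportional
to fitness. This matches the Wright–Fisher engines standard forward
simulators use, and guarantees exact census sizes every generation.
Excluding selfing perturbs $N_{eVk}$ only at order $1/N$ (the
no-selfing Wright–Fisher model has $N_{eVk} \approx N + 1/2$), far below
the resolution of any test here. Demographic events — splits, admixture
(uniform parental deme over the sources, which are then retired),
resizes — are declared in generations before present; generation 0 is the
sampled generation.

### The inversion

A chromosomal inversion is a flag carried by a haplotype. In inversion
heterozygotes, crossovers falling inside the inverted interval are
*discarded*, not relocated — the standard zero-recombination-region
recipe — so suppression is absolute (a property the tests verify exactly
over $10^4$ meioses). The polymorphism is held near frequency $q = 0.5$ by
frequency-dependent selection with per-copy relative fitness

$$ w(q) = 1 - (q - 0.5) \times 0.2, $$

advantageous below $0.5$ and deleterious above. The engine applies $w$
multiplicatively per inverted haplotype ($w^2$ for homozygotes), the form
used by the fitness-callback recipe this model is taken from; a
carrier-level (dominant) variant was tried and rejected because its
restoring force vanishes as $q \to 1$, letting the inversion drift to
fixation in most small-population replicates. Under the per-copy form the
stationary distribution of $q$ at $N = 100$ is approximately
Ornstein–Uhlenbeck with sd $\approx 0.11$, so desk-scale replicates hold
$q \in [0.3, 0.7]$ with high probability. In `balanced` mode a single
inverted haplotype is introduced 1000 generations before present and the
replicate is re-run (on the continuation of its own RNG stream) if the
inversion is lost *or fixed* — either absorbing state abolishes the
polymorphism whose LD signature is being studied. In `recent_low` mode the
introduction happens 50 generations before present, so the inversion is
still rare (~0.15) at sampling; only loss triggers a retry.

## Scenario presets and desk-scale rescaling

Full-scale presets reproduce the study conditions: demes of 500–1000
diploids on a 250-Mb sequence, mutation rate $5\times10^{-9}$ (within the
$1$–$5\times10^{-9}$ range the study quotes; the upper end is the default
because it yields the quoted 0.5–1 million SNPs over 20 pooled
chromosomes), 10,000 total generations, 100 sampled individuals, 20
replicate chromosomes. These are expensive, so every preset also has a
desk variant built by `rescale_scenario()`: deme sizes divided by a factor
$f$ (default 10), $\mu$, map rate and $m$ multiplied by $f$, and times
divided by $f$. This preserves the compound parameters $N\mu$, $Nc$ and
$Nm$ — the quantities population-genetic equilibria depend on — so the
rescaled run sits in the same regime at a fraction of the cost. The desk
genome is 10 Mb over 5 pooled chromosomes, and the run length is raised
where needed to keep at least $10N$ generations of burn-in before the
earliest event.

Two deliberate deviations from uniform rescaling:

* the balanced-inversion pre-period stays at 1000 generations even at
  desk scale — it is an equilibration device (time for the balancing to
  settle near $q = 0.5$), not part of the studied demography;
* the admixture ("synthetic population") bias tests keep the *literal*
  isolation and mixing times ($T = 1000$, $t = 5$) with rescaled deme
  sizes. Rescaling the times too would shift the admixture-LD signal out
  of the estimator's fixed $c$-window and let desk-scale drift LD (ten
  times larger at a fixed $c$) swamp it, inverting the phenomenon the
  scenario exists to show. With literal times the desk runs reproduce it
  cleanly: recent $\hat N_e \approx 45$ against a true post-mix size of
  100, with ancestral estimates near the five-deme sum.

The source–sink decline/expansion variants need post-change sizes the
study design leaves open; the defaults mirror the inversion scenario
(decline to 100 at generation 10; bottleneck to 100 at generation 30 with
recovery at 10; expansion to 10,000 at generation 10) and are ordinary
config parameters.

## The estimator

The estimator is deliberately a transparent moment method, not a
reimplementation of GONE's genetic-algorithm trajectory fit (whose
internal recursions are published elsewhere). Genotypes are treated as
unphased throughout; LD is measured as the squared Pearson correlation of
dosage vectors (composite $r^2$), the standard phase-free surrogate.

All intra-chromosome SNP pairs with genetic distance
$c \in [0.001, 0.05]$ Morgan — the window used by GONE's defaults, whose
lower edge sets the $1/(2c) = 500$-generation horizon — are assigned to 30
log-spaced bins (geometric midpoints; an optional per-bin cap subsamples
pairs with a private seeded RNG stream that leaves the caller's RNG state
untouched). Bins are pooled across chromosomes by pair-count-weighted
averaging; a split-halves mode reproduces the two-pools-averaged protocol.
Each bin then inverts the Sved-type equilibrium expectation

$$ E[r^2] \approx \frac{1}{\alpha + 4 N_e c} + \frac{1}{n},
   \qquad \alpha = 2 \text{ (unphased)}, $$

to

$$ \hat N_e(c) = \frac{1/(\bar r^2 - 1/n) - \alpha}{4c}, \qquad
   t = \frac{1}{2c}, $$

with $n$ the number of diploids. Bins whose corrected $\bar r^2$ leaves
the invertible range $(0, 1/\alpha)$ are dropped and reported in the
trajectory's `dropped` attribute. Genetic distance is taken as map
distance directly: at $c \le 0.05$ the Haldane correction is below 5% and
far inside the estimator's noise. No smoothing or interpolation is done
between bins; the trajectory is reported at the mapped bin times only.

Numerical behaviour worth knowing: on constant-$N$ panmictic data the
recent and mid windows are recovered well (typically within 10–30%), but
the deepest bins ($t \gtrsim 2N$) overestimate $N_e$, because those times
exceed the coalescent depth of the population and $\bar r^2$ saturates
above the asymptote $1/\alpha$ more slowly than the closed form assumes.
This is why window-based comparisons here use the median over a window,
and why desk-scale constant-$N$ checks use $N = 200$ so that the
ancestral window stays within about $2N$ generations.

## The structure screen and the remedies

`genotype_pca()` centres and unit-scales the dosage columns and takes the
top components by singular value, orienting each so its largest-|loading|
SNP is positive (determinism). `assign_groups()` runs seeded multi-start
k-means on the top two components and canonicalizes labels by group size,
then PC1 mean. The default of two groups is a user decision, not
inferred: a within-group sum-of-squares profile can be printed as a hint
but is never auto-applied. PCA + k-means stands in for Bayesian admixture
software by design — the remedy being tested only needs the groups, and
on the low-migration scenarios the two demes separate completely on PC1.
When testing the no-structure null on panmictic cohorts, thin the SNPs
first (LD between nearby columns inflates the leading eigenvalue even
without structure).

`restrict_and_reestimate()` applies the remedy: subset to one inferred
group (at least 10 individuals), re-filter monomorphic and sub-MAF sites,
and re-run the full estimation. `mask_region()` applies the inversion
remedy by discarding every SNP inside the closed interval on every
chromosome.

## What the generator emulates, and what it does not

The simulator reproduces the mechanisms that create the studied biases:
drift LD at scale $1/(\alpha + 4Nc)$, admixture LD from allele-frequency
differences between merged or migrating demes, and the non-recombining
haplotype blocks of an inversion polymorphism. It does not model
overlapping generations, selection beyond the inversion, non-uniform
recombination maps, gene conversion, crossover interference, genotyping
error, or gene flow through the centre of old inversions. Passing tests
therefore show that the estimator and remedies behave correctly under the
idealized mechanisms — not that real data are free of additional
complications. Likewise the desk-scale property tests are directional
reproductions of the full-scale phenomenology (sign tests over 10
replicates), not numeric reproductions of published curves: a moment
estimator at a tenth of the population size cannot, and should not, match
a genetic-algorithm fit at full size point by point.

## Problem sizes and determinism

The test-suite simulations use the desk presets: 5 chromosomes of 10 Mb,
demes of 100–200 diploids, 1000–2000 generations, 10 replicates per
directional claim, with analytic identities (fitness model, NeVk sums,
time mapping, brute-force $r^2$ equivalence, format round-trips) checked
exactly. Every random step flows from one master seed: chromosome seeds
are drawn from it by `sample.int`, each chromosome runs on its own stream
(retries continue that stream), the sampling draw, pair subsampling and
k-means starts take explicit seeds, and the pair subsampler
saves/restores the global RNG state. Two runs with the same seed produce
byte-identical PED/MAP/TSV outputs; the run manifest records a
canonical-JSON md5 of the resolved configuration, stable under key
reordering.
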