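---
title: "Models and methods: cline displacement under partially dominant mating traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cline displacement under partially dominant mating traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinedom)
```

## The scientific question

When two differentiated populations meet and hybridize along a transect, the
geographic cline in a mating-trait allele need not stay where the two
populations first made contact. If the trait allele is *partially dominant* —
heterozygotes express a fraction $d$ of the dominant-homozygote phenotype —
then hybrids resemble the dominant parental phenotype more than the recessive
one. Under assortative mating this biases who backcrosses with whom, and can
push the mating-trait cline off the neutral genomic background, producing
asymmetric introgression of the *recessive* phenotype into the dominant
population's range. `clinedom` implements (i) an individual-based simulator of
this process, (ii) smooth-cline fitting and displacement analysis of its
output, and (iii) a two-locus dominance/epistasis analysis of how a
plumage-like quantitative phenotype maps onto two diagnostic genomic regions,
plus synthetic-data generators so the entire pipeline runs without external
data.

## The simulator

Space is the unit interval. Two species are initialized at generation 0: $K$
individuals uniform on $[0, 0.48]$ homozygous for allele 0 at every locus and
$K$ individuals uniform on $[0.52, 1]$ homozygous for allele 1 (defaults
$K = 800$). Allele 1 at the mating-trait loci is the dominant allele. Each
individual carries 1 or 2 unlinked mating-trait loci and 3 unlinked neutral
loci.

Generations are discrete and non-overlapping, and there are no explicit
sexes: every adult acts once as a mother and is available as a father
(single-sex bookkeeping keeps the model minimal and mirrors the
hybrid-zone-simulator family this design follows). One generation consists
of, for each adult in transect order:

1. **Mate search.** Candidate fathers are drawn without replacement with
   probability proportional to a Gaussian encounter kernel
   $\exp(-(x_m - x_c)^2 / 2\sigma_{mate}^2)$, and each drawn candidate is
   accepted with probability $a^{\Delta^2}$, where $\Delta$ is the absolute
   difference of the two mating-trait phenotypes and $a \in (0, 1]$ is the
   heterospecific:homospecific mating ratio — a maximally different male
   ($\Delta = 1$) is accepted at exactly $a$ times the rate of an identical
   one. After 50 rejected candidates the mother goes unmated for the
   generation (the cap guarantees termination under extreme assortment and
   is configurable). The mating-trait phenotype is the mean over mating loci
   of $\{0, d, 1\}$ for dosages $\{0, 1, 2\}$, with $d$ the dominance
   coefficient.
2. **Fecundity.** The mother's offspring count is Poisson with mean given by
   Beverton–Holt regulation $\mu = R / (1 + (R - 1)\,\rho / \rho_0)$, where
   $\rho$ is the Gaussian-kernel local density (SD $\sigma_{dd} = 0.01$,
   self included, divided by the in-transect kernel mass so a uniform
   population has flat density) and $\rho_0 = 2 K \sigma_{dd} \sqrt{2\pi}$ is
   the kernel density of a uniform population at total carrying capacity
   $2K$. This form makes $\mu = R$ at low density and exactly 1 at uniform
   carrying capacity.
3. **Inheritance and dispersal.** Each offspring receives one uniformly
   sampled allele per parent per locus (free recombination), starts at the
   mother's location, and disperses by a Gaussian step (SD
   $\sigma_{disp}$) reflected at the transect boundaries (reflection
   conserves transect occupancy; absorbing boundaries would leak the
   population).

Default parameters: growth rate $R = 1.05$,
$\sigma_{dd} = 0.01$, $K = 800$ per species, 500 generations, no loss of
hybrid fitness (the `hybrid_fitness` multiplier is a hook fixed at 1), and
the $2 \times 2 \times 2$ scenario grid of 1 or 2 mating loci, $a \in \{0.5,
0.75\}$ and $d \in \{0.5, 0.75\}$.

**Dispersal SD.** The dispersal distance is a free parameter of the model.
The default $\sigma_{disp} = 0.01$ equals the density-dependence SD, giving
the model one natural spatial scale; both are exposed as parameters, as is
the mate-encounter kernel SD (default $\sigma_{disp}$).

### Numerical choices

* The density and encounter kernels are truncated at 6 SD using a sorted
  sliding window; the neglected tail is $< 1.5 \times 10^{-8}$ of the kernel
  mass. If no candidate falls inside a mother's encounter window, the single
  nearest individual is used (its weight dominates all farther candidates by
  eight orders of magnitude or more).
* Without-replacement candidate draws are implemented as with-replacement
  draws that skip already-tried candidates, which is sequentially equivalent.
* The generation loop is compiled (Rcpp) but consumes R's RNG stream, so
  `set.seed()` gives bit-identical trajectories.
* Mothers are processed in order of transect location within a generation.

### Realized density vs nominal carrying capacity

Although $\mu(\rho_0) = 1$ exactly, the *realized* quasi-equilibrium
population size sits below $2K$: the self-term contributes
$\approx 1/(\sigma_{dd}\sqrt{2\pi}) \approx 40$ individuals of kernel density
independent of $K$, and because offspring settle near their mothers while
regulation restores only 5% per generation, families aggregate and the
kernel density an average individual experiences exceeds the uniform
expectation. At $K = 800$ the population fluctuates around roughly 85–95% of
$2K$ (with transient excursions in both directions) and is demographically
stable over hundreds of generations. This is a documented property of the
model, not a failure of regulation; it has no bearing on the cline analyses,
which work with allele frequencies.

## Cline fitting and displacement

For a snapshot, each individual contributes a point (location, allele
frequency), where the frequency is its mean dosage over the locus class
(mating or pooled neutral) divided by 2. `fit_cline()` fits a penalized
thin-plate regression spline `frequency ~ s(location, k = 20)` with REML
smoothness selection (mgcv) and predicts on 1001 evenly spaced locations,
clamped to $[0, 1]$.

*Why REML and k = 20:* smoothness selection by mgcv's `"P-ML"` variant
degenerates on very-low-noise data (its Pearson scale estimate drives heavy
oversmoothing: maximum error 0.07 on a noiseless wide logistic cline,
against $5 \times 10^{-4}$ under REML), and a 10-function basis cannot
track clines narrower than about a tenth of the transect, which these
simulations routinely produce. With $k = 20$ and REML the fit recovers a
noiseless logistic of width 0.1 to within 0.02 everywhere away from the
edges, and on binomially sampled genotypes (400 individuals) recovers the
generating center with bias $< 0.001$. The penalty shrinks unused
flexibility, so wide clines are not overfit.

Derived quantities:

* **Center** — the location where the fitted curve crosses frequency 0.5.
  With several crossings (smoother wiggle), the midpoint of the outermost
  crossings; if the fit is above 0.5 everywhere the crossing exited through
  the recessive-side boundary and the center is 0, below 0.5 everywhere
  gives 1. The "region within half a dispersal distance" of the crossing is
  collapsed to the crossing point itself; the window matters only for
  plotting.
* **Width** — the distance between the outermost 0.1 crossing and the
  outermost 0.9 crossing. For a logistic of
  nominal width $w$ this equals $w \ln 9 / 2$. A never-crossed threshold is
  replaced by the nearer transect boundary and the summary flagged.
* **Movement class** — final centers are classified RH (center < 0.45),
  S (0.45–0.55) or DH (center > 0.55): displaced toward the recessive
  homozygote's side, stable, or displaced toward the dominant homozygote's
  side. The printed bins are discretized labels of these continuous
  cut-points.
* **Displacement** — mating center minus neutral center; positive values
  point toward the dominant-homozygote side. The per-replicate neutral
  center is fitted on the pooled mean frequency of the three neutral loci
  (per-locus fitting is available, but pooling gives the single
  mating/neutral pair per replicate that the paired test needs).
* **Displacement test** — a paired one-sided Wilcoxon signed-rank test of
  mating vs neutral centers (alternative: mating > neutral), exact for
  $\le 25$ untied pairs, normal approximation with tie correction
  otherwise.

Kilometre rescaling of displacement is exposed as
`displacement_km(displacement, dispersal_sd, km_per_dispersal)` with a
*user-supplied* conversion factor: translating transect units into
kilometres requires a real-world dispersal distance, which is knowledge
about a particular natural system rather than about the model, so the
package never chooses the factor itself.

## The experiment grid

`run_experiment()` runs the eight scenarios with derived, recorded seeds
(scenario $i$, replicate $r$ uses `base_seed + 10000 (i - 1) + r`), and
`summarize_grid()` reports per-scenario RH/S/DH frequencies, the pooled DH
frequency, mean and SD of |displacement|, and per-scenario paired Wilcoxon
tests restricted to DH replicates (reported as non-computable below 3 DH
replicates; a pooled-across-scenarios DH test is included for scaled-down
replicate counts). Classification uses final-generation centers; cline
fitting at every snapshot (`fit = "snapshots"`) is available for
center-over-time trajectories but is off by default — at the default
profile it would mean ~19,000 spline fits, and the final-generation
summaries are what the classification and tests need.

**Problem sizes.** The package's default experiment profile is 12 replicates
per scenario (96 runs of 500 generations at $K = 800$), the scale used by
the acceptance analysis and tests; 50 replicates per scenario is the
full design and runs in roughly four times the time. Extinct replicates
are recorded, logged and excluded from summaries.

**Significance threshold.** "Significantly displaced" means the paired
Wilcoxon p-value is below $\alpha = 0.05$.

## Hybrid index, heterozygosity and the two-locus inheritance analysis

For a matrix of diagnostic-SNP dosages (counting personata-type alleles)
with loci labelled by region (43 on chromosome 1A, 49 around ASIP on
chromosome 20 by default):

* **Hybrid index** — mean dosage over non-missing loci / 2.
* **Interclass heterozygosity** — fraction of non-missing loci with dosage 1.
* **Region classes** — per region, alba-type if the region HI $\le 0.25$,
  personata-type if $\ge 0.75$, heterozygote otherwise. The default
  thresholds separate F1-like from backcross-like composites and are
  configurable. Individuals unclassifiable in either region or with more
  than 50% missing data are excluded: an explicit rule rather than a list of
  ambiguous individuals excluded by ID, so the same criterion applies to any
  dataset.
* **Phenotype lookup** — the deterministic 3×3 class table: alba-type ASIP
  (AA) or heterozygous (Ap) genotypes give alba plumage on an alba 1A
  background (aa), alba-like hybrid plumage on aP and intermediate plumage
  on PP; pp gives personata-like hybrid plumage on aa and personata plumage
  on aP or PP; (AA, PP) is the never-observed cell and returns an explicit
  sentinel. Genotype-phenotype associations in real hybrid zones are
  tendencies rather than certainties; the table fixes one deterministic
  default, and alternate tables can be supplied.

**Model comparison.** Candidate models encode each region as additive
(0/0.5/1), completely dominant (heterozygote scored with the dominant
homozygote: alba allele dominant at ASIP, personata allele at 1A) or
partially dominant (heterozygote as a free level), with or without
epistasis (all pairwise products of the two regions' encoding columns), plus
an intercept-only null. The default set applies the same mode to both
regions — the inheritance-mode hypothesis as a series of six models;
`model_set = "full"`
enumerates all per-region combinations, with the caveat that data generated
by the deterministic class-mean mechanism make the ASIP heterozygote exactly
equivalent to AA, so in the full set a chr20-complete-dominance hybrid model
fits such data equally well with fewer parameters and wins on parsimony.

Models are fitted by OLS and ranked by **BIC** (AICc is reported alongside).
BIC is used for the winner flag because it is selection-consistent: under a
true small model, AICc admits a larger model with appreciable probability
(~15–25% across spurious one- and two-parameter extensions at $n = 200$),
which would make generator-recovery claims unreliable. Ties go to the
smaller model. Structural rank deficiencies caused by the empty (AA, PP)
cell are resolved by dropping redundant epistasis columns (the fitted
subspace, RSS and rank do not depend on which collinear column is removed);
a model whose main-effect block is itself deficient — a whole genotype class
absent from the data — is skipped with a diagnostic.

## Synthetic data

* **Crosses** (`simulate_cross_genotypes()`): parental haplotypes are all-0
  or all-1 across each region (diagnostic SNPs fixed in the parental
  populations); gametes switch source haplotype with probability $r$
  between adjacent within-region loci (default $r = 0.005$, small enough
  that each region mostly segregates as a block yet occasionally yields
  recombinant genotypes) and freely between regions; P, F1, F2 and
  backcross classes follow the standard pedigrees; entries go missing
  independently (default 3%). Individuals falling in the (AA, PP) cell are
  resampled by default (viability-style filtering of the never-observed
  genotype).
* **Phenotypes** (`simulate_phenotypes()`): expected class from the lookup
  table, plus Gaussian noise around ordered class means on an arbitrary
  white-plumage-pixel-like scale (defaults 100, 75, 50, 25, 0; only the
  ordering and separation relative to the noise SD matter, since real pixel
  counts are image- and protocol-dependent). A pure-additive mechanism is available
  as a control generator.
* **Transect samples** (`simulate_transect_sample()`): dosages
  $\sim \mathrm{Binomial}(2, p(x))$ along a logistic cline of known center
  and width — the test harness for cline recovery.
* **Composition** (`sample_hybrid_zone_composition()`): multinomial plumage
  classes at frequencies typical of a hybrid-zone transect (33% alba, 29% personata,
  20% alba-like, 4% intermediate, 14% personata-like), at any sample size.

### What the generators do and do not emulate

They reproduce the two-block diagnostic architecture, cross-pedigree
genotype structure, missingness, and the class-mean phenotype mechanism.
They do not emulate sequencing or genotyping error, linkage maps beyond the
two blocks, within-class phenotype structure (e.g. the partially expressed
ASIP heterozygote producing slightly less white plumage than AA), or
population structure. Consequently, passing the recovery tests shows the
estimators are correct under the stated mechanism, not that the mechanism
itself is the truth about any real hybrid zone.

## Known limitations

* Realized density sits below nominal carrying capacity (see above).
* One-dimensional space, no explicit sexes, no linked loci, no extrinsic or
  intrinsic selection against hybrids: all deliberate non-goals.
* The displacement-to-kilometres conversion is user-supplied by design.
* The simulated DH (dominant-homozygote-ward movement) frequency is a
  stochastic outcome over replicate sets; with 96 replicates its binomial
  sampling SD alone is about 5 percentage points.

## A worked run

```{r example, eval = FALSE}
library(clinedom)

# one scenario, three replicates (desk scale)
res <- run_scenario(sim_params(pref_ratio = 0.5, dominance = 0.75),
                    n_replicates = 3, base_seed = 100)
res$replicates[, c("seed", "center_mating", "center_neutral",
                   "movement_class", "displacement")]

# the full grid at the default profile (minutes, not seconds)
results <- run_experiment(default_scenario_grid(), n_replicates = 12,
                          base_seed = 1)
summarize_grid(results)

# inheritance-model recovery on synthetic crosses
dat <- simulate_inheritance_dataset(n = 200, mechanism = "epistatic",
                                    noise_sd = 5, seed = 7)
inheritance_analysis(dat$genotypes, dat$phenotypes$phenotype)$report
```
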