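#' Simulation scenario parameters
#'
#' Builds the full parameterization of one hybrid-zone scenario: a
#' one-dimensional transect of length 1 on which two species, each at
#' carrying capacity `carrying_capacity_per_species`, meet. Mating is
#' assortative on a trait controlled by `n_mating_loci` biallelic loci whose
#' trait allele is partially dominant (`dominance` is the proportion of the
#' dominant-homozygote phenotype expressed by heterozygotes); `pref_ratio` is
#' the ratio of heterospecific to homospecific matings (1 = random mating).
#' Reproduction is density dependent (Beverton-Holt, low-density growth rate
#' `growth_rate`, Gaussian density kernel SD `density_sd`) and offspring
#' disperse with Gaussian SD `dispersal_sd` under reflecting boundaries.
#'
#' @param n_mating_loci number of mate-choice loci (1 or 2).
#' @param n_neutral_loci number of selectively neutral loci.
#' @param pref_ratio heterospecific:homospecific mating ratio in (0, 1].
#' @param dominance dominance coefficient in [0, 1] (0.5 = codominant).
#' @param carrying_capacity_per_species per-species carrying capacity K.
#' @param growth_rate low-density per-generation growth rate R.
#' @param density_sd SD of the Gaussian density-dependence kernel.
#' @param dispersal_sd SD of offspring dispersal (transect units).
#' @param mate_sd SD of the mate-encounter kernel; defaults to `dispersal_sd`.
#' @param range_a,range_b initial range limits of the two species; disjoint
#'   sub-intervals of [0, 1]. Species B (in `range_b`) is fixed for allele 1
#'   at every locus, and the mating-trait allele 1 is the dominant allele.
#' @param n_generations number of generations to simulate.
#' @param snapshot_interval record a snapshot every this many generations.
#' @param hybrid_fitness fecundity multiplier hook (1 = no loss of hybrid
#'   fitness).
#' @param max_mate_rejections mate-search cap: after this many rejected
#'   candidates the mother is unmated for the generation.
#' @param seed integer RNG seed for [run_simulation()]; `NULL` uses the
#'   current RNG state.
#' @return An object of class `sim_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(pref_ratio = 0.5, dominance = 0.75, n_generations = 10)
#' p$dominance
sim_params <- function(n_mating_loci = 1L,
                       n_neutral_loci = 3L,
                       pref_ratio = 0.5,
                       dominance = 0.5,
                       carrying_capacity_per_species = 800L,
                       growth_rate = 1.05,
                       density_sd = 0.01,
                       dispersal_sd = 0.01,
                       mate_sd = dispersal_sd,
                       range_a = c(0, 0.48),
                       range_b = c(0.52, 1),
                       n_generations = 500L,
                       snapshot_interval = 5L,
                       hybrid_fitness = 1,
                       max_mate_rejections = 50L,
                       seed = NULL) {
  p <- list(
    n_mating_loci = as.integer(n_mating_loci),
    n_neutral_loci = as.integer(n_neutral_loci),
    pref_ratio = pref_ratio,
    dominance = dominance,
    carrying_capacity_per_species = as.integer(carrying_capacity_per_species),
    growth_rate = growth_rate,
    density_sd = density_sd,
    dispersal_sd = dispersal_sd,
    mate_sd = mate_sd,
    range_a = as.numeric(range_a),
    range_b = as.numeric(range_b),
    n_generations = as.integer(n_generations),
    snapshot_interval = as.integer(snapshot_interval),
    hybrid_fitness = hybrid_fitness,
    max_mate_rejections = as.integer(max_mate_rejections),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(
    p$n_mating_loci >= 1L, p$n_neutral_loci >= 1L,
    p$pref_ratio > 0, p$pref_ratio <= 1,
    p$dominance >= 0, p$dominance <= 1,
    p$carrying_capacity_per_species >= 1L,
    p$growth_rate > 0, p$density_sd > 0, p$dispersal_sd >= 0, p$mate_sd > 0,
    length(p$range_a) == 2L, length(p$range_b) == 2L,
    p$n_generations >= 0L, p$snapshot_interval >= 1L,
    p$hybrid_fitness >= 0, p$max_mate_rejections >= 1L
  )
  ra <- p$range_a; rb <- p$range_b
  if (ra[1] < 0 || rb[2] > 1 || ra[2] <= ra[1] || rb[2] <= rb[1] ||
      ra[2] > rb[1]) {
    stop("range_a and range_b must be disjoint increasing sub-intervals of [0, 1]")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Hybrid-zone simulation scenario\n")
  cat(sprintf("  mating loci: %d  neutral loci: %d\n",
              x$n_mating_loci, x$n_neutral_loci))
  cat(sprintf("  pref_ratio: %g  dominance: %g\n", x$pref_ratio, x$dominance))
  cat(sprintf("  K per species: %d  growth rate: %g\n",
              x$carrying_capacity_per_species, x$growth_rate))
  cat(sprintf("  density_sd: %g  dispersal_sd: %g  mate_sd: %g\n",
              x$density_sd, x$dispersal_sd, x$mate_sd))
  cat(sprintf("  generations: %d (snapshot every %d)\n",
              x$n_generations, x$snapshot_interval))
  invisible(x)
}

#' Construct a population
#'
#' A population is a set of individuals with 1-D locations and diploid
#' dosage genotypes (count of allele 1) at the mating-trait and neutral loci.
#'
#' @param location numeric vector of positions in [0, 1].
#' @param mating integer matrix (individuals x mating loci) of dominant-allele
#'   dosages in {0, 1, 2}.
#' @param neutral integer matrix (individuals x neutral loci) of allele-1
#'   dosages in {0, 1, 2}.
#' @param generation non-negative generation counter.
#' @param extinct logical flag set when a generation produced no offspring.
#' @return An object of class `population`.
#' @export
population <- function(location, mating, neutral, generation = 0L,
                       extinct = FALSE) {
  mating <- as.matrix(mating); storage.mode(mating) <- "integer"
  neutral <- as.matrix(neutral); storage.mode(neutral) <- "integer"
  n <- length(location)
  stopifnot(nrow(mating) == n, nrow(neutral) == n, generation >= 0)
  if (n > 0) {
    stopifnot(all(location >= 0 & location <= 1),
              all(mating %in% 0:2), all(neutral %in% 0:2))
  }
  structure(list(location = as.numeric(location), mating = mating,
                 neutral = neutral, generation = as.integer(generation),
                 extinct = isTRUE(extinct)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals, generation %d%s\n",
              length(x$location), x$generation,
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

#' Mating-trait phenotype of a genotype
#'
#' Per locus, the dominant homozygote expresses phenotype 1, the recessive
#' homozygote 0, and the heterozygote expresses `dominance` (the proportion of
#' the dominant-homozygote phenotype expressed by heterozygotes). The trait is
#' the mean of the per-locus phenotypes.
#'
#' @param mating_genotype vector of per-locus dominant-allele dosages {0,1,2}.
#' @param dominance dominance coefficient in [0, 1].
#' @return Trait value in [0, 1].
#' @export
#' @examples
#' mating_trait(c(1), 0.75)     # 0.75
#' mating_trait(c(1, 0), 0.5)   # 0.25
mating_trait <- function(mating_genotype, dominance) {
  if (length(mating_genotype) == 0L) stop("empty mating genotype")
  stopifnot(all(mating_genotype %in% 0:2), dominance >= 0, dominance <= 1)
  mean(c(0, dominance, 1)[mating_genotype + 1L])
}

#' Probability that a female accepts an encountered male
#'
#' Gaussian preference kernel `pref_ratio^(delta^2)` with
#' `delta = |trait_female - trait_male|`, calibrated so a maximally different
#' male (delta = 1) is accepted at exactly `pref_ratio` times the rate of an
#' identical male — `pref_ratio` is the heterospecific:homospecific mating
#' ratio.
#'
#' @param trait_female,trait_male mating-trait values in [0, 1] (vectorized).
#' @param pref_ratio ratio in (0, 1].
#' @return Acceptance probability in (0, 1].
#' @export
#' @examples
#' acceptance_probability(0, 1, 0.75)    # 0.75
#' acceptance_probability(0, 0.5, 0.5)   # 0.5^0.25
acceptance_probability <- function(trait_female, trait_male, pref_ratio) {
  if (any(pref_ratio <= 0)) stop("pref_ratio must be > 0")
  pref_ratio^((trait_female - trait_male)^2)
}

#' Kernel-smoothed local density
#'
#' Effective number of neighbors at a location: the Gaussian kernel sum over
#' all individuals (self included) divided by the edge-correction factor
#' `pnorm((1 - x)/sd) - pnorm(-x/sd)` (the kernel mass falling inside the
#' transect), so a uniformly distributed population has spatially flat
#' density.
#'
#' @param location query position in [0, 1].
#' @param pop a [population()] (or any list with a `location` element).
#' @param density_sd kernel SD.
#' @return Effective neighbor count (>= 0).
#' @export
local_density <- function(location, pop, density_sd) {
  stopifnot(density_sd > 0, length(pop$location) > 0)
  ksum <- sum(exp(-0.5 * ((pop$location - location) / density_sd)^2))
  edge <- pnorm((1 - location) / density_sd) - pnorm(-location / density_sd)
  ksum / edge
}

#' Expected offspring number under density regulation
#'
#' Beverton-Holt regulation `mu = R / (1 + (R - 1) * rho / rho0)` where
#' `rho0 = 2 * K * density_sd * sqrt(2 * pi)` is the kernel density expected
#' under a uniform population at total carrying capacity 2K on the unit
#' transect: `mu = R` at low density and exactly 1 at carrying capacity. The
#' result is multiplied by the `hybrid_fitness` hook (1 by default).
#'
#' @param rho local kernel density (see [local_density()]).
#' @param params a [sim_params()] object.
#' @return Poisson mean for the per-mother offspring count.
#' @export
expected_offspring <- function(rho, params) {
  stopifnot(rho >= 0)
  R <- params$growth_rate
  rho0 <- 2 * params$carrying_capacity_per_species * params$density_sd *
    sqrt(2 * pi)
  params$hybrid_fitness * R / (1 + (R - 1) * rho / rho0)
}

#' Choose a father for a mother by kernel-weighted assortative mate search
#'
#' Candidates (all individuals except the mother) are drawn without
#' replacement with probability proportional to the Gaussian encounter kernel
#' `exp(-(x_mother - x_cand)^2 / (2 * mate_sd^2))`; each drawn candidate is
#' accepted with [acceptance_probability()] of the two mating traits. Returns
#' the index of the first accepted candidate, or `NA` once
#' `max_mate_rejections` candidates have been rejected (the mother is then
#' unmated this generation).
#'
#' @param mother_index index of the mother in `pop`.
#' @param pop a [population()].
#' @param params a [sim_params()].
#' @return Integer index of the father in `pop`, or `NA_integer_`.
#' @export
choose_father <- function(mother_index, pop, params) {
  n <- length(pop$location)
  if (n <= 1L) return(NA_integer_)
  cand <- setdiff(seq_len(n), mother_index)
  x <- pop$location[mother_index]
  w <- exp(-0.5 * ((pop$location[cand] - x) / params$mate_sd)^2)
  tf <- mating_trait(pop$mating[mother_index, ], params$dominance)
  rejections <- 0L
  while (rejections < params$max_mate_rejections && length(cand) > 0L) {
    if (all(w <= 0)) break
    k <- sample.int(length(cand), 1L, prob = w)
    tm <- mating_trait(pop$mating[cand[k], ], params$dominance)
    if (runif(1) < acceptance_probability(tf, tm, params$pref_ratio)) {
      return(cand[k])
    }
    cand <- cand[-k]; w <- w[-k]
    rejections <- rejections + 1L
  }
  NA_integer_
}

#' Mendelian offspring genotype
#'
#' At every locus independently, one allele is sampled uniformly from each
#' parent's two alleles (loci are unlinked). The offspring location is the
#' mother's; dispersal is applied separately by [disperse()].
#'
#' @param mother_index,father_index parent indices in `pop`.
#' @param pop a [population()].
#' @return A list with `location`, `mating` and `neutral` dosage vectors.
#' @export
make_offspring <- function(mother_index, father_index, pop) {
  transmit <- function(dosage) {
    ifelse(dosage == 1L, rbinom(length(dosage), 1L, 0.5), dosage %/% 2L)
  }
  list(location = pop$location[mother_index],
       mating = transmit(pop$mating[mother_index, ]) +
         transmit(pop$mating[father_index, ]),
       neutral = transmit(pop$neutral[mother_index, ]) +
         transmit(pop$neutral[father_index, ]))
}

#' Reflect positions into the unit transect
#'
#' @param x numeric positions (any real values).
#' @return Positions folded into [0, 1] by repeated reflection at 0 and 1.
#' @export
#' @examples
#' reflect_unit(c(-0.01, 0.5, 1.03))  # 0.01 0.50 0.97
reflect_unit <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Gaussian natal dispersal with reflecting boundaries
#'
#' @param location positions in [0, 1].
#' @param dispersal_sd dispersal SD (0 = no movement).
#' @return Dispersed positions in [0, 1].
#' @export
disperse <- function(location, dispersal_sd) {
  reflect_unit(location + rnorm(length(location), 0, dispersal_sd))
}

#' Initialize the two-species contact population
#'
#' K individuals uniform on `range_a`, homozygous for allele 0 at every locus
#' (mating trait 0, recessive), and K individuals uniform on `range_b`,
#' homozygous for allele 1 (mating trait 1, dominant); generation 0.
#'
#' @param params a [sim_params()].
#' @return A [population()] of 2K individuals.
#' @export
initialize_population <- function(params) {
  K <- params$carrying_capacity_per_species
  loc <- c(runif(K, params$range_a[1], params$range_a[2]),
           runif(K, params$range_b[1], params$range_b[2]))
  dos <- rep(c(0L, 2L), each = K)
  population(
    location = loc,
    mating = matrix(dos, nrow = 2L * K, ncol = params$n_mating_loci),
    neutral = matrix(dos, nrow = 2L * K, ncol = params$n_neutral_loci),
    generation = 0L
  )
}

#' Advance the population one generation
#'
#' Non-overlapping generations: every adult acts once as mother (mothers are
#' processed in order of transect location), searches for a father
#' ([choose_father()] semantics), and on success produces
#' `Poisson(expected_offspring)` offspring built by Mendelian transmission
#' and dispersed. The returned population contains only the offspring. The
#' loop runs in compiled code implementing exactly this process.
#'
#' @param pop a [population()].
#' @param params a [sim_params()].
#' @return The offspring [population()]; if no offspring were produced the
#'   result is empty with `extinct = TRUE`.
#' @export
run_generation <- function(pop, params) {
  if (length(pop$location) == 0L) {
    return(population(numeric(0),
                      matrix(integer(0), 0, params$n_mating_loci),
                      matrix(integer(0), 0, params$n_neutral_loci),
                      generation = pop$generation + 1L, extinct = TRUE))
  }
  ord <- order(pop$location)
  res <- generation_core(pop$location[ord],
                         pop$mating[ord, , drop = FALSE],
                         pop$neutral[ord, , drop = FALSE],
                         params$dominance, params$pref_ratio,
                         params$density_sd, params$dispersal_sd,
                         params$mate_sd, params$growth_rate,
                         as.numeric(params$carrying_capacity_per_species),
                         params$hybrid_fitness, params$max_mate_rejections)
  population(res$location, res$mating, res$neutral,
             generation = pop$generation + 1L,
             extinct = length(res$location) == 0L)
}

snapshot_frame <- function(pop) {
  n <- length(pop$location)
  data.frame(
    generation = rep(pop$generation, n),
    individual = seq_len(n),
    location = pop$location,
    mating_freq = if (n) rowMeans(pop$mating) / 2 else numeric(0),
    neutral_freq = if (n) rowMeans(pop$neutral) / 2 else numeric(0)
  )
}

#' Run a full hybrid-zone simulation
#'
#' Initializes the two-species contact and runs `n_generations` generations,
#' recording a snapshot at generation 0 and every `snapshot_interval`
#' generations (plus the final generation). Each snapshot row carries an
#' individual's location, its mating-class allele frequency (mean
#' dominant-allele dosage over mating loci / 2) and its neutral-class allele
#' frequency.
#'
#' @param params a [sim_params()]; if `params$seed` is non-`NULL` the RNG is
#'   seeded with it, making the trajectory fully reproducible.
#' @return An object of class `hz_trajectory`: list with `snapshots` (one
#'   stacked data frame), `final` (the final [population()]), `extinct`,
#'   `params`.
#' @export
#' @examples
#' p <- sim_params(carrying_capacity_per_species = 60, n_generations = 5,
#'                 snapshot_interval = 5, seed = 1)
#' tr <- run_simulation(p)
#' unique(tr$snapshots$generation)
run_simulation <- function(params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  pop <- initialize_population(params)
  snaps <- list(snapshot_frame(pop))
  extinct <- FALSE
  if (params$n_generations > 0L) {
    for (g in seq_len(params$n_generations)) {
      pop <- run_generation(pop, params)
      if (pop$extinct) { extinct <- TRUE }
      if (g %% params$snapshot_interval == 0L || g == params$n_generations ||
          extinct) {
        snaps[[length(snaps) + 1L]] <- snapshot_frame(pop)
      }
      if (extinct) break
    }
  }
  structure(list(snapshots = do.call(rbind, snaps), final = pop,
                 extinct = extinct, params = params),
            class = "hz_trajectory")
}

#' @export
print.hz_trajectory <- function(x, ...) {
  gens <- unique(x$snapshots$generation)
  cat(sprintf("hz_trajectory: %d snapshots (generations %d..%d)%s\n",
              length(gens), min(gens), max(gens),
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}
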