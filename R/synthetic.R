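#' Diagnostic-SNP genotype container
#'
#' @param dosage integer matrix (individuals x loci) of personata-allele
#'   dosages in {0, 1, 2}, `NA` = missing; column names are locus ids.
#' @param region character/factor of region labels per locus, `"chr1A"` or
#'   `"chr20"`.
#' @param class optional per-individual cross-class labels.
#' @return An object of class `diagnostic_genotypes`.
#' @export
diagnostic_genotypes <- function(dosage, region, class = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(ncol(dosage) == length(region),
            all(region %in% c("chr1A", "chr20")),
            all(dosage %in% c(0:2, NA)))
  if (!is.null(class)) stopifnot(length(class) == nrow(dosage))
  structure(list(dosage = dosage, region = as.character(region),
                 class = class),
            class = "diagnostic_genotypes")
}

#' @export
print.diagnostic_genotypes <- function(x, ...) {
  cat(sprintf("diagnostic_genotypes: %d individuals x %d loci (chr1A: %d, chr20: %d)\n",
              nrow(x$dosage), ncol(x$dosage), sum(x$region == "chr1A"),
              sum(x$region == "chr20")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Cross-pedigree specification
#'
#' @param counts named integer vector of individuals per cross class; names
#'   from `P_alba`, `P_personata`, `F1`, `F2`, `BC_alba`, `BC_personata`.
#' @param loci named vector with elements `chr1A` and `chr20`: loci per
#'   diagnostic region (defaults 43 and 49).
#' @param r within-region recombination probability between adjacent loci
#'   per meiosis (regions recombine freely with each other).
#' @param missingness independent per-entry missing-data rate.
#' @param seed optional RNG seed.
#' @return An object of class `cross_spec`.
#' @export
cross_spec <- function(counts = c(P_alba = 30, P_personata = 30, F1 = 20,
                                  F2 = 60, BC_alba = 30, BC_personata = 30),
                       loci = c(chr1A = 43, chr20 = 49),
                       r = 0.005, missingness = 0.03, seed = NULL) {
  valid <- c("P_alba", "P_personata", "F1", "F2", "BC_alba", "BC_personata")
  stopifnot(all(names(counts) %in% valid), all(counts >= 0),
            r >= 0, r <= 0.5, missingness >= 0, missingness < 1,
            all(c("chr1A", "chr20") %in% names(loci)), all(loci >= 1))
  structure(list(counts = counts, loci = loci, r = r,
                 missingness = missingness,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cross_spec")
}

# gametes from n diploid parents given as two haplotype matrices (n x L).
# Switching between source haplotypes happens with probability r between
# adjacent within-region loci and probability 0.5 across the region boundary.
make_gametes <- function(hapA, hapB, switch_prob) {
  n <- nrow(hapA); L <- ncol(hapA)
  sw <- matrix(runif(n * (L - 1)) <
                 rep(switch_prob, each = n), n, L - 1)
  state <- matrix(0L, n, L)
  state[, 1] <- as.integer(runif(n) < 0.5)
  for (l in 2:L) state[, l] <- (state[, l - 1] + sw[, l - 1]) %% 2L
  out <- hapA
  out[state == 1L] <- hapB[state == 1L]
  out
}

#' Simulate diagnostic genotypes for cross classes
#'
#' Parental haplotypes are all-0 (alba) or all-1 (personata) across both
#' regions (the diagnostic SNPs are fixed for alternative alleles in the
#' parental populations). Gametes switch source haplotype with probability
#' `r` between adjacent within-region loci and recombine freely between the
#' chr1A and chr20 blocks; classes follow the standard pedigrees (F1 =
#' alba x personata; F2 = F1 x F1; backcrosses = F1 x parental). Missing
#' entries are assigned independently at the `missingness` rate.
#'
#' @param spec a [cross_spec()].
#' @param drop_unobserved resample any individual whose two-region class
#'   combination is the never-observed (AA, PP) cell (viability-style
#'   filtering; only F2-type genotypes can hit it).
#' @return A [diagnostic_genotypes()] with per-individual class labels.
#' @export
#' @examples
#' g <- simulate_cross_genotypes(cross_spec(counts = c(F1 = 5), seed = 1))
#' all(g$dosage == 1, na.rm = TRUE)
simulate_cross_genotypes <- function(spec, drop_unobserved = TRUE) {
  stopifnot(inherits(spec, "cross_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n1A <- spec$loci[["chr1A"]]; n20 <- spec$loci[["chr20"]]
  L <- n1A + n20
  region <- rep(c("chr1A", "chr20"), c(n1A, n20))
  # switch probabilities between adjacent loci; 0.5 across the block boundary
  switch_prob <- rep(spec$r, L - 1)
  switch_prob[n1A] <- 0.5
  alba_hap <- function(n) matrix(0L, n, L)
  pers_hap <- function(n) matrix(1L, n, L)
  f1_gamete <- function(n) make_gametes(alba_hap(n), pers_hap(n), switch_prob)

  gen_class <- function(class, n) {
    if (n == 0) return(NULL)
    switch(class,
      P_alba = alba_hap(n) + alba_hap(n),
      P_personata = pers_hap(n) + pers_hap(n),
      F1 = alba_hap(n) + pers_hap(n),
      F2 = f1_gamete(n) + f1_gamete(n),
      BC_alba = f1_gamete(n) + alba_hap(n),
      BC_personata = f1_gamete(n) + pers_hap(n),
      stop("unknown cross class: ", class)
    )
  }

  counts <- spec$counts[spec$counts > 0]
  dosage <- do.call(rbind, lapply(names(counts), function(cl) {
    gen_class(cl, counts[[cl]])
  }))
  cls <- rep(names(counts), counts)
  storage.mode(dosage) <- "integer"

  if (drop_unobserved) {
    for (iter in 1:100) {
      g <- diagnostic_genotypes(dosage, region, cls)
      ind <- classify_individuals(g)
      bad <- which(!is.na(ind$class_chr20) & !is.na(ind$class_chr1A) &
                     ind$class_chr20 == "AA" & ind$class_chr1A == "PP")
      if (length(bad) == 0) break
      for (b in bad) dosage[b, ] <- gen_class(cls[b], 1L)
    }
  }

  if (spec$missingness > 0) {
    na_mask <- matrix(runif(length(dosage)) < spec$missingness,
                      nrow(dosage), ncol(dosage))
    dosage[na_mask] <- NA_integer_
  }
  rownames(dosage) <- sprintf("ind_%04d", seq_len(nrow(dosage)))
  colnames(dosage) <- paste0(region, "_", unlist(lapply(c(n1A, n20), seq_len)))
  diagnostic_genotypes(dosage, region, cls)
}

#' Phenotype-model specification
#'
#' Class means sit on an arbitrary white-plumage-pixel-like scale, strictly
#' ordered from most white (alba) to least white (personata); only the
#' ordering and the separation relative to `noise_sd` matter.
#'
#' @param means named numeric vector of class means over
#'   [plumage_levels()].
#' @param noise_sd Gaussian noise SD added to the class mean.
#' @param seed optional RNG seed.
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(means = c("alba" = 100, "alba-like hybrid" = 75,
                                     "intermediate" = 50,
                                     "personata-like hybrid" = 25,
                                     "personata" = 0),
                           noise_sd = 5, seed = NULL) {
  stopifnot(identical(sort(names(means)), sort(plumage_levels())),
            noise_sd >= 0)
  m <- means[plumage_levels()]
  if (any(diff(m) >= 0)) {
    stop("class means must be strictly decreasing from alba to personata")
  }
  structure(list(means = m, noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phenotype_spec")
}

#' Simulate phenotypes from genotypes under the two-locus mechanism
#'
#' Classifies each individual's two diagnostic regions, looks up the expected
#' plumage class ([phenotype_class_lookup()]) and draws the phenotype as the
#' class mean plus Gaussian noise. Unclassifiable individuals and any
#' individual in the unobserved (AA, PP) cell are flagged and their phenotype
#' withheld (`NA`).
#'
#' @param geno a [diagnostic_genotypes()].
#' @param pspec a [phenotype_spec()].
#' @param mechanism `"epistatic"` (the class-lookup mechanism, default) or
#'   `"additive"` (phenotype linear in the two regions' additive scores:
#'   a pure additive two-locus control model on the same scale).
#' @return A data frame: `individual`, `class_chr20`, `class_chr1A`,
#'   `plumage_class`, `phenotype`, `flagged`.
#' @export
simulate_phenotypes <- function(geno, pspec,
                                mechanism = c("epistatic", "additive")) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(geno, "diagnostic_genotypes"),
            inherits(pspec, "phenotype_spec"))
  if (!is.null(pspec$seed)) set.seed(pspec$seed)
  ind <- classify_individuals(geno)
  cls <- as.character(ind$plumage_class)
  if (mechanism == "epistatic") {
    mu <- unname(pspec$means[cls])  # NA for unobserved/unclassified
  } else {
    score <- function(f) (as.integer(f) - 1) / 2  # 0 / 0.5 / 1
    span <- pspec$means[["alba"]] - pspec$means[["personata"]]
    mu <- pspec$means[["alba"]] -
      span * (score(ind$class_chr20) + score(ind$class_chr1A)) / 2
    mu[is.na(ind$class_chr20) | is.na(ind$class_chr1A)] <- NA_real_
  }
  flagged <- is.na(mu)
  phen <- mu + rnorm(length(mu), 0, pspec$noise_sd)
  phen[flagged] <- NA_real_
  data.frame(individual = ind$individual,
             class_chr20 = ind$class_chr20, class_chr1A = ind$class_chr1A,
             plumage_class = ind$plumage_class,
             phenotype = phen, flagged = flagged)
}

#' Simulate a full inheritance-analysis dataset
#'
#' Cross genotypes plus phenotypes generated under a chosen mechanism, sized
#' by scaling the default cross mix to about `n` individuals.
#'
#' @param n total number of individuals.
#' @param mechanism passed to [simulate_phenotypes()].
#' @param noise_sd phenotype noise SD (default 5, i.e. 5% of the 0-100
#'   class-mean range).
#' @param r within-region recombination probability.
#' @param missingness per-entry missing rate.
#' @param seed RNG seed.
#' @return A list with `genotypes` and `phenotypes`.
#' @export
simulate_inheritance_dataset <- function(n = 200,
                                         mechanism = c("epistatic", "additive"),
                                         noise_sd = 5, r = 0.005,
                                         missingness = 0.03, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.null(seed)) set.seed(seed)
  mix <- c(P_alba = 0.15, P_personata = 0.15, F1 = 0.10, F2 = 0.30,
           BC_alba = 0.15, BC_personata = 0.15)
  counts <- round(mix * n)
  geno <- simulate_cross_genotypes(
    cross_spec(counts = counts, r = r, missingness = missingness)
  )
  phen <- simulate_phenotypes(geno, phenotype_spec(noise_sd = noise_sd),
                              mechanism = mechanism)
  list(genotypes = geno, phenotypes = phen)
}

#' Sample genotype points along a known logistic cline
#'
#' Test harness for the cline module: locations uniform on [0, 1] and
#' per-individual dosage `Binomial(2, p(x))` with
#' `p(x) = 1 / (1 + exp(-4 (x - center) / width))`; frequency = dosage / 2.
#'
#' @param center cline center in [0, 1].
#' @param width cline width (> 0); the 0.1/0.9-crossing width of this shape
#'   is `width * log(9) / 2`.
#' @param n number of individuals (>= 20).
#' @param seed optional RNG seed.
#' @return A data frame with columns `location`, `frequency`.
#' @export
simulate_transect_sample <- function(center, width, n, seed = NULL) {
  stopifnot(width > 0, n >= 20)
  if (!is.null(seed)) set.seed(seed)
  loc <- runif(n)
  p <- plogis(4 * (loc - center) / width)
  data.frame(location = loc, frequency = rbinom(n, 2, p) / 2)
}

#' Sample hybrid-zone plumage-class composition
#'
#' Multinomial draw over the five plumage classes at frequencies typical of a
#' phenotyped hybrid-zone transect sample: 33% alba, 29% personata, 20%
#' alba-like hybrids, 4% intermediates and 14% personata-like hybrids
#' (a composition characteristic of samples of about n = 104).
#'
#' @param n number of individuals.
#' @param seed optional RNG seed.
#' @return Factor of plumage-class labels over [plumage_levels()].
#' @export
sample_hybrid_zone_composition <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- c("alba" = 0.33, "personata" = 0.29, "alba-like hybrid" = 0.20,
             "intermediate" = 0.04, "personata-like hybrid" = 0.14)
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = plumage_levels())
}
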