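#' Hybrid index of a diagnostic-SNP genotype
#'
#' Composite genotype scaled 0 to 1: the mean dosage of one population's
#' diagnostic alleles over the non-missing loci, divided by 2. By package
#' convention dosages count personata-type alleles, so 0 is a pure alba
#' composite and 1 a pure personata composite.
#'
#' @param dosages per-locus dosages in {0, 1, 2}, `NA` = missing.
#' @return Hybrid index in [0, 1]; `NA` (with a warning) if all loci are
#'   missing.
#' @export
#' @examples
#' hybrid_index(c(2, 2, NA, 0))  # 2/3
hybrid_index <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) {
    warning("all loci missing: hybrid index undefined")
    return(NA_real_)
  }
  stopifnot(all(dosages[ok] %in% 0:2))
  mean(dosages[ok]) / 2
}

#' Interclass heterozygosity of a diagnostic-SNP genotype
#'
#' Fraction of non-missing diagnostic loci at which the individual carries
#' one allele from each parental population (dosage 1).
#'
#' @inheritParams hybrid_index
#' @return Heterozygosity in [0, 1]; `NA` (with a warning) if all loci are
#'   missing.
#' @export
#' @examples
#' interclass_heterozygosity(c(1, 0, NA, 2))  # 1/3
interclass_heterozygosity <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) {
    warning("all loci missing: heterozygosity undefined")
    return(NA_real_)
  }
  stopifnot(all(dosages[ok] %in% 0:2))
  mean(dosages[ok] == 1)
}

#' Classify a genomic region's composite genotype
#'
#' Maps a region's hybrid index (and heterozygosity, accepted for alternate
#' user-supplied rules) to one of three genotype classes: alba-type for
#' HI <= `lower`, personata-type for HI >= `upper`, heterozygote otherwise.
#'
#' @param hi region hybrid index (vectorized).
#' @param het region heterozygosity (unused by the default HI-threshold rule;
#'   kept so alternate classifiers share the signature).
#' @param lower,upper HI thresholds (defaults 0.25 and 0.75, chosen to
#'   separate F1-like from backcross-like composites).
#' @return Factor with levels `alba-type`, `heterozygote`, `personata-type`;
#'   `NA` for undefined HI.
#' @export
classify_region_genotype <- function(hi, het = NULL, lower = 0.25,
                                     upper = 0.75) {
  stopifnot(lower < upper)
  cls <- ifelse(is.na(hi), NA_character_,
                ifelse(hi <= lower, "alba-type",
                       ifelse(hi >= upper, "personata-type", "heterozygote")))
  factor(cls, levels = c("alba-type", "heterozygote", "personata-type"))
}

region_class_codes <- list(
  chr20 = c("alba-type" = "AA", "heterozygote" = "Ap", "personata-type" = "pp"),
  chr1A = c("alba-type" = "aa", "heterozygote" = "aP", "personata-type" = "PP")
)

#' Plumage classes
#' @return Character vector of the five plumage classes in alba-to-personata
#'   order (the `unobserved` sentinel excluded).
#' @export
plumage_levels <- function() {
  c("alba", "alba-like hybrid", "intermediate", "personata-like hybrid",
    "personata")
}

default_phenotype_table <- function() {
  # rows: chr20 ASIP class (AA / Ap / pp); cols: chr1A class (aa / aP / PP).
  # Capital letters mark the partially dominant allele of each region (A =
  # alba allele at ASIP, P = personata allele at 1A). The (AA, PP) cell is
  # never observed and returns an explicit sentinel.
  matrix(c("alba", "alba-like hybrid", "unobserved",
           "alba", "alba-like hybrid", "intermediate",
           "personata-like hybrid", "personata", "personata"),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("AA", "Ap", "pp"), c("aa", "aP", "PP")))
}

#' Expected plumage class of a two-region genotype
#'
#' Deterministic lookup of the expected head-plumage class from the genotype
#' classes of the ASIP region (chromosome 20; alba allele A partially
#' dominant) and the chromosome-1A region (personata allele P partially
#' dominant): alba-type ASIP genotypes (AA or Ap) give alba plumage on an
#' alba 1A background (aa), alba-like hybrid plumage with a 1A heterozygote
#' (aP) and intermediate plumage with a personata 1A genotype (PP); the
#' personata-type ASIP homozygote (pp) gives personata-like hybrid plumage on
#' an alba 1A background and personata plumage otherwise. The (AA, PP)
#' combination is never observed and maps to the `"unobserved"` sentinel.
#'
#' @param chr20_class ASIP genotype class: `"AA"`, `"Ap"` or `"pp"`
#'   (vectorized).
#' @param chr1A_class chromosome-1A class: `"aa"`, `"aP"` or `"PP"`.
#' @param table optional alternate 3x3 lookup table (rows AA/Ap/pp, columns
#'   aa/aP/PP).
#' @return Factor over the five plumage classes plus `"unobserved"`; `NA` in,
#'   `NA` out.
#' @export
#' @examples
#' phenotype_class_lookup("AA", "aa")  # alba
#' phenotype_class_lookup("pp", "aa")  # personata-like hybrid
phenotype_class_lookup <- function(chr20_class, chr1A_class,
                                   table = default_phenotype_table()) {
  stopifnot(identical(dim(table), c(3L, 3L)))
  chr20_class <- as.character(chr20_class)
  chr1A_class <- as.character(chr1A_class)
  ok <- !is.na(chr20_class) & !is.na(chr1A_class)
  stopifnot(all(chr20_class[ok] %in% rownames(table)),
            all(chr1A_class[ok] %in% colnames(table)))
  out <- rep(NA_character_, length(chr20_class))
  out[ok] <- table[cbind(chr20_class[ok], chr1A_class[ok])]
  factor(out, levels = c(plumage_levels(), "unobserved"))
}

#' Classify individuals from a diagnostic genotype matrix
#'
#' Computes overall and per-region hybrid index and interclass
#' heterozygosity, the per-region genotype classes, and the expected plumage
#' class for each individual. Individuals that are unclassifiable in either
#' region or exceed `max_missing` missingness are flagged `excluded` (the
#' generalization of excluding ambiguous recombinant individuals by ID).
#'
#' @param geno a [diagnostic_genotypes()] object.
#' @param lower,upper HI classification thresholds, see
#'   [classify_region_genotype()].
#' @param max_missing maximum tolerated per-individual missing fraction.
#' @return A data frame with one row per individual: `individual`, `hi`,
#'   `het`, per-region `hi_*`/`het_*`, `class_chr20`, `class_chr1A`,
#'   `plumage_class`, `missing_fraction`, `excluded`.
#' @export
classify_individuals <- function(geno, lower = 0.25, upper = 0.75,
                                 max_missing = 0.5) {
  stopifnot(inherits(geno, "diagnostic_genotypes"))
  d <- geno$dosage
  is20 <- geno$region == "chr20"
  is1A <- geno$region == "chr1A"
  row_stat <- function(cols, f) {
    apply(d[, cols, drop = FALSE], 1, function(x) suppressWarnings(f(x)))
  }
  hi20 <- row_stat(is20, hybrid_index)
  hi1A <- row_stat(is1A, hybrid_index)
  het20 <- row_stat(is20, interclass_heterozygosity)
  het1A <- row_stat(is1A, interclass_heterozygosity)
  c20 <- classify_region_genotype(hi20, het20, lower, upper)
  c1A <- classify_region_genotype(hi1A, het1A, lower, upper)
  code20 <- factor(unname(region_class_codes$chr20[as.character(c20)]),
                   levels = c("AA", "Ap", "pp"))
  code1A <- factor(unname(region_class_codes$chr1A[as.character(c1A)]),
                   levels = c("aa", "aP", "PP"))
  miss <- rowMeans(is.na(d))
  data.frame(
    individual = rownames(d) %||% as.character(seq_len(nrow(d))),
    hi = row_stat(rep(TRUE, ncol(d)), hybrid_index),
    het = row_stat(rep(TRUE, ncol(d)), interclass_heterozygosity),
    hi_chr20 = hi20, het_chr20 = het20,
    hi_chr1A = hi1A, het_chr1A = het1A,
    class_chr20 = code20, class_chr1A = code1A,
    plumage_class = phenotype_class_lookup(code20, code1A),
    missing_fraction = miss,
    excluded = is.na(code20) | is.na(code1A) | miss > max_missing,
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

encode_region <- function(classes, mode, region = c("chr20", "chr1A")) {
  region <- match.arg(region)
  # numeric score = personata-ness of the composite genotype
  lev <- if (region == "chr20") c("AA", "Ap", "pp") else c("aa", "aP", "PP")
  cls <- factor(as.character(classes), levels = lev)
  if (mode == "additive") {
    m <- matrix(c(0, 0.5, 1)[as.integer(cls)], ncol = 1)
    colnames(m) <- paste0(region, "_score")
  } else if (mode == "dominant") {
    # the heterozygote is scored with the dominant homozygote: the alba
    # allele is dominant at chr20 (Ap == AA), the personata allele at chr1A
    # (aP == PP)
    sc <- if (region == "chr20") c(0, 0, 1) else c(0, 1, 1)
    m <- matrix(sc[as.integer(cls)], ncol = 1)
    colnames(m) <- paste0(region, "_dom")
  } else if (mode == "partial") {
    # heterozygote as a free level: indicators vs the alba-type baseline
    m <- cbind(as.numeric(cls == lev[2]), as.numeric(cls == lev[3]))
    colnames(m) <- paste0(region, "_", lev[2:3])
  } else {
    stop("unknown inheritance mode: ", mode)
  }
  m
}

#' Numeric design encodings for the inheritance-model comparison
#'
#' Builds, per inheritance model, the numeric design matrix over the
#' two-region genotype classes. Modes per region: `additive` (codominant
#' score 0/0.5/1), `dominant` (heterozygote scored with the dominant
#' homozygote: alba allele dominant at chr20, personata allele dominant at
#' chr1A) and `partial` (heterozygote as a free level, two indicator
#' columns). Epistasis adds all pairwise products of the two regions'
#' encoding columns. The default model set applies the same mode to both
#' regions (the inheritance-mode hypothesis: 3 modes x with/without
#' epistasis, plus an intercept-only null); `model_set = "full"` enumerates
#' all per-region mode combinations.
#'
#' @param class_chr20,class_chr1A per-individual region classes (`AA/Ap/pp`
#'   and `aa/aP/PP`); individuals with `NA` in either region are excluded
#'   with a message.
#' @param model_set `"shared"` (default) or `"full"`.
#' @return A list with `designs` (named list of design matrices, `NULL` for
#'   the null model), `keep` (logical row filter applied), `n_excluded`.
#' @export
build_model_designs <- function(class_chr20, class_chr1A,
                                model_set = c("shared", "full")) {
  model_set <- match.arg(model_set)
  keep <- !is.na(class_chr20) & !is.na(class_chr1A)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " unclassified individual(s) excluded from designs")
  }
  c20 <- class_chr20[keep]
  c1A <- class_chr1A[keep]
  modes <- c("additive", "dominant", "partial")
  combos <- if (model_set == "shared") {
    data.frame(m20 = modes, m1A = modes)
  } else {
    expand.grid(m20 = modes, m1A = modes, stringsAsFactors = FALSE)
  }
  designs <- list(null = NULL)
  for (i in seq_len(nrow(combos))) {
    e20 <- encode_region(c20, combos$m20[i], "chr20")
    e1A <- encode_region(c1A, combos$m1A[i], "chr1A")
    base <- cbind(e20, e1A)
    nm <- if (model_set == "shared") combos$m20[i] else {
      paste0("chr20:", combos$m20[i], "|chr1A:", combos$m1A[i])
    }
    designs[[nm]] <- base
    epi <- matrix(0, nrow(base), 0)
    for (a in seq_len(ncol(e20))) {
      for (b in seq_len(ncol(e1A))) {
        col <- e20[, a] * e1A[, b]
        epi <- cbind(epi, col)
        colnames(epi)[ncol(epi)] <- paste0(colnames(e20)[a], "x",
                                           colnames(e1A)[b])
      }
    }
    designs[[paste0(nm, "+epistasis")]] <- cbind(base, epi)
  }
  list(designs = designs, keep = keep, n_excluded = n_excluded)
}

#' Fit and compare the inheritance models
#'
#' Ordinary least-squares fit of each candidate model to the continuous
#' phenotype, ranked by an information criterion. The default criterion is
#' BIC (selection-consistent, so recovery of a true small model does not
#' degrade with added candidates); small-sample-corrected AICc is reported
#' alongside. Design columns that are identically zero (structurally empty
#' genotype cells, e.g. the unobserved AA/PP combination) are dropped before
#' fitting; models whose design is still rank-deficient are skipped with a
#' diagnostic. Equal-criterion ties go to the model with fewer parameters.
#'
#' @param designs result of [build_model_designs()] (its `keep` filter is
#'   applied to `phenotype`), or a bare named list of design matrices.
#' @param phenotype continuous phenotype values, one per individual.
#' @param criterion `"bic"` or `"aicc"`.
#' @return An object of class `inheritance_report`: list with `comparison`
#'   (one row per model: `model`, `k`, `rss`, `r_squared`, `aicc`, `bic`,
#'   `skipped`, `winner`), `winner`, `effects` (named coefficient vector of
#'   the winning model) and `residual_sd`.
#' @export
fit_and_compare <- function(designs, phenotype, criterion = c("bic", "aicc")) {
  criterion <- match.arg(criterion)
  if (is.list(designs) && !is.null(designs$designs)) {
    phenotype <- phenotype[designs$keep]
    designs <- designs$designs
  }
  ok <- !is.na(phenotype)
  phenotype <- phenotype[ok]
  designs <- lapply(designs, function(d) {
    if (is.null(d)) NULL else d[ok, , drop = FALSE]
  })
  n <- length(phenotype)
  kmax <- max(vapply(designs, function(d) if (is.null(d)) 0L else ncol(d),
                     integer(1)))
  if (n <= kmax + 3) stop("too few individuals for the largest model")
  eps <- 1e-12
  rows <- list()
  fits <- list()
  for (nm in names(designs)) {
    X <- cbind(`(Intercept)` = rep(1, n), designs[[nm]])
    nonzero <- colSums(abs(X)) > 0
    X <- X[, nonzero, drop = FALSE]
    if (qr(X)$rank < ncol(X)) {
      # a structurally empty genotype cell can make an interaction column
      # collinear with the main effects; such deficiencies are resolved by
      # dropping redundant epistasis columns (the fitted subspace, and hence
      # RSS and rank, do not depend on which collinear column goes). A
      # deficient main-effect block means a whole genotype class is absent:
      # the model is skipped.
      is_epi <- grepl("x", colnames(X), fixed = TRUE)
      mains <- X[, !is_epi, drop = FALSE]
      if (qr(mains)$rank < ncol(mains)) {
        rows[[nm]] <- data.frame(model = nm, k = NA_integer_, rss = NA_real_,
                                 r_squared = NA_real_, aicc = NA_real_,
                                 bic = NA_real_, skipped = TRUE)
        next
      }
      Xr <- mains
      for (j in which(is_epi)) {
        Xtry <- cbind(Xr, X[, j, drop = FALSE])
        if (qr(Xtry)$rank == ncol(Xtry)) Xr <- Xtry
      }
      X <- Xr
    }
    f <- stats::lm.fit(X, phenotype)
    rss <- sum(f$residuals^2)
    kf <- ncol(X) + 1  # + residual variance
    ll <- -n / 2 * (log(2 * pi * max(rss, eps) / n) + 1)
    aicc <- -2 * ll + 2 * kf + 2 * kf * (kf + 1) / max(n - kf - 1, 1)
    bic <- -2 * ll + kf * log(n)
    tss <- sum((phenotype - mean(phenotype))^2)
    rows[[nm]] <- data.frame(model = nm, k = kf, rss = rss,
                             r_squared = 1 - rss / max(tss, eps),
                             aicc = aicc, bic = bic, skipped = FALSE)
    fits[[nm]] <- f
  }
  cmp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  crit <- if (criterion == "bic") cmp$bic else cmp$aicc
  usable <- which(!cmp$skipped)
  ordu <- usable[order(crit[usable], cmp$k[usable])]
  winner <- cmp$model[ordu[1]]
  cmp$winner <- cmp$model == winner
  wf <- fits[[winner]]
  structure(list(
    comparison = cmp[order(!cmp$winner, crit), ],
    winner = winner,
    effects = coef(wf),
    residual_sd = sqrt(sum(wf$residuals^2) /
                         max(length(phenotype) - length(coef(wf)), 1)),
    criterion = criterion,
    n = n
  ), class = "inheritance_report")
}

#' @export
print.inheritance_report <- function(x, ...) {
  cat(sprintf("Inheritance model comparison (n = %d, criterion = %s)\n",
              x$n, toupper(x$criterion)))
  print(x$comparison, digits = 4, row.names = FALSE)
  cat("winning model:", x$winner, "\n")
  cat("effects:\n")
  print(round(x$effects, 3))
  invisible(x)
}

#' Full inheritance analysis of a genotype matrix and phenotype
#'
#' Convenience wrapper: classify individuals, build the model designs over
#' the non-excluded ones, and run the model comparison.
#'
#' @param geno a [diagnostic_genotypes()] object.
#' @param phenotype phenotype vector aligned with the genotype rows.
#' @param ... passed to [fit_and_compare()].
#' @param model_set passed to [build_model_designs()].
#' @return A list with `individuals` (from [classify_individuals()]) and
#'   `report` (an `inheritance_report`).
#' @export
inheritance_analysis <- function(geno, phenotype, model_set = "shared", ...) {
  ind <- classify_individuals(geno)
  use <- !ind$excluded
  des <- build_model_designs(ind$class_chr20[use], ind$class_chr1A[use],
                             model_set = model_set)
  list(individuals = ind,
       report = fit_and_compare(des, phenotype[use], ...))
}
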