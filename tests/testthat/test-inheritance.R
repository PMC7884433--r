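test_that("hybrid index and heterozygosity are missing-aware", {
  expect_equal(hybrid_index(c(0, 0, 0)), 0)
  expect_equal(hybrid_index(c(2, 2)), 1)
  expect_equal(hybrid_index(c(2, 2, NA, 0)), 2 / 3)
  expect_equal(interclass_heterozygosity(c(1, 1, 1)), 1)
  expect_equal(interclass_heterozygosity(c(0, 2, 2)), 0)
  expect_equal(interclass_heterozygosity(c(1, 0, NA, 2)), 1 / 3)
  expect_warning(expect_true(is.na(hybrid_index(c(NA, NA)))), "missing")
  expect_warning(expect_true(is.na(interclass_heterozygosity(NA))), "missing")
})

test_that("hybrid index and heterozygosity ignore locus order and empty loci", {
  set.seed(2)
  for (i in 1:20) {
    d <- sample(c(0:2, NA), 30, replace = TRUE)
    perm <- sample(30)
    expect_equal(hybrid_index(d), hybrid_index(d[perm]))
    expect_equal(interclass_heterozygosity(d),
                 interclass_heterozygosity(d[perm]))
    expect_equal(hybrid_index(d), hybrid_index(c(d, NA, NA)))
  }
})

test_that("region genotype classification uses the HI thresholds", {
  expect_equal(as.character(classify_region_genotype(0.02, 0.02)),
               "alba-type")
  expect_equal(as.character(classify_region_genotype(0.5, 1.0)),
               "heterozygote")
  expect_equal(as.character(classify_region_genotype(0.9, 0.1)),
               "personata-type")
  expect_equal(as.character(classify_region_genotype(c(0.25, 0.75))),
               c("alba-type", "personata-type"))  # inclusive thresholds
  expect_true(is.na(classify_region_genotype(NA)))
})

test_that("phenotype lookup covers the 9-cell grid with one unobserved cell", {
  expect_equal(as.character(phenotype_class_lookup("AA", "aa")), "alba")
  expect_equal(as.character(phenotype_class_lookup("pp", "aa")),
               "personata-like hybrid")
  expect_equal(as.character(phenotype_class_lookup("pp", "aP")), "personata")
  expect_equal(as.character(phenotype_class_lookup("AA", "PP")), "unobserved")
  grid <- expand.grid(c20 = c("AA", "Ap", "pp"), c1A = c("aa", "aP", "PP"))
  cls <- phenotype_class_lookup(grid$c20, grid$c1A)
  expect_false(anyNA(cls))
  expect_equal(sum(cls == "unobserved"), 1L)
  # heterozygous ASIP behaves like the alba homozygote except on PP
  expect_equal(as.character(phenotype_class_lookup("Ap", "aa")), "alba")
  expect_equal(as.character(phenotype_class_lookup("Ap", "PP")),
               "intermediate")
})

test_that("model design encodings follow the stated conventions", {
  des <- build_model_designs(c("pp", "Ap", "AA"), c("aa", "aP", "PP"))$designs
  add <- des$additive
  expect_equal(add[, "chr20_score"], c(1, 0.5, 0))
  expect_equal(add[, "chr1A_score"], c(0, 0.5, 1))
  dom <- des$dominant
  expect_equal(dom[, "chr20_dom"], c(1, 0, 0))  # Ap scored with AA
  expect_equal(dom[, "chr1A_dom"], c(0, 1, 1))  # aP scored with PP
  epi <- des$`additive+epistasis`
  expect_equal(epi[, "chr20_scorexchr1A_score"], c(0, 0.25, 0))
  par <- des$partial
  expect_equal(colnames(par),
               c("chr20_Ap", "chr20_pp", "chr1A_aP", "chr1A_PP"))
  expect_equal(par[1, ], c(chr20_Ap = 0, chr20_pp = 1, chr1A_aP = 0,
                           chr1A_PP = 0))
  # full set enumerates per-region mode combinations
  full <- build_model_designs(c("pp", "Ap", "AA"), c("aa", "aP", "PP"),
                              model_set = "full")$designs
  expect_equal(length(full), 1 + 9 * 2)
  expect_true("chr20:dominant|chr1A:partial+epistasis" %in% names(full))
  # unclassified individuals are excluded with a message
  expect_message(
    d2 <- build_model_designs(c("pp", NA), c("aa", "aP")), "excluded")
  expect_equal(sum(d2$keep), 1L)
})

test_that("fit_and_compare ranks a constant phenotype as intercept-only", {
  cls20 <- rep(c("AA", "Ap", "pp"), 20)
  cls1A <- rep(c("aa", "aP", "aa"), 20)
  des <- build_model_designs(cls20, cls1A)
  rep <- fit_and_compare(des, rep(5, 60))
  expect_equal(rep$winner, "null")
})

test_that("fit_and_compare recovers the generating mechanism", {
  dat <- simulate_inheritance_dataset(n = 200, mechanism = "epistatic",
                                      noise_sd = 5, seed = 7)
  res <- inheritance_analysis(dat$genotypes, dat$phenotypes$phenotype)
  expect_equal(res$report$winner, "partial+epistasis")
  add <- simulate_inheritance_dataset(n = 200, mechanism = "additive",
                                      noise_sd = 5, seed = 7)
  res2 <- inheritance_analysis(add$genotypes, add$phenotypes$phenotype)
  expect_equal(res2$report$winner, "additive")
})

test_that("model ranking is invariant to linear phenotype rescaling", {
  dat <- simulate_inheritance_dataset(n = 150, mechanism = "epistatic",
                                      noise_sd = 5, seed = 12)
  ind <- classify_individuals(dat$genotypes)
  use <- !ind$excluded & !is.na(dat$phenotypes$phenotype)
  des <- build_model_designs(ind$class_chr20[use], ind$class_chr1A[use])
  y <- dat$phenotypes$phenotype[use]
  r1 <- fit_and_compare(des, y)
  r2 <- fit_and_compare(des, 3.7 * y - 12)
  expect_equal(r1$comparison$model, r2$comparison$model)
  expect_equal(r1$winner, r2$winner)
})

test_that("rank-deficient models are skipped with a diagnostic", {
  # perfectly correlated regions (only the two parental cells present):
  # every two-region design is collinear and must be skipped
  cls20 <- rep(c("AA", "pp"), 30)
  cls1A <- rep(c("aa", "PP"), 30)
  des <- build_model_designs(cls20, cls1A)
  set.seed(1)
  y <- rnorm(60) + (cls20 == "pp")
  rep <- fit_and_compare(des, y)
  expect_true(any(rep$comparison$skipped))
  expect_false(rep$comparison$skipped[rep$comparison$model == rep$winner])
})
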