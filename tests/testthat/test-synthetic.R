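test_that("cross generators produce the expected genotype structure", {
  g <- simulate_cross_genotypes(cross_spec(
    counts = c(P_alba = 10, P_personata = 10, F1 = 10),
    missingness = 0, seed = 1
  ))
  expect_s3_class(g, "diagnostic_genotypes")
  expect_equal(ncol(g$dosage), 92)
  expect_equal(sum(g$region == "chr1A"), 43)
  expect_equal(sum(g$region == "chr20"), 49)
  alba <- g$dosage[g$class == "P_alba", ]
  expect_true(all(alba == 0))
  pers <- g$dosage[g$class == "P_personata", ]
  expect_true(all(pers == 2))
  # fixed parental haplotypes force full F1 heterozygosity at any r
  f1 <- g$dosage[g$class == "F1", ]
  expect_true(all(f1 == 1))
})

test_that("F2 regions segregate 1:2:1 as single Mendelian loci when r = 0", {
  g <- simulate_cross_genotypes(cross_spec(counts = c(F2 = 1200), r = 0,
                                           missingness = 0, seed = 2),
                                drop_unobserved = FALSE)
  for (reg in c("chr1A", "chr20")) {
    block <- g$dosage[, g$region == reg]
    # with r = 0 every locus in the block carries the same dosage
    expect_true(all(apply(block, 1, function(x) length(unique(x)) == 1)))
    dos <- block[, 1]
    expect_gt(chisq.test(tabulate(dos + 1, 3),
                         p = c(1, 2, 1) / 4)$p.value, 0.01)
  }
})

test_that("triangle fixtures: F1 at (0.5, 1), parentals at the corners", {
  g <- simulate_cross_genotypes(cross_spec(
    counts = c(P_alba = 5, P_personata = 5, F1 = 5), r = 0, missingness = 0,
    seed = 3
  ))
  ind <- classify_individuals(g)
  f1 <- ind[g$class == "F1", ]
  expect_true(all(f1$hi == 0.5) && all(f1$het == 1))
  pa <- ind[g$class == "P_alba", ]
  expect_true(all(pa$hi == 0) && all(pa$het == 0))
  pp <- ind[g$class == "P_personata", ]
  expect_true(all(pp$hi == 1) && all(pp$het == 0))
})

test_that("crosses respect the triangle constraint", {
  g <- simulate_cross_genotypes(cross_spec(seed = 4))
  ind <- classify_individuals(g)
  ok <- !ind$excluded
  expect_true(all(ind$het[ok] <= 2 * pmin(ind$hi[ok], 1 - ind$hi[ok]) + 0.05))
})

test_that("phenotypes follow the class means and ordering", {
  g <- simulate_cross_genotypes(cross_spec(
    counts = c(P_alba = 5, P_personata = 5, F1 = 5), missingness = 0,
    seed = 5
  ))
  ph <- simulate_phenotypes(g, phenotype_spec(noise_sd = 0))
  expect_equal(ph$phenotype[g$class == "P_alba"], rep(100, 5))
  expect_equal(ph$phenotype[g$class == "P_personata"], rep(0, 5))
  # F1 between fixed parents is (Ap, aP): alba-like hybrid mean
  expect_equal(as.character(ph$plumage_class[g$class == "F1"]),
               rep("alba-like hybrid", 5))
  expect_equal(ph$phenotype[g$class == "F1"], rep(75, 5))
  # class-mean ordering is preserved in generated data
  full <- simulate_inheritance_dataset(n = 300, noise_sd = 1, seed = 6)
  means <- tapply(full$phenotypes$phenotype, full$phenotypes$plumage_class,
                  mean)
  means <- means[plumage_levels()]
  means <- means[!is.na(means)]
  expect_true(all(diff(means) < 0))
})

test_that("phenotype_spec rejects unordered class means", {
  expect_error(phenotype_spec(means = c(
    "alba" = 0, "alba-like hybrid" = 75, "intermediate" = 50,
    "personata-like hybrid" = 25, "personata" = 100
  )), "decreasing")
})

test_that("the unobserved (AA, PP) cell is filtered from crosses", {
  g <- simulate_cross_genotypes(cross_spec(counts = c(F2 = 800), r = 0,
                                           missingness = 0, seed = 7))
  ind <- classify_individuals(g)
  expect_false(any(ind$plumage_class == "unobserved", na.rm = TRUE))
})

test_that("transect samples follow the generating logistic cline", {
  pts <- simulate_transect_sample(center = 0.5, width = 0.1, n = 4000,
                                  seed = 8)
  near <- abs(pts$location - 0.5) < 0.01
  expect_equal(mean(pts$frequency[near]), 0.5, tolerance = 0.1)
  # mean dosage tracks 2 p(x) away from the center too
  right <- pts$location > 0.55 & pts$location < 0.6
  p_right <- mean(plogis(4 * (pts$location[right] - 0.5) / 0.1))
  expect_equal(mean(pts$frequency[right]), p_right, tolerance = 0.05)
  # recovery of the generating center through the cline module
  centers <- vapply(1:10, function(s) {
    cline_center(fit_cline(simulate_transect_sample(0.6, 0.1, 400,
                                                    seed = 400 + s)))
  }, numeric(1))
  expect_lt(abs(mean(centers) - 0.6), 0.02)
})

test_that("hybrid-zone composition sampling matches the stated frequencies", {
  x <- sample_hybrid_zone_composition(1e5, seed = 9)
  frac <- as.numeric(table(x)[plumage_levels()]) / 1e5
  expect_equal(frac, c(0.33, 0.20, 0.04, 0.14, 0.29), tolerance = 0.05)
  expect_true(all(abs(frac - c(0.33, 0.20, 0.04, 0.14, 0.29)) < 0.01))
  expect_equal(length(sample_hybrid_zone_composition(104, seed = 1)), 104)
})

test_that("generators are deterministic under a fixed seed", {
  s <- cross_spec(seed = 11)
  expect_identical(simulate_cross_genotypes(s), simulate_cross_genotypes(s))
  expect_identical(simulate_transect_sample(0.5, 0.2, 100, seed = 3),
                   simulate_transect_sample(0.5, 0.2, 100, seed = 3))
  d1 <- simulate_inheritance_dataset(n = 100, seed = 13)
  d2 <- simulate_inheritance_dataset(n = 100, seed = 13)
  expect_identical(d1$phenotypes, d2$phenotypes)
})
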