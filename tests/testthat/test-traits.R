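test_that("chi-square goodness of fit reproduces hand-computed values", {
  perfect <- chisq_goodness(c(75, 25), c(3, 1))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p.value, 1)

  # F2 bullseye colour counts of the intraspecific cross: 37 red, 11 pale
  f2 <- chisq_goodness(c(37, 11), c(3, 1))
  expect_equal(f2$chi2, 1 / 36 + 1 / 12, tolerance = 1e-12)
  expect_equal(f2$p.value, 0.739, tolerance = 1e-3)
  expect_equal(f2$df, 1L)

  # interspecific F2: 40 parent-A-like, 96 hybrid-like, 41 parent-B-like
  cod <- chisq_goodness(c(40, 96, 41), c(1, 2, 1))
  expect_equal(cod$chi2, 1.283, tolerance = 1e-3)
  expect_gt(cod$p.value, 0.05)   # Mendelian 1:2:1 not rejected
  expect_equal(cod$df, 2L)

  # tiny expected counts are flagged, Yates correction shrinks chi2
  expect_true(chisq_goodness(c(3, 0), c(15, 1))$low_expected)
  expect_lt(chisq_goodness(c(37, 11), c(3, 1), correct = TRUE)$chi2,
            f2$chi2)
})

test_that("the best Mendelian ratio is chosen by goodness of fit", {
  pick <- best_mendelian_ratio(c(37, 11),
                               list("1:1", "2:1", "3:1", "15:1"))
  expect_equal(pick$best_label, "3:1")
  expect_equal(nrow(pick$table), 4L)
  expect_equal(best_mendelian_ratio(c(50, 50), list("1:1", "3:1"))$best_label,
               "1:1")
  both <- best_mendelian_ratio(c(96, 81), list("3:1", "1:1"))
  expect_equal(nrow(both$table), 2L)
  expect_true(all(both$table$p.value >= 0 & both$table$p.value <= 1))
  expect_equal(both$best_label, "1:1")
})

test_that("co-segregation measures concordance with a permutation p", {
  # the blind-genotyping design: every individual matches its phenotype
  coh <- tibble::tibble(
    phenotype = rep(c("parent_A", "hybrid", "parent_B"), c(10, 19, 9)),
    genotype  = rep(c("AA", "AB", "BB"), c(10, 19, 9)))
  map <- c(parent_A = "AA", hybrid = "AB", parent_B = "BB")
  cs <- cosegregation(coh, map, R = 2000, seed = 101)
  expect_equal(cs$n, 38L)
  expect_equal(cs$concordance, 1)
  expect_lt(cs$perm_p, 0.01)

  # inverted map: zero concordance
  inv <- c(parent_A = "BB", hybrid = "AA", parent_B = "AB")
  expect_equal(cosegregation(coh, inv, R = 100, seed = 102)$concordance, 0)

  # missing genotypes excluded with a report
  coh2 <- coh
  coh2$genotype[1:3] <- "missing"
  cs2 <- cosegregation(coh2, map, R = 100, seed = 103)
  expect_equal(cs2$n_missing, 3L)
  expect_equal(cs2$n, 35L)

  # exact enumeration oracle on a 4-individual toy: permutation p converges
  # to the exact fraction of genotype orderings with >= observed concordance
  toy <- tibble::tibble(phenotype = c("x", "x", "y", "y"),
                        genotype  = c("AA", "BB", "BB", "BB"))
  tmap <- c(x = "AA", y = "BB")
  obs <- sum(tmap[toy$phenotype] == toy$genotype)
  perms <- combinat_perms(toy$genotype)
  exact_p <- mean(vapply(perms, function(g)
    sum(tmap[toy$phenotype] == g) >= obs, TRUE))
  cs3 <- cosegregation(toy, tmap, R = 20000, seed = 104)
  expect_equal(cs3$perm_p, exact_p, tolerance = 0.02)
})

test_that("standard curves convert absorbance to concentration", {
  conc <- c(0, 1, 2, 4)
  sc <- suppressWarnings(standard_curve_cf(conc * 0.5, conc))  # exact fit
  expect_equal(sc$conversion_factor, 2)
  expect_equal(sc$intercept, 0)
  # symmetric noise keeps the conversion factor inside the reported CI
  noisy <- conc * 0.5 + c(0.01, -0.01, 0.01, -0.01)
  scn <- standard_curve_cf(noisy, conc)
  expect_gt(scn$cf_ci[2], 2)
  expect_lt(scn$cf_ci[1], 2.2)
  # replicates allowed, but >= 3 distinct concentrations required
  expect_silent(standard_curve_cf(c(0.01, 0.52, 0.49, 0.99), c(0, 1, 1, 2)))
  expect_error(standard_curve_cf(c(0, 1, 1.1), c(0, 1, 1)), "distinct")
})

test_that("pigment concentration follows the assay formula", {
  expect_equal(pigment_concentration(0, 10, 1, 0.25, 0.05, 0.04), 0)
  # hand arithmetic: 0.2 * 10 * 1 * 0.25 / (0.05 * 0.04) = 250
  expect_equal(pigment_concentration(0.2, 10, 1, 0.25, 0.05, 0.04), 250)
  # linear in absorbance, inverse in tissue mass
  expect_equal(pigment_concentration(0.4, 10, 1, 0.25, 0.05, 0.04), 500)
  expect_equal(pigment_concentration(0.2, 10, 1, 0.25, 0.05, 0.08), 125)
  # microlitre suffixes convert to ml
  expect_equal(pigment_concentration(0.2, 10, 1, 0.25, "50ul", 0.04), 250)
})

test_that("bullseye geometry and identity ratios match printed values", {
  expect_equal(bullseye_proportion(15, 100), 15)
  expect_equal(bullseye_proportion(3, 100), 3)
  expect_equal(fold_ratio(15, 3), 5)     # the fivefold bullseye reduction
  expect_equal(bullseye_proportion(7, 7), 100)
  expect_equal(bullseye_proportion(0, 5), 0)
  expect_error(bullseye_proportion(8, 7), "total")
  expect_error(fold_ratio(1, 0), "> 0")

  id <- percent_identity(5, 249)
  expect_equal(id$rounded, 98)           # 5 differing residues out of 249
  expect_equal(id$percent, 100 * 244 / 249)
  expect_equal(percent_identity(0, 100)$percent, 100)
  expect_equal(percent_identity(100, 100)$percent, 0)
})

test_that("preference tests reproduce the first-landing statistics", {
  choices <- c(rep(1, 34), rep(0, 6))    # 34 of 40 bees on the focal flower
  pt <- preference_test(choices)
  expect_equal(pt$proportion, 0.85)
  expect_equal(pt$p.value, 3.51e-7, tolerance = 0.002)
  expect_equal(pt$df, 39L)

  even <- preference_test(rep(c(1, 0), 20))
  expect_equal(even$t, 0)
  expect_equal(even$p.value, 1)

  allsame <- preference_test(rep(1, 10))
  expect_true(allsame$degenerate)
  expect_true(is.na(allsame$p.value))
  expect_equal(allsame$binom_p, 2^-10 * 2, tolerance = 1e-12)

  # t-based and exact binomial p agree in order of magnitude at n = 40
  expect_lt(abs(log10(pt$p.value) - log10(pt$binom_p)), 1.5)
})

test_that("discrete 3:1 cohorts reject at the exact binomial rate", {
  # n = 48 makes the Pearson test discrete: rejection at alpha = 0.05 is
  # |O - 36| >= 6, with exact probability 0.0646 under a true 3:1 model
  sims <- withr::with_seed(106, rbinom(10000, 48, 0.75))
  p_of <- vapply(0:48, function(o)
    chisq_goodness(c(o, 48 - o), c(3, 1))$p.value, 0)
  rate <- mean(p_of[sims + 1] < 0.05)
  exact <- sum(dbinom(which(p_of < 0.05) - 1, 48, 0.75))
  expect_equal(exact, 0.0646, tolerance = 1e-3)
  expect_lt(abs(rate - exact), 3 * sqrt(exact * (1 - exact) / 10000))
})

test_that("tidiers and plots expose results as tibbles and ggplots", {
  f2 <- chisq_goodness(c(37, 11), c(3, 1))
  expect_s3_class(tidy(f2), "tbl_df")
  expect_equal(glance(f2)$df, 1L)
  expect_s3_class(autoplot(f2), "ggplot")
  pt <- preference_test(c(rep(1, 34), rep(0, 6)))
  expect_equal(tidy(pt)$proportion, 0.85)
  sim <- simulate_counts(n_genes = 200, n_biased = 10, seed = 105)
  de <- de_filter(de_test(sim$counts, sim$groups))
  expect_s3_class(plot_de_volcano(de), "ggplot")
})
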