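#' Chi-square goodness of fit to a Mendelian ratio
#'
#' Pearson chi-square test of observed class counts against an expected
#' ratio (e.g. 3:1 for a dominant single-locus trait in an F2, 1:2:1 for a
#' codominant one). Plain Pearson by default; Yates' continuity correction
#' is available for two-class tests.
#'
#' @param observed Non-negative integer counts per class.
#' @param ratio Positive expected ratio parts, same length as `observed`.
#' @param correct Apply Yates' continuity correction (default FALSE).
#' @return An object of class `seg_test`: list with `observed`, `expected`,
#'   `ratio`, `chi2`, `df`, `p.value`, `low_expected` (TRUE when any
#'   expected count < 1, a validity warning).
#' @export
chisq_goodness <- function(observed, ratio, correct = FALSE) {
  stopifnot(length(observed) == length(ratio), all(observed >= 0),
            all(ratio > 0), length(observed) >= 2L)
  expected <- sum(observed) * ratio / sum(ratio)
  if (correct) {
    chi2 <- sum((abs(observed - expected) - 0.5)^2 / expected)
    df <- length(observed) - 1L
    p <- pchisq(chi2, df, lower.tail = FALSE)
  } else {
    ht <- suppressWarnings(chisq.test(observed, p = ratio / sum(ratio)))
    chi2 <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 chi2 = chi2, df = df, p.value = p,
                 low_expected = any(expected < 1)),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("<seg_test> %s vs %s: chi2 = %.4g (df %d), p = %.4g\n",
              paste(x$observed, collapse = ":"),
              paste(x$ratio, collapse = ":"), x$chi2, x$df, x$p.value))
  invisible(x)
}

parse_ratio <- function(r) {
  if (is.character(r)) as.numeric(strsplit(r, ":")[[1]]) else as.numeric(r)
}

#' Select the best-fitting Mendelian ratio
#'
#' Tests the observed counts against each candidate ratio with
#' [chisq_goodness()] and returns the candidate with the largest
#' goodness-of-fit p-value, together with the full comparison table.
#'
#' @param observed Class counts.
#' @param candidates List of candidate ratios, each a numeric vector or a
#'   string like `"3:1"`. At least two.
#' @return List with `best` (the winning ratio, numeric), `best_label`,
#'   and `table` (tibble: `ratio`, `chi2`, `p.value`).
#' @export
best_mendelian_ratio <- function(observed,
                                 candidates = list("1:1", "2:1", "3:1", "15:1")) {
  stopifnot(length(candidates) >= 2L)
  rats <- lapply(candidates, parse_ratio)
  if (any(vapply(rats, length, 0L) != length(observed)))
    abort("every candidate ratio must have one part per observed class")
  tests <- lapply(rats, function(r) chisq_goodness(observed, r))
  tab <- tibble(
    ratio = vapply(rats, paste, "", collapse = ":"),
    chi2 = vapply(tests, function(t) t$chi2, 0),
    p.value = vapply(tests, function(t) t$p.value, 0)
  )
  best_i <- order(-tab$p.value, tab$chi2)[1L]
  list(best = rats[[best_i]], best_label = tab$ratio[best_i], table = tab)
}

#' Genotype-phenotype co-segregation
#'
#' Concordance between marker genotypes and phenotype classes in a
#' segregating population: the fraction of (non-missing) individuals whose
#' genotype equals the one `expected_map` assigns to their phenotype, with a
#' permutation p-value (probability of at least the observed concordance
#' when genotypes are shuffled across individuals).
#'
#' @param cohort Tibble with columns `phenotype` and `genotype` (genotype
#'   `"missing"` or `NA` excluded with a report).
#' @param expected_map Named character vector: phenotype class -> expected
#'   genotype. Must cover every phenotype present.
#' @param R Number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return An object of class `coseg_test`: list with `n`, `n_missing`,
#'   `concordant`, `concordance`, `perm_p`.
#' @export
cosegregation <- function(cohort, expected_map, R = 10000, seed = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("phenotype", "genotype") %in% names(cohort)))
  assert_seed(seed)
  miss <- is.na(cohort$genotype) | cohort$genotype == "missing"
  dat <- cohort[!miss, ]
  if (!nrow(dat)) abort("no individuals with non-missing genotypes")
  if (!all(dat$phenotype %in% names(expected_map)))
    abort("expected_map must cover every phenotype class")
  want <- unname(expected_map[dat$phenotype])
  hits <- sum(want == dat$genotype)
  perm_p <- with_seed_or_not(seed, {
    perm <- vapply(seq_len(R), function(i)
      sum(want == sample(dat$genotype)), 0L)
    mean(perm >= hits)
  })
  structure(list(n = nrow(dat), n_missing = sum(miss), concordant = hits,
                 concordance = hits / nrow(dat), perm_p = perm_p),
            class = "coseg_test")
}

#' @export
print.coseg_test <- function(x, ...) {
  cat(sprintf(
    "<coseg_test> %d/%d concordant (%.1f%%), permutation p = %.4g (%d missing)\n",
    x$concordant, x$n, 100 * x$concordance, x$perm_p, x$n_missing))
  invisible(x)
}

#' Conversion factor from a standard curve
#'
#' Ordinary least squares of absorbance on known concentration; the
#' conversion factor is the reciprocal slope (concentration units per
#' absorbance unit), as obtained from a quercetin-galactoside or
#' cyanidin-glucoside dilution series.
#'
#' @param absorbances Absorbance readings (AU).
#' @param known_concs Matching known concentrations; at least 3 distinct
#'   values (replicates allowed).
#' @param level Confidence level for the reported interval (default 0.95).
#' @return List with `conversion_factor`, `slope`, `intercept`, `cf_ci`
#'   (interval from the slope CI) and the fitted `model`.
#' @export
standard_curve_cf <- function(absorbances, known_concs, level = 0.95) {
  stopifnot(length(absorbances) == length(known_concs))
  if (length(unique(known_concs)) < 3L)
    abort("need >= 3 distinct concentrations")
  fit <- lm(absorbances ~ known_concs)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps)
    abort("standard curve slope is zero")
  ci <- confint(fit, "known_concs", level = level)
  list(conversion_factor = 1 / slope, slope = slope,
       intercept = unname(coef(fit)[1L]),
       cf_ci = sort(1 / as.numeric(ci)), model = fit)
}

#' Pigment concentration from an absorbance assay
#'
#' Spectrophotometric flavonoid quantification:
#' `A * CF * V_cuvette * V_extract / (V_loaded * mass)`, giving mg of
#' flavonol or anthocyanin equivalent per g of fresh tissue. All volumes in
#' ml, mass in g; values suffixed `"ul"` (e.g. `"50ul"`) are converted from
#' microlitres.
#'
#' @param absorbance Absorbance reading (AU, A350 for flavonols, A530 for
#'   anthocyanins).
#' @param conversion_factor mg ml^-1 AU^-1 from [standard_curve_cf()].
#' @param vol_cuvette Total cuvette volume (ml).
#' @param vol_extract Total extract volume (ml).
#' @param vol_loaded Extract volume loaded into the cuvette (ml).
#' @param tissue_mass Fresh tissue mass (g).
#' @return mg equivalent per g fresh weight.
#' @export
pigment_concentration <- function(absorbance, conversion_factor, vol_cuvette,
                                  vol_extract, vol_loaded, tissue_mass) {
  vol_cuvette <- parse_volume(vol_cuvette)
  vol_extract <- parse_volume(vol_extract)
  vol_loaded <- parse_volume(vol_loaded)
  stopifnot(absorbance >= 0, conversion_factor > 0, vol_cuvette > 0,
            vol_extract > 0, vol_loaded > 0, tissue_mass > 0)
  absorbance * conversion_factor * vol_cuvette * vol_extract /
    (vol_loaded * tissue_mass)
}

parse_volume <- function(v) {
  if (is.character(v)) {
    if (grepl("ul$", v)) return(as.numeric(sub("ul$", "", v)) / 1000)
    if (grepl("ml$", v)) return(as.numeric(sub("ml$", "", v)))
    return(as.numeric(v))
  }
  v
}

#' Bullseye geometry ratios
#'
#' `bullseye_proportion()` is the percentage of petal area covered by the
#' pigmented proximal region; `fold_ratio()` is the plain ratio of two such
#' percentages (e.g. a fivefold bullseye reduction between sister species).
#'
#' @param pigmented_area,total_area Areas in any common unit, with
#'   `0 <= pigmented_area <= total_area` and `total_area > 0`.
#' @param a,b Two positive quantities (`b > 0`).
#' @return A percentage, or a fold ratio.
#' @export
bullseye_proportion <- function(pigmented_area, total_area) {
  if (any(total_area <= 0) || any(pigmented_area < 0) ||
      any(pigmented_area > total_area))
    abort("need 0 <= pigmented_area <= total_area and total_area > 0")
  100 * pigmented_area / total_area
}

#' @rdname bullseye_proportion
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) abort("denominator must be > 0")
  a / b
}

#' Percent identity from a difference count
#'
#' @param n_diff Number of differing positions.
#' @param aligned_length Alignment length (> 0, `n_diff <= aligned_length`).
#' @return List with `percent` (raw) and `rounded` (nearest integer).
#' @export
percent_identity <- function(n_diff, aligned_length) {
  stopifnot(aligned_length > 0, n_diff >= 0, n_diff <= aligned_length)
  p <- 100 * (aligned_length - n_diff) / aligned_length
  list(percent = p, rounded = round(p))
}

#' First-landing preference test
#'
#' Proportion of trials in which the focal flower was chosen first, with a
#' two-sided one-sample t-test of the binary outcomes against 0.5 and, as a
#' distribution-free companion, the exact binomial p-value. With zero
#' variance (all trials identical) the t statistic is undefined and only the
#' proportion and exact p are reported.
#'
#' @param choices Binary vector (1 = focal flower chosen first), n >= 2.
#' @param alternative Sidedness of both tests (default `"two.sided"`).
#' @return An object of class `pref_test`: list with `n`, `proportion`,
#'   `t`, `df`, `p.value` (t-based; NA when degenerate), `binom_p`,
#'   `degenerate`.
#' @export
preference_test <- function(choices, alternative = "two.sided") {
  stopifnot(all(choices %in% c(0, 1)))
  n <- length(choices)
  if (n < 2L) abort("need n >= 2 trials")
  k <- sum(choices)
  prop <- k / n
  bp <- binom.test(k, n, p = 0.5, alternative = alternative)$p.value
  if (sd(choices) == 0) {
    res <- list(n = n, proportion = prop, t = NA_real_, df = n - 1L,
                p.value = NA_real_, binom_p = bp, degenerate = TRUE)
  } else {
    ht <- t.test(choices, mu = 0.5, alternative = alternative)
    res <- list(n = n, proportion = prop, t = unname(ht$statistic),
                df = unname(ht$parameter), p.value = ht$p.value,
                binom_p = bp, degenerate = FALSE)
  }
  structure(res, class = "pref_test")
}

#' @export
print.pref_test <- function(x, ...) {
  cat(sprintf(
    "<pref_test> %.0f%% of %d first landings on the focal flower; t = %.3f (df %d), p = %.3g; exact binomial p = %.3g\n",
    100 * x$proportion, x$n, x$t %||% NA, x$df, x$p.value, x$binom_p))
  invisible(x)
}
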