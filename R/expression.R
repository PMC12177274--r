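#' Median-of-ratios size factors
#'
#' For each sample, the median across reference genes (genes with positive
#' counts in every sample) of the ratio between the sample's count and the
#' gene's geometric mean. The standard library-size normalisation used for
#' count-based differential expression.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (ncol(counts) == 1L)
    return(setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    abort("no gene has positive counts in every sample")
  log_gm <- rowMeans(log(counts[allpos, , drop = FALSE]))
  f <- apply(counts[allpos, , drop = FALSE], 2L,
             function(cnt) exp(median(log(cnt) - log_gm)))
  setNames(f, colnames(counts))
}

#' Two-group differential-expression test on normalised counts
#'
#' A transparent stand-in for negative-binomial DE machinery: counts are
#' normalised by [size_factors()], the log2 fold change is computed from
#' group means with a pseudocount, and the p-value comes from Welch's t-test
#' on `log2(normalised + 1)`. Genes with zero variance in both groups and
#' equal means get `p = 1`.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Factor or character vector of length `ncol(counts)` with
#'   exactly two levels; the first level is the fold-change numerator
#'   (proximal vs distal in the petal design).
#' @param pseudocount Added to group means before the log-ratio (default 1).
#' @return Tibble with `gene`, `log2fc`, `pvalue`.
#' @export
de_test <- function(counts, groups, pseudocount = 1) {
  # character input: level order = order of first appearance, so the first
  # group named is the fold-change numerator
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(counts))
  if (min(table(groups)) < 2L) abort("need >= 2 replicates per group")
  f <- size_factors(counts)
  norm <- sweep(counts, 2L, f, "/")
  g1 <- groups == levels(groups)[1L]
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, !g1, drop = FALSE])
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  lx <- log2(norm + 1)
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    x <- lx[i, g1]; y <- lx[i, !g1]
    if (sd(x) == 0 && sd(y) == 0) {
      if (mean(x) == mean(y)) return(1)
      return(0)
    }
    t.test(x, y, var.equal = FALSE)$p.value
  }, 0)
  tibble(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
         log2fc = unname(lfc), pvalue = pv)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' `padj_i = min_{j >= rank(i)} (m / rank_j) p_j`, capped at 1. Monotone and
#' idempotent.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is differentially expressed when `|log2fc| >= lfc_cut` and
#' `padj < alpha` — the fourfold / adjusted-p < 1e-5 rule used to call
#' region-biased petal genes. Counts of proximal-biased (`log2fc >= +cut`)
#' and distal-biased (`log2fc <= -cut`) genes are attached.
#'
#' @param records Tibble with at least `log2fc` and `padj` columns (e.g.
#'   [de_test()] output piped through [bh_adjust()]), or with `pvalue` only,
#'   in which case `padj` is computed here.
#' @param lfc_cut Absolute log2-fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 1e-5).
#' @return The records with `padj` and logical `flag_de` columns; attribute
#'   `n_biased` is a named vector `c(proximal =, distal =)`.
#' @export
de_filter <- function(records, lfc_cut = 2, alpha = 1e-5) {
  stopifnot(is.data.frame(records), "log2fc" %in% names(records))
  if (!"padj" %in% names(records)) {
    if (!"pvalue" %in% names(records))
      abort("records need a `padj` or `pvalue` column")
    records$padj <- bh_adjust(records$pvalue)
  }
  records$flag_de <- abs(records$log2fc) >= lfc_cut & records$padj < alpha
  attr(records, "n_biased") <- c(
    proximal = sum(records$flag_de & records$log2fc >= lfc_cut),
    distal   = sum(records$flag_de & records$log2fc <= -lfc_cut)
  )
  records
}

#' Efficiency-corrected relative expression (Pfaffl-type)
#'
#' Relative expression of a target gene against a reference gene using the
#' real per-cycle amplification efficiency of each primer pair:
#' `ratio = E_ref^Cq_ref / E_target^Cq_target`. With perfect doubling
#' (`E = 2`) this reduces to `2^-(Cq_target - Cq_ref)`. Efficiencies given as
#' a percentage (e.g. 95) or fraction (0.95) are converted to `1 + e`.
#'
#' @param cq_target,cq_ref Quantification cycles (> 0).
#' @param e_target,e_ref Amplification factor per cycle, in (1, 2]; values in
#'   (0, 1] or (2, 100] are interpreted as efficiency fractions/percentages
#'   and converted.
#' @return Numeric ratio(s).
#' @export
pfaffl_relative_expression <- function(cq_target, cq_ref, e_target = 2,
                                       e_ref = 2) {
  e_target <- normalize_efficiency(e_target)
  e_ref <- normalize_efficiency(e_ref)
  stopifnot(all(cq_target > 0), all(cq_ref > 0))
  e_ref^cq_ref / e_target^cq_target
}

normalize_efficiency <- function(e) {
  e <- ifelse(e > 2, 1 + e / 100, e)  # 95 (percent) -> 1.95
  if (any(e <= 1) || any(e > 2))
    abort("efficiency must be an amplification factor in (1, 2] (or a percent)")
  e
}

#' Relative expression for a Cq table
#'
#' Applies [pfaffl_relative_expression()] sample-wise to a long Cq table with
#' exactly one reference gene per sample (housekeeping-gene normalisation).
#'
#' @param records Tibble with columns `gene`, `sample`, `cq`, `efficiency`,
#'   `is_reference` (e.g. from [simulate_cq()]).
#' @return Tibble with `gene`, `sample`, `rel_expression` for every
#'   non-reference gene.
#' @export
qpcr_relative_expression <- function(records) {
  need <- c("gene", "sample", "cq", "efficiency", "is_reference")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  refs <- dplyr::filter(records, .data$is_reference)
  if (any(table(refs$sample) != 1L) ||
      !setequal(refs$sample, unique(records$sample)))
    abort("exactly one reference observation required per sample")
  tgt <- dplyr::filter(records, !.data$is_reference)
  ref_idx <- match(tgt$sample, refs$sample)
  tibble(
    gene = tgt$gene, sample = tgt$sample,
    rel_expression = pfaffl_relative_expression(
      tgt$cq, refs$cq[ref_idx], tgt$efficiency, refs$efficiency[ref_idx])
  )
}

#' Assumption-guided two-sample test chooser
#'
#' The decision rule used for pairwise expression comparisons: Shapiro-Wilk
#' on both groups; if both look normal (p >= `alpha`), an F-test of variance
#' homogeneity picks between Student's (equal variances) and Welch's t-test;
#' if either group looks non-normal, the Wilcoxon rank-sum test is used.
#' Groups too small for a normality test (n < 3) force the nonparametric
#' branch.
#'
#' @param x,y Numeric samples, each with n >= 2.
#' @param alpha Assumption-test level (default 0.05).
#' @param var_test `"F"` (default) or `"levene"` (Brown-Forsythe: absolute
#'   deviations from medians compared by ANOVA F).
#' @return An object of class `two_sample_test`: list with `test` (one of
#'   `"student"`, `"welch"`, `"wilcoxon"`), `p.value`, `statistic`, and the
#'   assumption p-values.
#' @export
choose_two_sample_test <- function(x, y, alpha = 0.05,
                                   var_test = c("F", "levene")) {
  var_test <- match.arg(var_test)
  if (length(x) < 2L || length(y) < 2L) abort("each group needs n >= 2")
  shapiro_p <- c(NA_real_, NA_real_)
  if (length(x) >= 3L && length(y) >= 3L && sd(x) > 0 && sd(y) > 0) {
    shapiro_p <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  }
  var_p <- NA_real_
  if (all(!is.na(shapiro_p)) && all(shapiro_p >= alpha)) {
    var_p <- if (var_test == "F") {
      var.test(x, y)$p.value
    } else {
      z <- c(abs(x - median(x)), abs(y - median(y)))
      g <- factor(rep(c("x", "y"), c(length(x), length(y))))
      stats::anova(lm(z ~ g))[1L, "Pr(>F)"]
    }
    if (var_p >= alpha) {
      ht <- t.test(x, y, var.equal = TRUE)
      chosen <- "student"
    } else {
      ht <- t.test(x, y, var.equal = FALSE)
      chosen <- "welch"
    }
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
    chosen <- "wilcoxon"
  }
  structure(list(test = chosen, p.value = ht$p.value,
                 statistic = unname(ht$statistic),
                 shapiro_p = shapiro_p, var_p = var_p),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("<two_sample_test> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p.value))
  invisible(x)
}
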