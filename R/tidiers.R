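#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_vline position_dodge labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.seg_test <- function(x, ...) {
  tibble(class = seq_along(x$observed), observed = x$observed,
         expected = x$expected)
}

#' @exportS3Method generics::glance
glance.seg_test <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p.value = x$p.value,
         low_expected = x$low_expected)
}

#' @exportS3Method generics::tidy
tidy.pref_test <- function(x, ...) {
  tibble(n = x$n, proportion = x$proportion, t = x$t, df = x$df,
         p.value = x$p.value, binom_p = x$binom_p, degenerate = x$degenerate)
}

#' @exportS3Method generics::tidy
tidy.coseg_test <- function(x, ...) {
  tibble(n = x$n, n_missing = x$n_missing, concordant = x$concordant,
         concordance = x$concordance, perm_p = x$perm_p)
}

#' @exportS3Method generics::tidy
tidy.two_sample_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p.value = x$p.value)
}

#' @exportS3Method generics::tidy
tidy.species_tree_fit <- function(x, ...) x$support

#' @exportS3Method generics::glance
glance.species_tree_fit <- function(x, ...) {
  tibble(n_taxa = length(x$tree$tip.label), score = x$score,
         n_candidates = x$n_candidates,
         mean_q = mean(x$support$q, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.mcl_clusters <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.mcl_clusters <- function(x, ...) {
  tibble(n_clusters = length(unique(x$clusters$cluster)),
         n_nodes = nrow(x$clusters), iterations = x$iterations,
         converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.ortholog_set <- function(x, ...) x$manifest

#' Observed-versus-expected plot for a segregation test
#'
#' @param object A `seg_test` from [chisq_goodness()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.seg_test <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "count")
  ggplot(d, aes(factor(.data$class), .data$count, fill = .data$kind)) +
    geom_col(position = position_dodge()) +
    labs(x = "phenotype class", y = "individuals", fill = NULL,
         title = sprintf("chi-square = %.3g, p = %.3g",
                         object$chi2, object$p.value)) +
    theme_minimal()
}

#' Per-branch quartet support plot for a species-tree fit
#'
#' @param object A `species_tree_fit`.
#' @param ... Unused.
#' @return A ggplot of quartet support per internal branch, with the 1/3
#'   random-resolution floor marked.
#' @exportS3Method ggplot2::autoplot
autoplot.species_tree_fit <- function(object, ...) {
  d <- object$support
  ggplot(d, aes(.data$split, .data$q)) +
    geom_col() +
    geom_hline(yintercept = 1 / 3, linetype = 2) +
    labs(x = "branch (one bipartition side)", y = "quartet support q") +
    theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param records A [de_filter()] output (columns `log2fc`, `padj`,
#'   `flag_de`).
#' @param lfc_cut,alpha Thresholds to draw (defaults match [de_filter()]).
#' @return A ggplot.
#' @export
plot_de_volcano <- function(records, lfc_cut = 2, alpha = 1e-5) {
  stopifnot(all(c("log2fc", "padj") %in% names(records)))
  ggplot(records, aes(.data$log2fc, -log10(.data$padj),
                      colour = .data$flag_de)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = 2) +
    geom_hline(yintercept = -log10(alpha), linetype = 2) +
    labs(x = "log2 fold change (proximal / distal)",
         y = "-log10 adjusted p", colour = "DE") +
    theme_minimal()
}
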