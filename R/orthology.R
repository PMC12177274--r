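#' Extract single-copy ortholog trees by Maximum Inclusion
#'
#' Iteratively extracts from a cleaned homolog tree the rooted subtree
#' (either side of any branch, or the whole tree) that contains no repeated
#' taxon and covers the greatest number of distinct taxa. The winning subtree
#' is emitted as an ortholog and its tips are deleted from the working tree
#' (collapsing unary nodes with length summation) until no duplication-free
#' subtree with at least `min_taxa` taxa remains. Ties between equally
#' taxon-rich candidates break by smaller total branch length, then by
#' lexicographically smallest tip label.
#'
#' Long-tip trimming ([trim_long_tips()] with the absolute/relative cutoffs)
#' is applied once up front by default; set `retrim = TRUE` to re-apply it
#' between iterations.
#'
#' @param tree A homolog tree (`phylo`, tips `taxon@id`).
#' @param params A [cleaning_params()] (absolute/relative trimming cutoffs).
#' @param min_taxa Minimum distinct taxa for an emitted ortholog (default 4).
#' @param trim Apply [trim_long_tips()] before extraction (default TRUE).
#' @param retrim Re-apply trimming after each extraction (default FALSE).
#' @return An object of class `ortholog_set`: list with `orthologs` (list of
#'   `phylo`), `manifest` (tibble: `ortholog_id`, `n_taxa`, `tips`) and
#'   `discarded_tips` (character: tips never placed in an ortholog).
#' @export
maximum_inclusion <- function(tree, params = cleaning_params(), min_taxa = 4,
                              trim = TRUE, retrim = FALSE) {
  stopifnot(inherits(tree, "phylo"), min_taxa >= 1)
  all_tips <- tree$tip.label
  work <- if (trim) trim_long_tips(tree, params) else tree
  orthologs <- list()
  repeat {
    if (!inherits(work, "phylo")) break
    best <- best_inclusion_subtree(work)
    if (is.null(best) || length(unique(taxon_of(best))) < min_taxa) break
    orthologs[[length(orthologs) + 1L]] <- subtree_keep(work, best)
    work <- drop_tips_safe(work, best)
    if (retrim && inherits(work, "phylo"))
      work <- trim_long_tips(work, params)
  }
  used <- unlist(lapply(orthologs, function(o) o$tip.label))
  manifest <- if (length(orthologs)) {
    dplyr::bind_rows(lapply(seq_along(orthologs), function(i) {
      tibble(ortholog_id = i,
             n_taxa = length(unique(taxon_of(orthologs[[i]]$tip.label))),
             tips = paste(sort(orthologs[[i]]$tip.label), collapse = ","))
    }))
  } else {
    tibble(ortholog_id = integer(0), n_taxa = integer(0), tips = character(0))
  }
  structure(list(orthologs = orthologs, manifest = manifest,
                 discarded_tips = setdiff(all_tips, used)),
            class = "ortholog_set")
}

# keep.tip that degrades gracefully for 1-2 tips
subtree_keep <- function(phy, tips) {
  if (length(tips) >= 2L) return(ape::keep.tip(phy, tips))
  degenerate_tree(tips)
}

# candidate duplication-free subtree with most distinct taxa, or NULL.
# Candidates: both sides of every branch, plus the full tip set.
best_inclusion_subtree <- function(phy) {
  tips <- phy$tip.label
  sets <- node_tipsets(phy)
  n_tip <- length(tips)
  root <- n_tip + 1L
  cand <- lapply(setdiff(seq_along(sets), root), function(nd) sets[[nd]])
  cand <- c(cand, lapply(cand, function(s) setdiff(seq_len(n_tip), s)),
            list(seq_len(n_tip)))
  cand <- cand[vapply(cand, length, 0L) >= 1L]
  dup_free <- vapply(cand, function(s) !anyDuplicated(taxon_of(tips[s])), TRUE)
  cand <- unique(lapply(cand[dup_free], sort))
  if (!length(cand)) return(NULL)
  n_taxa <- vapply(cand, function(s) length(unique(taxon_of(tips[s]))), 0L)
  top <- which(n_taxa == max(n_taxa))
  if (length(top) > 1L) {
    # smaller total branch length of the induced subtree
    tot <- vapply(top, function(i) induced_length(phy, cand[[i]]), 0)
    top <- top[tot == min(tot)]
    if (length(top) > 1L) {
      first_lab <- vapply(top, function(i) sort(tips[cand[[i]]])[1L], "")
      top <- top[order(first_lab)][1L]
    } else top <- top[1L]
  } else top <- top[1L]
  tips[cand[[top]]]
}

induced_length <- function(phy, tip_idx) {
  if (length(tip_idx) < 2L) return(0)
  sub <- ape::keep.tip(phy, phy$tip.label[tip_idx])
  sum(sub$edge.length)
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> %d ortholog(s), %d discarded tip(s)\n",
              length(x$orthologs), length(x$discarded_tips)))
  if (nrow(x$manifest)) print(x$manifest)
  invisible(x)
}
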