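#' Cleaning parameters for tree-based homology filtering
#'
#' Bundles the branch-length cutoffs used by [trim_long_tips()],
#' [cut_deep_paralogs()] and [maximum_inclusion()], and the column-occupancy
#' threshold used by [clean_columns()]. Units for the length cutoffs are
#' expected substitutions per site.
#'
#' @param abs_cutoff Pendant branches longer than this are removed outright
#'   (default 0.4 subs/site).
#' @param rel_cutoff Pendant branches longer than this *and* more than
#'   `rel_factor` times the shortest pendant branch in the sister clade are
#'   removed (default 0.6 subs/site). The relative rule guards against
#'   moderately long tips that still dwarf their immediate neighbourhood.
#' @param rel_factor Multiplier for the relative rule (default 10).
#' @param deep_cutoff Internal branches at least this long mark ancient
#'   duplications; [cut_deep_paralogs()] splits trees there (default 1.0).
#' @param min_subclade_taxa Minimum number of distinct taxa a fragment must
#'   contain to survive deep-paralog cutting (default 4).
#' @param min_occupancy Minimum fraction of unambiguous characters a column
#'   must have to be kept by [clean_columns()] (default 0.1; boundary closed,
#'   i.e. occupancy exactly at the threshold is kept).
#' @return A list of class `cleaning_params`.
#' @export
cleaning_params <- function(abs_cutoff = 0.4, rel_cutoff = 0.6,
                            rel_factor = 10, deep_cutoff = 1.0,
                            min_subclade_taxa = 4, min_occupancy = 0.1) {
  stopifnot(abs_cutoff > 0, rel_cutoff > 0, rel_factor > 0, deep_cutoff > 0,
            min_subclade_taxa >= 1,
            min_occupancy > 0, min_occupancy <= 1)
  structure(
    list(abs_cutoff = abs_cutoff, rel_cutoff = rel_cutoff,
         rel_factor = rel_factor, deep_cutoff = deep_cutoff,
         min_subclade_taxa = min_subclade_taxa,
         min_occupancy = min_occupancy),
    class = "cleaning_params"
  )
}

#' Parse and write newick trees
#'
#' `parse_newick()` validates the string (reporting the offset of the first
#' structural problem) and returns an [ape::phylo] tree; `write_newick()` is
#' the inverse. Round-trips preserve topology, labels and branch lengths.
#' Labels may contain `"@"`, which the package reserves to separate the taxon
#' from the transcript identifier.
#'
#' @param text A newick string.
#' @param tree A `phylo` tree.
#' @param digits Significant digits for branch lengths on output.
#' @return `parse_newick()` returns a `phylo`; `write_newick()` a string.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        abort(sprintf("newick parse error at offset %d: unmatched ')'", i))
    }
  }
  if (depth > 0L)
    abort(sprintf("newick parse error at offset %d: %d unclosed '('",
                  length(chars), depth))
  if (!grepl(";\\s*$", text))
    abort(sprintf("newick parse error at offset %d: missing terminal ';'",
                  length(chars)))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    abort("newick parse error: string rejected by tree reader")
  phy$node.label <- NULL
  phy
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

aln_check <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 1L, !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L)
    abort("alignment rows must all have equal length")
  invisible(aln)
}

aln_matrix <- function(aln) {
  aln_check(aln)
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Remove low-occupancy alignment columns
#'
#' Keeps exactly the columns whose fraction of unambiguous characters
#' (A/C/G/T; gaps and N count as missing) is at least `min_occupancy`.
#' Mirrors occupancy cleaning at a 10% threshold; the boundary is closed.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param min_occupancy Minimum kept fraction, in (0, 1].
#' @return The cleaned alignment (named character vector). If every column is
#'   removed, an alignment of empty strings with attribute `empty = TRUE`.
#' @export
clean_columns <- function(aln, min_occupancy = 0.1) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  m <- aln_matrix(aln)
  occ <- colMeans(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m)))
  keep <- occ >= min_occupancy
  out <- apply(m[, keep, drop = FALSE], 1L, paste0, collapse = "")
  out <- setNames(as.character(out), rownames(m))
  if (!any(keep)) {
    out <- setNames(rep("", nrow(m)), rownames(m))
    attr(out, "empty") <- TRUE
  }
  out
}

#' Count informative characters in one alignment row
#'
#' The number of unambiguous nucleotides (A, C, G or T) in the row; gaps,
#' N and other ambiguity codes do not count. Used to pick which transcript
#' survives monophyly masking.
#'
#' @param aln Named character vector alignment.
#' @param id Row name.
#' @return Integer count.
#' @export
informative_chars <- function(aln, id) {
  aln_check(aln)
  if (!id %in% names(aln)) abort(sprintf("unknown alignment row '%s'", id))
  sum(strsplit(toupper(aln[[id]]), "")[[1]] %in% c("A", "C", "G", "T"))
}

#' Jukes-Cantor pairwise distances
#'
#' For each pair of rows, the mismatch fraction `p` over sites where both are
#' unambiguous is converted to `d = -3/4 * log(1 - 4p/3)` expected
#' substitutions per site. Saturated pairs (`p >= 0.75`, where the formula
#' diverges) are set to `ceiling` and flagged in attribute `capped`.
#'
#' @param aln Named character vector alignment with at least two rows.
#' @param ceiling Distance assigned to saturated pairs (default 5).
#' @return A symmetric matrix with zero diagonal; attribute `capped` lists
#'   saturated pairs (possibly empty).
#' @export
jc_distance <- function(aln, ceiling = 5) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) abort("need at least two rows")
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    if (!any(shared))
      abort(sprintf("no shared unambiguous sites between '%s' and '%s'",
                    rownames(m)[i], rownames(m)[j]))
    p <- mean(m[i, shared] != m[j, shared])
    if (p >= 0.75) {
      dij <- ceiling
      capped <- c(capped, paste(rownames(m)[i], rownames(m)[j], sep = "|"))
    } else {
      dij <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- dij
  }
  attr(d, "capped") <- capped
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ agglomeration (via [ape::nj()]), used here as the distance-based
#' stand-in for maximum-likelihood gene-tree inference. Negative estimated
#' branch lengths are clamped to zero and flagged.
#'
#' @param dist Symmetric numeric matrix with row/column names, `n >= 3`.
#' @return A `phylo` tree; attribute `clamped` gives the number of branches
#'   clamped to zero.
#' @export
neighbor_joining <- function(dist) {
  stopifnot(is.matrix(dist), nrow(dist) >= 3L, isTRUE(all.equal(dist, t(dist))))
  if (any(is.na(dist)) || any(is.nan(dist))) abort("NaN/NA in distance matrix")
  phy <- ape::nj(as.dist(dist))
  n_neg <- sum(phy$edge.length < 0)
  phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped") <- n_neg
  phy
}

# tip indices descending from each node (tips map to themselves)
node_tipsets <- function(phy) {
  n_tip <- length(phy$tip.label)
  edge <- stats::reorder(phy, "postorder")$edge  # children before parents
  sets <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

pendant_lengths <- function(phy) {
  n_tip <- length(phy$tip.label)
  idx <- match(seq_len(n_tip), phy$edge[, 2L])
  setNames(phy$edge.length[idx], phy$tip.label)
}

degenerate_tree <- function(tips) {
  structure(list(tip.label = tips, degenerate = TRUE), class = "degenerate_tree")
}

drop_tips_safe <- function(phy, drop) {
  keep <- setdiff(phy$tip.label, drop)
  if (length(keep) < 2L) return(degenerate_tree(keep))
  ape::keep.tip(phy, keep)
}

#' Remove implausibly long terminal branches
#'
#' Applies two rules to pendant (tip) branches, both evaluated on the input
#' tree before any removal: (1) absolute — pendant length greater than
#' `abs_cutoff`; (2) relative — pendant length greater than `rel_cutoff` and
#' more than `rel_factor` times the shortest pendant branch among the tips of
#' the sister clade. Offending tips are removed together; unary nodes are then
#' collapsed with their branch lengths summed, so path lengths between
#' surviving tips are conserved.
#'
#' @param tree A `phylo` tree with branch lengths in subs/site.
#' @param params A [cleaning_params()] object.
#' @return The trimmed tree with attribute `removed` (tibble: `tip`, `rule`,
#'   `pendant`). If fewer than two tips survive, a degenerate stub of class
#'   `degenerate_tree` carrying the survivors is returned.
#' @export
trim_long_tips <- function(tree, params = cleaning_params()) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "cleaning_params"))
  pend <- pendant_lengths(tree)
  n_tip <- length(tree$tip.label)
  sets <- node_tipsets(tree)
  rule <- rep(NA_character_, n_tip)
  for (i in seq_len(n_tip)) {
    if (pend[i] > params$abs_cutoff) { rule[i] <- "absolute"; next }
    if (pend[i] > params$rel_cutoff) {
      parent <- tree$edge[match(i, tree$edge[, 2L]), 1L]
      sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], i)
      sib_tips <- setdiff(unlist(sets[sibs]), i)
      if (length(sib_tips) &&
          pend[i] > params$rel_factor * min(pend[sib_tips]))
        rule[i] <- "relative"
    }
  }
  bad <- which(!is.na(rule))
  removed <- tibble(tip = tree$tip.label[bad], rule = rule[bad],
                    pendant = unname(pend[bad]))
  out <- if (length(bad)) drop_tips_safe(tree, tree$tip.label[bad]) else tree
  attr(out, "removed") <- removed
  out
}

#' Collapse monophyletic same-taxon tip groups to their best transcript
#'
#' Wherever two or more tips of the same taxon form a monophyletic group
#' (maximal clade containing tips of only that taxon), only the tip whose
#' alignment row has the most informative characters is kept; ties break by
#' lexicographically smallest tip label. The reduction is iterated to a fixed
#' point.
#'
#' @param tree A `phylo` with tips labelled `taxon@id`.
#' @param aln Named character alignment covering every tip.
#' @return The masked tree with attribute `masked` listing removed tips.
#' @export
mask_monophyletic_duplicates <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"))
  aln_check(aln)
  if (!all(tree$tip.label %in% names(aln)))
    abort("alignment is missing rows for some tips")
  info <- vapply(tree$tip.label, function(id) informative_chars(aln, id), 0L)
  masked <- character(0)
  repeat {
    if (!inherits(tree, "phylo") || length(tree$tip.label) < 3L) break
    tax <- taxon_of(tree$tip.label)
    n_tip <- length(tree$tip.label)
    sets <- node_tipsets(tree)
    mono <- vapply(sets, function(s) length(unique(tax[s])) == 1L, TRUE)
    parent_of <- function(nd) tree$edge[match(nd, tree$edge[, 2L]), 1L]
    # maximal mono-taxon clades with >= 2 tips
    drop <- character(0)
    for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
      if (!mono[nd]) next
      p <- parent_of(nd)
      if (!is.na(p) && mono[p]) next  # not maximal
      grp <- tree$tip.label[sets[[nd]]]
      best <- grp[order(-info[grp], grp)][1L]
      drop <- c(drop, setdiff(grp, best))
    }
    if (!length(drop)) break
    masked <- c(masked, drop)
    tree <- drop_tips_safe(tree, drop)
  }
  attr(tree, "masked") <- masked
  tree
}

#' Split a homolog tree at deep-paralog branches
#'
#' Every internal branch whose length is at least `deep_cutoff` (marking an
#' ancient duplication) is cut; fragments containing at least
#' `min_subclade_taxa` distinct taxa become independent homolog trees, smaller
#' fragments are reported discarded. With no qualifying branch the input is
#' returned as a singleton list.
#'
#' @param tree A `phylo` tree.
#' @param params A [cleaning_params()] object.
#' @return A list of `phylo` trees with attribute `discarded` (tibble:
#'   `tips`, `n_taxa` per discarded fragment).
#' @export
cut_deep_paralogs <- function(tree, params = cleaning_params()) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "cleaning_params"))
  n_tip0 <- length(tree$tip.label)
  has_deep <- any(tree$edge[, 2L] > n_tip0 &
                    tree$edge.length >= params$deep_cutoff)
  if (!has_deep) {
    out <- list(tree)
    attr(out, "discarded") <- tibble(tips = character(0), n_taxa = integer(0))
    return(out)
  }
  discarded <- list()
  kept <- list()
  recurse <- function(phy) {
    if (inherits(phy, "phylo") && !is.null(phy$edge.length)) {
      n_tip <- length(phy$tip.label)
      internal <- phy$edge[, 2L] > n_tip
      deep <- which(internal & phy$edge.length >= params$deep_cutoff)
      if (length(deep)) {
        e <- deep[which.max(phy$edge.length[deep])]
        node <- phy$edge[e, 2L]
        clade <- ape::extract.clade(phy, node)
        rest <- drop_tips_safe(phy, clade$tip.label)
        recurse(clade)
        recurse(rest)
        return(invisible())
      }
    }
    tips <- phy$tip.label
    n_taxa <- length(unique(taxon_of(tips)))
    if (inherits(phy, "phylo") && n_taxa >= params$min_subclade_taxa) {
      kept[[length(kept) + 1L]] <<- phy
    } else {
      discarded[[length(discarded) + 1L]] <<-
        tibble(tips = paste(tips, collapse = ","), n_taxa = n_taxa)
    }
    invisible()
  }
  recurse(tree)
  out <- kept
  attr(out, "discarded") <-
    if (length(discarded)) dplyr::bind_rows(discarded)
    else tibble(tips = character(0), n_taxa = integer(0))
  out
}
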