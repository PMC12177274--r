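# quartet machinery: subsets are keyed by the sorted 4 taxa joined with "|";
# resolutions are indexed 1 = t1t2|t3t4, 2 = t1t3|t2t4, 3 = t1t4|t2t3
# (t1 < t2 < t3 < t4).

quartet_key <- function(q) paste(sort(q), collapse = "|")

# which of the three resolutions pairs `pair` within sorted quartet `qs`
pair_resolution <- function(qs, pair) {
  i <- match(pair, qs)
  if (all(c(1L, 2L) %in% i) || all(c(3L, 4L) %in% i)) return(1L)
  if (all(c(1L, 3L) %in% i) || all(c(2L, 4L) %in% i)) return(2L)
  3L
}

# nontrivial bipartition sides of a (rooted-storage) tree, as tip labels
tree_clades <- function(phy) {
  n_tip <- length(phy$tip.label)
  sets <- node_tipsets(phy)
  out <- list()
  for (nd in (n_tip + 1L):(n_tip + phy$Nnode)) {
    s <- sets[[nd]]
    if (length(s) >= 2L && length(s) <= n_tip - 2L)
      out[[length(out) + 1L]] <- phy$tip.label[s]
  }
  out
}

#' Quartet topologies induced by one gene tree
#'
#' For every 4-taxon subset of the tree's tips, reports which of the three
#' unrooted resolutions the tree induces (found via the bipartition that
#' splits the subset two against two). Unresolved (polytomy) subsets are
#' skipped. Trees with fewer than four tips contribute nothing.
#'
#' @param tree A `phylo` tree with taxon tip labels.
#' @return Tibble with columns `t1`-`t4` (sorted taxa) and `resolution`
#'   (1 = `t1,t2 | t3,t4`; 2 = `t1,t3 | t2,t4`; 3 = `t1,t4 | t2,t3`).
#' @export
induced_quartets <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  empty <- tibble(t1 = character(0), t2 = character(0), t3 = character(0),
                  t4 = character(0), resolution = integer(0))
  if (length(tips) < 4L) return(empty)
  clades <- tree_clades(tree)
  subsets <- utils::combn(sort(tips), 4L)
  rows <- list()
  for (s in seq_len(ncol(subsets))) {
    qs <- subsets[, s]
    res <- NA_integer_
    for (cl in clades) {
      inside <- qs[qs %in% cl]
      if (length(inside) == 2L) { res <- pair_resolution(qs, inside); break }
    }
    if (!is.na(res))
      rows[[length(rows) + 1L]] <-
        tibble(t1 = qs[1], t2 = qs[2], t3 = qs[3], t4 = qs[4],
               resolution = res)
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

#' Tally quartet resolutions across gene trees
#'
#' @param gene_trees List of `phylo` gene trees (taxa may be missing from
#'   individual trees; a subset is counted only in trees containing all four
#'   taxa and resolving them).
#' @param taxa Optional full taxon set (default: union over trees).
#' @return Tibble with `t1`-`t4` and counts `n1`, `n2`, `n3` of the three
#'   resolutions.
#' @export
quartet_table <- function(gene_trees, taxa = NULL) {
  taxa <- sort(taxa %||% unique(unlist(lapply(gene_trees,
                                              function(t) t$tip.label))))
  if (length(taxa) < 4L) abort("need at least 4 taxa")
  subsets <- utils::combn(taxa, 4L)
  keys <- apply(subsets, 2L, paste, collapse = "|")
  counts <- matrix(0L, ncol(subsets), 3L)
  for (gt in gene_trees) {
    iq <- induced_quartets(gt)
    if (!nrow(iq)) next
    k <- paste(iq$t1, iq$t2, iq$t3, iq$t4, sep = "|")
    row <- match(k, keys)
    ok <- !is.na(row)
    for (i in which(ok))
      counts[row[i], iq$resolution[i]] <- counts[row[i], iq$resolution[i]] + 1L
  }
  tibble(t1 = subsets[1, ], t2 = subsets[2, ], t3 = subsets[3, ],
         t4 = subsets[4, ], n1 = counts[, 1], n2 = counts[, 2],
         n3 = counts[, 3])
}

# resolution vector of a candidate topology over the canonical subset list
topology_resolutions <- function(phy, subsets) {
  clades <- tree_clades(phy)
  vapply(seq_len(ncol(subsets)), function(s) {
    qs <- subsets[, s]
    for (cl in clades) {
      inside <- qs[qs %in% cl]
      if (length(inside) == 2L) return(pair_resolution(qs, inside))
    }
    NA_integer_
  }, 0L)
}

#' Convert quartet support to a coalescent-unit branch length
#'
#' Inverts the multispecies-coalescent expectation
#' `q = 1 - (2/3) exp(-d)` for an internal species-tree branch:
#' `d = -log(3 (1 - q) / 2)`. Perfect support (`q = 1`) gives an infinite
#' estimate and is capped at `cap` with attribute `capped` set.
#'
#' @param q Quartet support, in `[1/3, 1]` (1/3 is the random-resolution
#'   floor).
#' @param cap Length reported when `q = 1` (default 9 coalescent units).
#' @return Numeric vector of coalescent-unit lengths; attribute `capped` is a
#'   logical vector marking capped entries.
#' @export
coalescent_branch_length <- function(q, cap = 9) {
  if (any(q < 1/3 - 1e-12) || any(q > 1 + 1e-12))
    abort("q must lie in [1/3, 1]")
  q <- pmin(pmax(q, 1/3), 1)
  d <- ifelse(q >= 1, cap, -log(3 * (1 - q) / 2))
  d <- pmin(d, cap)
  attr(d, "capped") <- q >= 1
  d
}

# four neighbour tip groups around each internal edge of an unrooted tree
edge_neighbor_groups <- function(phy) {
  phy <- ape::unroot(phy)
  n_tip <- length(phy$tip.label)
  nb <- vector("list", n_tip + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  comp_tips <- function(start, avoid) {
    seen <- c(avoid, start)
    stack <- start
    tips <- integer(0)
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (v <= n_tip) tips <- c(tips, v)
      for (w in nb[[v]]) if (!w %in% seen) {
        seen <- c(seen, w); stack <- c(stack, w)
      }
    }
    phy$tip.label[tips]
  }
  internal <- which(phy$edge[, 2L] > n_tip)
  lapply(internal, function(e) {
    u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    gu <- lapply(setdiff(nb[[u]], v), comp_tips, avoid = c(u, v))
    gv <- lapply(setdiff(nb[[v]], u), comp_tips, avoid = c(u, v))
    list(u_side = gu, v_side = gv,
         split = sort(unlist(lapply(gv, identity))))
  })
}

#' Exact maximum-quartet-support species tree
#'
#' Enumerates every unrooted binary topology on the taxon set
#' (`(2n-5)!!` of them) and returns the one maximising the number of
#' gene-tree-induced quartets it agrees with — the coalescent-consistent
#' maximum-quartet-support criterion, solved exactly for small taxon sets.
#' Each internal branch is annotated with its quartet support `q` (frequency
#' of the agreeing resolution among gene-tree quartets that span the branch's
#' four neighbouring subtrees, so `q` reflects that single branch) and the
#' corresponding coalescent-unit length from [coalescent_branch_length()].
#'
#' @param gene_trees List of `phylo` gene trees; missing taxa allowed.
#' @param taxa Optional taxon set (default: union over gene trees).
#' @param max_n Enumeration guard (default 9 taxa).
#' @param cap Coalescent-length cap for perfectly supported branches.
#' @return An object of class `species_tree_fit`: list with `tree` (`phylo`,
#'   internal branch lengths in coalescent units, node labels = `q`),
#'   `support` (tibble: `split`, `q`, `coal_len`, `capped`, `n_quartets`),
#'   `score`, `n_candidates`, and the `quartet_table` used.
#' @export
exact_quartet_species_tree <- function(gene_trees, taxa = NULL, max_n = 9,
                                       cap = 9) {
  qt <- quartet_table(gene_trees, taxa)
  taxa <- sort(unique(c(qt$t1, qt$t2, qt$t3, qt$t4)))
  n <- length(taxa)
  if (n > max_n)
    abort(sprintf(
      "%d taxa exceeds max_n = %d: exact enumeration is infeasible, use a heuristic search tool",
      n, max_n))
  subsets <- utils::combn(taxa, 4L)
  counts <- as.matrix(qt[, c("n1", "n2", "n3")])
  candidates <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  scores <- vapply(candidates, function(cand) {
    res <- topology_resolutions(cand, subsets)
    sum(counts[cbind(seq_len(nrow(counts)), res)])
  }, 0)
  best_i <- which.max(scores)
  best <- candidates[[best_i]]
  # per-branch support from the quartets spanning the four neighbour groups
  groups <- edge_neighbor_groups(best)
  keys <- apply(subsets, 2L, paste, collapse = "|")
  support_rows <- lapply(groups, function(g) {
    four <- c(g$u_side, g$v_side)
    combos <- expand.grid(lapply(four, identity), stringsAsFactors = FALSE)
    agree <- 0; total <- 0
    for (r in seq_len(nrow(combos))) {
      qs <- sort(unlist(combos[r, ]))
      row <- match(paste(qs, collapse = "|"), keys)
      # the resolution this branch implies: pair = the two taxa on the v side
      inside <- qs[qs %in% unlist(g$v_side)]
      res <- pair_resolution(qs, inside)
      agree <- agree + counts[row, res]
      total <- total + sum(counts[row, ])
    }
    q <- if (total > 0) agree / total else NA_real_
    tibble(split = paste(g$split, collapse = ","), q = unname(q),
           n_quartets = unname(total))
  })
  support <- dplyr::bind_rows(support_rows)
  d <- rep(NA_real_, nrow(support))
  capped <- rep(FALSE, nrow(support))
  ok <- !is.na(support$q) & support$q >= 1/3
  if (any(ok)) {
    dd <- coalescent_branch_length(support$q[ok], cap = cap)
    d[ok] <- as.numeric(dd)
    capped[ok] <- attr(dd, "capped")
  }
  low <- !is.na(support$q) & support$q < 1/3
  d[low] <- 0  # below the random floor: no signal, length indistinguishable from 0
  support$coal_len <- d
  support$capped <- capped
  # write lengths/support onto the unrooted best topology
  fit_tree <- ape::unroot(best)
  n_tip <- length(fit_tree$tip.label)
  fit_tree$edge.length <- rep(0, nrow(fit_tree$edge))
  sets <- node_tipsets(fit_tree)
  fit_tree$node.label <- rep("", fit_tree$Nnode)
  for (i in seq_len(nrow(support))) {
    split_tips <- strsplit(support$split[i], ",")[[1]]
    hit <- which(vapply(seq_along(sets), function(nd) {
      nd > n_tip && setequal(fit_tree$tip.label[sets[[nd]]], split_tips)
    }, TRUE))
    if (length(hit) == 1L) {
      e <- match(hit, fit_tree$edge[, 2L])
      fit_tree$edge.length[e] <- support$coal_len[i]
      fit_tree$node.label[hit - n_tip] <- formatC(support$q[i], digits = 4,
                                                  format = "f")
    }
  }
  structure(list(tree = fit_tree, support = support,
                 score = scores[best_i], n_candidates = length(candidates),
                 quartet_table = qt),
            class = "species_tree_fit")
}

#' @export
print.species_tree_fit <- function(x, ...) {
  cat(sprintf("<species_tree_fit> %d taxa, score %g over %d candidate topologies\n",
              length(x$tree$tip.label), x$score, x$n_candidates))
  print(x$support)
  invisible(x)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' A lightweight MSC simulator for recovery experiments: within each species
#' branch the lineages present coalesce at rate 1 per pair per coalescent
#' unit; lineages surviving to the root coalesce freely. One haploid sample
#' per species. The species tree must be rooted and ultrametric with branch
#' lengths in coalescent units.
#'
#' @param species_tree Rooted ultrametric `phylo`, lengths in coalescent
#'   units.
#' @param n_loci Number of independent gene trees.
#' @param seed RNG seed.
#' @return List of `phylo` gene trees with coalescent-unit branch lengths.
#' @export
sim_msc_gene_trees <- function(species_tree, n_loci, seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"), n_loci >= 1)
  assert_seed(seed)
  phy <- species_tree
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth) - depth  # time before present; tips ~ 0
  parent_of <- function(nd) phy$edge[match(nd, phy$edge[, 2L]), 1L]
  with_seed_or_not(seed, {
    lapply(seq_len(n_loci), function(l) {
      coalesce <- function(lins, t0, t1) {
        t <- t0
        while (length(lins) >= 2L) {
          k <- length(lins)
          t <- t + rexp(1, k * (k - 1) / 2)
          if (t >= t1) break
          pick <- sample.int(k, 2L)
          a <- lins[[pick[1L]]]; b <- lins[[pick[2L]]]
          joined <- list(
            nwk = sprintf("(%s:%.8f,%s:%.8f)", a$nwk, t - a$h, b$nwk, t - b$h),
            h = t)
          lins <- c(lins[-pick], list(joined))
        }
        lins
      }
      sim_node <- function(nd) {
        lins <- if (nd <= n_tip) {
          list(list(nwk = phy$tip.label[nd], h = age[nd]))
        } else {
          kids <- phy$edge[phy$edge[, 1L] == nd, 2L]
          unlist(lapply(kids, sim_node), recursive = FALSE)
        }
        p <- parent_of(nd)
        top <- if (is.na(p)) Inf else age[p]
        coalesce(lins, age[nd], top)
      }
      root <- n_tip + 1L
      res <- sim_node(root)
      stopifnot(length(res) == 1L)
      parse_newick(paste0(res[[1L]]$nwk, ";"))
    })
  })
}
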