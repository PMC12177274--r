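# Fixture builders and independent oracle implementations used across tests.
# Oracles deliberately take different computational routes from the package.

taxon_of_test <- function(labels) sub("@.*$", "", labels)

# all distinct orderings of a small vector (exact permutation enumeration)
combinat_perms <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_perms(x[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(x[i], r)
  }
  out
}

# deterministic pseudo-random nucleotide vector (no RNG state touched)
sample_seq_det <- function(n) {
  c("A", "C", "G", "T")[(cumsum(seq_len(n) * 7L) %% 4L) + 1L]
}

barbell_graph <- function(w_clique = 5, w_bridge = 1) {
  cl1 <- c("a1", "a2", "a3", "a4"); cl2 <- c("b1", "b2", "b3", "b4")
  rows <- list()
  for (s in list(cl1, cl2))
    for (i in 1:3) for (j in (i + 1):4)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(id_a = s[i], id_b = s[j], score = w_clique)
  rows[[length(rows) + 1L]] <-
    tibble::tibble(id_a = "a1", id_b = "b1", score = w_bridge)
  dplyr::bind_rows(rows)
}

# direct re-implementation of the MCL expansion/inflation iteration,
# written matrix-free-of-package-code; clusters = connected components of
# the nonzero structure of the limit matrix (igraph route)
oracle_mcl <- function(graph, inflation = 1.4, tol = 1e-6, max_iter = 200) {
  ids <- sort(unique(c(graph$id_a, graph$id_b)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(graph))) {
    A[graph$id_a[r], graph$id_b[r]] <- graph$score[r]
    A[graph$id_b[r], graph$id_a[r]] <- graph$score[r]
  }
  selfw <- apply(A, 2, max); selfw[selfw == 0] <- 1
  diag(A) <- selfw
  M <- A %*% diag(1 / colSums(A))
  for (it in seq_len(max_iter)) {
    Mn <- (M %*% M)^inflation
    Mn[Mn < 1e-9] <- 0
    Mn <- Mn %*% diag(1 / colSums(Mn))
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  g <- igraph::graph_from_adjacency_matrix((M > 0) + 0, mode = "max")
  comp <- igraph::components(g)$membership
  split(ids, comp)
}

same_partition <- function(clusters_tbl, member_list) {
  a <- lapply(split(clusters_tbl$id, clusters_tbl$cluster), sort)
  b <- lapply(member_list, sort)
  setequal(lapply(a, paste, collapse = ","), lapply(b, paste, collapse = ","))
}

# all tip sets that form one side of some branch (plus the full set),
# computed by deleting each edge from an igraph copy of the tree
oracle_subtree_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  g <- igraph::graph_from_edgelist(phy$edge, directed = FALSE)
  sets <- list(sort(phy$tip.label))
  for (e in seq_len(nrow(phy$edge))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, phy$edge[e, ]))
    comp <- igraph::components(g2)$membership
    for (side in unique(comp)) {
      tips <- which(comp == side & seq_along(comp) <= n_tip)
      if (length(tips))
        sets[[length(sets) + 1L]] <- sort(phy$tip.label[tips])
    }
  }
  unique(sets)
}

# brute-force Maximum Inclusion: enumerate duplication-free subtree tip sets,
# greedily take the taxon-richest (package tie-breaks mirrored), delete, repeat
oracle_mi <- function(phy, min_taxa = 4) {
  taxon <- function(x) sub("@.*$", "", x)
  out <- list()
  work <- phy
  repeat {
    if (!inherits(work, "phylo")) break
    cand <- oracle_subtree_sets(work)
    cand <- cand[vapply(cand, function(s) !anyDuplicated(taxon(s)), TRUE)]
    if (!length(cand)) break
    ntax <- vapply(cand, function(s) length(unique(taxon(s))), 0L)
    best <- which(ntax == max(ntax))
    if (length(best) > 1L) {
      tot <- vapply(best, function(i) {
        s <- cand[[i]]
        if (length(s) < 2) 0 else sum(ape::keep.tip(work, s)$edge.length)
      }, 0)
      best <- best[tot == min(tot)]
      if (length(best) > 1L)
        best <- best[order(vapply(best, function(i) cand[[i]][1], ""))][1]
    }
    s <- cand[[best[1]]]
    if (length(unique(taxon(s))) < min_taxa) break
    out[[length(out) + 1L]] <- s
    keep <- setdiff(work$tip.label, s)
    work <- if (length(keep) >= 2) ape::keep.tip(work, keep) else NULL
  }
  out
}

# random homolog tree: n tips drawn over a small taxon pool (duplicates allowed)
random_homolog_tree <- function(n_tips = 12, n_taxa = 6) {
  phy <- ape::rtree(n_tips)
  tax <- sample(LETTERS[seq_len(n_taxa)], n_tips, replace = TRUE)
  copy <- stats::ave(seq_len(n_tips), tax, FUN = seq_along)
  phy$tip.label <- sprintf("%s@%d", tax, copy)
  phy
}

# quartet resolution by the path-length route: pairing with the minimal
# summed pairwise distance (all branch lengths set to 1)
oracle_quartet_resolution <- function(phy, qs) {
  p2 <- phy
  p2$edge.length <- rep(1, nrow(p2$edge))
  d <- ape::cophenetic.phylo(p2)
  qs <- sort(qs)
  s1 <- d[qs[1], qs[2]] + d[qs[3], qs[4]]
  s2 <- d[qs[1], qs[3]] + d[qs[2], qs[4]]
  s3 <- d[qs[1], qs[4]] + d[qs[2], qs[3]]
  s <- c(s1, s2, s3)
  if (sum(s == min(s)) > 1) return(NA_integer_)  # unresolved
  which.min(s)
}

# resolution of every 4-subset of a tree at once (path-distance route,
# topological distances computed a single time)
oracle_tree_resolutions <- function(phy, subsets) {
  p2 <- phy
  p2$edge.length <- rep(1, nrow(p2$edge))
  d <- ape::cophenetic.phylo(p2)
  vapply(seq_len(ncol(subsets)), function(s) {
    qs <- subsets[, s]
    if (!all(qs %in% phy$tip.label)) return(NA_integer_)
    v <- c(d[qs[1], qs[2]] + d[qs[3], qs[4]],
           d[qs[1], qs[3]] + d[qs[2], qs[4]],
           d[qs[1], qs[4]] + d[qs[2], qs[3]])
    if (sum(v == min(v)) > 1) return(NA_integer_)
    which.min(v)
  }, 0L)
}

# total quartet agreement of topology `cand` with gene trees, via the oracle
# resolution routine on every 4-subset
oracle_quartet_score <- function(cand, gene_trees, gene_res = NULL) {
  taxa <- sort(cand$tip.label)
  subsets <- utils::combn(taxa, 4)
  rc <- oracle_tree_resolutions(cand, subsets)
  if (is.null(gene_res))
    gene_res <- lapply(gene_trees, oracle_tree_resolutions, subsets = subsets)
  score <- 0
  for (rg in gene_res)
    score <- score + sum(!is.na(rg) & !is.na(rc) & rg == rc)
  score
}

# step-up BH computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    padj_sorted[i] <- min(prev, 1)
  }
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# independent event-by-event gene-family tip-count simulator (queue-based,
# no tree construction) for the Monte-Carlo moment comparison
oracle_family_tip_count <- function(phy, dup_rate, loss_rate) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  total <- 0L
  # each queue entry: (species node to enter, remaining branch length above it)
  queue <- list(list(node = root, rem = 0))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    rem <- cur$rem
    alive <- TRUE
    while (rem > 0 && (dup_rate + loss_rate) > 0) {
      t_ev <- stats::rexp(1, dup_rate + loss_rate)
      if (t_ev >= rem) break
      rem <- rem - t_ev
      if (stats::runif(1) < loss_rate / (dup_rate + loss_rate)) {
        alive <- FALSE; break
      }
      queue[[length(queue) + 1L]] <- list(node = cur$node, rem = rem)
    }
    if (!alive) next
    nd <- cur$node
    if (nd <= n_tip) { total <- total + 1L; next }
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    for (k in kids) {
      el <- phy$edge.length[match(k, phy$edge[, 2])]
      queue[[length(queue) + 1L]] <- list(node = k, rem = el)
    }
  }
  total
}

# six-taxon ultrametric species tree used by recovery experiments;
# internal branches >= 1 coalescent unit
recovery_species_tree <- function() {
  petalbull::parse_newick(
    "(((a:3,b:3):1.5,(c:2.5,d:2.5):2):1,(e:4.5,f:4.5):1);")
}
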