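#' Greedy redundancy reduction of a transcript set
#'
#' Records are sorted by decreasing length; each record joins the first
#' existing representative with which its containment identity (best gapless
#' placement of the shorter sequence inside the longer, matches / shorter
#' length) reaches `identity_threshold`, otherwise it becomes a new
#' representative. Mirrors greedy 0.99-identity dedup of assembled
#' transcriptomes. Idempotent: re-running on its own output changes nothing.
#'
#' @param records Tibble with columns `id`, `seq` (ids unique, seqs
#'   non-empty).
#' @param identity_threshold Fraction in (0, 1] (default 0.99).
#' @return List with `representatives` (tibble `id`, `seq`) and `members`
#'   (tibble `representative`, `id`).
#' @export
dedup_greedy <- function(records, identity_threshold = 0.99) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(records) == 0L)
    return(list(representatives = records,
                members = tibble(representative = character(0),
                                 id = character(0))))
  stopifnot(!anyDuplicated(records$id), all(nchar(records$seq) > 0))
  ord <- order(-nchar(records$seq), records$id)
  recs <- records[ord, ]
  reps <- integer(0)      # row indices into recs
  assign_to <- integer(nrow(recs))
  split_cache <- lapply(recs$seq, function(s) strsplit(toupper(s), "")[[1]])
  for (i in seq_len(nrow(recs))) {
    hit <- 0L
    for (r in reps) {
      if (containment_identity(split_cache[[i]], split_cache[[r]]) >=
          identity_threshold) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, i); assign_to[i] <- i }
    else assign_to[i] <- hit
  }
  list(
    representatives = recs[reps, ],
    members = tibble(representative = recs$id[assign_to], id = recs$id)
  )
}

# best gapless placement of the shorter vector inside the longer;
# identity = max matches / length(shorter)
containment_identity <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  m <- length(a); n <- length(b)
  best <- 0L
  for (off in 0:(n - m)) {
    matches <- sum(a == b[(off + 1L):(off + m)])
    if (matches > best) best <- matches
    if (best == m) break
  }
  best / m
}

seq_kmers <- function(s, k) {
  v <- toupper(s)
  L <- nchar(v)
  unique(substring(v, 1:(L - k + 1L), k:L))
}

#' Build a shared k-mer similarity graph
#'
#' All-by-all similarity scoring of sequences as the number of distinct
#' shared k-mers (single-strand; no reverse-complement matching). Pairs with
#' score below `min_score` get no edge. The graph is undirected with each
#' pair stored once (`id_a < id_b`) and no self-loops.
#'
#' @param records Tibble with `id`, `seq`.
#' @param k K-mer size (>= 4, default 21).
#' @param min_score Minimum score to keep an edge (default 1).
#' @return Tibble with columns `id_a`, `id_b`, `score`.
#' @export
build_similarity_graph <- function(records, k = 21, min_score = 1) {
  stopifnot(k >= 4)
  if (any(nchar(records$seq) < k))
    abort("k exceeds the length of the shortest sequence")
  sets <- lapply(records$seq, seq_kmers, k = k)
  n <- nrow(records)
  rows <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sc <- length(intersect(sets[[i]], sets[[j]]))
    if (sc >= min_score) {
      a <- records$id[i]; b <- records$id[j]
      rows[[length(rows) + 1L]] <-
        tibble(id_a = min(a, b), id_b = max(a, b), score = sc)
    }
  }
  if (!length(rows))
    return(tibble(id_a = character(0), id_b = character(0),
                  score = numeric(0)))
  dplyr::bind_rows(rows)
}

#' Markov clustering of a similarity graph
#'
#' Standard MCL: build a column-stochastic transition matrix from the edge
#' scores (self-loops of weight equal to each node's maximum incident edge
#' weight are added first, a common stabilisation), then iterate expansion
#' (matrix squaring) and inflation (elementwise power `inflation`, column
#' renormalisation, pruning of entries below `prune`) until the largest
#' column change drops below `tol`. Clusters are read off the limit matrix:
#' attractors are rows with positive diagonal; each node joins the cluster of
#' its largest-probability attractor (ties by lexicographic node id), and
#' attractors sharing support are merged.
#'
#' @param graph Edge tibble (`id_a`, `id_b`, `score`), or additionally a
#'   character vector of isolated node ids via `nodes`.
#' @param inflation Inflation exponent > 1 (default 1.4, the setting used for
#'   refining transcript clusters).
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 200).
#' @param prune Entries below this are zeroed each iteration (default 1e-9).
#' @param nodes Optional full node set (to include singletons with no edge).
#' @return An object of class `mcl_clusters`: list with `clusters` (tibble
#'   `cluster`, `id`), `iterations`, `converged`.
#' @export
mcl <- function(graph, inflation = 1.4, tol = 1e-6, max_iter = 200,
                prune = 1e-9, nodes = NULL) {
  stopifnot(inflation > 1)
  ids <- sort(unique(c(graph$id_a, graph$id_b, nodes)))
  if (!length(ids)) abort("empty graph")
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph)) {
    ia <- match(graph$id_a, ids); ib <- match(graph$id_b, ids)
    if (any(ia == ib)) abort("self-loops are not allowed in the input graph")
    if (any(graph$score < 0)) abort("scores must be >= 0")
    M[cbind(ia, ib)] <- graph$score
    M[cbind(ib, ia)] <- graph$score
  }
  loop <- apply(M, 2L, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(sprintf("MCL did not converge in %d iterations; returning partial result",
                 max_iter))
  clusters <- read_off_clusters(M, ids)
  structure(list(clusters = clusters, iterations = iter,
                 converged = converged),
            class = "mcl_clusters")
}

read_off_clusters <- function(M, ids) {
  n <- length(ids)
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate safeguard
  # assign each node to its largest-probability attractor (ties: lexicographic)
  owner <- integer(n)
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    if (max(w) <= 0) { owner[j] <- j; next }
    cand <- attractors[w == max(w)]
    owner[j] <- cand[order(ids[cand])][1L]
  }
  # merge attractors that share any node support (attractor systems)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (j in seq_len(n)) {
    sup <- attractors[M[attractors, j] > 0]
    if (length(sup) > 1L) for (s in sup[-1L]) union2(sup[1L], s)
  }
  for (j in seq_len(n)) union2(j, owner[j])
  root <- vapply(seq_len(n), find, 0L)
  cl_id <- as.integer(factor(root, levels = sort(unique(root))))
  tibble(cluster = cl_id, id = ids) |> dplyr::arrange(.data$cluster, .data$id)
}
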