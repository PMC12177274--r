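#' Species tree template for the simulators
#'
#' Wraps a rooted binary tree whose branch lengths are in coalescent units
#' together with a multiplier that converts coalescent units into expected
#' substitutions per site (so simulated gene trees carry subs/site lengths,
#' matching what the cleaning operators expect).
#'
#' @param newick Rooted binary newick string with branch lengths in
#'   coalescent units and unique tip labels.
#' @param subs_scale Substitutions/site per coalescent unit (default 0.02,
#'   a shallow-radiation scale under which default cleaning cutoffs leave
#'   genuine branches untouched).
#' @return An object of class `sim_species_tree` (fields `tree`, `subs_scale`).
#' @export
sim_species_tree <- function(newick, subs_scale = 0.02) {
  phy <- if (inherits(newick, "phylo")) newick else parse_newick(newick)
  if (length(phy$tip.label) < 2L) abort("species tree needs >= 2 tips")
  if (anyDuplicated(phy$tip.label)) abort("tip labels must be unique")
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    abort("species tree needs non-negative branch lengths")
  stopifnot(subs_scale > 0)
  structure(list(tree = phy, subs_scale = subs_scale),
            class = "sim_species_tree")
}

#' Configuration for gene-family simulation
#'
#' @param n_families Number of families to simulate.
#' @param dup_rate,loss_rate Poisson rates of duplication/loss events per
#'   branch per coalescent unit.
#' @param seq_length Alignment length in sites.
#' @param contaminant_prob Probability that a tip's pendant branch is inflated
#'   to `contaminant_length`, mimicking misassembled long-branch transcripts.
#' @param contaminant_length Pendant length (subs/site) given to contaminants
#'   (default 0.8, comfortably past the 0.4 absolute trimming cutoff).
#' @param seed RNG seed.
#' @return A list of class `gene_family_config`.
#' @export
gene_family_config <- function(n_families = 1, dup_rate = 0, loss_rate = 0,
                               seq_length = 500, contaminant_prob = 0,
                               contaminant_length = 0.8, seed = NULL) {
  stopifnot(n_families >= 1, dup_rate >= 0, loss_rate >= 0, seq_length >= 1,
            contaminant_prob >= 0, contaminant_prob <= 1,
            contaminant_length > 0)
  assert_seed(seed)
  structure(list(n_families = n_families, dup_rate = dup_rate,
                 loss_rate = loss_rate, seq_length = seq_length,
                 contaminant_prob = contaminant_prob,
                 contaminant_length = contaminant_length, seed = seed),
            class = "gene_family_config")
}

# one gene lineage evolving down the species tree; returns nested node list
# or NULL if the lineage is lost. Nodes: list(label=, children=, blen=, dup=)
# blen in coalescent units (scaled later).
evolve_lineage <- function(stree, sp_node, remaining, acc, cfg) {
  rate <- cfg$dup_rate + cfg$loss_rate
  if (rate > 0 && remaining > 0) {
    t_ev <- rexp(1, rate)
    if (t_ev < remaining) {
      is_dup <- runif(1) < cfg$dup_rate / rate
      if (!is_dup) return(NULL)  # loss
      a <- evolve_lineage(stree, sp_node, remaining - t_ev, 0, cfg)
      b <- evolve_lineage(stree, sp_node, remaining - t_ev, 0, cfg)
      blen <- acc + t_ev
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a) || is.null(b)) {  # collapse single-child dup node
        kid <- if (is.null(a)) b else a
        kid$blen <- kid$blen + blen
        return(kid)
      }
      return(list(children = list(a, b), blen = blen, dup = TRUE))
    }
  }
  # reached sp_node with no event in this stretch
  phy <- stree$tree
  n_tip <- length(phy$tip.label)
  blen_here <- acc + remaining
  if (sp_node <= n_tip)
    return(list(label = phy$tip.label[sp_node], blen = blen_here, dup = FALSE))
  kids <- phy$edge[phy$edge[, 1L] == sp_node, 2L]
  sub <- list()
  for (k in kids) {
    el <- phy$edge.length[match(k, phy$edge[, 2L])]
    r <- evolve_lineage(stree, k, el, 0, cfg)
    if (!is.null(r)) sub[[length(sub) + 1L]] <- r
  }
  if (!length(sub)) return(NULL)
  if (length(sub) == 1L) {
    kid <- sub[[1L]]
    kid$blen <- kid$blen + blen_here
    return(kid)
  }
  list(children = sub, blen = blen_here, dup = FALSE)
}

gene_node_to_newick <- function(node) {
  if (!is.null(node$label))
    return(sprintf("%s:%.10f", node$label, node$blen))
  inner <- vapply(node$children, gene_node_to_newick, "")
  sprintf("(%s):%.10f", paste(inner, collapse = ","), node$blen)
}

count_tips_nested <- function(node) {
  if (!is.null(node$label)) return(1L)
  sum(vapply(node$children, count_tips_nested, 0L))
}

# locus-tracking ground truth: a duplication founds a new locus in its
# second child while the first continues the parental locus; tips sharing a
# locus are related by speciation events only (the single-copy groups)
true_ortholog_groups <- function(node) {
  groups <- new.env()
  occ <- new.env()  # per-taxon occurrence counter, in-order (= newick order)
  next_locus <- 1L
  walk <- function(n, locus) {
    if (!is.null(n$label)) {
      k <- get0(n$label, envir = occ, inherits = FALSE, ifnotfound = 0L) + 1L
      assign(n$label, k, envir = occ)
      cur <- get0(as.character(locus), envir = groups, inherits = FALSE,
                  ifnotfound = character(0))
      assign(as.character(locus), c(cur, paste(n$label, k, sep = "\r")),
             envir = groups)
      return(invisible())
    }
    if (isTRUE(n$dup)) {
      walk(n$children[[1L]], locus)
      for (k in seq_along(n$children)[-1L]) {
        next_locus <<- next_locus + 1L
        walk(n$children[[k]], next_locus)
      }
    } else {
      for (k in n$children) walk(k, locus)
    }
    invisible()
  }
  walk(node, 1L)
  out <- lapply(sort(as.integer(ls(groups))), function(l)
    get(as.character(l), envir = groups))
  out
}

#' Simulate a gene family along a species tree
#'
#' Grows one gene lineage from the root of the species tree; duplication and
#' loss events occur as a Poisson process along each branch (a duplication
#' copies the whole subtending lineage, a loss kills it). Tips are labelled
#' `taxon@family.copy`. Branch lengths are converted to substitutions/site
#' with `subs_scale`; each tip may then be turned into a long-branch
#' contaminant with probability `contaminant_prob`.
#'
#' @param species_tree A [sim_species_tree()].
#' @param cfg A [gene_family_config()]; `cfg$n_families` independent families
#'   are drawn.
#' @return A list of families; each is a list with elements `tree` (`phylo`,
#'   or degenerate stub), `ortholog_groups` (list of tip-label vectors: the
#'   true single-copy groups by locus tracking — a duplication founds a new
#'   locus in one descendant lineage, so tips of one locus are related by
#'   speciations only), `contaminants` (character) and `degenerate`
#'   (logical, fewer than two surviving tips).
#' @export
simulate_gene_family <- function(species_tree, cfg = gene_family_config()) {
  stopifnot(inherits(species_tree, "sim_species_tree"),
            inherits(cfg, "gene_family_config"))
  with_seed_or_not(cfg$seed, {
    lapply(seq_len(cfg$n_families), function(fam) {
      phy <- species_tree$tree
      root <- length(phy$tip.label) + 1L
      g <- evolve_lineage(species_tree, root, 0, 0, cfg)
      if (is.null(g) || count_tips_nested(g) < 2L) {
        tips <- if (is.null(g)) character(0) else g$label
        return(list(tree = degenerate_tree(tips),
                    ortholog_groups = list(), contaminants = character(0),
                    degenerate = TRUE))
      }
      groups <- true_ortholog_groups(g)
      txt <- paste0(gene_node_to_newick(g), ";")
      gt <- parse_newick(txt)
      # number copies per taxon, deterministically by tree order
      copy_no <- stats::ave(seq_along(gt$tip.label), gt$tip.label,
                            FUN = seq_along)
      new_lab <- sprintf("%s@%d.%d", gt$tip.label, fam, copy_no)
      relabel <- setNames(new_lab, paste(gt$tip.label, copy_no, sep = "\r"))
      # truth-group keys are occurrence-indexed in the same in-order walk
      # that produced the newick, so they map 1:1 onto the new labels
      groups <- lapply(groups, function(grp) unname(relabel[grp]))
      gt$tip.label <- new_lab
      gt$edge.length <- gt$edge.length * species_tree$subs_scale
      contam <- character(0)
      if (cfg$contaminant_prob > 0) {
        hit <- runif(length(gt$tip.label)) < cfg$contaminant_prob
        if (any(hit)) {
          tip_edges <- match(which(hit), gt$edge[, 2L])
          gt$edge.length[tip_edges] <- cfg$contaminant_length
          contam <- gt$tip.label[hit]
        }
      }
      list(tree = gt, ortholog_groups = groups, contaminants = contam,
           degenerate = FALSE)
    })
  })
}

#' Simulate aligned sequences along a gene tree (Jukes-Cantor)
#'
#' The root sequence is uniform over A/C/G/T; along each branch of length `b`
#' subs/site every site changes to each other base with probability
#' `(1 - exp(-4b/3)) / 4`. Closed-form JC expectations make the generator
#' itself testable.
#'
#' @param gene_tree A `phylo` with branch lengths in subs/site.
#' @param seq_length Number of sites (>= 1).
#' @param seed RNG seed.
#' @return Named character vector, one aligned row per tip.
#' @export
simulate_sequences <- function(gene_tree, seq_length, seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (!is.numeric(seq_length) || seq_length < 1) abort("seq_length must be >= 1")
  assert_seed(seed)
  bases <- c("A", "C", "G", "T")
  with_seed_or_not(seed, {
    gene_tree <- stats::reorder(gene_tree)  # cladewise: parents before children
    n_tip <- length(gene_tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + gene_tree$Nnode)
    seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
    for (e in seq_len(nrow(gene_tree$edge))) {
      p <- gene_tree$edge[e, 1L]; ch <- gene_tree$edge[e, 2L]
      b <- gene_tree$edge.length[e]
      p_change <- 0.75 * (1 - exp(-4 * b / 3))
      s <- seqs[[p]]
      mut <- runif(seq_length) < p_change
      if (any(mut)) {
        # draw uniformly among the three other bases
        shift <- sample.int(3L, sum(mut), replace = TRUE)
        s[mut] <- ((s[mut] - 1L + shift) %% 4L) + 1L
      }
      seqs[[ch]] <- s
    }
    out <- vapply(seq_len(n_tip),
                  function(i) paste0(bases[seqs[[i]]], collapse = ""), "")
    setNames(out, gene_tree$tip.label)
  })
}

#' Assemble a per-taxon transcript set with redundant isoforms
#'
#' Collects this taxon's tips across simulated families (each with its
#' simulated sequences) and, with probability `isoform_rate` per record, adds
#' a near-identical duplicate (>= 99.5% identity) mimicking redundant
#' assembly isoforms — the input the 0.99-identity dedup stage is meant to
#' collapse. Record ids follow `taxon@family.copy.isoform`.
#'
#' @param taxon Taxon label.
#' @param families Output of [simulate_gene_family()] where each element
#'   additionally has a `sequences` field (named character vector, e.g. from
#'   [simulate_sequences()]).
#' @param isoform_rate Probability of emitting a duplicate isoform.
#' @param seed RNG seed.
#' @return Tibble with columns `id`, `seq`.
#' @export
make_transcript_set <- function(taxon, families, isoform_rate = 0, seed = NULL) {
  stopifnot(isoform_rate >= 0, isoform_rate <= 1)
  assert_seed(seed)
  bases <- c("A", "C", "G", "T")
  with_seed_or_not(seed, {
    rows <- list()
    for (fam in families) {
      if (isTRUE(fam$degenerate)) next
      seqs <- fam$sequences
      if (is.null(seqs)) abort("families must carry a `sequences` field")
      mine <- fam$tree$tip.label[taxon_of(fam$tree$tip.label) == taxon]
      for (tip in mine) {
        s <- seqs[[tip]]
        rows[[length(rows) + 1L]] <- tibble(id = paste0(tip, ".1"), seq = s)
        if (runif(1) < isoform_rate) {
          v <- strsplit(s, "")[[1]]
          n_max <- floor(0.004 * length(v))  # keeps identity >= 99.5%
          n_mut <- if (n_max >= 1L) sample.int(n_max, 1L) else 0L
          if (n_mut > 0L) {
            pos <- sample.int(length(v), n_mut)
            v[pos] <- vapply(v[pos], function(b)
              sample(setdiff(bases, b), 1L), "")
          }
          rows[[length(rows) + 1L]] <-
            tibble(id = paste0(tip, ".2"), seq = paste0(v, collapse = ""))
        }
      }
    }
    if (!length(rows)) abort(sprintf("taxon '%s' absent from all families", taxon))
    dplyr::bind_rows(rows)
  })
}

#' Simulate a single-locus F2 cohort
#'
#' Genotypes are drawn from the Mendelian 1:2:1 expectation of an F1 selfing;
#' the dominant model collapses AA and Aa into one phenotype class, the
#' codominant model keeps all three classes.
#'
#' @param n_individuals Cohort size (>= 1).
#' @param model `"dominant"` or `"codominant"`.
#' @param seed RNG seed.
#' @return Tibble with columns `id`, `genotype` (AA/Aa/aa), `phenotype`.
#' @export
simulate_f2 <- function(n_individuals, model = c("dominant", "codominant"),
                        seed = NULL) {
  stopifnot(n_individuals >= 1)
  model <- match.arg(model)
  assert_seed(seed)
  with_seed_or_not(seed, {
    g <- sample(c("AA", "Aa", "aa"), n_individuals, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
    ph <- switch(model,
      dominant   = ifelse(g == "aa", "recessive", "dominant"),
      codominant = c(AA = "parent_A", Aa = "intermediate",
                     aa = "parent_B")[g])
    tibble(id = sprintf("F2_%03d", seq_len(n_individuals)),
           genotype = g, phenotype = unname(ph))
  })
}

#' Simulate an efficiency-aware Cq table
#'
#' Emits one target and one reference observation per sample, constructed so
#' that at `noise_sd = 0` the efficiency-corrected (Pfaffl-type) relative
#' expression recovers `true_rel_expression` exactly:
#' `Cq_target = log_Et(Er^Cq_ref / r)`. Gaussian cycle noise is added to both
#' channels when `noise_sd > 0`.
#'
#' @param true_rel_expression Numeric vector of true target/reference ratios,
#'   one per sample (values > 0).
#' @param efficiency_target,efficiency_ref Amplification factors per cycle,
#'   in (1, 2] (2 = perfect doubling).
#' @param base_cq Reference-gene quantification cycle (default 20).
#' @param noise_sd SD of cycle noise (default 0).
#' @param seed RNG seed.
#' @return Tibble with columns `gene`, `sample`, `cq`, `efficiency`,
#'   `is_reference`.
#' @export
simulate_cq <- function(true_rel_expression, efficiency_target = 2,
                        efficiency_ref = 2, base_cq = 20, noise_sd = 0,
                        seed = NULL) {
  if (efficiency_target <= 1 || efficiency_ref <= 1)
    abort("efficiencies must be > 1 (amplification factor per cycle)")
  stopifnot(efficiency_target <= 2, efficiency_ref <= 2, noise_sd >= 0,
            all(true_rel_expression > 0), base_cq > 0)
  assert_seed(seed)
  with_seed_or_not(seed, {
    n <- length(true_rel_expression)
    cq_ref <- base_cq + rnorm(n, 0, noise_sd)
    cq_tgt <- log(efficiency_ref^cq_ref / true_rel_expression,
                  base = efficiency_target) + rnorm(n, 0, noise_sd)
    dplyr::bind_rows(
      tibble(gene = "target", sample = sprintf("S%02d", seq_len(n)),
             cq = cq_tgt, efficiency = efficiency_target,
             is_reference = FALSE),
      tibble(gene = "reference", sample = sprintf("S%02d", seq_len(n)),
             cq = cq_ref, efficiency = efficiency_ref, is_reference = TRUE)
    )
  })
}

#' Simulate first-landing choice trials
#'
#' `n` i.i.d. Bernoulli(`p`) draws; 1 codes a first landing on the focal
#' flower.
#'
#' @param n Number of trials (>= 1).
#' @param p Per-trial probability of choosing the focal flower.
#' @param seed RNG seed.
#' @return Integer vector of 0/1.
#' @export
simulate_choices <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || n < 1) abort("n must be >= 1")
  stopifnot(p >= 0, p <= 1)
  assert_seed(seed)
  with_seed_or_not(seed, rbinom(n, 1L, p))
}

#' Simulate a two-region count matrix with planted region-biased genes
#'
#' Negative-binomial counts for `n_genes` genes across `n_reps` proximal and
#' `n_reps` distal replicates; the first `n_biased` genes are planted with a
#' true log2 fold change of `+lfc` (proximal-biased) or `-lfc`
#' (distal-biased), alternating. Emulates the two-region petal RNA-seq design
#' feeding the differential-expression filter.
#'
#' @param n_genes Total genes (default 2000).
#' @param n_biased Number of planted biased genes (default 50).
#' @param n_reps Replicates per region (default 5, the study's design).
#' @param lfc Planted absolute log2 fold change (default 4: a sixteenfold
#'   change, matching the strongly region-biased regulators the two-region
#'   design is meant to flag, well past the fourfold DE cutoff).
#' @param size NB size (inverse dispersion) parameter (default 50, the low
#'   dispersion typical of well-expressed genes).
#' @param mean_range Range of baseline means, log-uniform (default 50-500).
#' @param seed RNG seed.
#' @return List with `counts` (integer matrix genes x samples), `groups`
#'   (factor proximal/distal per sample) and `truth` (tibble: `gene`,
#'   `true_lfc`).
#' @export
simulate_counts <- function(n_genes = 2000, n_biased = 50, n_reps = 5,
                            lfc = 4, size = 50, mean_range = c(50, 500),
                            seed = NULL) {
  stopifnot(n_genes >= 1, n_biased >= 0, n_biased <= n_genes, n_reps >= 2,
            lfc >= 0, size > 0)
  assert_seed(seed)
  with_seed_or_not(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    base_mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    true_lfc <- rep(0, n_genes)
    if (n_biased > 0)
      true_lfc[seq_len(n_biased)] <- rep_len(c(lfc, -lfc), n_biased)
    # biased genes sit at baseline in one region and are switched up
    # by 2^lfc in the other, like a regulator induced in a single domain
    mu_prox <- base_mu * 2^pmax(true_lfc, 0)
    mu_dist <- base_mu * 2^pmax(-true_lfc, 0)
    draw <- function(mu) matrix(
      rnbinom(n_genes * n_reps, mu = rep(mu, n_reps), size = size),
      nrow = n_genes)
    counts <- cbind(draw(mu_prox), draw(mu_dist))
    rownames(counts) <- genes
    colnames(counts) <- c(sprintf("prox_%d", seq_len(n_reps)),
                          sprintf("dist_%d", seq_len(n_reps)))
    groups <- factor(rep(c("proximal", "distal"), each = n_reps),
                     levels = c("proximal", "distal"))
    list(counts = counts, groups = groups,
         truth = tibble(gene = genes, true_lfc = true_lfc))
  })
}
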