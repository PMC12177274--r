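test_that("newick parsing round-trips and reports malformed input", {
  phy <- parse_newick("(A:0.1,B:0.2);")
  expect_equal(length(phy$tip.label), 2L)
  expect_equal(sort(phy$edge.length), c(0.1, 0.2))

  rt <- withr::with_seed(1, ape::rtree(50))
  txt <- write_newick(rt)
  back <- parse_newick(txt)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(rt))[[1]], 0)
  expect_equal(sort(back$edge.length), sort(rt$edge.length), tolerance = 1e-9)

  expect_error(parse_newick("(A:0.1,"), "offset")
  expect_error(parse_newick("(A:0.1,B:0.2))"), "offset")
})

test_that("column cleaning keeps occupancy >= threshold and is idempotent", {
  aln <- c(r1 = "A-CN", r2 = "A-C-", r3 = "A--N")
  out <- clean_columns(aln, 0.5)
  expect_equal(unname(out), c("AC", "AC", "A-"))
  # all-gap column always removed
  expect_false(grepl("-", paste(clean_columns(c(a = "-A", b = "-C"), 0.5),
                                collapse = "")))
  # boundary closed: 1 non-gap among 10 rows at threshold 0.10 is kept
  aln10 <- setNames(c("A", rep("-", 9)), paste0("r", 1:10))
  expect_equal(nchar(clean_columns(aln10, 0.1)[[1]]), 1L)
  # ungapped alignment unchanged; idempotence
  full <- c(x = "ACGT", y = "TGCA")
  expect_equal(clean_columns(full), full)
  expect_equal(clean_columns(clean_columns(aln, 0.5), 0.5),
               clean_columns(aln, 0.5))
  # everything removed -> flagged empty
  gone <- clean_columns(c(a = "--", b = "NN"), 0.5)
  expect_true(isTRUE(attr(gone, "empty")))
})

test_that("informative character counting ignores gaps and ambiguity", {
  aln <- c(a = "------", b = "ACGT--", c = "ANNN--")
  expect_equal(informative_chars(aln, "a"), 0L)
  expect_equal(informative_chars(aln, "b"), 4L)
  expect_equal(informative_chars(aln, "c"), 1L)
  expect_error(informative_chars(aln, "zz"), "unknown")
})

test_that("JC distances match the closed form and an independent routine", {
  same <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  expect_equal(jc_distance(same)[1, 2], 0)

  # p = 0.1: 10 mismatches over 100 sites
  v <- strsplit(strrep("ACGT", 25), "")[[1]]
  w <- v; w[1:10] <- ifelse(v[1:10] == "A", "C", "A")
  aln <- c(a = paste0(v, collapse = ""), b = paste0(w, collapse = ""))
  d <- jc_distance(aln)
  expect_equal(d[1, 2], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(d[1, 2], 0.10732, tolerance = 1e-4)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))

  # cross-check against the reference JC69 implementation in ape
  rt <- parse_newick("((A:0.05,B:0.08):0.02,(C:0.1,D:0.03):0.04);")
  big <- simulate_sequences(rt, 5000, seed = 3)
  bin <- ape::as.DNAbin(lapply(big, function(s) strsplit(tolower(s), "")[[1]]))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  mine <- jc_distance(big)
  expect_equal(unclass(mine)[rownames(ref), colnames(ref)], unclass(ref),
               tolerance = 1e-8, ignore_attr = TRUE)

  # saturation: p >= 0.75 capped and flagged
  sat <- c(a = strrep("A", 100), b = strrep("C", 100))
  ds <- jc_distance(sat, ceiling = 7)
  expect_equal(ds[1, 2], 7)
  expect_length(attr(ds, "capped"), 1L)
  # zero shared unambiguous sites is an error
  expect_error(jc_distance(c(a = "AC--", b = "--GT")), "shared")
})

test_that("neighbor joining recovers additive topologies deterministically", {
  # additive distances on ((A,B),(C,D)) with distinct internal branch
  tr <- parse_newick("((A:0.1,B:0.2):0.05,(C:0.15,D:0.12):0.05);")
  d <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(d)
  expect_equal(ape::dist.topo(ape::unroot(nj1), ape::unroot(tr))[[1]], 0)
  # four-point condition oracle: AB|CD pairing has the smallest sum
  s <- c(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"],
         d["A", "D"] + d["B", "C"])
  expect_equal(which.min(s), 1L)

  # 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- neighbor_joining(d3)
  pl <- setNames(nj3$edge.length[match(1:3, nj3$edge[, 2])], nj3$tip.label)
  expect_equal(pl[["A"]], 1)  # (dAB + dAC - dBC)/2
  expect_equal(pl[["B"]], 2)
  expect_equal(pl[["C"]], 3)

  # permuting the input order leaves the unrooted topology unchanged
  perm <- rev(rownames(d))
  nj2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(nj2), ape::unroot(nj1))[[1]], 0)
  dd <- d; dd[1, 2] <- NaN; dd[2, 1] <- NaN
  expect_error(neighbor_joining(dd), "NaN")
})

test_that("long-tip trimming applies absolute and relative rules", {
  t1 <- parse_newick("(A@1:0.5,(B@1:0.01,C@1:0.01):0.01);")
  r1 <- trim_long_tips(t1)
  expect_equal(attr(r1, "removed")$tip, "A@1")
  expect_equal(attr(r1, "removed")$rule, "absolute")

  # 0.35 with sister 0.30: neither rule fires
  t2 <- parse_newick("((A@1:0.35,B@1:0.30):0.1,(C@1:0.1,D@1:0.1):0.1);")
  expect_equal(nrow(attr(trim_long_tips(t2), "removed")), 0L)

  # relative rule: > 0.6 and > 10x the sister pendant (absolute cutoff
  # raised so the relative rule is the one that decides)
  loose <- cleaning_params(abs_cutoff = 2)
  t3 <- parse_newick("((A@1:0.65,B@1:0.01):0.1,(C@1:0.1,D@1:0.1):0.1);")
  r3 <- trim_long_tips(t3, loose)
  expect_equal(attr(r3, "removed")$rule, "relative")
  # same length but sister comparable: kept
  t4 <- parse_newick("((A@1:0.65,B@1:0.3):0.1,(C@1:0.1,D@1:0.1):0.1);")
  expect_equal(nrow(attr(trim_long_tips(t4, loose), "removed")), 0L)

  # unary collapse after removal sums branch lengths (path conservation)
  t5 <- parse_newick("((A@1:0.45,B@1:0.02):0.03,(C@1:0.1,D@1:0.1):0.1);")
  r5 <- trim_long_tips(t5)
  pend <- r5$edge.length[match(match("B@1", r5$tip.label), r5$edge[, 2])]
  expect_equal(pend, 0.02 + 0.03)
  # pairwise path lengths between survivors conserved
  d_before <- ape::cophenetic.phylo(t5)[c("B@1", "C@1", "D@1"),
                                        c("B@1", "C@1", "D@1")]
  d_after <- ape::cophenetic.phylo(r5)[c("B@1", "C@1", "D@1"),
                                       c("B@1", "C@1", "D@1")]
  expect_equal(d_after, d_before)
})

test_that("monophyly masking keeps the most informative transcript", {
  aln <- setNames(c("ACGTA", "ACG--", "AC---", "ACGTT", "ACGTA"),
                  c("A@1", "A@2", "A@3", "B@1", "C@1"))
  # sisters A@1 (5 informative) and A@2 (3): A@1 survives
  t1 <- parse_newick("((A@1:.1,A@2:.1):.1,(B@1:.1,C@1:.1):.1);")
  m1 <- mask_monophyletic_duplicates(t1, aln)
  expect_setequal(m1$tip.label, c("A@1", "B@1", "C@1"))

  # same-taxon tips separated by another taxon: both kept
  t2 <- parse_newick("((A@1:.1,B@1:.1):.1,(A@2:.1,C@1:.1):.1);")
  m2 <- mask_monophyletic_duplicates(t2, aln)
  expect_setequal(m2$tip.label, c("A@1", "A@2", "B@1", "C@1"))

  # nested clade (A@1,(A@2,A@3)) reduces to the single best tip
  aln3 <- setNames(c(paste0(strrep("A", 50), strrep("-", 50)),
                     paste0(strrep("A", 90), strrep("-", 10)),
                     paste0(strrep("A", 70), strrep("-", 30)),
                     strrep("C", 100), strrep("G", 100)),
                   c("A@1", "A@2", "A@3", "B@1", "C@1"))
  t3 <- parse_newick(
    "((A@1:.1,(A@2:.1,A@3:.1):.1):.1,(B@1:.1,C@1:.1):.1);")
  m3 <- mask_monophyletic_duplicates(t3, aln3)
  expect_setequal(m3$tip.label, c("A@2", "B@1", "C@1"))

  expect_error(mask_monophyletic_duplicates(t1, aln[-1]), "missing")
})

test_that("deep-paralog cutting splits on long internal branches", {
  big <- parse_newick(paste0(
    "(((A@1:.1,B@1:.1):.1,(C@1:.1,D@1:.1):.1):1.2,",
    "((E@1:.1,F@1:.1):.1,(G@1:.1,H@1:.1):.1):.1);"))
  cc <- cut_deep_paralogs(big)
  expect_length(cc, 2L)
  sizes <- sort(vapply(cc, function(x) length(x$tip.label), 0L))
  expect_equal(sizes, c(4L, 4L))

  # one side with only 3 distinct taxa: emitted alone, small side reported
  small <- parse_newick(paste0(
    "(((A@1:.1,B@1:.1):.1,C@1:.1):1.2,",
    "((E@1:.1,F@1:.1):.1,(G@1:.1,H@1:.1):.1):.1);"))
  cs <- cut_deep_paralogs(small)
  expect_length(cs, 1L)
  expect_equal(attr(cs, "discarded")$n_taxa, 3L)

  # no deep branch: singleton list with the input untouched
  none <- parse_newick("((A@1:.1,B@1:.1):.2,(C@1:.1,D@1:.1):.1);")
  cn <- cut_deep_paralogs(none)
  expect_length(cn, 1L)
  expect_equal(write_newick(cn[[1]]), write_newick(none))
})

test_that("trimming removes injected long-branch contaminants", {
  st <- sim_species_tree(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);",
    subs_scale = 0.02)
  fams <- simulate_gene_family(st, gene_family_config(
    n_families = 60, contaminant_prob = 0.1, seed = 61))
  injected <- 0L; removed <- 0L
  for (f in fams) {
    if (f$degenerate || !length(f$contaminants)) next
    tr <- trim_long_tips(f$tree)
    injected <- injected + length(f$contaminants)
    removed <- removed + sum(f$contaminants %in% attr(tr, "removed")$tip)
    # cleaning never adds tips
    kept <- if (inherits(tr, "phylo")) tr$tip.label else tr$tip.label
    expect_true(all(kept %in% f$tree$tip.label))
  }
  expect_gt(injected, 20L)
  expect_gte(removed / injected, 0.95)
})
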