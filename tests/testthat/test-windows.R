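test_that("p-distance uses the pairwise-complete convention", {
  expect_equal(as.numeric(p_distance("ACGT", "ACGT")), 0)
  expect_equal(as.numeric(p_distance("ACGT", "ACGA")), 0.25)
  expect_equal(as.numeric(p_distance("ACGN", "ACGA")), 0)
  expect_equal(attr(p_distance("ACGN", "ACGA"), "n_compared"), 3L)
  expect_true(is.na(p_distance("NNN", "ACG")))
  expect_error(p_distance("ACGT", "ACG"), "lengths differ")
  # heterozygous codes differ only when allele sets are disjoint
  expect_equal(as.numeric(p_distance("R", "A")), 0)
  expect_equal(as.numeric(p_distance("R", "C")), 1)
  # symmetry and range over random sequences
  set.seed(3)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = "")
    d1 <- as.numeric(p_distance(a, b)); d2 <- as.numeric(p_distance(b, a))
    expect_identical(d1, d2)
    if (!is.na(d1)) expect_true(d1 >= 0 && d1 <= 1)
    expect_equal(as.numeric(p_distance(a, a)), 0)
  }
})

test_that("window construction follows the size/step arithmetic", {
  aln <- alignment_set(list(s = sapply(c("a", "b"), function(x)
    strrep("ACGT", 15000), USE.NAMES = TRUE)))
  w <- make_windows(aln, size = 25000, step = 5000)
  expect_equal(nrow(w), 8)
  expect_equal(w$start, seq(0, 35000, by = 5000))
  expect_true(all(w$end - w$start == 25000))
  short <- alignment_set(list(s = c(a = strrep("A", 20000),
                                    b = strrep("A", 20000))))
  expect_equal(nrow(make_windows(short)), 0)
  expect_error(make_windows(aln, size = 0), "positive")
  # formula property on random sizes
  set.seed(8)
  for (i in 1:5) {
    L <- sample(30000:80000, 1); step <- sample(c(2000, 5000, 30000), 1)
    a2 <- alignment_set(list(s = c(a = strrep("A", L))))
    w2 <- make_windows(a2, size = 25000, step = step)
    expect_equal(nrow(w2), floor((L - 25000) / step) + 1)
  }
})

test_that("windows with too little known sequence are invalidated", {
  known <- strrep("A", 1000)
  partial <- paste0(strrep("N", 600), strrep("A", 400))  # 40% known
  aln <- alignment_set(list(s = c(a = known, b = partial)))
  w <- make_windows(aln, size = 1000, step = 1000, min_known = 0.5)
  expect_false(w$valid[1])
  expect_equal(w$min_known_fraction[1], 0.4)
  wd <- window_distances(aln, w, "a")
  expect_false(wd$valid[1])
})

test_that("neighbor joining recovers additive metrics exactly", {
  # 4-taxon additive tree: ((a:2,b:3):1,(c:4,d:5));
  lab <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 9
  d["c", "d"] <- d["d", "c"] <- 9
  tr <- nj_tree(d)
  expect_true(has_clade(tr, c("a", "b")))
  expect_true(has_clade(tr, c("c", "d")))
  expect_false(has_clade(tr, c("a", "c")))
  # exact branch lengths on additive input: tip edges 2,3,4,5; internal 1
  tip_edges <- tr$edge[, 2] <= 4
  lens <- setNames(tr$edge.length[tip_edges],
                   tr$tip.label[tr$edge[tip_edges, 2]])
  expect_equal(lens[lab], c(a = 2, b = 3, c = 4, d = 5))
  expect_equal(tr$edge.length[!tip_edges], 1)
  # 3 taxa: three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  l3 <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(l3, c(x = 1, y = 2, z = 3))
  dn <- d; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(nj_tree(dn), "NA/NaN")
})

test_that("topology census canonicalizes rotations and counts clades", {
  t1 <- "((a:1,b:1):1,(c:1,d:1):1);"
  t2 <- "((d:9,c:2):1,(b:5,a:1):3);"   # same unrooted topology
  t3 <- "((a:1,c:1):1,(b:1,d:1):1);"
  expect_identical(canonical_topology(t1), canonical_topology(t2))
  expect_false(identical(canonical_topology(t1), canonical_topology(t3)))
  cen <- topology_census(c(rep(t1, 6), rep(t2, 4), rep(t3, 2)),
                         reference = t1, focal_clade = c("a", "b"))
  expect_equal(cen$total, 12)
  expect_equal(cen$n_distinct, 2)
  expect_equal(sum(cen$counts), cen$total)
  expect_equal(cen$reference_count, 10)
  expect_equal(cen$reference_frequency, 10 / 12)
  expect_equal(cen$clade_present, 10)
  expect_error(topology_census(c(t1, "((a:1,b:1):1,(c:1,e:1):1);")),
               "leaf sets")
})

test_that("canonical topology agrees with an independent tree comparator", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (i in 1:8) {
    t1 <- ape::rtree(6)
    t2 <- ape::rtree(6)
    same <- identical(canonical_topology(t1), canonical_topology(t2))
    rf0 <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
    expect_identical(same, rf0)
    # a reshuffled copy of t1 is always identical
    t1b <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
      t1, sample(t1$tip.label))))
    expect_identical(canonical_topology(t1), canonical_topology(t1b))
  }
})

test_that("window trees recover the generating topology on long windows", {
  tr <- sim_tree()
  nc <- simulate_noncoding_alignment(tr, 50000, seed = 23)
  d <- window_distance_matrix(nc$alignment, names(nc$alignment$seqs)[1],
                              0, 50000)
  wt <- nj_tree(d)
  expect_identical(canonical_topology(wt), canonical_topology(tr$phy))
})

test_that("neutral-locus sampling enforces spacing, flanks and presence", {
  L <- 60000
  base <- strrep("A", L)
  species <- c("gracilis", "concolor", "pallidus", "flavicornis",
               "PSW54", "dendroicus", "elongatus")
  seqs <- setNames(rep(base, 7), species)
  # dendroicus unknown over the first half: loci there have 5 present
  seqs[["dendroicus"]] <- paste0(strrep("N", 30000), strrep("A", 30000))
  # elongatus unknown everywhere: 5 of 6 ingroup present at best
  seqs[["elongatus"]] <- strrep("N", L)
  aln <- alignment_set(list(s = seqs))
  loci <- sample_neutral_loci(aln)
  expect_true(all(loci$end - loci$start == 500))
  gaps <- loci$start[-1] - loci$end[-nrow(loci)]
  expect_true(all(gaps >= 15000))
  expect_true(all(loci$n_present >= 4))
  # CDS plus 5 kb flank is avoided entirely
  cds <- data.frame(scaffold = "s", start = 20000, end = 21000)
  loci2 <- sample_neutral_loci(aln, cds = cds)
  expect_true(all(loci2$end <= 15000 | loci2$start >= 26000))
  # a species must have <= 20% missing to count as present
  seqs3 <- setNames(rep(base, 7), species)
  for (sp in c("concolor", "pallidus", "flavicornis")) seqs3[[sp]] <- strrep("N", L)
  aln3 <- alignment_set(list(s = seqs3))
  expect_equal(nrow(sample_neutral_loci(aln3)), 0)
})
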