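test_that("fractional site counts match direct enumeration", {
  expect_equal(ng86_site_counts("TTT")$S, 1 / 3)
  expect_equal(ng86_site_counts("TTT")$N, 8 / 3)
  expect_equal(ng86_site_counts("ATG")$S, 0)
  expect_equal(ng86_site_counts("ATG")$N, 3)
  # conservation S + N = 3 for every sense codon, and agreement with the
  # independent enumerator
  for (cd in sample(sense_codons(), 12)) {
    sc <- ng86_site_counts(cd)
    expect_equal(sc$S + sc$N, 3)
    expect_equal(sc$S, oracle_site_count(cd))
  }
})

test_that("pathway averaging matches exhaustive enumeration", {
  pw <- ng86_pathways("CCT", "CAG")
  expect_equal(pw$sd, 0.5)
  expect_equal(pw$nd, 1.5)
  expect_equal(pw$n_paths, 2L)
  set.seed(11)
  sense <- sense_codons()
  for (i in 1:60) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    pw <- ng86_pathways(c1, c2)
    orc <- oracle_pathways(c1, c2)
    if (is.null(orc)) {
      expect_identical(pw$n_paths, 0L)
    } else {
      expect_equal(pw$sd, unname(orc["sd"]), info = paste(c1, c2))
      expect_equal(pw$nd, unname(orc["nd"]), info = paste(c1, c2))
    }
  }
})

test_that("pairwise dN/dS is symmetric, zero on identity, and flags edge cases", {
  s1 <- "ATGGCTCCTAAAGGG"
  s2 <- "ATGGCACAGAAAGGG"
  a <- ng86_pair(s1, s2); b <- ng86_pair(s2, s1)
  expect_equal(a$dn, b$dn)
  expect_equal(a$ds, b$ds)
  ident <- ng86_pair(s1, s1)
  expect_equal(ident$dn, 0)
  expect_equal(ident$ds, 0)
  # codons with N in either sequence are skipped
  skipped <- ng86_pair("ATGNNN", "ATGGCT")
  expect_equal(skipped$n_codons, 1L)
  expect_equal(skipped$n_skipped, 1L)
  expect_error(ng86_pair("NNN", "NNN"), "comparable")
  # saturated synonymous divergence -> undefined under the log correction
  sat <- ng86_pair(strrep("TTT", 20), strrep("TTC", 20))
  expect_true(is.na(sat$ds))
  expect_true("jc_undefined" %in% sat$flags)
})

test_that("species aggregation follows the sum and mean conventions", {
  rates <- data.frame(
    gene = c("g1", "g2"), species = "sp1",
    dn = c(1, 3), ds = c(4, 2), ratio = c(0.25, 1.5))
  agg <- rate_aggregates(rates)
  expect_equal(agg$sum_ratio, 4 / 6)
  expect_equal(agg$mean_ratio, (0.25 + 1.5) / 2)
  # ratio >= 10 excluded from the mean, kept in the sums
  rates2 <- rbind(rates, data.frame(gene = "g3", species = "sp1",
                                    dn = 12, ds = 1, ratio = 12))
  agg2 <- rate_aggregates(rates2)
  expect_equal(agg2$n_ratio_genes, 2L)
  expect_equal(agg2$mean_ratio, (0.25 + 1.5) / 2)
  expect_equal(agg2$sum_ratio, 16 / 7)
  # dS = 0: no per-gene ratio, dN still contributes to the sums
  rates3 <- rbind(rates, data.frame(gene = "g3", species = "sp1",
                                    dn = 0.5, ds = 0, ratio = NA))
  agg3 <- rate_aggregates(rates3)
  expect_equal(agg3$n_ratio_genes, 2L)
  expect_equal(agg3$sum_ratio, 4.5 / 6)
  # single gene: sum-based and mean-based ratios coincide
  one <- rate_aggregates(rates[1, ])
  expect_equal(one$sum_ratio, one$mean_ratio)
})

test_that("rate table on simulated genes recovers omega ordering", {
  design <- pair_design()
  sim_lo <- simulate_codon_alignment(sim_tree(omega = 0.2), n_genes = 2,
                                     gene_length = 2000, seed = 5)
  sim_hi <- simulate_codon_alignment(sim_tree(omega = 1), n_genes = 2,
                                     gene_length = 2000, seed = 5)
  rt_lo <- species_rate_table(sim_gene_alignments(sim_lo), design)
  rt_hi <- species_rate_table(sim_gene_alignments(sim_hi), design)
  expect_true(all(rt_lo$aggregates$sum_ratio < rt_hi$aggregates$sum_ratio))
  expect_true(all(rt_lo$aggregates$sum_ratio < 0.4))
  expect_true(all(rt_hi$aggregates$sum_ratio > 0.7))
})

test_that("effective codon number hits the closed-form extremes", {
  uniform <- setNames(rep(1000, 61), sense_codons())
  expect_equal(enc(uniform), 61)
  code <- genetic_code()[sense_codons()]
  one_per_aa <- setNames(rep(0, 61), sense_codons())
  for (aa in unique(code)) one_per_aa[names(code)[code == aa][1]] <- 1000
  expect_equal(enc(one_per_aa), 20)
  # range property on random usage
  set.seed(4)
  for (i in 1:20) {
    counts <- setNames(rpois(61, lambda = sample(c(2, 10, 40), 1)),
                       sense_codons())
    if (sum(counts) == 0) next
    nc <- enc(counts)
    expect_true(is.na(nc) || (nc >= 20 && nc <= 61))
  }
  expect_error(enc(setNames(numeric(0), character(0))), "named")
})

test_that("codon composition reports GC3 and normalized usage", {
  g <- gene_alignment("g", c(a = "GGGGGCGGA", b = "GGGGGGGGG"))
  comp <- codon_composition(list(g))
  expect_equal(comp$gc3[comp$species == "b"], 1.0)
  expect_equal(comp$gc3[comp$species == "a"], 2 / 3)
  props <- attr(comp, "proportions")
  expect_equal(unname(rowSums(props)), c(1, 1))
  # GC-biased stationary frequencies shift GC3 accordingly
  pi_gc <- setNames(rep(0, 61), sense_codons())
  third <- substring(sense_codons(), 3, 3)
  pi_gc[third %in% c("G", "C")] <- 1
  pi_gc <- pi_gc / sum(pi_gc)
  sim <- simulate_codon_alignment(sim_tree(), n_genes = 1, gene_length = 400,
                                  pi = unname(pi_gc), seed = 8)
  compsim <- codon_composition(sim_gene_alignments(sim))
  expect_true(all(compsim$gc3 > 0.9))
})

test_that("codon-bias/rate correlations run on simulated genes", {
  sim <- simulate_codon_alignment(sim_tree(), n_genes = 15,
                                  gene_length = 200, seed = 13)
  ga <- sim_gene_alignments(sim)
  rt <- species_rate_table(ga, pair_design())
  corr <- enc_rate_correlation(ga, rt$rates)
  expect_equal(nrow(corr), 6)
  expect_true(all(abs(corr$rho_dn) <= 1, na.rm = TRUE))
  expect_true(all(corr$p_ds >= 0 & corr$p_ds <= 1, na.rm = TRUE))
})
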