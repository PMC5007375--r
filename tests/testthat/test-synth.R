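test_that("identical seeds give byte-identical simulations", {
  tr <- sim_tree()
  a <- simulate_codon_alignment(tr, n_genes = 3, gene_length = 50, seed = 2)
  b <- simulate_codon_alignment(tr, n_genes = 3, gene_length = 50, seed = 2)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  c <- simulate_codon_alignment(tr, n_genes = 3, gene_length = 50, seed = 3)
  expect_false(identical(a$genes, c$genes))
  n1 <- simulate_noncoding_alignment(tr, 5000, seed = 4)
  n2 <- simulate_noncoding_alignment(tr, 5000, seed = 4)
  expect_identical(n1$alignment$seqs, n2$alignment$seqs)
})

test_that("zero branch lengths copy the root everywhere", {
  flat <- ape::read.tree(text = "(a:0,(b:0,(c:0,d:0):0):0);")
  sim <- simulate_codon_alignment(sim_tree(flat, omega = 1), n_genes = 1,
                                  gene_length = 40, seed = 6)
  expect_equal(length(unique(unlist(sim$genes[[1]]))), 1L)
  expect_true(all(sim$truth$edge_changes$changes == 0))
})

test_that("simulated coding sequences contain no internal stops and equal lengths", {
  sim <- simulate_codon_alignment(sim_tree(omega = 1), n_genes = 4,
                                  gene_length = 150, seed = 9)
  for (g in sim$genes) {
    expect_equal(length(unique(nchar(g))), 1L)
    for (s in g) expect_false(any(split_codons(s) %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("tree validation rejects invalid parameters", {
  expect_error(sim_tree(rho = c(nosuch = 2)), "unknown tip")
  expect_error(sim_tree(rho = 0), "rho")
  expect_error(sim_tree(omega = -1), "omega")
  expect_error(simulate_codon_alignment(sim_tree(), n_genes = 0, seed = 1),
               "at least one gene")
  expect_error(simulate_codon_alignment(sim_tree(), n_genes = 1,
                                        gene_length = 10),
               "seed")
})

test_that("nucleotide divergence follows the Jukes-Cantor closed form", {
  t <- 0.3
  two <- ape::read.tree(text = sprintf("(a:%f,b:0,c:0);", t))
  sim <- simulate_noncoding_alignment(sim_tree(two), 200000, seed = 10)
  p <- as.numeric(p_distance(sim$alignment$seqs[[1]][["a"]],
                             sim$alignment$seqs[[1]][["b"]]))
  expect_equal(p, 0.75 * (1 - exp(-4 * t / 3)), tolerance = 0.02)
})

test_that("terminal rate multipliers scale realized divergence", {
  tr <- sim_tree(rho = c(concolor = 2))
  sim <- simulate_noncoding_alignment(tr, 300000, seed = 12)
  aln <- sim$alignment
  d_con <- as.numeric(p_distance(aln$seqs[[1]][["concolor"]],
                                 aln$seqs[[1]][["gracilis"]]))
  d_pal <- as.numeric(p_distance(aln$seqs[[1]][["pallidus"]],
                                 aln$seqs[[1]][["gracilis"]]))
  # concolor gains an extra 0.020 substitutions/site on its terminal
  expect_gt(d_con, d_pal + 0.01)
  # default depth: every ingroup species within ~5% of the outgroup
  base <- simulate_noncoding_alignment(sim_tree(), 300000, seed = 12)
  for (sp in setdiff(base$alignment$species, "gracilis")) {
    d <- as.numeric(p_distance(base$alignment$seqs[[1]][[sp]],
                               base$alignment$seqs[[1]][["gracilis"]]))
    expect_lt(d, 0.06)
  }
})

test_that("injected unknown-base runs are recorded and placed", {
  sim <- simulate_noncoding_alignment(sim_tree(), 20000, n_mask_runs = 3,
                                      mask_run_length = 500, seed = 14)
  expect_equal(nrow(sim$mask_runs), 3)
  for (i in 1:3) {
    r <- sim$mask_runs[i, ]
    piece <- substring(sim$alignment$seqs[[r$scaffold]][[r$species]],
                       r$start + 1, r$end)
    expect_equal(piece, strrep("N", 500))
  }
})

test_that("read-depth tracks honour the Poisson copy-number model", {
  regions <- data.frame(scaffold = "s1", start = 40000, end = 50000, cn = 4)
  tk <- simulate_read_depth(c(s1 = 200000), regions, mean_depth = 30,
                            seed = 15)
  expect_equal(median(tk$depth$s1), 30, tolerance = 0.04)
  expect_equal(mean(tk$depth$s1[40001:50000]), 60, tolerance = 0.02)
  expect_error(simulate_read_depth(c(s1 = 1000),
                                   data.frame(scaffold = "s1", start = 10,
                                              end = 10, cn = 3),
                                   seed = 1),
               "zero-length")
  # bedGraph round trip
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tk, path)
  back <- read_bedgraph(path)
  expect_identical(back$depth$s1, tk$depth$s1)
})

test_that("mapping population obeys Haldane recombination and design", {
  mm <- simulate_mapping_population(2000, list(c(0, 10), c(0)), seed = 16)
  expect_true(all(mm$queen == "A/B"))
  x <- phase_double(mm)$coding
  # adjacent markers 10 cM apart
  rf_adj <- recombination_fraction(x["chr1_m01|0", ], x["chr1_m02|0", ])
  expect_equal(rf_adj, haldane_rf(10), tolerance = 0.15)
  expect_equal(haldane_rf(10), (1 - exp(-0.2)) / 2)
  # markers on different chromosomes assort independently
  rf_cross <- recombination_fraction(x["chr1_m01|0", ], x["chr2_m01|0", ])
  expect_equal(rf_cross, 0.5, tolerance = 0.06)
  expect_error(simulate_mapping_population(1, list(c(0, 10)), seed = 1),
               "two offspring")
  expect_error(simulate_mapping_population(10, list(numeric(0)), seed = 1),
               "at least one marker")
})

test_that("expression matrix defaults, null and planted shift behave", {
  em <- simulate_expression_matrix(seed = 17)
  expect_equal(ncol(em), 29)
  expect_true(all(em >= 0))
  expect_equal(colnames(em)[1], "head")
  expect_error(simulate_expression_matrix(10, fast_gene_ids = 11, seed = 1),
               "outside")
  expect_error(simulate_expression_matrix(10, head_shift = -1, seed = 1),
               ">= 0")
  # null: no tissue significant after FDR in >= 90% of replicates
  hits <- 0L
  for (s in 1:10) {
    m <- simulate_expression_matrix(400, 29, fast_gene_ids = 1:40,
                                    head_shift = 0, seed = 100 + s)
    ec <- expression_contrast(m, 1:40)
    if (any(ec$tests$significant)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
  # strong shift: the head contrast is significant and positive
  m <- simulate_expression_matrix(400, 29, fast_gene_ids = 1:40,
                                  head_shift = 5, seed = 18)
  ec <- expression_contrast(m, 1:40)
  head_row <- ec$tests[ec$tests$tissue == "head", ]
  expect_true(head_row$significant)
  expect_gt(head_row$mean_diff, 0)
})
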