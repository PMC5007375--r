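toy_aln <- function() {
  alignment_set(list(
    s1 = c(spA = "ATGGCCTTTACGATGA", spB = "ATGGCATTTACGATGA"),
    s2 = c(spA = "GGCCAT", spB = "GGCCAT")))
}

test_that("alignment I/O round-trips and validates", {
  aln <- toy_aln()
  dir <- tempfile()
  write_alignment(aln, dir)
  back <- load_alignment(setNames(file.path(dir, c("s1.fasta", "s2.fasta")),
                                  c("s1", "s2")))
  expect_equal(back$seqs, aln$seqs)
  expect_equal(back$species, aln$species)
  expect_error(alignment_set(list(s1 = c(a = "ACGT", b = "ACG"))), "unequal")
  expect_error(alignment_set(list(s1 = c(a = "ACGT"), s2 = c(b = "ACGT"))),
               "species set differs")
  # lowercase input uppercased; unsupported symbols become N with warning
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">spA", "acgj", ">spB", "ACGT"), f)
  expect_warning(got <- load_alignment(c(sx = f)), "replaced by N")
  expect_equal(got$seqs$sx[["spA"]], "ACGN")
})

test_that("gene extraction handles strand, frame and bounds", {
  aln <- toy_aln()
  plus <- extract_gene(aln, gene_model("gp", "s1",
                                       data.frame(start = 0, end = 6)))
  expect_equal(split_codons(plus$seqs[["spA"]]), c("ATG", "GCC"))
  minus <- extract_gene(aln, gene_model("gm", "s2",
                                        data.frame(start = 0, end = 6),
                                        strand = "-"))
  expect_equal(split_codons(minus$seqs[["spA"]]), c("ATG", "GCC"))
  # minus-strand extraction equals the reverse complement of the plus read
  expect_equal(minus$seqs[["spA"]], plus$seqs[["spA"]])
  expect_error(extract_gene(aln, gene_model("gx", "s2",
                                            data.frame(start = 0, end = 9))),
               "outside scaffold")
  expect_error(extract_gene(aln, gene_model("gf", "s1",
                                            data.frame(start = 0, end = 4))),
               "multiple of 3")
  # N survives complementing
  aln2 <- alignment_set(list(s = c(a = "NNGCAT", b = "GGGCAT")))
  mg <- extract_gene(aln2, gene_model("g", "s", data.frame(start = 0, end = 6),
                                      strand = "-"))
  expect_equal(mg$seqs[["a"]], "ATGCNN")
})

test_that("gene models parse from GFF3 and BED with coordinate conversion", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tsrc\tCDS\t1\t6\t.\t+\t0\tID=cds1;Parent=geneA"), gff)
  gm <- read_gene_models(gff)[["geneA"]]
  expect_equal(gm$intervals$start, 0)
  expect_equal(gm$intervals$end, 6)
  bed <- tempfile(fileext = ".bed")
  writeLines("s1\t0\t6\tgeneB\t0\t+", bed)
  gb <- read_gene_models(bed)[["geneB"]]
  expect_equal(gb$intervals$start, 0)
})

test_that("consensus calling follows the coverage and allele rules", {
  # no call at >= 5x emits the reference; below 5x emits N
  expect_equal(consensus_call(NA, 1, 6, "A"), "A")
  expect_equal(consensus_call(NA, 1, 5, "A"), "A")
  expect_equal(consensus_call(NA, 1, 4, "A"), "N")
  # more than 3 alleles masked regardless of call
  expect_equal(consensus_call("C", 4, 50, "A"), "N")
  # explicit calls win; heterozygous calls become IUPAC (or N when masked)
  expect_equal(consensus_call("G", 1, 2, "A"), "G")
  expect_equal(consensus_call("A/G", 2, 10, "A"), "R")
  expect_equal(consensus_call("A/G", 2, 10, "A", het = "mask"), "N")
  expect_error(consensus_call("A", 1, -1, "A"), "negative depth")
})

test_that("gene QC applies length, missingness and stop-mask rules", {
  tr <- sim_tree()
  sim <- simulate_codon_alignment(tr, n_genes = 1, gene_length = 299,
                                  seed = 20)
  short <- gene_qc(sim_gene_alignments(sim)[[1]])
  expect_false(short$pass)
  expect_true("length" %in% short$reasons)
  sim2 <- simulate_codon_alignment(tr, n_genes = 1, gene_length = 300,
                                   seed = 20)
  ok <- gene_qc(sim_gene_alignments(sim2)[[1]])
  expect_true(ok$pass)
  # one species 25% unknown fails the missing-data rule
  g <- sim_gene_alignments(sim2)[[1]]
  n <- nchar(g$seqs[[1]])
  bad <- g$seqs
  substr(bad[["concolor"]], 1, ceiling(0.25 * n)) <-
    strrep("N", ceiling(0.25 * n))
  miss <- gene_qc(gene_alignment("g", bad))
  expect_false(miss$pass)
  expect_true("missing" %in% miss$reasons)
  # an internal stop masks that codon column in every species
  stopped <- g$seqs
  substr(stopped[["pallidus"]], 13, 15) <- "TAA"
  sq <- gene_qc(gene_alignment("g", stopped))
  expect_true(sq$pass)
  expect_equal(sq$n_masked_codons, 1L)
  for (sp in names(sq$gene$seqs))
    expect_equal(substr(sq$gene$seqs[[sp]], 13, 15), "NNN")
  # idempotence
  again <- gene_qc(sq$gene)
  expect_equal(again$gene$seqs, sq$gene$seqs)
  expect_equal(again$pass, sq$pass)
})

test_that("column masking drops gapped codon columns codon-wise", {
  g <- gene_alignment("g", c(a = "ATGGCC", b = "AT-GCC"))
  dropped <- mask_columns(g)
  expect_equal(dropped$gene$seqs[["a"]], "GCC")
  expect_equal(dropped$masked_fraction, 0.5)
  clean <- gene_alignment("g", c(a = "ATGGCC", b = "ATGGCC"))
  expect_equal(mask_columns(clean)$gene$seqs, clean$seqs)
  expect_identical(mask_columns(g, "none")$gene$seqs, g$seqs)
  expect_error(mask_columns(g, "bogus"))
})
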