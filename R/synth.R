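# Synthetic-data generators. Each simulator takes an explicit seed, emits
# the statistical structure the downstream analysis assumes, and returns a
# truth table so parameter recovery can be tested rather than assumed.

#' Simulate codon-aligned genes along a species tree
#'
#' Site-independent codon evolution under a Goldman-Yang-style model:
#' off-diagonal rates proportional to the target codon frequency, times
#' `kappa` for transitions and the branch's omega for nonsynonymous
#' changes; multi-nucleotide codon changes are disallowed and stop codons
#' are outside the state space, so simulated sequences never contain
#' internal stops. The generator is scaled to one expected substitution
#' per site so branch lengths (times the branch rate multiplier rho) are
#' in expected substitutions/site.
#'
#' Convergent amino-acid sites can be planted after simulation: at each
#' chosen column every foreground leaf is overwritten with a codon for a
#' residue that no other species carries there, and the site is recorded
#' in the truth table.
#'
#' @param tree A [sim_tree()].
#' @param n_genes Number of genes.
#' @param gene_length Gene length in codons (single value or per gene).
#' @param kappa Transition/transversion rate ratio.
#' @param pi Codon frequencies (61-vector summing to 1); uniform default.
#' @param n_convergent Number of convergent sites to plant.
#' @param foreground Species receiving planted sites (default: the
#'   mutualists of the default design).
#' @param seed Integer seed (required).
#' @return Object of class `codon_sim`: `genes` (list gene id -> named
#'   character vector of coding sequences), `tree`, and `truth` with
#'   `edge_changes` (per-branch realized changed-site counts, before
#'   planting) and `convergent_sites` (gene, codon column, residue,
#'   foreground).
#' @export
simulate_codon_alignment <- function(tree, n_genes = 20, gene_length = 300,
                                     kappa = 2, pi = NULL, n_convergent = 0,
                                     foreground = DEFAULT_PAIRS$mutualist,
                                     seed) {
  validate_sim_tree(tree)
  if (n_genes < 1) stop2("need at least one gene")
  set_seed_strict(seed)
  lens <- rep_len(gene_length, n_genes)
  if (any(lens <= 0)) stop2("gene lengths must be positive")
  total <- sum(lens)
  P_list <- codon_P_list(tree, kappa, pi)
  root_probs <- if (is.null(pi)) rep(1 / 61, 61) else pi
  sim <- simulate_along_tree(tree$phy, total, root_probs, P_list)
  codons <- sense_codons()
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  bounds <- c(0L, cumsum(lens))
  species <- tree$phy$tip.label
  gene_states <- lapply(seq_len(n_genes), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    lapply(sim$tip_states, function(st) st[idx])
  })
  names(gene_states) <- gene_ids

  truth_sites <- data.frame(gene = character(0), codon = integer(0),
                            residue = character(0), foreground = character(0))
  if (n_convergent > 0) {
    if (!all(foreground %in% species))
      stop2("foreground species absent from tree")
    aa_of <- translate_codons(codons)
    slots <- data.frame(gene = rep(gene_ids, lens),
                        codon = unlist(lapply(lens, seq_len)))
    pick <- slots[sample.int(nrow(slots), n_convergent), , drop = FALSE]
    for (r in seq_len(n_convergent)) {
      gid <- pick$gene[r]; col <- pick$codon[r]
      present <- translate_codons(codons[vapply(
        gene_states[[gid]][setdiff(species, foreground)],
        function(st) st[col], integer(1))])
      residue <- sample(setdiff(setdiff(unique(aa_of), "*"), present), 1)
      target_codon <- which(aa_of == residue)[1]
      for (sp in foreground) gene_states[[gid]][[sp]][col] <- target_codon
      truth_sites <- rbind(truth_sites, data.frame(
        gene = gid, codon = col, residue = residue,
        foreground = paste(sort(foreground), collapse = ",")))
    }
  }

  genes <- lapply(gene_states, function(gs)
    vapply(gs, function(st) paste(codons[st], collapse = ""), character(1)))
  structure(list(
    genes = genes, tree = tree,
    params = list(n_genes = n_genes, gene_length = lens, kappa = kappa,
                  seed = seed),
    truth = list(edge_changes = data.frame(tree$phy$edge,
                                           changes = sim$edge_changes),
                 convergent_sites = truth_sites)),
    class = "codon_sim")
}

#' Gene alignments from a codon simulation
#' @param sim A `codon_sim`.
#' @return List of `gene_alignment` objects.
#' @export
sim_gene_alignments <- function(sim) {
  lapply(names(sim$genes), function(g) gene_alignment(g, sim$genes[[g]]))
}

#' Simulate noncoding scaffold alignments along a species tree
#'
#' Nucleotide evolution under Jukes-Cantor (default) or HKY when `kappa`
#' or non-uniform `pi` is given; the generator is scaled to one expected
#' substitution/site as for the codon process. Runs of unknown bases can
#' be injected to exercise window validity rules; they are recorded in the
#' returned `mask_runs` table.
#'
#' @param tree A [sim_tree()].
#' @param scaffold_lengths Integer vector (optionally named) of scaffold
#'   lengths in bases.
#' @param kappa Transition/transversion ratio (1 = Jukes-Cantor).
#' @param pi Base frequencies.
#' @param n_mask_runs Number of N runs to inject.
#' @param mask_run_length Length of each N run.
#' @param seed Integer seed (required).
#' @return List: `alignment` (an [alignment_set()]), `truth` with per-edge
#'   changed-site counts per scaffold, `mask_runs`.
#' @export
simulate_noncoding_alignment <- function(tree, scaffold_lengths = 100000,
                                         kappa = 1, pi = rep(0.25, 4),
                                         n_mask_runs = 0, mask_run_length = 0,
                                         seed) {
  validate_sim_tree(tree)
  if (any(scaffold_lengths <= 0)) stop2("scaffold lengths must be positive")
  set_seed_strict(seed)
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scaf%02d", seq_along(scaffold_lengths))
  P_list <- nucleotide_P_list(tree, kappa, pi)
  changes <- list()
  seqs <- lapply(names(scaffold_lengths), function(sc) {
    sim <- simulate_along_tree(tree$phy, scaffold_lengths[[sc]], pi, P_list)
    changes[[sc]] <<- sim$edge_changes
    vapply(sim$tip_states, function(st)
      rawToChar(as.raw(c(65L, 67L, 71L, 84L)[st])), character(1))
  })
  names(seqs) <- names(scaffold_lengths)
  mask_runs <- data.frame(scaffold = character(0), species = character(0),
                          start = integer(0), end = integer(0))
  if (n_mask_runs > 0 && mask_run_length > 0) {
    for (i in seq_len(n_mask_runs)) {
      sc <- sample(names(seqs), 1)
      sp <- sample(tree$phy$tip.label, 1)
      L <- scaffold_lengths[[sc]]
      if (mask_run_length >= L) stop2("mask run longer than scaffold")
      start <- sample.int(L - mask_run_length, 1) - 1L  # 0-based
      substr(seqs[[sc]][[sp]], start + 1L, start + mask_run_length) <-
        strrep("N", mask_run_length)
      mask_runs <- rbind(mask_runs, data.frame(
        scaffold = sc, species = sp, start = start,
        end = start + mask_run_length))
    }
  }
  list(alignment = alignment_set(seqs),
       truth = list(edge_changes = changes), mask_runs = mask_runs)
}

#' Simulate a read-depth track with planted copy-number gains
#'
#' Per-base depth is Poisson with mean `mean_depth * CN / 2`, so CN = 2 is
#' the diploid baseline and a planted CN = 4 region doubles the expected
#' depth.
#'
#' @param scaffold_lengths Named or unnamed integer vector of lengths.
#' @param regions Data frame (`scaffold`, `start`, `end`, `cn`) of planted
#'   copy-number regions, 0-based half-open; may be empty.
#' @param mean_depth Expected depth at CN = 2.
#' @param seed Integer seed (required).
#' @return Object of class `depth_track`: `depth` (list scaffold ->
#'   integer per-base vector), `truth` (the planted regions).
#' @export
simulate_read_depth <- function(scaffold_lengths, regions = NULL,
                                mean_depth = 30, seed) {
  if (mean_depth <= 0) stop2("mean_depth must be > 0")
  if (any(scaffold_lengths <= 0)) stop2("scaffold lengths must be positive")
  set_seed_strict(seed)
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scaf%02d", seq_along(scaffold_lengths))
  if (is.null(regions))
    regions <- data.frame(scaffold = character(0), start = integer(0),
                          end = integer(0), cn = numeric(0))
  if (nrow(regions) && any(regions$end <= regions$start))
    stop2("zero-length copy-number region")
  depth <- lapply(names(scaffold_lengths), function(sc) {
    L <- scaffold_lengths[[sc]]
    cn <- rep(2, L)
    rr <- regions[regions$scaffold == sc, , drop = FALSE]
    for (i in seq_len(nrow(rr))) {
      if (rr$end[i] > L) stop2("region beyond scaffold end")
      cn[(rr$start[i] + 1L):rr$end[i]] <- rr$cn[i]
    }
    rpois(L, mean_depth * cn / 2)
  })
  names(depth) <- names(scaffold_lengths)
  structure(list(depth = depth, mean_depth = mean_depth, truth = regions),
            class = "depth_track")
}

#' Write / read a depth track in bedGraph format
#' @param track A `depth_track` (or list of per-scaffold integer vectors).
#' @param path Output file.
#' @return `path`, invisibly (writer); a `depth_track` (reader).
#' @export
write_bedgraph <- function(track, path) {
  depth <- if (inherits(track, "depth_track")) track$depth else track
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in names(depth)) {
    r <- rle(depth[[sc]])
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    writeLines(sprintf("%s\t%d\t%d\t%d", sc, starts, ends, r$values), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  bg <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("scaffold", "start", "end", "depth"))
  depth <- lapply(split(bg, bg$scaffold), function(b) {
    b <- b[order(b$start), ]
    rep(as.integer(b$depth), b$end - b$start)
  })
  structure(list(depth = depth, mean_depth = NA, truth = NULL),
            class = "depth_track")
}

#' Haldane map function: recombination fraction from map distance
#' @param d_cM Map distance in centimorgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_rf <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate a single-family mapping population
#'
#' Emulates genotyping the diploid worker offspring of one colony: the
#' queen is heterozygous (A/B) at every marker by construction and the
#' haploid father carries allele A everywhere, so each offspring is
#' homozygous when it inherits the paternal-matching maternal allele and
#' heterozygous otherwise. Maternal gametes recombine between adjacent
#' markers with the Haldane map function; chromosomes assort
#' independently.
#'
#' @param n_offspring Number of genotyped offspring (>= 2).
#' @param chromosomes List of numeric vectors: marker positions in cM per
#'   chromosome (each non-empty).
#' @param missing_rate Probability a genotype is missing at random.
#' @param seed Integer seed (required).
#' @return Object of class `marker_matrix`: `queen` (genotype per
#'   marker), `geno` (marker x offspring genotype matrix, `"A/A"` or
#'   `"A/B"`), `info` (marker, chromosome, position), `truth`
#'   (chromosome assignment per marker).
#' @export
simulate_mapping_population <- function(n_offspring = 47, chromosomes,
                                        missing_rate = 0, seed) {
  if (n_offspring < 2) stop2("need at least two offspring")
  if (!length(chromosomes) || any(!lengths(chromosomes)))
    stop2("each chromosome needs at least one marker")
  set_seed_strict(seed)
  if (is.null(names(chromosomes)))
    names(chromosomes) <- sprintf("chr%d", seq_along(chromosomes))
  info <- do.call(rbind, lapply(names(chromosomes), function(ch)
    data.frame(marker = sprintf("%s_m%02d", ch,
                                seq_along(chromosomes[[ch]])),
               chromosome = ch, pos_cM = sort(chromosomes[[ch]]))))
  m <- nrow(info)
  maternal <- matrix(0L, m, n_offspring)  # 0 = allele A (paternal-matching)
  row0 <- 1L
  for (ch in names(chromosomes)) {
    pos <- sort(chromosomes[[ch]])
    k <- length(pos)
    rf <- haldane_rf(diff(pos))
    for (o in seq_len(n_offspring)) {
      g <- integer(k)
      g[1] <- sample(0:1, 1)
      if (k > 1) {
        flips <- runif(k - 1) < rf
        for (i in 2:k) g[i] <- if (flips[i - 1]) 1L - g[i - 1] else g[i - 1]
      }
      maternal[row0:(row0 + k - 1L), o] <- g
    }
    row0 <- row0 + k
  }
  geno <- ifelse(maternal == 0L, "A/A", "A/B")
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA_character_
  dimnames(geno) <- list(info$marker, sprintf("off%02d", seq_len(n_offspring)))
  structure(list(queen = setNames(rep("A/B", m), info$marker), geno = geno,
                 info = info,
                 truth = setNames(info$chromosome, info$marker)),
            class = "marker_matrix")
}

#' Simulate a per-gene, multi-tissue expression matrix
#'
#' Baseline expression mass is drawn independently per gene and tissue
#' from a gamma distribution; genes in `fast_gene_ids` have their
#' head-tissue mass multiplied by `1 + head_shift`, so `head_shift = 0`
#' is an exact null and large values concentrate expression in heads.
#' The default of 29 tissues matches the tissue panel of the fly
#' expression compendium the contrast was designed for.
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues (first column is `"head"`).
#' @param fast_gene_ids Integer indices of the fast-evolving gene set.
#' @param head_shift Non-negative head-tissue elevation for fast genes.
#' @param seed Integer seed (required).
#' @return Numeric matrix genes x tissues, non-negative.
#' @export
simulate_expression_matrix <- function(n_genes = 2000, n_tissues = 29,
                                       fast_gene_ids = integer(0),
                                       head_shift = 0, seed) {
  if (head_shift < 0) stop2("head_shift must be >= 0")
  if (length(fast_gene_ids) &&
      (min(fast_gene_ids) < 1 || max(fast_gene_ids) > n_genes))
    stop2("fast_gene_ids outside 1..n_genes")
  set_seed_strict(seed)
  mat <- matrix(rgamma(n_genes * n_tissues, shape = 2, rate = 2),
                n_genes, n_tissues)
  mat[fast_gene_ids, 1] <- mat[fast_gene_ids, 1] * (1 + head_shift)
  dimnames(mat) <- list(sprintf("g%05d", seq_len(n_genes)),
                        c("head", sprintf("tissue%02d", seq_len(n_tissues - 1) + 1L)))
  mat
}
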