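# Counting-method dN/dS (Nei-Gojobori 1986) with pathway averaging and
# Jukes-Cantor correction, species-level aggregation with the outlier
# filters used genome-wide, and codon usage statistics (Wright's
# effective number of codons, GC3, usage proportions).

#' Fractional synonymous/nonsynonymous site counts of a coding sequence
#'
#' For every codon, each of the three positions contributes the fraction
#' of its possible single-base changes that are synonymous, with changes
#' into stop codons excluded from the denominator; S + N = 3 per counted
#' codon. Codons containing non-ACGT characters or stops are skipped and
#' tallied.
#'
#' @param seq Coding nucleotide string (length a multiple of 3) or a
#'   character vector of codons.
#' @return List: `S`, `N`, `n_codons` (counted), `n_skipped`.
#' @export
ng86_site_counts <- function(seq) {
  codons <- if (length(seq) == 1L && nchar(seq[1]) > 3L) split_codons(seq)
            else toupper(seq)
  sc <- ng86_codon_sites()[codon_index(codons)]
  ok <- !is.na(sc)
  S <- sum(sc[ok])
  list(S = S, N = 3 * sum(ok) - S, n_codons = sum(ok), n_skipped = sum(!ok))
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN and dS by the Nei-Gojobori counting method
#'
#' Site counts are averaged between the two sequences; codon differences
#' at more than one position are averaged with equal weights over all
#' orderings of single-base steps that avoid stop codons. Proportions are
#' Jukes-Cantor corrected (`d = -3/4 log(1 - 4p/3)`); when a proportion
#' reaches 3/4 the corresponding rate is undefined and flagged.
#'
#' @param seq1,seq2 Codon-aligned coding sequences of equal length.
#' @return List: `dn`, `ds`, `ratio`, `pn`, `ps`, `S`, `N`, `Sd`, `Nd`,
#'   `n_codons`, `n_skipped`, `flags` (character vector, possibly empty,
#'   from `ds0`, `jc_undefined`).
#' @export
ng86_pair <- function(seq1, seq2) {
  c1 <- if (length(seq1) > 1L) toupper(seq1) else split_codons(seq1)
  c2 <- if (length(seq2) > 1L) toupper(seq2) else split_codons(seq2)
  if (length(c1) != length(c2)) stop2("sequences differ in codon count")
  i1 <- codon_index(c1); i2 <- codon_index(c2)
  sites <- ng86_codon_sites()
  pair <- ng86_pair_tables()
  usable <- !is.na(i1) & !is.na(i2)
  usable[usable] <- !is.na(sites[i1[usable]]) & !is.na(sites[i2[usable]])
  # drop codon pairs whose every mutational pathway is blocked by a stop
  usable[usable] <- !is.na(pair$sd[cbind(i1[usable], i2[usable])])
  n_used <- sum(usable)
  if (n_used == 0L) stop2("no comparable codons")
  i1 <- i1[usable]; i2 <- i2[usable]
  S <- (sum(sites[i1]) + sum(sites[i2])) / 2
  N <- 3 * n_used - S
  Sd <- sum(pair$sd[cbind(i1, i2)])
  Nd <- sum(pair$nd[cbind(i1, i2)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ds <- jc_correct(ps); dn <- jc_correct(pn)
  flags <- character(0)
  if ((!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75))
    flags <- c(flags, "jc_undefined")
  if (!is.na(ds) && ds == 0) flags <- c(flags, "ds0")
  ratio <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
  list(dn = dn, ds = ds, ratio = ratio, pn = pn, ps = ps, S = S, N = N,
       Sd = Sd, Nd = Nd, n_codons = n_used,
       n_skipped = length(usable) - n_used, flags = flags)
}

#' Per-gene, per-species substitution rates with species aggregates
#'
#' Computes dN/dS of every non-reference species against the reference for
#' each gene, then aggregates per species two ways: the mean of per-gene
#' ratios (genes with undefined ratio or ratio >= `max_ratio` excluded, as
#' extreme ratios typically reflect assembly or annotation error) and the
#' ratio of summed dN to summed dS (robust to outlying loci; dS = 0 genes
#' contribute their dN to the sums but no per-gene ratio).
#'
#' @param gene_alns List of `gene_alignment` objects.
#' @param design A [pair_design()].
#' @param max_ratio Per-gene ratio filter (default 10).
#' @return List: `rates` (data frame gene x species: dn, ds, ratio,
#'   flags), `aggregates` (per species: mean_dn, mean_ds, mean_ratio,
#'   n_ratio_genes, sum_dn, sum_ds, sum_ratio).
#' @export
species_rate_table <- function(gene_alns, design = pair_design(),
                               max_ratio = 10) {
  if (!length(gene_alns)) stop2("empty gene set")
  species <- setdiff(names(gene_alns[[1]]$seqs), design$reference)
  check_design_species(design, names(gene_alns[[1]]$seqs), "gene alignments")
  rows <- list()
  for (g in gene_alns) {
    ref <- g$seqs[[design$reference]]
    for (sp in species) {
      r <- ng86_pair(g$seqs[[sp]], ref)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$gene_id, species = sp, dn = r$dn, ds = r$ds,
        ratio = r$ratio, flags = paste(r$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  list(rates = rates, aggregates = rate_aggregates(rates, max_ratio))
}

#' Aggregate a per-gene rate table to species-level summaries
#'
#' Accepts any long table of per-gene, per-species dN/dS estimates (from
#' [species_rate_table()] or an external model fit) and reports, per
#' species, the mean of per-gene ratios over genes with a defined ratio
#' below `max_ratio`, and the outlier-robust ratio of summed dN to summed
#' dS (dS = 0 genes contribute to the sums but have no per-gene ratio).
#'
#' @param rates Data frame with columns `gene`, `species`, `dn`, `ds`,
#'   `ratio`.
#' @param max_ratio Per-gene ratio filter (default 10).
#' @return Data frame per species: mean_dn, mean_ds, mean_ratio,
#'   n_ratio_genes, sum_dn, sum_ds, sum_ratio.
#' @export
rate_aggregates <- function(rates, max_ratio = 10) {
  rates$ratio_used <- !is.na(rates$ratio) & rates$ratio < max_ratio
  agg <- do.call(rbind, lapply(split(rates, rates$species), function(d) {
    data.frame(species = d$species[1],
               mean_dn = mean(d$dn, na.rm = TRUE),
               mean_ds = mean(d$ds, na.rm = TRUE),
               mean_ratio = mean(d$ratio[d$ratio_used]),
               n_ratio_genes = sum(d$ratio_used),
               sum_dn = sum(d$dn, na.rm = TRUE),
               sum_ds = sum(d$ds, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  agg$sum_ratio <- ifelse(agg$sum_ds > 0, agg$sum_dn / agg$sum_ds, NA_real_)
  rownames(agg) <- NULL
  agg
}

#' Wide gene-by-species table of one rate statistic
#' @param rates `rates` element of [species_rate_table()].
#' @param statistic One of `"dn"`, `"ds"`, `"ratio"`.
#' @return Data frame with `unit` (gene id) plus one column per species.
#' @export
rate_statistic_table <- function(rates, statistic = c("ds", "dn", "ratio")) {
  statistic <- match.arg(statistic)
  wide <- stats::reshape(rates[, c("gene", "species", statistic)],
                         idvar = "gene", timevar = "species",
                         direction = "wide")
  names(wide) <- sub(paste0("^", statistic, "\\."), "", names(wide))
  names(wide)[1] <- "unit"
  rownames(wide) <- NULL
  wide
}

# Synonymous-family classes of the standard code for Wright's estimator:
# the two non-degenerate amino acids (Met, Trp) contribute the constant 2;
# Ile is the single 3-fold family; Leu, Ser and Arg are 6-fold families.
enc_families <- function() {
  if (!is.null(.cr_cache$fam)) return(.cr_cache$fam)
  code <- genetic_code()
  fam <- split(sense_codons(), code[sense_codons()])
  fam <- fam[lengths(fam) > 1L]
  .cr_cache$fam <- fam
  fam
}

#' Wright's effective number of codons (Nc)
#'
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean codon
#' homozygosity `F = (n * sum(p^2) - 1) / (n - 1)` over the synonymous
#' families with k codons (families with fewer than 2 counted codons or
#' non-positive F are unusable). A degeneracy class with no usable family
#' is imputed by the mean of the observed class means. The result is
#' capped at 61; `NA` when no class is observed.
#'
#' @param counts Named numeric vector of codon counts (names are codons);
#'   missing codons count 0.
#' @return Nc in [20, 61], or `NA`.
#' @export
enc <- function(counts) {
  if (!length(counts) || is.null(names(counts))) stop2("named codon counts required")
  full <- setNames(numeric(61), sense_codons())
  counts <- counts[names(counts) %in% sense_codons()]
  full[names(counts)] <- full[names(counts)] + as.numeric(counts)
  if (sum(full) == 0) stop2("no sense codons counted")
  fams <- enc_families()
  fhat <- lapply(fams, function(cods) {
    n <- sum(full[cods])
    if (n < 2) return(NA_real_)
    p <- full[cods] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  })
  sizes <- lengths(fams)
  class_mean <- vapply(c(2, 3, 4, 6), function(k) {
    v <- unlist(fhat[sizes == k])
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(class_mean) <- c("F2", "F3", "F4", "F6")
  if (all(is.na(class_mean))) return(NA_real_)
  imput <- mean(class_mean, na.rm = TRUE)
  class_mean[is.na(class_mean)] <- imput
  nc <- 2 + 9 / class_mean["F2"] + 1 / class_mean["F3"] +
    5 / class_mean["F4"] + 3 / class_mean["F6"]
  unname(min(nc, 61))
}

#' Codon counts of one or more coding sequences
#' @param seqs Character vector of coding sequences.
#' @return Named integer vector over the 61 sense codons.
#' @export
codon_counts <- function(seqs) {
  cods <- unlist(lapply(seqs, split_codons))
  tab <- table(factor(cods, levels = sense_codons()))
  setNames(as.integer(tab), names(tab))
}

#' Codon usage composition per species
#'
#' Per species: proportions of the 61 sense codons, GC3 (fraction of
#' third positions that are G or C, over unambiguous codons) and Wright's
#' Nc computed from the concatenated coding sequence.
#'
#' @param gene_alns List of `gene_alignment` objects.
#' @return Data frame species x (gc3, enc) plus a `proportions` attribute
#'   (species x 61 matrix).
#' @export
codon_composition <- function(gene_alns) {
  if (!length(gene_alns)) stop2("no genes supplied")
  species <- names(gene_alns[[1]]$seqs)
  props <- matrix(0, length(species), 61,
                  dimnames = list(species, sense_codons()))
  gc3 <- numeric(length(species)); nc <- numeric(length(species))
  for (i in seq_along(species)) {
    seqs <- vapply(gene_alns, function(g) g$seqs[[species[i]]], character(1))
    counts <- codon_counts(seqs)
    if (sum(counts) == 0) stop2("no sense codons for species ", species[i])
    props[i, ] <- counts / sum(counts)
    third <- substring(names(counts), 3, 3)
    gc3[i] <- sum(counts[third %in% c("G", "C")]) / sum(counts)
    nc[i] <- enc(counts)
  }
  out <- data.frame(species = species, gc3 = gc3, enc = nc,
                    stringsAsFactors = FALSE)
  attr(out, "proportions") <- props
  out
}

#' Rank correlation of per-gene codon bias with substitution rates
#'
#' Computes each gene's Nc (per species, from that species' sequence) and
#' its Spearman correlation with the gene's dN and dS for the same
#' species.
#'
#' @param gene_alns List of `gene_alignment` objects.
#' @param rates `rates` element of [species_rate_table()].
#' @return Data frame per species: rho and p for Nc~dN and Nc~dS.
#' @export
enc_rate_correlation <- function(gene_alns, rates) {
  species <- unique(rates$species)
  gene_ids <- vapply(gene_alns, function(g) g$gene_id, character(1))
  out <- lapply(species, function(sp) {
    ncs <- vapply(gene_alns, function(g)
      tryCatch(enc(codon_counts(g$seqs[[sp]])), error = function(e) NA_real_),
      numeric(1))
    d <- rates[rates$species == sp, ]
    d <- d[match(gene_ids, d$gene), ]
    ct <- function(y) {
      ok <- !is.na(ncs) & !is.na(y)
      if (sum(ok) < 3) return(c(NA_real_, NA_real_))
      r <- suppressWarnings(cor.test(ncs[ok], y[ok], method = "spearman"))
      c(unname(r$estimate), r$p.value)
    }
    cn <- ct(d$dn); cs <- ct(d$ds)
    data.frame(species = sp, rho_dn = cn[1], p_dn = cn[2],
               rho_ds = cs[1], p_ds = cs[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
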