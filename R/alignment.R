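# Species alignment container and the consensus-calling, gene-extraction
# and gene-QC rules applied before any rate estimation.
#
# An alignment_set holds, per scaffold, one equal-length sequence per
# species in reference coordinates (0-based half-open internally). The
# alphabet is A/C/G/T plus N (unknown), "-" (gap) and, optionally, IUPAC
# ambiguity codes produced by heterozygous consensus calls.

ALIGN_ALPHABET <- c("A", "C", "G", "T", "N", "-",
                    "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a species alignment set
#'
#' @param seqs Named list: scaffold id -> named character vector of
#'   equal-length sequences (one per species).
#' @return Object of class `alignment_set` with elements `seqs` and
#'   `species`.
#' @export
alignment_set <- function(seqs) {
  if (!is.list(seqs) || is.null(names(seqs)) || any(names(seqs) == ""))
    stop2("'seqs' must be a named list of scaffolds")
  species <- NULL
  for (sc in names(seqs)) {
    v <- seqs[[sc]]
    if (is.null(names(v)) || any(names(v) == ""))
      stop2("scaffold ", sc, ": sequences must be named by species")
    if (length(unique(nchar(v))) != 1L)
      stop2("scaffold ", sc, ": rows have unequal lengths")
    sp <- sort(names(v))
    if (is.null(species)) species <- sp
    else if (!identical(species, sp))
      stop2("species set differs between scaffolds (", sc, ")")
    seqs[[sc]] <- toupper(v)
  }
  structure(list(seqs = seqs, species = species), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  lens <- vapply(x$seqs, function(v) nchar(v[1]), numeric(1))
  cat("Alignment set:", length(x$seqs), "scaffold(s),",
      length(x$species), "species,", sum(lens), "aligned bases\n")
  invisible(x)
}

scaffold_length <- function(aln, scaffold) nchar(aln$seqs[[scaffold]][1])

#' Read a species alignment from per-scaffold FASTA files
#'
#' Each file holds one scaffold with one record per species. Sequences are
#' uppercased; characters outside the supported alphabet are replaced by N
#' with a warning (the replacement count is attached as attribute
#' `n_unknown_symbols`).
#'
#' @param paths Named character vector: scaffold id -> FASTA path. Unnamed
#'   paths use the file base name.
#' @return An [alignment_set()].
#' @export
load_alignment <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(fa|fasta|fna)$", "", basename(paths))
  n_fixed <- 0L
  seqs <- lapply(paths, function(p) {
    ss <- Biostrings::readBStringSet(p)
    v <- toupper(setNames(as.character(ss), names(ss)))
    bad <- gsub(paste(ALIGN_ALPHABET, collapse = "|"), "", v)
    nb <- sum(nchar(bad))
    if (nb > 0) {
      n_fixed <<- n_fixed + nb
      for (ch in unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
        v <- gsub(ch, "N", v, fixed = TRUE)
    }
    v
  })
  if (n_fixed > 0)
    warning(n_fixed, " unsupported symbols replaced by N", call. = FALSE)
  out <- alignment_set(seqs)
  attr(out, "n_unknown_symbols") <- n_fixed
  out
}

#' Write a species alignment as one FASTA file per scaffold
#'
#' @param aln An [alignment_set()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_alignment <- function(aln, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(aln$seqs), function(sc) {
    p <- file.path(dir, paste0(sc, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs[[sc]]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Describe a gene model in reference coordinates
#'
#' @param gene_id Gene identifier.
#' @param scaffold Scaffold holding the gene.
#' @param intervals Data frame with `start`/`end` columns, 0-based
#'   half-open, sorted and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param frame Bases to trim from the coding start (0, 1 or 2).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold, intervals, strand = "+", frame = 0) {
  if (!strand %in% c("+", "-")) stop2("strand must be '+' or '-'")
  if (!frame %in% 0:2) stop2("frame must be 0, 1 or 2")
  intervals <- as.data.frame(intervals)[, c("start", "end")]
  if (any(intervals$end <= intervals$start)) stop2("empty or reversed interval")
  o <- order(intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals$start[-1] < intervals$end[-nrow(intervals)]))
    stop2("CDS intervals overlap")
  structure(list(gene_id = gene_id, scaffold = scaffold,
                 intervals = intervals, strand = strand, frame = frame),
            class = "gene_model")
}

#' Read gene models from GFF3 (CDS features) or 6-column BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention at this boundary. CDS rows are grouped by
#' their `Parent` (or `ID`) attribute.
#'
#' @param path File path; format chosen by extension (`.gff`/`.gff3` vs
#'   `.bed`).
#' @return List of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path)) {
    bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    names(bed)[1:6] <- c("scaffold", "start", "end", "name", "frame", "strand")
    return(lapply(split(bed, bed$name), function(b)
      gene_model(b$name[1], b$scaffold[1],
                 data.frame(start = b$start, end = b$end),
                 strand = b$strand[1], frame = b$frame[1])))
  }
  gff <- read.table(path, sep = "\t", comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
  names(gff) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  if (!nrow(gff)) stop2("no CDS features in ", path)
  att <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  gid <- att(gff$attributes, "Parent")
  gid[is.na(gid)] <- att(gff$attributes[is.na(gid)], "ID")
  gff$gene <- gid
  lapply(split(gff, gff$gene), function(g) {
    ph <- suppressWarnings(as.integer(g$phase))
    first <- which.min(if (g$strand[1] == "+") g$start else -g$end)
    gene_model(g$gene[1], g$seqid[1],
               data.frame(start = g$start - 1L, end = g$end),
               strand = g$strand[1],
               frame = if (!is.na(ph[first])) ph[first] else 0L)
  })
}

revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Extract a codon-aligned gene from the species alignment
#'
#' Concatenates the CDS intervals, reverse-complements minus-strand genes
#' (N and IUPAC codes are complemented correctly, gaps preserved) and trims
#' the frame offset.
#'
#' @param aln An [alignment_set()].
#' @param gene A [gene_model()].
#' @return Object of class `gene_alignment`: list with `gene_id`, `seqs`
#'   (named codon-aligned strings), `missing_fraction` per species, and
#'   `masked_codons` (indices masked so far, empty here).
#' @export
extract_gene <- function(aln, gene) {
  sc <- aln$seqs[[gene$scaffold]]
  if (is.null(sc)) stop2("scaffold ", gene$scaffold, " not in alignment")
  L <- nchar(sc[1])
  if (any(gene$intervals$start < 0) || any(gene$intervals$end > L))
    stop2("gene ", gene$gene_id, ": interval outside scaffold bounds")
  pieces <- vapply(names(sc), function(sp)
    paste(substring(sc[[sp]], gene$intervals$start + 1L, gene$intervals$end),
          collapse = ""), character(1))
  if (gene$strand == "-") pieces <- setNames(revcomp(pieces), names(pieces))
  if (gene$frame > 0) pieces <- substring(pieces, gene$frame + 1L)
  if (nchar(pieces[1]) == 0L || nchar(pieces[1]) %% 3L != 0L)
    stop2("gene ", gene$gene_id, ": CDS length not a multiple of 3")
  gene_alignment(gene$gene_id, pieces)
}

#' @rdname extract_gene
#' @param gene_id Gene identifier.
#' @param seqs Named character vector of equal-length, frame-aligned
#'   coding sequences.
#' @export
gene_alignment <- function(gene_id, seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop2("gene ", gene_id, ": rows have unequal lengths")
  if (nchar(seqs[1]) %% 3L != 0L)
    stop2("gene ", gene_id, ": length not a multiple of 3")
  miss <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(!(ch %in% c("A", "C", "G", "T")))
  }, numeric(1))
  structure(list(gene_id = gene_id, seqs = toupper(seqs),
                 missing_fraction = miss, masked_codons = integer(0)),
            class = "gene_alignment")
}

#' Consensus base calling from genotype, allele count and depth
#'
#' Encodes the reference-backed consensus rules used when projecting
#' short-read genotype calls onto a reference: an explicit genotype call
#' wins (heterozygous biallelic calls become IUPAC ambiguity codes, or N
#' under `het = "mask"`); a site with more than 3 alleles is masked as
#' unknown; with no call, the reference base is emitted only at 5x or
#' greater coverage, otherwise N.
#'
#' @param genotype Character vector: called base, `"X/Y"` for a
#'   heterozygous call, or `NA` for no call.
#' @param n_alleles Integer vector of alleles observed at the site.
#' @param depth Non-negative read depth.
#' @param ref Reference base.
#' @param min_depth Coverage needed to call the reference (default 5).
#' @param max_alleles Sites with more alleles are masked (default 3).
#' @param het `"iupac"` (default) or `"mask"` for heterozygous calls.
#' @return Character vector of consensus bases.
#' @export
consensus_call <- function(genotype, n_alleles, depth, ref,
                           min_depth = 5, max_alleles = 3,
                           het = c("iupac", "mask")) {
  het <- match.arg(het)
  if (any(depth < 0)) stop2("negative depth")
  n <- max(length(genotype), length(n_alleles), length(depth), length(ref))
  genotype <- rep_len(genotype, n); n_alleles <- rep_len(n_alleles, n)
  depth <- rep_len(depth, n); ref <- rep_len(toupper(ref), n)
  iupac <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  out <- character(n)
  for (i in seq_len(n)) {
    if (n_alleles[i] > max_alleles) { out[i] <- "N"; next }
    g <- genotype[i]
    if (!is.na(g)) {
      if (grepl("/", g, fixed = TRUE)) {
        al <- sort(toupper(strsplit(g, "/", fixed = TRUE)[[1]]))
        out[i] <- if (al[1] == al[2]) al[1]
          else if (het == "mask") "N"
          else iupac[paste(al, collapse = "")]
        if (is.na(out[i])) out[i] <- "N"
      } else out[i] <- toupper(g)
    } else out[i] <- if (depth[i] >= min_depth) ref[i] else "N"
  }
  out
}

#' Gene-level quality control and premature-stop masking
#'
#' A gene passes when sequence is present for the required number of
#' species, it is at least `min_codons` codons long, and every species has
#' less than `max_missing` unknown or gap characters. Premature stop
#' codons (typically misalignment artifacts) do not fail a gene: the
#' affected codon column is masked to NNN in every species, preserving the
#' alignment.
#'
#' @param g A `gene_alignment`.
#' @param n_species Required species count (default 7).
#' @param min_codons Minimum codon count (default 300).
#' @param max_missing Maximum tolerated missing-data fraction per species
#'   (default 0.20); computed before stop masking.
#' @return List: `pass`, `reasons` (character, empty when passing),
#'   `gene` (the stop-masked `gene_alignment`), `n_masked_codons`.
#' @export
gene_qc <- function(g, n_species = 7, min_codons = 300, max_missing = 0.20) {
  reasons <- character(0)
  if (length(g$seqs) != n_species)
    reasons <- c(reasons, "species")
  n_codons <- nchar(g$seqs[1]) %/% 3L
  if (n_codons < min_codons) reasons <- c(reasons, "length")
  if (any(g$missing_fraction >= max_missing)) reasons <- c(reasons, "missing")
  codmat <- vapply(g$seqs, split_codons, character(n_codons))
  if (n_codons == 1L) codmat <- matrix(codmat, nrow = 1,
                                       dimnames = list(NULL, names(g$seqs)))
  stop_cols <- which(apply(codmat, 1, function(r) any(r %in% STOP_CODONS)))
  new_cols <- setdiff(stop_cols, g$masked_codons)
  if (length(new_cols)) {
    codmat[new_cols, ] <- "NNN"
    seqs <- apply(codmat, 2, paste, collapse = "")
    gm <- gene_alignment(g$gene_id, seqs)
    gm$missing_fraction <- g$missing_fraction  # pre-masking, per contract
    gm$masked_codons <- sort(union(g$masked_codons, stop_cols))
    g <- gm
  }
  list(pass = length(reasons) == 0L, reasons = reasons, gene = g,
       n_masked_codons = length(stop_cols))
}

#' Mask or drop unreliable codon columns
#'
#' Stand-in for alignment-block filtering: under the default policy any
#' codon column containing a gap in any species is removed (codon-wise, so
#' the result stays a multiple of 3). `"none"` is the identity.
#'
#' @param g A `gene_alignment`.
#' @param policy `"drop-gap-columns"` (default) or `"none"`.
#' @return List: `gene` (filtered `gene_alignment`), `masked_fraction`.
#' @export
mask_columns <- function(g, policy = c("drop-gap-columns", "none")) {
  policy <- match.arg(policy)
  if (policy == "none") return(list(gene = g, masked_fraction = 0))
  n_codons <- nchar(g$seqs[1]) %/% 3L
  codmat <- vapply(g$seqs, split_codons, character(n_codons))
  if (n_codons == 1L) codmat <- matrix(codmat, nrow = 1,
                                       dimnames = list(NULL, names(g$seqs)))
  drop <- apply(codmat, 1, function(r) any(grepl("-", r, fixed = TRUE)))
  keep <- codmat[!drop, , drop = FALSE]
  if (!nrow(keep)) stop2("gene ", g$gene_id, ": no gap-free codon columns")
  out <- gene_alignment(g$gene_id, apply(keep, 2, paste, collapse = ""))
  out$masked_codons <- integer(0)
  list(gene = out, masked_fraction = mean(drop))
}
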