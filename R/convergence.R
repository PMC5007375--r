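# Scan translated gene alignments for convergent amino-acid substitutions
# among a foreground lineage set, with a symmetric background control.
#
# A column is convergent for a foreground subset F' (|F'| >= 2) when all
# members of F' share residue a and no species outside F' carries a
# (shared-exclusive mode); strict-background-uniform mode additionally
# requires every non-F' species to share a single residue b != a, the
# pattern shown by all worked examples of site-level convergence (e.g.
# two foreground lineages converging on aspartic acid while all other
# species retain asparagine). Columns containing any gap or unknown
# residue are excluded from the sites-examined denominator and tallied.

UNKNOWN_AA <- c("X", "-", "*", "?")

#' Translate gene alignments to protein alignments
#' @param gene_alns List of `gene_alignment` objects.
#' @return Named list: gene id -> named character vector of amino-acid
#'   strings.
#' @export
translate_gene_alignments <- function(gene_alns) {
  out <- lapply(gene_alns, function(g)
    vapply(g$seqs, function(s)
      paste(translate_codons(split_codons(s)), collapse = ""), character(1)))
  names(out) <- vapply(gene_alns, function(g) g$gene_id, character(1))
  out
}

#' Scan protein alignments for convergent substitutions
#'
#' @param proteins Named list: gene id -> named character vector of
#'   equal-length amino-acid strings (one per species), as produced by
#'   [translate_gene_alignments()].
#' @param foreground Character vector of foreground species (>= 2, subset
#'   of the alignment species).
#' @param mode `"shared-exclusive"` (default) or
#'   `"strict-background-uniform"`.
#' @return List: `records` (data frame: gene, position (1-based within
#'   the translated gene), subset, subset_size, residue, background,
#'   mode), `totals` with `sites_examined`, `sites_excluded`,
#'   `n_convergent` (subset size >= 2), `n_fully_convergent`
#'   (subset = all foreground), and their percentages of sites examined
#'   at printed precision.
#' @export
scan_convergent_sites <- function(proteins, foreground,
                                  mode = c("shared-exclusive",
                                           "strict-background-uniform")) {
  mode <- match.arg(mode)
  if (length(foreground) < 2) stop2("need at least two foreground species")
  records <- list()
  sites_examined <- 0L; sites_excluded <- 0L
  for (gid in names(proteins)) {
    aln <- proteins[[gid]]
    if (!all(foreground %in% names(aln)))
      stop2("foreground species missing from gene ", gid)
    mat <- do.call(rbind, strsplit(aln, ""))
    rownames(mat) <- names(aln)
    fg <- mat[foreground, , drop = FALSE]
    bg <- mat[setdiff(rownames(mat), foreground), , drop = FALSE]
    ok <- colSums(matrix(mat %in% UNKNOWN_AA, nrow = nrow(mat))) == 0L
    sites_examined <- sites_examined + sum(ok)
    sites_excluded <- sites_excluded + sum(!ok)
    bg_uniform <- colSums(bg != bg[rep(1L, nrow(bg)), , drop = FALSE]) == 0L
    for (res in setdiff(unique(as.vector(fg)), UNKNOWN_AA)) {
      fg_n <- colSums(fg == res)
      hit <- ok & fg_n >= 2L & colSums(bg == res) == 0L
      if (mode == "strict-background-uniform")
        hit <- hit & bg_uniform & bg[1L, ] != res
      for (col in which(hit)) {
        members <- foreground[fg[, col] == res]
        records[[length(records) + 1L]] <- data.frame(
          gene = gid, position = col,
          subset = paste(sort(members), collapse = ","),
          subset_size = length(members), residue = res,
          background = paste(sort(unique(bg[, col])), collapse = ","),
          mode = mode, stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(records)) {
    r <- do.call(rbind, records)
    r[order(r$gene, r$position), , drop = FALSE]
  } else {
    data.frame(gene = character(0), position = integer(0),
               subset = character(0), subset_size = integer(0),
               residue = character(0), background = character(0),
               mode = character(0), stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  n_full <- sum(records$subset_size == length(foreground))
  totals <- list(
    sites_examined = sites_examined, sites_excluded = sites_excluded,
    n_convergent = nrow(records), n_fully_convergent = n_full,
    pct_convergent = if (sites_examined > 0)
      format_percent(nrow(records), sites_examined) else NA_real_,
    pct_fully_convergent = if (sites_examined > 0)
      format_percent(n_full, sites_examined) else NA_real_)
  list(records = records, totals = totals)
}

#' Per-gene summary of convergent sites
#'
#' @param records `records` data frame from [scan_convergent_sites()].
#' @param full_size Size of the full foreground set.
#' @param min_full Threshold for the "genes with at least k fully
#'   convergent sites" list (default 3).
#' @return List: `per_gene` (gene, n_convergent, n_fully_convergent),
#'   `genes_with_min_full` (character vector), `total_convergent`,
#'   `total_fully_convergent`.
#' @export
gene_summary <- function(records, full_size, min_full = 3) {
  if (!nrow(records)) {
    return(list(per_gene = data.frame(gene = character(0),
                                      n_convergent = integer(0),
                                      n_fully_convergent = integer(0)),
                genes_with_min_full = character(0),
                total_convergent = 0L, total_fully_convergent = 0L))
  }
  per_gene <- do.call(rbind, lapply(split(records, records$gene), function(d)
    data.frame(gene = d$gene[1], n_convergent = nrow(d),
               n_fully_convergent = sum(d$subset_size == full_size),
               stringsAsFactors = FALSE)))
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       genes_with_min_full =
         per_gene$gene[per_gene$n_fully_convergent >= min_full],
       total_convergent = sum(per_gene$n_convergent),
       total_fully_convergent = sum(per_gene$n_fully_convergent))
}
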