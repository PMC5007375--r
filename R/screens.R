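# Genome screens: nuclear-mitochondrial insertion (NuMt) counting from
# homology hit tables, depth-based copy-number estimation with the
# life-history consistency rule, and transposable-element candidate
# filtering.

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12 columns: qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path File path.
#' @return Data frame with the standard column names.
#' @export
read_blast6 <- function(path) {
  read.table(path, sep = "\t", stringsAsFactors = FALSE,
             col.names = c("qseqid", "sseqid", "pident", "length",
                           "mismatch", "gapopen", "qstart", "qend",
                           "sstart", "send", "evalue", "bitscore"))
}

#' Count nuclear insertions of mitochondrial genes from homology hits
#'
#' A hit counts as an introgression of its query (seed) gene when its
#' e-value is below `e_max` and its alignment spans at least `min_cov` of
#' the seed length. Malformed rows (missing coordinates, e-value or an
#' unknown seed) are skipped and tallied.
#'
#' @param hits Data frame with at least `qseqid`, `qstart`, `qend`,
#'   `evalue` (e.g. from [read_blast6()]).
#' @param seed_lengths Named numeric vector: query id -> seed length.
#' @param e_max E-value threshold (default 1e-20, exclusive).
#' @param min_cov Minimum seed coverage (default 0.35, inclusive).
#' @return List: `per_gene` (named counts over all seeds),
#'   `total`, `genes_with_copy` (number of seed genes with >= 1 counted
#'   hit), `n_malformed`.
#' @export
numt_count <- function(hits, seed_lengths, e_max = 1e-20, min_cov = 0.35) {
  need <- c("qseqid", "qstart", "qend", "evalue")
  if (!all(need %in% names(hits))) stop2("hit table lacks required columns")
  span <- abs(hits$qend - hits$qstart) + 1
  known <- hits$qseqid %in% names(seed_lengths)
  malformed <- !known | is.na(hits$evalue) | is.na(span) |
    (known & span > seed_lengths[hits$qseqid] + 1e-9)
  ok <- !malformed
  cov <- span[ok] / seed_lengths[hits$qseqid[ok]]
  counted <- hits$evalue[ok] < e_max & cov >= min_cov
  per_gene <- table(factor(hits$qseqid[ok][counted],
                           levels = names(seed_lengths)))
  per_gene <- setNames(as.integer(per_gene), names(per_gene))
  list(per_gene = per_gene, total = sum(per_gene),
       genes_with_copy = sum(per_gene >= 1), n_malformed = sum(malformed))
}

#' Estimate region copy number from a read-depth track
#'
#' `CN = 2 * mean(region depth) / median(genome depth)`, with both the
#' genome-wide median and region means computed over unmasked positions
#' only (the median normalizer is robust to the planted gains themselves).
#' Fully masked regions get `NA` and a flag.
#'
#' @param track A `depth_track` (see [simulate_read_depth()] /
#'   [read_bedgraph()]).
#' @param regions Data frame (`scaffold`, `start`, `end`), 0-based
#'   half-open.
#' @param mask Optional data frame of masked intervals, same columns.
#' @return Data frame: `scaffold`, `start`, `end`, `cn`, `masked_out`
#'   (fully masked flag).
#' @export
cn_estimate <- function(track, regions, mask = NULL) {
  depth <- track$depth
  unmasked <- lapply(names(depth), function(sc) {
    keep <- rep(TRUE, length(depth[[sc]]))
    if (!is.null(mask) && nrow(mask)) {
      mm <- mask[mask$scaffold == sc, , drop = FALSE]
      for (i in seq_len(nrow(mm)))
        keep[(mm$start[i] + 1L):mm$end[i]] <- FALSE
    }
    keep
  })
  names(unmasked) <- names(depth)
  med <- median(unlist(lapply(names(depth), function(sc)
    depth[[sc]][unmasked[[sc]]])))
  if (!is.finite(med) || med <= 0) stop2("genome median depth is undefined")
  out <- regions
  out$cn <- NA_real_
  out$masked_out <- FALSE
  for (i in seq_len(nrow(regions))) {
    sc <- regions$scaffold[i]
    idx <- (regions$start[i] + 1L):regions$end[i]
    use <- idx[unmasked[[sc]][idx]]
    if (!length(use)) { out$masked_out[i] <- TRUE; next }
    out$cn[i] <- 2 * mean(depth[[sc]][use]) / med
  }
  out
}

#' Flag regions with life-history-consistent copy-number gains
#'
#' A region is `mutualist-amplified` when every mutualist copy number is
#' at least `cn_min` and at least `fold` times every generalist copy
#' number; symmetrically for `generalist-amplified`. Regions missing any
#' ingroup species are skipped and counted.
#'
#' @param cn Data frame with columns `region`, `species`, `cn` (long) or
#'   a regions x species matrix with region ids as row names.
#' @param design A [pair_design()].
#' @param cn_min Minimum copy number in the amplified class (default 1.5).
#' @param fold Minimum fold difference between classes (default 1.5).
#' @return List: `calls` (region, class), `counts`, `n_skipped`.
#' @export
duplication_consistency <- function(cn, design = pair_design(),
                                    cn_min = 1.5, fold = 1.5) {
  if (is.data.frame(cn) && all(c("region", "species", "cn") %in% names(cn))) {
    wide <- stats::reshape(cn[, c("region", "species", "cn")],
                           idvar = "region", timevar = "species",
                           direction = "wide")
    names(wide) <- sub("^cn\\.", "", names(wide))
    rownames(wide) <- wide$region
    cn <- as.matrix(wide[, -1, drop = FALSE])
  }
  mut <- design$pairs$mutualist; gen <- design$pairs$generalist
  if (!all(c(mut, gen) %in% colnames(cn)))
    stop2("copy-number table lacks design species")
  complete <- rowSums(is.na(cn[, c(mut, gen), drop = FALSE])) == 0L
  m <- cn[complete, , drop = FALSE]
  mut_min <- apply(m[, mut, drop = FALSE], 1, min)
  mut_max <- apply(m[, mut, drop = FALSE], 1, max)
  gen_min <- apply(m[, gen, drop = FALSE], 1, min)
  gen_max <- apply(m[, gen, drop = FALSE], 1, max)
  class <- rep("none", nrow(m))
  class[mut_min >= cn_min & mut_min >= fold * gen_max] <- "mutualist-amplified"
  class[gen_min >= cn_min & gen_min >= fold * mut_max] <- "generalist-amplified"
  calls <- data.frame(region = rownames(m), class = class,
                      stringsAsFactors = FALSE)
  list(calls = calls,
       counts = c(mutualist_amplified = sum(class == "mutualist-amplified"),
                  generalist_amplified = sum(class == "generalist-amplified"),
                  none = sum(class == "none")),
       n_skipped = sum(!complete))
}

#' Filter transposable-element candidate predictions
#'
#' Rules applied in order, each removal logged with the first rule that
#' triggered: (1) redundancy removal - candidates at least 80% identical
#' over at least 80% of their length are represented by the single
#' longest sequence; (2) length - candidates shorter than `min_len`
#' bases are removed; (3) protein similarity - candidates with a protein
#' hit of bit score at least `bit_max`, or at least 50% similarity over
#' at least 50% of their length, are removed as false positives.
#'
#' @param candidates Data frame: `id`, `length`.
#' @param protein_hits Optional data frame: `id`, `bitscore`,
#'   `similarity` (percent), `coverage` (fraction of candidate length).
#' @param pairwise Optional data frame of pairwise alignments: `id1`,
#'   `id2`, `identity` (percent), `coverage` (fraction of the shorter
#'   sequence aligned).
#' @param min_len Minimum length (default 80; shorter removed).
#' @param bit_max Bit-score removal threshold (default 100, inclusive).
#' @param cluster_identity,cluster_coverage 80/80 clustering thresholds.
#' @return List: `retained` (ids), `removed` (data frame id, rule).
#' @export
te_filter <- function(candidates, protein_hits = NULL, pairwise = NULL,
                      min_len = 80, bit_max = 100,
                      cluster_identity = 80, cluster_coverage = 0.8) {
  removed <- data.frame(id = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(ids, rule) {
    ids <- setdiff(ids, removed$id)
    if (length(ids))
      removed <<- rbind(removed, data.frame(id = ids, rule = rule,
                                            stringsAsFactors = FALSE))
  }
  # 1. redundancy: union-find over 80/80-similar pairs, keep longest
  if (!is.null(pairwise) && nrow(pairwise)) {
    sim <- pairwise[pairwise$identity >= cluster_identity &
                      pairwise$coverage >= cluster_coverage, , drop = FALSE]
    if (nrow(sim)) {
      ids <- candidates$id
      parent <- seq_along(ids); names(parent) <- ids
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(sim))) {
        i <- find(match(sim$id1[r], ids)); j <- find(match(sim$id2[r], ids))
        if (i != j) parent[j] <- i
      }
      roots <- vapply(seq_along(ids), find, integer(1))
      for (cl in split(seq_along(ids), roots)) {
        if (length(cl) < 2) next
        keep <- cl[which.max(candidates$length[cl])]
        drop(ids[setdiff(cl, keep)], "redundant")
      }
    }
  }
  # 2. length
  drop(candidates$id[candidates$length < min_len], "length")
  # 3. protein similarity
  if (!is.null(protein_hits) && nrow(protein_hits)) {
    bad <- protein_hits$bitscore >= bit_max |
      (protein_hits$similarity >= 50 & protein_hits$coverage >= 0.5)
    drop(unique(protein_hits$id[bad]), "protein")
  }
  list(retained = setdiff(candidates$id, removed$id), removed = removed)
}
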