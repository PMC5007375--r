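# Sliding-window genetic distances, window trees, topology census and
# neutral-locus sampling.
#
# p-distances use the pairwise-complete convention: only sites where both
# sequences are known enter the denominator. Known means any non-N,
# non-gap symbol; IUPAC ambiguity codes are known, and two bases differ
# only when their allele sets are disjoint (so a heterozygous R vs a
# reference A does not count as a difference).

# byte -> allele bitmask (A=1, C=2, G=4, T=8); 0 = unknown (N, gap, other)
allele_mask_table <- function() {
  if (!is.null(.cr_cache$amask)) return(.cr_cache$amask)
  tab <- integer(256)
  set <- function(ch, m) tab[utf8ToInt(ch) + 1L] <<- m
  set("A", 1L); set("C", 2L); set("G", 4L); set("T", 8L)
  set("R", 5L); set("Y", 10L); set("S", 6L); set("W", 9L)
  set("K", 12L); set("M", 3L); set("B", 14L); set("D", 13L)
  set("H", 11L); set("V", 7L)
  .cr_cache$amask <- tab
  tab
}

seq_masks <- function(seq) {
  allele_mask_table()[as.integer(charToRaw(seq)) + 1L]
}

#' Proportion of differing sites between two aligned sequences
#'
#' `p = (# sites where both sequences are known and differ) / (# sites
#' where both are known)`. Returns `NA` (undefined) when no site is
#' comparable.
#'
#' @param seq1,seq2 Aligned sequences of equal length.
#' @return Numeric in [0, 1], with attributes `n_compared` and `n_diff`.
#' @export
p_distance <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop2("sequence lengths differ")
  m1 <- seq_masks(seq1); m2 <- seq_masks(seq2)
  comp <- m1 > 0L & m2 > 0L
  diff <- comp & bitwAnd(m1, m2) == 0L
  nc <- sum(comp); nd <- sum(diff)
  structure(if (nc == 0L) NA_real_ else nd / nc,
            n_compared = nc, n_diff = nd)
}

#' Build sliding windows over every scaffold of an alignment
#'
#' Windows start at 0, `step`, `2*step`, ... and must fit entirely on the
#' scaffold (no shorter trailing window). A window is valid only when
#' every species has known sequence over at least `min_known` of its
#' length.
#'
#' @param aln An [alignment_set()].
#' @param size Window size in bases (default 25000).
#' @param step Step size (default 5000).
#' @param min_known Minimum known fraction per species (default 0.5).
#' @return Data frame: `scaffold`, `start`, `end` (0-based half-open),
#'   `min_known_fraction` (worst species), `valid`.
#' @export
make_windows <- function(aln, size = 25000, step = 5000, min_known = 0.5) {
  if (size <= 0 || step <= 0) stop2("size and step must be positive")
  out <- list()
  for (sc in names(aln$seqs)) {
    L <- scaffold_length(aln, sc)
    if (L < size) next
    starts <- seq.int(0L, L - size, by = step)
    known_cum <- lapply(aln$seqs[[sc]], function(s)
      c(0, cumsum(seq_masks(s) > 0L)))
    kf <- sapply(known_cum, function(cs) (cs[starts + size + 1L] - cs[starts + 1L]) / size)
    kf <- matrix(kf, nrow = length(starts))
    worst <- apply(kf, 1, min)
    out[[sc]] <- data.frame(scaffold = sc, start = starts,
                            end = starts + size,
                            min_known_fraction = worst,
                            valid = worst >= min_known)
  }
  if (!length(out))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), min_known_fraction = numeric(0),
                      valid = logical(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-window genetic distance of each species from the reference
#'
#' @param aln An [alignment_set()].
#' @param windows Output of [make_windows()].
#' @param reference Reference species label.
#' @return Long data frame: `scaffold`, `start`, `end`, `species`,
#'   `distance`, `valid` (window valid and distance defined).
#' @export
window_distances <- function(aln, windows, reference) {
  if (!reference %in% aln$species) stop2("reference species not in alignment")
  species <- setdiff(aln$species, reference)
  out <- list()
  for (sc in unique(windows$scaffold)) {
    w <- windows[windows$scaffold == sc, , drop = FALSE]
    mref <- seq_masks(aln$seqs[[sc]][[reference]])
    for (sp in species) {
      msp <- seq_masks(aln$seqs[[sc]][[sp]])
      comp <- mref > 0L & msp > 0L
      diff <- comp & bitwAnd(mref, msp) == 0L
      ccum <- c(0, cumsum(comp)); dcum <- c(0, cumsum(diff))
      nc <- ccum[w$end + 1L] - ccum[w$start + 1L]
      nd <- dcum[w$end + 1L] - dcum[w$start + 1L]
      out[[paste(sc, sp)]] <- data.frame(
        scaffold = sc, start = w$start, end = w$end, species = sp,
        distance = ifelse(nc > 0, nd / nc, NA_real_),
        valid = w$valid & nc > 0)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Wide table of valid per-window distances
#'
#' Reshapes [window_distances()] output to one row per window with one
#' column per species, keeping windows valid for every species.
#'
#' @param wd Output of [window_distances()].
#' @return Data frame with `unit` (scaffold:start) plus species columns.
#' @export
distance_table <- function(wd) {
  wd$unit <- paste0(wd$scaffold, ":", wd$start)
  keep <- stats::aggregate(valid ~ unit, wd, all)
  wide <- stats::reshape(wd[, c("unit", "species", "distance")],
                         idvar = "unit", timevar = "species",
                         direction = "wide")
  names(wide) <- sub("^distance\\.", "", names(wide))
  wide <- wide[wide$unit %in% keep$unit[keep$valid], , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around the standard neighbor-joining algorithm used here
#' as the per-window tree builder; negative branch-length estimates are
#' clamped to zero.
#'
#' @param d Symmetric, zero-diagonal distance matrix (n >= 3) with row
#'   names.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) stop2("distance matrix has NA/NaN")
  if (nrow(d) < 3) stop2("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0))
    stop2("distance matrix must be symmetric with zero diagonal")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' All-pairs p-distance matrix for one window
#' @param aln An [alignment_set()].
#' @param scaffold,start,end Window coordinates (0-based half-open).
#' @return Symmetric distance matrix over species.
#' @export
window_distance_matrix <- function(aln, scaffold, start, end) {
  sp <- aln$species
  seqs <- substring(aln$seqs[[scaffold]][sp], start + 1L, end)
  d <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- as.numeric(p_distance(seqs[i], seqs[j]))
  }
  d
}

# Children lists for recursive traversal of an ape tree.
phylo_children <- function(phy) split(phy$edge[, 2], phy$edge[, 1])

#' Canonical form of an unrooted tree topology
#'
#' Ignores branch lengths and rooting: the tree is re-rooted at its
#' alphabetically first leaf and children are sorted recursively, so any
#' rotation or rooting of the same topology maps to the same string.
#'
#' @param phy A `phylo` object or Newick string.
#' @return Canonical Newick-like topology string (no branch lengths).
#' @export
canonical_topology <- function(phy) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  phy <- ape::unroot(phy)
  anchor <- sort(phy$tip.label)[1]
  phy <- ape::root(phy, outgroup = anchor, resolve.root = TRUE)
  children <- phylo_children(phy)
  ntip <- length(phy$tip.label)
  canon <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- sort(vapply(children[[as.character(node)]], canon, character(1)))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  canon(ntip + 1L)
}

# Tip-label sets below each edge of a tree (rooted representation).
edge_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  children <- phylo_children(phy)
  sets <- vector("list", ntip + phy$Nnode)
  fill <- function(node) {
    if (node <= ntip) return(sets[[node]] <<- phy$tip.label[node])
    kids <- children[[as.character(node)]]
    sets[[node]] <<- sort(unique(unlist(lapply(kids, fill))))
  }
  fill(ntip + 1L)
  lapply(seq_len(nrow(phy$edge)), function(e) sets[[phy$edge[e, 2]]])
}

#' Does a tree contain a given unrooted split?
#' @param phy `phylo` or Newick string.
#' @param clade Character vector of tip labels.
#' @return Logical.
#' @export
has_clade <- function(phy, clade) {
  if (is.character(phy) && length(phy) == 1 && grepl("\\(", phy))
    phy <- ape::read.tree(text = phy)
  clade <- sort(clade)
  if (!all(clade %in% phy$tip.label)) return(FALSE)
  rest <- sort(setdiff(phy$tip.label, clade))
  for (s in edge_tip_sets(phy))
    if (identical(s, clade) || identical(s, rest)) return(TRUE)
  FALSE
}

#' Census of window-tree topologies
#'
#' Canonicalizes each tree (branch lengths and rooting ignored), tabulates
#' distinct topologies, counts how many trees match a reference topology
#' and how many contain a focal clade as an unrooted split.
#'
#' @param trees List of `phylo` objects or Newick strings.
#' @param reference Optional reference tree/Newick.
#' @param focal_clade Optional character vector of tip labels.
#' @return List: `counts` (named, decreasing), `total`,
#'   `n_distinct`, `reference_count`, `reference_frequency`,
#'   `clade_present`.
#' @export
topology_census <- function(trees, reference = NULL, focal_clade = NULL) {
  phys <- lapply(trees, function(t)
    if (is.character(t)) ape::read.tree(text = t) else t)
  leafsets <- lapply(phys, function(p) sort(p$tip.label))
  if (length(unique(leafsets)) != 1L) stop2("trees have differing leaf sets")
  keys <- vapply(phys, canonical_topology, character(1))
  counts <- sort(table(keys), decreasing = TRUE)
  ref_count <- NA_integer_
  if (!is.null(reference)) {
    rk <- canonical_topology(reference)
    ref_count <- sum(keys == rk)
  }
  clade_n <- NA_integer_
  if (!is.null(focal_clade))
    clade_n <- sum(vapply(phys, has_clade, logical(1), clade = focal_clade))
  list(counts = c(counts), total = length(keys),
       n_distinct = length(counts),
       reference_count = ref_count,
       reference_frequency = if (is.na(ref_count)) NA_real_
                             else ref_count / length(keys),
       clade_present = clade_n)
}

#' Sample putatively neutral loci away from genes and repeats
#'
#' Greedy left-to-right sampling of fixed-length loci that avoid repeats
#' and coding sequence (plus a flank) entirely, keep a minimum gap between
#' consecutive loci, and have adequately complete sequence in a minimum
#' number of ingroup species.
#'
#' @param aln An [alignment_set()].
#' @param cds Data frame (`scaffold`, `start`, `end`) of coding intervals;
#'   may be empty.
#' @param repeats Data frame of repeat intervals, same columns.
#' @param design A [pair_design()]; its non-reference species are checked
#'   for presence.
#' @param locus_len Locus length (default 500).
#' @param min_gap Minimum gap between sampled loci (default 15000).
#' @param cds_flank Exclusion flank around CDS (default 5000).
#' @param min_species Minimum present ingroup species (default 4).
#' @param max_missing A species is present at a locus when its unknown+gap
#'   fraction is at most this (default 0.20).
#' @return Data frame: `scaffold`, `start`, `end`, `n_present`.
#' @export
sample_neutral_loci <- function(aln, cds = NULL, repeats = NULL,
                                design = pair_design(), locus_len = 500,
                                min_gap = 15000, cds_flank = 5000,
                                min_species = 4, max_missing = 0.20) {
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0))
  cds <- cds %||% empty
  repeats <- repeats %||% empty
  ingroup <- intersect(ingroup_species(design), aln$species)
  loci <- list()
  for (sc in names(aln$seqs)) {
    L <- scaffold_length(aln, sc)
    mask <- rbind(
      if (nrow(cds)) {
        cc <- cds[cds$scaffold == sc, c("start", "end"), drop = FALSE]
        if (nrow(cc)) data.frame(start = pmax(0L, cc$start - cds_flank),
                                 end = pmin(L, cc$end + cds_flank))
      },
      if (nrow(repeats)) repeats[repeats$scaffold == sc,
                                 c("start", "end"), drop = FALSE])
    allowed <- if (is.null(mask) || !nrow(mask)) {
      IRanges::IRanges(start = 1L, end = L)
    } else {
      ir <- IRanges::reduce(IRanges::IRanges(start = mask$start + 1L,
                                             end = mask$end))
      IRanges::setdiff(IRanges::IRanges(start = 1L, end = L), ir)
    }
    masks <- lapply(aln$seqs[[sc]][ingroup], seq_masks)
    prev_end <- -Inf  # 0-based end of last sampled locus
    for (k in seq_along(allowed)) {
      run_start <- IRanges::start(allowed)[k] - 1L  # 0-based
      run_end <- IRanges::end(allowed)[k]           # 0-based half-open end
      s <- max(run_start, prev_end + min_gap)
      while (s + locus_len <= run_end) {
        present <- sum(vapply(masks, function(m)
          mean(m[(s + 1L):(s + locus_len)] == 0L) <= max_missing,
          logical(1)))
        if (present >= min_species) {
          loci[[length(loci) + 1L]] <- data.frame(
            scaffold = sc, start = s, end = s + locus_len,
            n_present = present)
          prev_end <- s + locus_len
          s <- prev_end + min_gap
        } else {
          s <- s + locus_len
        }
      }
    }
  }
  if (!length(loci))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_present = integer(0)))
  do.call(rbind, c(loci, make.row.names = FALSE))
}
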