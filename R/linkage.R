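# Mapping-population marker QC, unknown-phase doubling and a simple
# recombination-fraction linkage grouping.
#
# The design is a single haplodiploid family: a heterozygous queen, a
# haploid father, diploid worker offspring. Each informative marker
# reduces to which maternal allele an offspring inherited: offspring are
# homozygous when the paternal-matching maternal allele was transmitted
# and heterozygous otherwise, so the homozygous:heterozygous split is the
# maternal allele ratio, expected 1:1.

#' Marker quality control for a single-family mapping population
#'
#' Rules, applied in order (each removal logged with the first rule
#' triggered): (1) the queen must be genotyped heterozygous; (2) at least
#' `min_genotyped` of offspring genotyped; (3) at most 2 alleles observed
#' across queen and offspring; (4) the maternal allele ratio must not
#' differ significantly from 1:1 by an exact two-sided test on the
#' homozygous/heterozygous offspring counts at level `alpha`.
#'
#' @param mm A `marker_matrix` (see [simulate_mapping_population()]).
#' @param min_genotyped Minimum genotyped fraction (default 0.75).
#' @param alpha Allele-ratio test level (default 0.05).
#' @return List: `retained` (a filtered `marker_matrix`), `removed`
#'   (data frame marker, rule), `ratio_p` (named p-values for markers
#'   reaching rule 4).
#' @export
marker_qc <- function(mm, min_genotyped = 0.75, alpha = 0.05) {
  if (!ncol(mm$geno)) stop2("zero offspring")
  markers <- rownames(mm$geno)
  removed <- data.frame(marker = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  ratio_p <- setNames(rep(NA_real_, length(markers)), markers)
  keep <- logical(length(markers))
  for (i in seq_along(markers)) {
    q <- mm$queen[[markers[i]]]
    qa <- strsplit(q, "/", fixed = TRUE)[[1]]
    if (length(qa) != 2 || qa[1] == qa[2]) {
      removed <- rbind(removed, data.frame(marker = markers[i],
                                           rule = "queen_not_heterozygous"))
      next
    }
    g <- mm$geno[i, ]
    typed <- !is.na(g)
    if (mean(typed) < min_genotyped) {
      removed <- rbind(removed, data.frame(marker = markers[i],
                                           rule = "undergenotyped"))
      next
    }
    alleles <- unique(c(qa, unlist(strsplit(g[typed], "/", fixed = TRUE))))
    if (length(alleles) > 2) {
      removed <- rbind(removed, data.frame(marker = markers[i],
                                           rule = "too_many_alleles"))
      next
    }
    het <- vapply(strsplit(g[typed], "/", fixed = TRUE),
                  function(a) a[1] != a[2], logical(1))
    p <- binom.test(sum(!het), length(het), 0.5)$p.value
    ratio_p[markers[i]] <- p
    if (p < alpha) {
      removed <- rbind(removed, data.frame(marker = markers[i],
                                           rule = "allele_ratio"))
      next
    }
    keep[i] <- TRUE
  }
  retained <- mm
  retained$queen <- mm$queen[keep]
  retained$geno <- mm$geno[keep, , drop = FALSE]
  if (!is.null(mm$info)) retained$info <- mm$info[keep, , drop = FALSE]
  if (!is.null(mm$truth)) retained$truth <- mm$truth[keep]
  list(retained = retained, removed = removed, ratio_p = ratio_p)
}

# Inheritance coding: 1 = heterozygous offspring (alternative maternal
# allele), 0 = homozygous (paternal-matching allele), NA = missing.
inheritance_coding <- function(mm) {
  code <- matrix(NA_integer_, nrow(mm$geno), ncol(mm$geno),
                 dimnames = dimnames(mm$geno))
  for (i in seq_len(nrow(mm$geno))) {
    g <- mm$geno[i, ]
    typed <- which(!is.na(g))
    het <- vapply(strsplit(g[typed], "/", fixed = TRUE),
                  function(a) a[1] != a[2], logical(1))
    code[i, typed] <- as.integer(het)
  }
  code
}

#' Double unknown-phase markers with mirrored phases
#'
#' The parental phase of each marker is unknown, so each marker is
#' duplicated: one copy with the observed inheritance coding, one with
#' the coding flipped. Grouping the doubled set yields mirrored linkage
#' groups over the same loci, deduplicated afterwards with
#' [dedup_groups()]. Applying the flip twice restores the original
#' coding.
#'
#' @param mm A `marker_matrix`.
#' @return Object of class `phased_markers`: `coding` (2k x n 0/1
#'   matrix, rows `<marker>|0` and `<marker>|1`), `locus` (underlying
#'   marker id per row).
#' @export
phase_double <- function(mm) {
  x <- inheritance_coding(mm)
  flipped <- 1L - x
  rownames(flipped) <- paste0(rownames(x), "|1")
  rownames(x) <- paste0(rownames(x), "|0")
  coding <- rbind(x, flipped)
  structure(list(coding = coding,
                 locus = sub("\\|[01]$", "", rownames(coding))),
            class = "phased_markers")
}

#' Deduplicate mirrored linkage groups
#'
#' Groups built from a phase-doubled marker set come in mirrored pairs
#' over identical underlying locus sets; one member of each pair is kept
#' (the one whose lexicographically first row name sorts first -
#' deterministic).
#'
#' @param groups List of character vectors of doubled-marker row names.
#' @param locus Named map row name -> underlying locus id (e.g.
#'   `setNames(pm$locus, rownames(pm$coding))`).
#' @return List of groups, one per distinct locus set.
#' @export
dedup_groups <- function(groups, locus) {
  if (!length(groups)) return(groups)
  key <- vapply(groups, function(g)
    paste(sort(unique(locus[g])), collapse = ","), character(1))
  first <- vapply(groups, function(g) sort(g)[1], character(1))
  keep <- unlist(lapply(split(seq_along(groups), key), function(idx)
    idx[order(first[idx])][1]))
  groups[sort(keep)]
}

#' Pairwise recombination fraction between coded markers
#' @param x,y 0/1 inheritance codings (NA = missing).
#' @return Fraction of informative offspring with differing coding, or
#'   `NA` when no offspring is informative for both.
#' @export
recombination_fraction <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!sum(ok)) return(NA_real_)
  mean(x[ok] != y[ok])
}

#' Group markers by recombination-fraction linkage
#'
#' Estimates all pairwise recombination fractions on the phase-doubled
#' coding and forms single-linkage groups (transitive closure) of pairs
#' with rf below `rf_max`; pairs with no informative offspring are never
#' linked. Mirrored groups are deduplicated; groups smaller than
#' `min_loci` underlying loci are reported separately.
#'
#' @param pm A `phased_markers` object (or a `marker_matrix`, which is
#'   phase-doubled first).
#' @param rf_max Linkage threshold (default 0.2, exclusive).
#' @param min_loci Minimum loci per reported group (default 3).
#' @return List: `groups` (lists of underlying locus ids), `small_groups`,
#'   `n_groups`, `rf` (matrix over doubled markers).
#' @export
linkage_groups <- function(pm, rf_max = 0.2, min_loci = 3) {
  if (inherits(pm, "marker_matrix")) pm <- phase_double(pm)
  x <- pm$coding
  m <- nrow(x)
  rf <- matrix(NA_real_, m, m, dimnames = list(rownames(x), rownames(x)))
  diag(rf) <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    rf[i, j] <- rf[j, i] <- recombination_fraction(x[i, ], x[j, ])
  }
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (!is.na(rf[i, j]) && rf[i, j] < rf_max) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  raw_groups <- lapply(split(rownames(x), roots), identity)
  locus_map <- setNames(pm$locus, rownames(pm$coding))
  groups <- dedup_groups(unname(raw_groups), locus_map)
  loci <- lapply(groups, function(g) sort(unique(locus_map[g])))
  big <- lengths(loci) >= min_loci
  list(groups = lapply(loci[big], unname),
       small_groups = lapply(loci[!big], unname),
       n_groups = sum(big), rf = rf)
}
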