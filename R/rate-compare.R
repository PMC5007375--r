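# The paired mutualist/generalist statistical framework: per-pair paired
# tests, the all-pairs consistency classifier, FDR control, the
# reverse-foreground filter for selection scans, 2x2 over-representation,
# and per-tissue expression contrasts.

#' Per-pair paired tests on a unit-by-species value table
#'
#' For each (mutualist, generalist) pair: a paired t-test and a Wilcoxon
#' signed-rank test over units complete for both members, plus the count
#' and fraction of units where the mutualist value exceeds the
#' generalist's (ties excluded from the sign counts). Tests are two-sided;
#' direction is read off the sign of the statistic.
#'
#' @param values Data frame with a `unit` column and one numeric column
#'   per species.
#' @param design A [pair_design()].
#' @return Data frame, one row per pair: `mutualist`, `generalist`, `n`,
#'   `t_stat`, `t_p`, `wilcox_stat`, `wilcox_p`, `n_greater`, `n_less`,
#'   `frac_greater`, `mean_diff`.
#' @export
paired_tests <- function(values, design = pair_design()) {
  check_ingroup_species(design, names(values), "value table")
  out <- lapply(seq_len(nrow(design$pairs)), function(i) {
    m <- design$pairs$mutualist[i]; g <- design$pairs$generalist[i]
    x <- values[[m]]; y <- values[[g]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) stop2("fewer than 2 complete units for pair ",
                             m, "/", g)
    tt <- t.test(x, y, paired = TRUE)
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    ng <- sum(x > y); nl <- sum(x < y)
    data.frame(mutualist = m, generalist = g, n = length(x),
               t_stat = unname(tt$statistic), t_p = tt$p.value,
               wilcox_stat = unname(wt$statistic), wilcox_p = wt$p.value,
               n_greater = ng, n_less = nl,
               frac_greater = if (ng + nl > 0) ng / (ng + nl) else NA_real_,
               mean_diff = mean(x - y), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify units by cross-pair consistency of rate differences
#'
#' A unit (gene or window) is `mutualist-faster` when the mutualist value
#' strictly exceeds the generalist value in every pair, `generalist-faster`
#' when it is strictly lower in every pair, and `inconsistent` otherwise
#' (any tie breaks consistency). Units missing any of the six ingroup
#' values are skipped.
#'
#' @param values Data frame with `unit` plus species columns.
#' @param design A [pair_design()].
#' @return List: `calls` (unit, per-pair differences, class), `counts`
#'   (named: mutualist_faster, generalist_faster, inconsistent),
#'   `n_evaluated`, `n_skipped`.
#' @export
classify_consistency <- function(values, design = pair_design()) {
  check_ingroup_species(design, names(values), "value table")
  sp <- ingroup_species(design)
  complete <- rowSums(is.na(values[, sp, drop = FALSE])) == 0L
  v <- values[complete, , drop = FALSE]
  diffs <- sapply(seq_len(nrow(design$pairs)), function(i)
    v[[design$pairs$mutualist[i]]] - v[[design$pairs$generalist[i]]])
  diffs <- matrix(diffs, nrow = nrow(v))
  colnames(diffs) <- paste0("d_", design$pairs$mutualist)
  class <- rep("inconsistent", nrow(v))
  class[rowSums(diffs > 0) == ncol(diffs)] <- "mutualist-faster"
  class[rowSums(diffs < 0) == ncol(diffs)] <- "generalist-faster"
  calls <- data.frame(unit = v$unit, diffs, class = class,
                      stringsAsFactors = FALSE)
  counts <- c(mutualist_faster = sum(class == "mutualist-faster"),
              generalist_faster = sum(class == "generalist-faster"),
              inconsistent = sum(class == "inconsistent"))
  list(calls = calls, counts = counts, n_evaluated = nrow(v),
       n_skipped = sum(!complete))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment; the rejection set at level `q` is every p-value
#' whose adjusted value is at most `q`.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q Target FDR (default 0.05).
#' @return List: `adjusted`, `rejected` (logical), `n_rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop2("p-values must be in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q, n_rejected = sum(adj <= q))
}

#' Drop hits that are also significant with the foreground reversed
#'
#' Selection-scan hygiene: genes called significant with the mutualist
#' lineages as foreground are re-tested with the generalist lineages as
#' foreground, and genes significant in both directions are discarded as
#' likely artifacts of generally high substitution rates.
#'
#' @param forward Character vector of ids significant in the forward scan.
#' @param reverse Ids significant in the reversed scan.
#' @return List: `retained`, `discarded`.
#' @export
reverse_foreground_filter <- function(forward, reverse) {
  discarded <- intersect(forward, reverse)
  list(retained = setdiff(forward, discarded), discarded = discarded)
}

#' Over-representation of a gene list in a hit set (2x2 Fisher test)
#'
#' @param hits_in_list Hits that are members of the list.
#' @param hits_total Total hits in the universe.
#' @param list_size Size of the list within the universe.
#' @param universe_size Size of the universe.
#' @return List: `odds_ratio` (0.5 added to each cell when any cell is 0,
#'   flagged by `continuity`), `p` (two-sided Fisher exact), `table`.
#' @export
enrichment_2x2 <- function(hits_in_list, hits_total, list_size,
                           universe_size) {
  a <- hits_in_list; b <- list_size - a
  cc <- hits_total - a; d <- universe_size - list_size - cc
  if (any(c(a, b, cc, d) < 0))
    stop2("inconsistent margins (negative cell count)")
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(c("hit", "non-hit"),
                                c("in-list", "background")))
  ft <- fisher.test(tab)
  continuity <- any(tab == 0)
  or <- if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  list(odds_ratio = or, p = ft$p.value, table = tab,
       continuity = continuity)
}

#' Per-tissue expression contrast between fast-evolving and other genes
#'
#' Each gene's expression profile is standardized to sum to one across
#' tissues (genes with an all-zero profile are excluded and counted),
#' then within each tissue the fast-evolving set is compared with the
#' comparison set by a Welch two-sample t-test, with BH correction across
#' tissues.
#'
#' @param mat Non-negative genes x tissues matrix with dimnames.
#' @param fast_ids Row names or indices of the fast-evolving set.
#' @param comparison_ids Rows to compare against (default: all others).
#' @param q FDR level for the significance flag (default 0.05).
#' @return List: `tests` (tissue, mean_diff, t, p, p_adj, significant),
#'   `n_excluded` (all-zero genes removed).
#' @export
expression_contrast <- function(mat, fast_ids, comparison_ids = NULL,
                                q = 0.05) {
  if (any(mat < 0)) stop2("expression matrix must be non-negative")
  if (is.numeric(fast_ids)) fast_ids <- rownames(mat)[fast_ids]
  rs <- rowSums(mat)
  n_excluded <- sum(rs == 0)
  keep <- rs > 0
  std <- mat[keep, , drop = FALSE] / rs[keep]
  fast <- intersect(fast_ids, rownames(std))
  comp <- if (is.null(comparison_ids)) setdiff(rownames(std), fast)
          else intersect(setdiff(comparison_ids, fast), rownames(std))
  if (length(fast) < 2 || length(comp) < 2)
    stop2("need at least two genes in each group")
  tests <- do.call(rbind, lapply(colnames(std), function(ti) {
    x <- std[fast, ti]; y <- std[comp, ti]
    tt <- t.test(x, y)  # Welch
    data.frame(tissue = ti, mean_diff = mean(x) - mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  fdr <- bh_fdr(tests$p, q)
  tests$p_adj <- fdr$adjusted
  tests$significant <- fdr$rejected
  list(tests = tests, n_excluded = n_excluded)
}
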