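# Standard nuclear genetic code tables and the Nei-Gojobori (1986)
# precomputations that the counting estimator relies on. All tables are
# built once per session and cached; stop codons (TAA, TAG, TGA) are
# excluded from the sense-codon state space throughout.

.cr_cache <- new.env(parent = emptyenv())

NUC_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' All 64 codons in fixed lexicographic order
#' @return Character vector of length 64.
#' @keywords internal
all_codons <- function() {
  if (is.null(.cr_cache$codons)) {
    g <- expand.grid(p3 = NUC_BASES, p2 = NUC_BASES, p1 = NUC_BASES,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    .cr_cache$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .cr_cache$codons
}

#' Sense codons of the standard nuclear genetic code
#' @return Character vector of length 61 (stop codons excluded).
#' @export
sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

#' The standard genetic code as a codon -> amino acid map
#' @return Named character vector over the 64 codons; stops are `"*"`.
#' @export
genetic_code <- function() {
  if (is.null(.cr_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .cr_cache$code <- setNames(as.character(gc[all_codons()]), all_codons())
  }
  .cr_cache$code
}

#' Split a nucleotide string into codons
#' @param seq Single character string, length a multiple of 3.
#' @return Character vector of codons (uppercased).
#' @export
split_codons <- function(seq) {
  if (!is_string(seq)) stop2("'seq' must be a single string")
  n <- nchar(seq)
  if (n %% 3L != 0L) stop2("sequence length ", n, " is not a multiple of 3")
  seq <- toupper(seq)
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Translate codons to amino acids
#'
#' Codons containing characters outside A/C/G/T (including N and gaps)
#' translate to `"X"`; stop codons translate to `"*"`.
#'
#' @param codons Character vector of codons.
#' @return Character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  aa <- unname(genetic_code()[toupper(codons)])
  aa[is.na(aa)] <- "X"
  aa
}

is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") & b2 %in% c("A", "G")) |
    (b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}

# Fractional synonymous site count per codon (NA for stops). For each of
# the three positions the fraction of possible single-base changes that are
# synonymous, with changes into stop codons removed from the denominator.
ng86_codon_sites <- function() {
  if (!is.null(.cr_cache$sites)) return(.cr_cache$sites)
  code <- genetic_code()
  codons <- all_codons()
  s <- rep(NA_real_, 64L)
  names(s) <- codons
  for (cd in setdiff(codons, STOP_CODONS)) {
    bases <- strsplit(cd, "")[[1]]
    tot <- 0
    for (pos in 1:3) {
      syn <- 0L; denom <- 0L
      for (b in setdiff(NUC_BASES, bases[pos])) {
        mut <- bases
        mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (code[mutc] == "*") next
        denom <- denom + 1L
        if (code[mutc] == code[cd]) syn <- syn + 1L
      }
      if (denom > 0L) tot <- tot + syn / denom
    }
    s[cd] <- tot
  }
  .cr_cache$sites <- s
  s
}

perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

#' Pathway-averaged substitution counts between two codons
#'
#' Enumerates every ordering of the single-base steps separating two sense
#' codons, discards orderings that pass through a stop codon, and averages
#' the synonymous/nonsynonymous step counts over the remaining pathways
#' with equal weights.
#'
#' @param codon1,codon2 Sense codons (strings of three bases).
#' @return List with `sd` (synonymous differences), `nd` (nonsynonymous
#'   differences) and `n_paths` (number of valid pathways; 0 when every
#'   pathway is blocked by a stop codon, in which case `sd`/`nd` are `NA`).
#' @export
ng86_pathways <- function(codon1, codon2) {
  code <- genetic_code()
  if (is.na(code[codon1]) || is.na(code[codon2]) ||
      code[codon1] == "*" || code[codon2] == "*")
    stop2("both codons must be sense codons")
  b1 <- strsplit(codon1, "")[[1]]
  b2 <- strsplit(codon2, "")[[1]]
  diffs <- which(b1 != b2)
  if (length(diffs) == 0L) return(list(sd = 0, nd = 0, n_paths = 1L))
  sd_tot <- 0; nd_tot <- 0; ok <- 0L
  for (ord in perms_of(diffs)) {
    cur <- b1; sd <- 0L; nd <- 0L; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b2[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (code[to] == "*") { blocked <- TRUE; break }
      if (code[from] == code[to]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (!blocked) { ok <- ok + 1L; sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd }
  }
  if (ok == 0L) return(list(sd = NA_real_, nd = NA_real_, n_paths = 0L))
  list(sd = sd_tot / ok, nd = nd_tot / ok, n_paths = ok)
}

# 64 x 64 lookup matrices of pathway-averaged Sd and Nd (NA outside the
# sense x sense block and for blocked pairs).
ng86_pair_tables <- function() {
  if (!is.null(.cr_cache$pair)) return(.cr_cache$pair)
  codons <- all_codons()
  n <- length(codons)
  sd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd <- sd
  sense <- setdiff(codons, STOP_CODONS)
  for (i in sense) {
    for (j in sense) {
      if (match(j, codons) < match(i, codons)) next
      pw <- ng86_pathways(i, j)
      sd[i, j] <- sd[j, i] <- pw$sd
      nd[i, j] <- nd[j, i] <- pw$nd
    }
  }
  .cr_cache$pair <- list(sd = sd, nd = nd)
  .cr_cache$pair
}

codon_index <- function(codons) match(toupper(codons), all_codons())
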