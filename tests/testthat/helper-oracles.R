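# Independent oracles, written deliberately in a different style from the
# package implementation so that agreement is informative.

# Recursive (depth-first) enumeration of mutational pathways between two
# codons, counting synonymous and nonsynonymous steps; pathways through
# stop codons are pruned. Returns averaged (sd, nd) or NULL when every
# pathway is blocked.
oracle_pathways <- function(c1, c2) {
  code <- convrates::genetic_code()
  walk <- function(cur, target) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(d)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (pos in d) {
      nb <- strsplit(cur, "")[[1]]
      nb[pos] <- strsplit(target, "")[[1]][pos]
      nxt <- paste(nb, collapse = "")
      if (code[[nxt]] == "*") next
      step <- if (code[[cur]] == code[[nxt]]) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (tail in walk(nxt, target))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- walk(c1, c2)
  if (!length(paths)) return(NULL)
  Reduce(`+`, paths) / length(paths)
}

# Synonymous site count of a codon by direct enumeration (independent of
# the cached table construction).
oracle_site_count <- function(codon) {
  code <- convrates::genetic_code()
  b <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; n <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      m <- b; m[pos] <- alt
      mc <- paste(m, collapse = "")
      if (code[[mc]] == "*") next
      n <- n + 1
      if (code[[mc]] == code[[codon]]) syn <- syn + 1
    }
    if (n > 0) total <- total + syn / n
  }
  total
}

# A tiny deterministic protein-alignment fixture builder.
protein_fixture <- function(cols, species) {
  # cols: list of named character vectors (species -> residue)
  seqs <- setNames(rep("", length(species)), species)
  for (col in cols) for (sp in species) seqs[sp] <- paste0(seqs[sp], col[[sp]])
  list(geneA = seqs)
}

default_species <- c("gracilis", "concolor", "pallidus", "flavicornis",
                     "PSW54", "dendroicus", "elongatus")
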