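# Substitution-process machinery shared by the codon and nucleotide
# simulators. Both processes are time-reversible continuous-time Markov
# chains; transition matrices are obtained by spectral decomposition of
# the symmetrized generator, which is numerically stable and exact up to
# floating point (no truncation of a matrix-exponential series).

# Codon generator in the Goldman-Yang style: off-diagonal rate to codon j
# is pi_j, multiplied by kappa for transitions and by omega for
# nonsynonymous changes; codon pairs differing at more than one position
# get rate 0, as do changes into stop codons (stops are outside the state
# space). The matrix is rescaled so the expected rate at stationarity is 1
# substitution/site, making branch lengths interpretable.
codon_generator <- function(kappa = 2, omega = 1, pi = NULL) {
  codons <- sense_codons()
  k <- length(codons)
  if (is.null(pi)) pi <- rep(1 / k, k)
  if (length(pi) != k || any(pi < 0)) stop2("'pi' must be 61 non-negative values")
  if (abs(sum(pi) - 1) > 1e-8) stop2("'pi' must sum to 1")
  code <- genetic_code()
  Q <- matrix(0, k, k, dimnames = list(codons, codons))
  bases <- strsplit(codons, "")
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      d <- which(bases[[i]] != bases[[j]])
      if (length(d) != 1L) next
      r <- pi[j]
      if (is_transition(bases[[i]][d], bases[[j]][d])) r <- r * kappa
      if (code[codons[i]] != code[codons[j]]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop2("degenerate rate matrix (all rates zero)")
  list(Q = Q / scale, pi = pi, states = codons)
}

# Nucleotide generator: Jukes-Cantor by default, HKY when kappa and/or a
# non-uniform pi is supplied. Same mean-rate-1 scaling.
nucleotide_generator <- function(kappa = 1, pi = rep(0.25, 4)) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop2("'pi' must be 4 non-negative values summing to 1")
  Q <- matrix(0, 4, 4, dimnames = list(NUC_BASES, NUC_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    r <- pi[j]
    if (is_transition(NUC_BASES[i], NUC_BASES[j])) r <- r * kappa
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  list(Q = Q / scale, pi = pi, states = NUC_BASES)
}

# P(t) = exp(Qt) for a reversible generator, via the symmetrization
# D^{1/2} Q D^{-1/2}. Rows are clipped at 0 and renormalized to absorb
# rounding at the 1e-12 level.
transition_matrix <- function(gen, t) {
  if (t < 0) stop2("branch length must be >= 0")
  k <- length(gen$pi)
  if (t == 0) return(diag(k))
  supp <- gen$pi > 0
  if (!all(supp)) {
    # zero-frequency states are unreachable (rates into them are 0) and,
    # started from the stationary root draw, never occupied: embed the
    # support-restricted matrix in an identity
    P <- diag(k)
    P[supp, supp] <- transition_matrix(
      list(Q = gen$Q[supp, supp, drop = FALSE], pi = gen$pi[supp]), t)
    return(P)
  }
  sq <- sqrt(gen$pi)
  B <- (sq * gen$Q) %*% diag(1 / sq)  # diag(sq) %*% Q %*% diag(1/sq)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  P <- diag(1 / sq) %*% es$vectors %*% (exp(es$values * t) * t(es$vectors)) %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Draw child states given parent states and a transition matrix.
evolve_states <- function(states, P) {
  k <- nrow(P)
  out <- integer(length(states))
  for (s in seq_len(k)) {
    idx <- which(states == s)
    if (length(idx)) out[idx] <- sample.int(k, length(idx), replace = TRUE,
                                            prob = P[s, ])
  }
  out
}

# Simulate site-independent evolution of n_sites characters along the
# tree. P_list holds one transition matrix per edge (rows of phy$edge).
# Returns integer state vectors at the tips plus the number of sites whose
# state differs across each edge (the realized, observable change count).
simulate_along_tree <- function(phy, n_sites, root_probs, P_list) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  tips <- vector("list", ntip)
  edge_changes <- integer(nrow(phy$edge))
  recurse <- function(node, states) {
    for (e in children[[as.character(node)]]) {
      child <- phy$edge[e, 2]
      cs <- evolve_states(states, P_list[[e]])
      edge_changes[e] <<- sum(cs != states)
      if (child <= ntip) tips[[child]] <<- cs else recurse(child, cs)
    }
  }
  root_states <- sample.int(length(root_probs), n_sites, replace = TRUE,
                            prob = root_probs)
  recurse(root, root_states)
  names(tips) <- phy$tip.label
  list(tip_states = tips, edge_changes = edge_changes,
       root_states = root_states)
}

# Per-edge transition matrices for a sim_tree. For the codon process omega
# can vary by edge, so a generator is built per distinct omega value.
codon_P_list <- function(st, kappa, pi) {
  lens <- effective_lengths(st)
  gens <- lapply(unique(st$omega), function(w) codon_generator(kappa, w, pi))
  names(gens) <- as.character(unique(st$omega))
  lapply(seq_along(lens), function(e)
    transition_matrix(gens[[as.character(st$omega[e])]], lens[e]))
}

nucleotide_P_list <- function(st, kappa, pi) {
  gen <- nucleotide_generator(kappa, pi)
  lens <- effective_lengths(st)
  lapply(lens, function(t) transition_matrix(gen, t))
}
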