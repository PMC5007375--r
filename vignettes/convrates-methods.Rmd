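---
title: "Methods: lineage-paired rates of molecular evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-paired rates of molecular evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convrates)
```

## The comparative question

`convrates` implements the comparative-genomic framework used to ask whether
lineages that have independently evolved the same life history — here, three
clades of obligate plant-nesting (mutualist) ants, each paired with its most
closely related free-living (generalist) congener — also show convergent
shifts in their rates of molecular evolution. The design is a seven-taxon
whole-genome alignment in the coordinates of a generalist reference species:
the outgroup plus three (mutualist, generalist) sister pairs. Every statistic
in the package is organized around that pairing, because comparing each
mutualist only with its closest generalist relative cancels shared
evolutionary history; pooled mutualist-versus-generalist comparisons would
not, and indeed individual mutualists need not be faster than every
generalist for the paired signal to be real.

Three layers of evidence are computed:

1. **Genome-wide distances.** Sliding-window p-distances of every ingroup
   species from the reference, compared within pairs by paired t-tests and
   Wilcoxon signed-rank tests, plus the count of windows where the mutualist
   is consistently farther.
2. **Coding rates.** Per-gene dN and dS of every species against the
   reference by the Nei–Gojobori (1986) counting method, aggregated per
   species both as means of per-gene ratios and as ratios of sums (robust to
   outlying loci), and classified per gene by cross-pair consistency.
3. **Convergent substitutions.** A scan of the translated alignments for
   columns where two or more foreground lineages share a residue absent from
   all other species.

Around these sit the supporting screens the full study needed: codon-usage
bias (Wright's ENC, GC3, usage proportions), depth-based copy-number calls
with a life-history consistency rule, NuMt (nuclear-mitochondrial insertion)
counting from homology hits, transposable-element candidate filtering,
neutral-locus sampling for demographic inference, and marker QC plus a simple
linkage grouping for a single-family mapping population.

## The counting estimator of dN/dS

The package deliberately uses the Nei–Gojobori counting estimator rather than
a maximum-likelihood codon model: it is closed-form, fast enough to run
genome-wide at desk scale, and exactly testable. For each codon, each
position contributes the fraction of its three possible single-base changes
that are synonymous, with changes into stop codons removed from the
denominator, so `S + N = 3` per codon (`ng86_site_counts()`). Differences
between codons separated at more than one position are averaged over all
orderings of single-base steps, discarding orderings that pass through a stop
codon (`ng86_pathways()`); the proportions `pS = Sd/S`, `pN = Nd/N` (site
counts averaged between the two sequences) receive the Jukes–Cantor
correction `d = -3/4 log(1 - 4p/3)`, undefined at `p >= 3/4` and flagged.
Codons containing unknown bases in either sequence are skipped and counted.
The test suite checks the pathway averaging against an independent recursive
enumerator on 1,000 random codon pairs and checks that a neutral simulation
(omega = 1, 50,000 codons) is estimated in [0.9, 1.1].

Counting methods are biased downward for dN/dS under strong selection at
high divergence; in the < 5% divergence regime this package targets the bias
is small (the omega = 0.2 simulations are estimated near 0.18), and because
every species is estimated with the same method, the *paired* comparisons
that carry the scientific claims are unaffected in direction.

Aggregation conventions: per-gene ratios are undefined when dS = 0 and such
genes are excluded from the mean-of-ratios (their dN still enters the
sum-of-dN over sum-of-dS aggregate); genes with ratio >= 10 are excluded from
ratio statistics as likely assembly or annotation artifacts. Both aggregates
are always reported side by side so outlier sensitivity is visible.

## Windows, distances and trees

Windows are built at starts `0, step, 2*step, ...` and must fit entirely on
the scaffold; there is no shorter trailing window, so all window statistics
are equal-width. Defaults are 25 kb windows with 5 kb steps; a window is
valid only when every species has known sequence over at least half of it.
The p-distance uses the pairwise-complete convention: only sites where both
sequences are known enter the denominator. IUPAC ambiguity codes (from
heterozygous consensus calls) count as known, and two symbols differ only
when their allele sets are disjoint, so a heterozygous A/G against a
reference A is not a difference. The alternative — masking heterozygous
sites — is available at the consensus-calling step (`het = "mask"`).

Per-window trees use neighbor joining on all-pairs p-distances (exact on
additive inputs, verified against the four-point and three-point closed
forms), with negative branch estimates clamped to zero. The topology census
canonicalizes each tree by re-rooting at the alphabetically first leaf and
sorting children recursively, so rotation and rooting never split a
topology class; the census also counts trees containing a focal split, e.g.
a mutualist-only clade, whose absence across windows argues against
parallel inheritance of mutualism-associated haplotypes.

## The paired statistical framework

`paired_tests()` reports, per pair, the paired t-test, the Wilcoxon
signed-rank test and the sign counts (ties excluded). Tests are two-sided;
directional claims are read off the sign of the statistic, which is the
conservative reading given that the original direction of each test is not
stated. `classify_consistency()` calls a unit mutualist-faster only when the
mutualist value strictly exceeds the generalist value in *all* pairs; any
tie breaks consistency. Under an exchangeable null each directional class
therefore occupies (1/2)^3 = 12.5% of units, a calibration the test suite
checks with a binomial 99% band at 2,000 simulated genes. FDR control is
Benjamini–Hochberg; the reverse-foreground filter discards genes that a
selection scan flags in both the forward and the reversed foreground
configuration, since double hits typically reflect generally high rates
rather than lineage-specific selection.

Expression contrasts standardize each gene's profile to sum to one across
tissues, then compare the fast-evolving set against all other genes within
each tissue. The Welch (unequal-variance) t-test is used — the source
analysis says only "t-tests", and equal variances between a small fast set
and thousands of background genes is not defensible. Note that
standardization couples tissues: concentrating expression in one tissue
necessarily depresses a fast set's standardized share elsewhere, so
secondary negative contrasts in other tissues are expected side effects, not
independent signals.

## The convergence scan

A column is convergent for a foreground subset F' (at least two species)
when all of F' share residue `a` and no species outside F' carries `a`
("shared-exclusive"). The stricter mode additionally requires all non-F'
species to share a single residue `b != a` — the pattern every published
site-level example of this analysis shows — but the genome-wide counting
rule behind the published totals is not spelled out, so both modes are
provided and reported; strict counts are necessarily a subset of
shared-exclusive counts, which the tests assert. Columns containing any gap
or unknown residue are excluded from the sites-examined denominator and
tallied. Positions are reported 1-based within the translated gene, matching
the "site 433" convention of the literature. The scan is symmetric by
construction: on exchangeable simulated data, swapping the foreground and
background species sets yields statistically indistinguishable counts
(checked with a two-sided binomial comparison).

## What the synthetic data emulate

The generators produce data with the statistical structure the analysis
assumes, plus truth tables, so every stage can be tested for parameter
recovery rather than merely for running.

**Tree.** The default topology places the three mutualists in three separate
clades — `(outgroup,(concolor,((dendroicus,elongatus),(pallidus,(flavicornis,
PSW54)))))` — with the ingroup ultrametric at root-to-tip depth 0.025
expected substitutions/site and the outgroup at the same depth, i.e. about
5% divergence between any ingroup species and the reference. Ultrametricity
is a deliberate choice: at rate multiplier rho = 1 the members of each pair
sit at identical expected distance from the reference, so the null
calibration of the paired tests and the consistency classifier is exact by
construction, and any rate shift is injected purely through per-branch
multipliers (rho = 1.5 on the three mutualist terminals is the standard
recovery condition). The exact placement of the first mutualist clade
relative to its generalist partner is configurable via Newick, since the
published phylogeny leaves some freedom there.

**Codon process.** Goldman–Yang-style: off-diagonal rate to codon j is
`pi_j`, times kappa for transitions, times the branch's omega for
nonsynonymous changes; multi-nucleotide changes are disallowed; stop codons
(TAA/TAG/TGA, standard nuclear code) are outside the state space, so
simulated coding sequences never contain internal stops. The generator is
rescaled to one expected substitution per site at stationarity, making
branch lengths interpretable, and transition matrices come from the spectral
decomposition of the symmetrized generator (exact; no series truncation).
Defaults: kappa = 2, omega = 0.2 (a typical genome-wide level of purifying
selection, matching sum-based dN/dS near 0.2), uniform codon frequencies.
Sites evolve independently; the truth table records per-edge changed-site
counts — the observable state changes, since under matrix-exponential
sampling no event-level trajectory exists (the contract is distributional
equivalence with an event-level simulator).

**Planted convergent sites** are imposed after simulation: at each chosen
column, every foreground leaf is overwritten with a codon for a residue that
no other species carries at that column, and the site is recorded. This
guarantees a known-positive set for the scanner's recall test (which must be
and is 100%).

**Noncoding process.** Jukes–Cantor by default (HKY via kappa/pi), same
scaling; realized divergence follows `p = 3/4 (1 - exp(-4t/3))`, which the
tests check in closed form. Runs of N can be injected to exercise the window
validity rules.

**Depth, mapping family, expression.** Read depth is Poisson with mean
`lambda * CN / 2` (CN = 2 baseline, lambda = 30 by default, matching typical
resequencing depth). The mapping family is a heterozygous queen with a
haploid father: each offspring's genotype collapses to which maternal allele
it inherited (homozygous = paternal-matching), maternal gametes recombine by
the Haldane map function, and chromosomes assort independently. The
expression matrix draws per-gene, per-tissue gamma mass with 29 tissues (the
tissue count of the fly expression compendium this contrast was designed
around), multiplying the head-tissue mass of designated fast genes by
`1 + head_shift` so that `head_shift = 0` is an exact null.

What the synthetic data do **not** emulate: indels and alignment error
(gaps only arise where injected), recombination and linked selection within
scaffolds, composition heterogeneity along the genome, annotation error
beyond planted premature stops, read-level sequencing noise, and genotyping
error in the mapping family. Passing recovery tests therefore demonstrates
the correctness of the estimators and decision rules under their assumed
models, not robustness to the full messiness of real assemblies; the QC
rules (coverage-based consensus, missingness thresholds, stop masking,
ratio filters) are the mechanisms the pipeline relies on to approach those
assumptions on real data.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) is
  converted at the boundary. BED input needs no conversion.
- `gene_qc` computes missingness before stop-masking (so masking cannot fail
  a gene), masks the stop-bearing codon column in every species to keep the
  alignment rectangular, and is idempotent. Genes of exactly 300 codons pass
  the default length rule; 299 fail.
- Wright's ENC uses family classes {2-fold x9, Ile as the 3-fold, 4-fold x5,
  6-fold x3 (Leu/Ser/Arg)} plus the constant 2 for Met and Trp. Families
  with fewer than two counted codons or non-positive homozygosity are
  unusable; a class with no usable family is imputed by the mean of the
  observed class means; results are capped at 61. Uniform usage gives
  exactly 61, one-codon-per-amino-acid gives exactly 20.
- Correlations between codon bias and rates are Spearman (the source does
  not name a coefficient; ranks are robust to the ENC scale).
- The Wilcoxon tests use the normal approximation (`exact = FALSE`) since
  zero differences and ties occur in rate tables.
- p-distances with an empty denominator, saturated Jukes–Cantor inputs,
  fully masked copy-number regions and marker pairs with no informative
  offspring all return flagged `NA` rather than failing.
- Every simulator requires an explicit integer seed and is byte-reproducible
  given it; nothing seeds implicitly.

## Problem sizes used in the checks

The recovery suites run at deliberate desk scale: 50,000 codons for the
neutral dN/dS check; 20 scaffolds of 520 kb (≈2,000 overlapping 25 kb
windows) and 200 genes of 300 codons for the rho = 1.5 recovery; 2,000 genes
for the null calibration plus 20 seeds of 200 non-overlapping 5 kb windows
for p-value uniformity (overlapping windows are serially correlated, which
is fine for detecting a shift but would invalidate a uniformity check);
three 70 cM chromosomes with 5 cM marker spacing and 48 offspring, over 20
seeds, for linkage recovery. The published genome-scale numbers (millions of
sites, tens of thousands of windows) derive from the real seven-genome
alignment and are not reproducible from synthetic data; what is asserted at
desk scale is correctness of the arithmetic on printed count pairs and
recovery of planted truth.

## Known limitations

- The counting dN/dS estimator is not a substitute for likelihood models
  when absolute omega or branch-site inference is the goal; this package
  consumes such results (significance sets) rather than producing them.
- The convergence scan does not reconstruct ancestral states, so it cannot
  distinguish convergent substitution from shared ancestral polymorphism;
  the window-topology census is the coarse control for that.
- The linkage grouping orders nothing within groups and estimates no map
  distances; it is a grouping stand-in, not a mapper.
- The Gblocks-style column filter is a simple gap rule, intentionally
  cruder than entropy-based block selection; it can be disabled.
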