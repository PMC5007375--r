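# The comparative skeleton: an outgroup/reference species and an ordered
# list of (mutualist, generalist) sister-pair labels. The defaults mirror
# the seven-taxon ant system the pipeline was designed around: three
# obligate plant-nesting (mutualist) lineages each paired with its most
# closely related free-living (generalist) congener, all compared against
# a generalist outgroup reference.

DEFAULT_REFERENCE <- "gracilis"
DEFAULT_PAIRS <- data.frame(
  mutualist  = c("concolor", "flavicornis", "dendroicus"),
  generalist = c("pallidus", "PSW54", "elongatus"),
  stringsAsFactors = FALSE
)

#' Define a lineage-pair comparison design
#'
#' @param reference Label of the outgroup/reference species against which
#'   distances and substitution rates are measured.
#' @param pairs Data frame with columns `mutualist` and `generalist`; one
#'   row per independently evolved sister pair.
#' @return Object of class `pair_design`.
#' @examples
#' pair_design()
#' @export
pair_design <- function(reference = DEFAULT_REFERENCE, pairs = DEFAULT_PAIRS) {
  if (!is_string(reference)) stop2("'reference' must be a single species label")
  if (!is.data.frame(pairs) || !all(c("mutualist", "generalist") %in% names(pairs)))
    stop2("'pairs' needs columns 'mutualist' and 'generalist'")
  labels <- c(reference, pairs$mutualist, pairs$generalist)
  if (anyDuplicated(labels)) stop2("species labels in the design must be distinct")
  structure(list(reference = reference,
                 pairs = pairs[, c("mutualist", "generalist")]),
            class = "pair_design")
}

#' @export
print.pair_design <- function(x, ...) {
  cat("Lineage-pair design; reference:", x$reference, "\n")
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  pair %d: %s (mutualist) vs %s (generalist)\n",
                i, x$pairs$mutualist[i], x$pairs$generalist[i]))
  invisible(x)
}

design_species <- function(design) {
  c(design$reference, design$pairs$mutualist, design$pairs$generalist)
}

ingroup_species <- function(design) {
  c(design$pairs$mutualist, design$pairs$generalist)
}

check_design_species <- function(design, available, where = "data") {
  missing <- setdiff(design_species(design), available)
  if (length(missing))
    stop2("design species absent from ", where, ": ",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}

check_ingroup_species <- function(design, available, where = "data") {
  missing <- setdiff(ingroup_species(design), available)
  if (length(missing))
    stop2("design species absent from ", where, ": ",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}
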