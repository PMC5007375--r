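#' @keywords internal
"_PACKAGE"

#' @importFrom stats binom.test cor.test fisher.test median p.adjust rgamma
#'   rpois runif t.test wilcox.test setNames sd
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Report a count as a percentage at printed precision
#'
#' Computes `100 * numerator / denominator` rounded to a fixed number of
#' significant digits, the convention used when quoting genome-scale
#' proportions (for example "4,283 of 5,906,079 sites (0.073%)").
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param sig Significant digits to keep (default 2).
#' @return Numeric percentage.
#' @examples
#' format_percent(4283, 5906079)  # 0.073
#' @export
format_percent <- function(numerator, denominator, sig = 2) {
  if (any(denominator <= 0)) stop2("denominator must be positive")
  if (any(numerator < 0)) stop2("numerator must be non-negative")
  signif(100 * numerator / denominator, sig)
}

# Seed handling: every stochastic entry point calls this once.
set_seed_strict <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop2("a single integer 'seed' is required for reproducibility")
  set.seed(as.integer(seed))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
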