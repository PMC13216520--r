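#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats prcomp kmeans wilcox.test fisher.test chisq.test p.adjust
#'   cor.test glm binomial coef vcov qnorm qt pnorm rnorm rpois rbeta runif
#'   median sd var complete.cases setNames quantile
#' @importFrom utils head tail
NULL

#' The ten canonical cancer hallmarks
#'
#' Fixed vocabulary of hallmark names used throughout the package. Gene-to-
#' hallmark maps and cohort configurations must draw hallmark names from this
#' list (order is conventional, not meaningful).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' canonical_hallmarks()
canonical_hallmarks <- function() {
  c(
    "genome_instability",
    "proliferative_signaling",
    "growth_suppressor_evasion",
    "apoptosis_resistance",
    "replicative_immortality",
    "angiogenesis",
    "invasion_metastasis",
    "metabolic_reprogramming",
    "immune_evasion",
    "inflammation"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# set.seed scoped to a block so callers' RNG state is untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# average ranks, descending (1 = largest); NA kept NA
rank_desc <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- rank(-x[ok], ties.method = "average")
  out
}

assert_probs <- function(p, what = "p-values") {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort(paste0(what, " must lie in [0, 1] and contain no NA"))
  }
  invisible(p)
}
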