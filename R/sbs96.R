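#' SBS96 channel names in canonical order
#'
#' The 96 single-base-substitution channels: six pyrimidine-referenced
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each combined with the
#' 16 possible flanking-base contexts. Ordering follows the COSMIC convention:
#' the C>A block first, flanks alphabetical (5' base varying slowest).
#'
#' @return Character vector of 96 channel names like `"A[C>A]A"`.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  subs <- substitution_classes()
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(DNA_BASES, DNA_BASES, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }), use.names = FALSE)
}

#' The six pyrimidine-referenced substitution classes
#'
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Classify single-base substitutions into SBS96 channels
#'
#' Assigns each substitution to one of the 96 trinucleotide-context channels.
#' Purine reference alleles are reverse-complemented (together with the
#' alternate allele and the context) so every channel is expressed relative to
#' the pyrimidine strand. Insertions, deletions and complex variants are
#' rejected, as are records whose context does not carry the reference base in
#' the middle position.
#'
#' @param mutations Data frame with columns `ref`, `alt`, `context3`
#'   (three-base plus-strand context centred on the mutated base). Extra
#'   columns are carried through.
#' @return The input with two added columns: `channel` (the SBS96 channel, or
#'   `NA` for rejected records) and `reject_reason` (`NA`, `"indel_or_complex"`,
#'   `"missing_context"` or `"context_mismatch"`).
#' @export
#' @examples
#' classify_sbs96(tibble::tibble(ref = c("C", "G"), alt = c("A", "T"),
#'                               context3 = c("ACA", "TGT")))
classify_sbs96 <- function(mutations) {
  ref <- toupper(mutations$ref)
  alt <- toupper(mutations$alt)
  ctx <- toupper(mutations$context3 %||% rep(NA_character_, nrow(mutations)))

  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  has_ctx <- !is.na(ctx) & nchar(ctx) == 3
  ctx_ok <- has_ctx & substr(ctx, 2, 2) == ref

  reason <- rep(NA_character_, nrow(mutations))
  reason[!snv] <- "indel_or_complex"
  reason[snv & !has_ctx] <- "missing_context"
  reason[snv & has_ctx & !ctx_ok] <- "context_mismatch"

  ok <- snv & ctx_ok
  channel <- rep(NA_character_, nrow(mutations))
  if (any(ok)) {
    r <- ref[ok]; a <- alt[ok]; c3 <- ctx[ok]
    pur <- r %in% c("A", "G")
    if (any(pur)) {
      r[pur] <- chartr("ACGT", "TGCA", r[pur])
      a[pur] <- chartr("ACGT", "TGCA", a[pur])
      c3[pur] <- revcomp(c3[pur])
    }
    channel[ok] <- paste0(
      substr(c3, 1, 1), "[", r, ">", a, "]", substr(c3, 3, 3)
    )
  }
  mutations$channel <- channel
  mutations$reject_reason <- reason
  mutations
}

#' Build per-sample SBS96 mutation spectra
#'
#' Counts classified substitutions per sample over the 96 channels. Rejected
#' records (indels, complex variants, missing or inconsistent contexts) are
#' excluded and tallied per reason.
#'
#' @param mutations Data frame of mutation records with `sample_id`, `ref`,
#'   `alt`, `context3`.
#' @return A tibble with one row per sample: `sample_id`, `total` (classified
#'   SNVs), and one integer column per channel. The per-reason rejection tally
#'   is attached as attribute `"rejections"`.
#' @export
build_spectra <- function(mutations) {
  channels <- sbs96_channels()
  cls <- classify_sbs96(mutations)
  rej <- table(cls$reject_reason)
  kept <- cls[!is.na(cls$channel), , drop = FALSE]

  samples <- unique(mutations$sample_id)
  counts <- matrix(0L, nrow = length(samples), ncol = 96,
                   dimnames = list(samples, channels))
  if (nrow(kept) > 0) {
    tab <- table(factor(kept$sample_id, levels = samples),
                 factor(kept$channel, levels = channels))
    counts <- matrix(as.integer(tab), nrow = length(samples),
                     dimnames = list(samples, channels))
  }
  out <- tibble::as_tibble(counts)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = samples, total = as.integer(rowSums(counts))),
    out
  )
  attr(out, "rejections") <- as.list(rej)
  out
}

#' Filter spectra by minimum mutation count
#'
#' Samples with fewer classified substitutions than `threshold` are excluded;
#' signature refitting is unreliable below about 50 mutations.
#'
#' @param spectra Tibble from [build_spectra()].
#' @param threshold Minimum total count to retain a sample (default 50).
#' @return List with `retained` (filtered spectra tibble) and `excluded`
#'   (character vector of dropped sample ids).
#' @export
apply_min_mutation_filter <- function(spectra, threshold = 50) {
  stopifnot(threshold >= 1)
  drop <- spectra$total < threshold
  if (all(drop) && nrow(spectra) > 0) {
    warn(sprintf("all %d samples fall below the %d-mutation threshold",
                 nrow(spectra), threshold))
  }
  list(
    retained = spectra[!drop, , drop = FALSE],
    excluded = spectra$sample_id[drop]
  )
}

#' The 48 copy-number classification channels
#'
#' Channel names of the standard 48-channel copy-number classification:
#' segments stratified by heterozygosity state (homozygous deletion, loss of
#' heterozygosity, heterozygous), total copy number, and segment size.
#' Homozygous deletions use three size bins; LOH (total CN 1, 2, 3-4, 5-8,
#' 9+) and heterozygous segments (2, 3-4, 5-8, 9+) use five, giving
#' 3 + 25 + 20 = 48 channels. Used here only to validate the dimension of a
#' supplied CN catalog; CN signature extraction itself is out of scope
#' (exposures are consumed as input).
#'
#' @return Character vector of 48 channel names like `"2:het:>40Mb"`.
#' @export
cn48_channels <- function() {
  homdel <- paste0("0:homdel:", c("0-100kb", "100kb-1Mb", ">1Mb"))
  sizes <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
  loh <- as.vector(outer(c("1", "2", "3-4", "5-8", "9+"), sizes,
                         function(cn, s) paste0(cn, ":LOH:", s)))
  het <- as.vector(outer(c("2", "3-4", "5-8", "9+"), sizes,
                         function(cn, s) paste0(cn, ":het:", s)))
  c(homdel, loh, het)
}

#' Validate a CN signature catalog's channel dimension
#'
#' Checks that a supplied copy-number signature catalog has exactly 48
#' channel rows and nonnegative entries.
#'
#' @param catalog Data frame whose first column names the CN channels.
#' @return The catalog, invisibly; errors on dimension or sign violations.
#' @export
validate_cn_catalog <- function(catalog) {
  if (nrow(catalog) != 48) {
    abort(sprintf("CN catalog must have 48 channel rows, found %d", nrow(catalog)))
  }
  vals <- as.matrix(catalog[, -1, drop = FALSE])
  if (any(is.na(vals)) || any(vals < 0)) {
    abort("CN catalog entries must be nonnegative and non-missing")
  }
  invisible(catalog)
}

# spectrum tibble row -> named 96-vector of counts
spectrum_counts <- function(spectra, i) {
  channels <- sbs96_channels()
  v <- as.numeric(spectra[i, channels])
  names(v) <- channels
  v
}
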