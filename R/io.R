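#' Read a MAF-like mutation table
#'
#' Reads a tab-delimited somatic mutation table (a thin subset of the MAF
#' columns: sample, gene, 1-based position, alleles, VAF, optional
#' trinucleotide context). `"."`, `"NA"` and blanks are treated as missing.
#'
#' @param path Path to a tab-delimited file with a header.
#' @param strict If `TRUE`, rows with VAF outside \[0, 1\] (or missing) are an
#'   error; if `FALSE` they are dropped with a message reporting the count.
#' @param col_map Optional named character vector remapping file headers to the
#'   canonical names, e.g. `c(Tumor_Sample_Barcode = "sample_id")`.
#' @return Tibble with columns `sample_id`, `gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `vaf`, `context3` (NA when absent). Number of dropped rows is
#'   attached as attribute `"n_dropped"`.
#' @export
read_mutation_table <- function(path, strict = TRUE, col_map = NULL) {
  df <- read_tsv_checked(path)
  if (!is.null(col_map)) {
    hit <- names(col_map)[names(col_map) %in% names(df)]
    names(df)[match(hit, names(df))] <- unname(col_map[hit])
  }
  required <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "vaf")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("mutation table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"context3" %in% names(df)) df$context3 <- NA_character_

  df$pos <- as.integer(df$pos)
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  df$context3 <- toupper(as.character(df$context3))
  df$context3[df$context3 %in% c("", ".", "NA")] <- NA_character_

  bad <- is.na(df$vaf) | df$vaf < 0 | df$vaf > 1
  if (any(bad)) {
    if (strict) {
      abort(sprintf("%d row(s) have VAF outside [0, 1]; use strict = FALSE to drop them",
                    sum(bad)))
    }
    inform(sprintf("dropped %d row(s) with VAF outside [0, 1]", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  out <- tibble::as_tibble(df[, c(required, "context3")])
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Read a gene-to-hallmark map
#'
#' Tab-delimited file with columns `gene` and `hallmark`; a gene may appear on
#' several rows (one per hallmark). Hallmark names must come from
#' [canonical_hallmarks()].
#'
#' @param path Path to the map file.
#' @param hallmarks Allowed hallmark vocabulary.
#' @return Tibble with columns `gene`, `hallmark` (one row per assignment).
#' @export
read_hallmark_map <- function(path, hallmarks = canonical_hallmarks()) {
  df <- read_tsv_checked(path)
  missing <- setdiff(c("gene", "hallmark"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("hallmark map is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(df$hallmark), hallmarks)
  if (length(unknown) > 0) {
    abort(sprintf("unknown hallmark name(s): %s", paste(unknown, collapse = ", ")))
  }
  dplyr::distinct(tibble::as_tibble(df[, c("gene", "hallmark")]))
}

#' Read a reference SBS signature catalog
#'
#' Reads a COSMIC-style catalog: one row per SBS96 channel (first column the
#' channel name, e.g. `"A[C>A]A"`), one column per signature. Rows are
#' reordered into the canonical channel order and each signature column is
#' renormalized to sum to one when its sum is within `1e-3` of one.
#'
#' @param path Path to a tab-delimited catalog file.
#' @return Tibble with column `channel` (96 rows, canonical order) followed by
#'   one numeric column per signature, each summing to 1.
#' @export
read_signature_catalog <- function(path) {
  df <- read_tsv_checked(path)
  names(df)[1] <- "channel"
  if (nrow(df) != 96) {
    abort(sprintf("signature catalog must have 96 channel rows, found %d", nrow(df)))
  }
  channels <- sbs96_channels()
  if (!setequal(df$channel, channels)) {
    abort("signature catalog channel names do not match the SBS96 channel set")
  }
  df <- df[match(channels, df$channel), , drop = FALSE]
  sigs <- setdiff(names(df), "channel")
  if (length(sigs) == 0) abort("signature catalog contains no signature columns")
  for (s in sigs) {
    v <- as.numeric(df[[s]])
    if (any(is.na(v)) || any(v < 0)) {
      abort(sprintf("signature '%s' has negative or missing entries", s))
    }
    tot <- sum(v)
    if (abs(tot - 1) > 1e-3) {
      abort(sprintf("signature '%s' sums to %.6f, outside 1 +/- 1e-3", s, tot))
    }
    df[[s]] <- v / tot
  }
  tibble::as_tibble(df)
}

#' Read a per-sample signature exposure matrix
#'
#' Tab-delimited matrix: first column `sample_id`, remaining columns
#' nonnegative exposures (one per signature, e.g. copy-number signatures).
#'
#' @param path Path to the file.
#' @param kind `"CN"` or `"SBS"`, recorded as attribute `"kind"`.
#' @return Tibble of exposures; attribute `"kind"` carries the signature type.
#' @export
read_exposure_matrix <- function(path, kind = c("CN", "SBS")) {
  kind <- match.arg(kind)
  df <- read_tsv_checked(path)
  names(df)[1] <- "sample_id"
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    abort(sprintf("duplicated sample id(s) in exposure matrix: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  sigs <- setdiff(names(df), "sample_id")
  if (length(sigs) == 0) abort("exposure matrix has no signature columns")
  for (s in sigs) {
    df[[s]] <- suppressWarnings(as.numeric(df[[s]]))
    if (any(df[[s]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative exposure in column '%s'", s))
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "kind") <- kind
  out
}

#' Read a per-patient feature table
#'
#' Tab-delimited table: first column `sample_id`, remaining columns numeric
#' features (immune cell fractions, stemness/EMT scores, ...). Blanks, `"."`
#' and `"NA"` parse to missing, never to zero.
#'
#' @param path Path to the file.
#' @param strict If `TRUE`, a non-numeric cell is an error; otherwise parsed
#'   to `NA` with a message.
#' @return Tibble with unique `sample_id` and numeric feature columns.
#' @export
read_feature_table <- function(path, strict = FALSE) {
  df <- read_tsv_checked(path)
  names(df)[1] <- "sample_id"
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    abort(sprintf("duplicated sample id(s) in feature table: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  for (f in setdiff(names(df), "sample_id")) {
    raw <- as.character(df[[f]])
    raw[raw %in% c("", ".", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad)) {
      if (strict) abort(sprintf("non-numeric value in feature '%s'", f))
      inform(sprintf("feature '%s': %d non-numeric cell(s) set to NA", f, sum(bad)))
    }
    df[[f]] <- num
  }
  tibble::as_tibble(df)
}

#' Write / read association result tables
#'
#' Association results (one row per tested feature, signature or hallmark:
#' estimate, confidence bounds, raw and adjusted p, method tag, direction) are
#' written as TSV with a deterministic column order and full double precision,
#' so a write-then-read round trip reproduces values to 1e-12.
#'
#' @param rows Tibble of association results.
#' @param path Output path.
#' @return `write_association_results()` returns `path` invisibly;
#'   `read_association_results()` returns the tibble.
#' @export
write_association_results <- function(rows, path) {
  lead <- intersect(
    c("feature", "estimate", "ci_lo", "ci_hi", "p_raw", "p_adj",
      "method", "direction"),
    names(rows)
  )
  rows <- rows[, c(lead, setdiff(names(rows), lead)), drop = FALSE]
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_association_results
#' @export
read_association_results <- function(path) {
  read_tsv_checked(path)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA", "."))
}
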