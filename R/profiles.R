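#' Per-patient hallmark VAF profiles
#'
#' Averages mutation VAFs per patient within each cancer hallmark. A mutation
#' in a gene mapped to several hallmarks contributes to each of them. Genes
#' absent from the map are counted and reported; patients with no mapped
#' mutation at all are excluded with a message.
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param hallmark_map Tibble with columns `gene`, `hallmark`.
#' @param impute If `TRUE`, hallmarks without mutations get the patient's
#'   overall mean VAF (flagged in the `imputed` column); if `FALSE` their
#'   `mean_vaf` stays `NA`.
#' @param max_missing Patients missing more than this many hallmarks are
#'   dropped (with a message) before imputation. Default 2: a profile built
#'   mostly from imputed values carries no ordering signal.
#' @return Long tibble: `sample_id`, `hallmark`, `n_mut`, `mean_vaf`,
#'   `imputed` — every retained patient has all 10 hallmark rows.
#' @export
compute_hallmark_profiles <- function(mutations, hallmark_map,
                                      impute = FALSE, max_missing = 2) {
  hallmarks <- canonical_hallmarks()
  unknown <- setdiff(unique(hallmark_map$hallmark), hallmarks)
  if (length(unknown) > 0) {
    abort(sprintf("hallmark map uses names outside the canonical ten: %s",
                  paste(unknown, collapse = ", ")))
  }

  mapped <- dplyr::inner_join(mutations, hallmark_map, by = "gene",
                              relationship = "many-to-many")
  n_unmapped <- length(setdiff(unique(mutations$gene), hallmark_map$gene))
  if (n_unmapped > 0) {
    inform(sprintf("%d gene(s) absent from the hallmark map were ignored",
                   n_unmapped))
  }
  lost <- setdiff(unique(mutations$sample_id), unique(mapped$sample_id))
  if (length(lost) > 0) {
    inform(sprintf("excluded %d patient(s) with zero mapped mutations",
                   length(lost)))
  }

  prof <- mapped |>
    dplyr::group_by(.data$sample_id, .data$hallmark) |>
    dplyr::summarise(n_mut = dplyr::n(), mean_vaf = mean(.data$vaf),
                     .groups = "drop") |>
    tidyr::complete(
      sample_id = unique(mapped$sample_id),
      hallmark = hallmarks,
      fill = list(n_mut = 0L, mean_vaf = NA_real_)
    ) |>
    dplyr::mutate(imputed = FALSE)

  miss <- prof |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_missing = sum(is.na(.data$mean_vaf)), .groups = "drop")
  drop_ids <- miss$sample_id[miss$n_missing > max_missing]
  if (length(drop_ids) > 0) {
    inform(sprintf("excluded %d patient(s) missing more than %d hallmark(s)",
                   length(drop_ids), max_missing))
    prof <- prof[!prof$sample_id %in% drop_ids, , drop = FALSE]
  }

  if (impute && anyNA(prof$mean_vaf)) {
    prof <- prof |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(
        imputed = is.na(.data$mean_vaf),
        mean_vaf = dplyr::coalesce(.data$mean_vaf,
                                   mean(.data$mean_vaf, na.rm = TRUE))
      ) |>
      dplyr::ungroup()
  }
  dplyr::arrange(prof, .data$sample_id, match(.data$hallmark, hallmarks))
}

#' Rank hallmarks within each patient by mean VAF
#'
#' Higher mean VAF receives the smaller rank (1 = highest = inferred earliest
#' acquisition); ties get the average of the tied rank positions. Patients
#' with fewer than two non-missing hallmarks cannot be ranked.
#'
#' @param profiles Long profile tibble from [compute_hallmark_profiles()].
#' @return The input with an added `rank` column (`NA` where `mean_vaf` is
#'   missing).
#' @export
rank_hallmarks <- function(profiles) {
  ok <- profiles |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_ok = sum(!is.na(.data$mean_vaf)), .groups = "drop")
  if (any(ok$n_ok == 0)) {
    abort("cannot rank: some patients have no non-missing hallmark VAF")
  }
  if (any(ok$n_ok < 2)) {
    abort("cannot rank: some patients have fewer than 2 non-missing hallmarks")
  }
  profiles |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rank = rank_desc(.data$mean_vaf)) |>
    dplyr::ungroup()
}

#' Wide patient-by-hallmark VAF matrix
#'
#' Pivots long profiles to the samples-by-hallmarks matrix consumed by PCA and
#' k-means. Patients with any remaining missing hallmark are dropped with a
#' message (use `impute = TRUE` upstream to keep them).
#'
#' @param profiles Long profile tibble.
#' @return Numeric matrix, rownames = sample ids, colnames = hallmarks.
#' @export
profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(
    profiles[, c("sample_id", "hallmark", "mean_vaf")],
    names_from = "hallmark", values_from = "mean_vaf"
  )
  m <- as.matrix(wide[, setdiff(names(wide), "sample_id")])
  rownames(m) <- wide$sample_id
  keep <- complete.cases(m)
  if (!all(keep)) {
    inform(sprintf(
      "excluded %d patient(s) with missing hallmark values (set impute = TRUE upstream to retain them)",
      sum(!keep)))
  }
  m[keep, , drop = FALSE]
}
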