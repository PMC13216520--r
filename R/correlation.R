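#' Substitution-frequency versus VAF correlation control
#'
#' Checks that substitution-type differences between VAF-defined clusters are
#' not artifacts of the clustering input: within hallmark genes, single-base
#' substitutions are grouped by gene and pyrimidine-normalized substitution
#' class (C>A, C>G, C>T, T>A, T>C, T>G); per (gene, class) the occurrence
#' count and mean VAF are computed, and per class the Pearson correlation
#' between count and mean VAF across genes is tested. Indels and complex
#' variants are excluded; classes observed in fewer than 3 genes are skipped.
#'
#' @param mutations Mutation tibble.
#' @param hallmark_map Tibble `gene`, `hallmark`; only mapped genes are used.
#' @param alpha Significance level for the `significant` flag.
#' @return Association tibble per substitution class: `feature`, `estimate`
#'   (Pearson r), `ci_lo`, `ci_hi`, `p_raw`, `p_adj` (BH across classes),
#'   `n_genes`, `method`, `significant`. The per-(gene, class) scatter table
#'   is attached as attribute `"scatter"`.
#' @export
substitution_vaf_correlation <- function(mutations, hallmark_map, alpha = 0.05) {
  snv <- mutations[
    nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1 &
      toupper(mutations$ref) %in% DNA_BASES &
      toupper(mutations$alt) %in% DNA_BASES &
      toupper(mutations$ref) != toupper(mutations$alt), , drop = FALSE]
  snv <- snv[snv$gene %in% unique(hallmark_map$gene), , drop = FALSE]
  if (nrow(snv) == 0) {
    abort("no single-base substitutions in hallmark genes")
  }
  ref <- toupper(snv$ref)
  alt <- toupper(snv$alt)
  pur <- ref %in% c("A", "G")
  ref[pur] <- chartr("AG", "TC", ref[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  snv$sub_class <- paste0(ref, ">", alt)

  scatter <- snv |>
    dplyr::group_by(.data$gene, .data$sub_class) |>
    dplyr::summarise(count = dplyr::n(), mean_vaf = mean(.data$vaf),
                     .groups = "drop")

  rows <- lapply(substitution_classes(), function(sc) {
    sub <- scatter[scatter$sub_class == sc, , drop = FALSE]
    if (nrow(sub) < 3) {
      inform(sprintf("substitution class %s skipped: fewer than 3 genes", sc))
      return(NULL)
    }
    if (sd(sub$count) == 0 || sd(sub$mean_vaf) == 0) {
      return(tibble::tibble(feature = sc, estimate = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_, p_raw = 1,
                            n_genes = nrow(sub), method = "pearson"))
    }
    ct <- cor.test(sub$count, sub$mean_vaf, method = "pearson")
    tibble::tibble(
      feature = sc, estimate = unname(ct$estimate),
      ci_lo = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
      ci_hi = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
      p_raw = ct$p.value, n_genes = nrow(sub), method = "pearson"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$p_adj <- bh_adjust(out$p_raw)
    out$significant <- out$p_adj < alpha
  }
  attr(out, "scatter") <- scatter
  out
}
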