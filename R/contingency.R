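#' Per-signature 2x2 dominant-count tables
#'
#' For every signature, cross-tabulates dominant-for-that-signature (yes/no)
#' against cluster (EGI/LGI). Margins equal the cluster sizes.
#'
#' @param labels Tibble `sample_id`, `label` (`"EGI"`/`"LGI"`).
#' @param calls Dominant-call tibble from [dominant_calls()].
#' @return Tibble: `signature`, `egi_dom`, `lgi_dom`, `egi_other`,
#'   `lgi_other`.
#' @export
dominant_count_tables <- function(labels, calls) {
  unlabeled <- setdiff(calls$sample_id, labels$sample_id)
  if (length(unlabeled) > 0) {
    abort(sprintf("sample(s) without a cluster label: %s",
                  paste(head(unlabeled, 5), collapse = ", ")))
  }
  dat <- dplyr::inner_join(calls, labels[, c("sample_id", "label")],
                           by = "sample_id")
  n_egi <- sum(dat$label == "EGI")
  n_lgi <- sum(dat$label == "LGI")
  wide <- dat |>
    dplyr::count(.data$signature, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  if (!"EGI" %in% names(wide)) wide$EGI <- 0L
  if (!"LGI" %in% names(wide)) wide$LGI <- 0L
  tibble::tibble(
    signature = wide$signature,
    egi_dom = as.integer(wide$EGI),
    lgi_dom = as.integer(wide$LGI),
    egi_other = n_egi - as.integer(wide$EGI),
    lgi_other = n_lgi - as.integer(wide$LGI)
  )
}

#' Test one 2x2 contingency table
#'
#' Expected cell frequencies are computed from the margins; when all four are
#' at least 5 a Pearson chi-square test (no continuity correction) is used,
#' otherwise the two-sided Fisher exact test (sum of hypergeometric
#' probabilities no larger than the observed table's). A zero margin yields
#' p = 1 with a degenerate flag.
#'
#' @param a,b,c,d Cell counts: rows dominant yes/no, columns EGI/LGI —
#'   `a` = EGI dominant, `b` = LGI dominant, `c` = EGI other, `d` = LGI other.
#' @return One-row tibble: `p_raw`, `method` (`"chisq"`/`"fisher"`/
#'   `"degenerate"`), `or` (cross-product odds ratio, 0.5 added to every cell
#'   when any is zero), `degenerate`.
#' @export
test_contingency <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), nrow = 2,
              dimnames = list(dominant = c("yes", "no"),
                              cluster = c("EGI", "LGI")))
  if (sum(m) == 0) abort("empty contingency table")
  or <- if (any(m == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else (a * d) / (b * c)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble::tibble(p_raw = 1, method = "degenerate", or = or,
                          degenerate = TRUE))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    p <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    method <- "chisq"
  } else {
    p <- fisher.test(m, alternative = "two.sided")$p.value
    method <- "fisher"
  }
  tibble::tibble(p_raw = p, method = method, or = or, degenerate = FALSE)
}

#' Cluster-association tests for every signature
#'
#' Builds the per-signature dominant-count tables, tests each with
#' [test_contingency()], and adjusts p-values across signatures by
#' Benjamini-Hochberg.
#'
#' @inheritParams dominant_count_tables
#' @param alpha Significance level for the `significant` flag.
#' @return Association tibble: `feature` (signature), `estimate` (odds ratio
#'   of being dominant in EGI vs LGI), counts, `p_raw`, `p_adj`, `method`,
#'   `direction`, `significant`.
#' @export
signature_cluster_tests <- function(labels, calls, alpha = 0.05) {
  tabs <- dominant_count_tables(labels, calls)
  res <- dplyr::bind_rows(lapply(seq_len(nrow(tabs)), function(i) {
    test_contingency(tabs$egi_dom[i], tabs$lgi_dom[i],
                     tabs$egi_other[i], tabs$lgi_other[i])
  }))
  out <- dplyr::bind_cols(
    tibble::tibble(feature = tabs$signature),
    tabs[, c("egi_dom", "lgi_dom", "egi_other", "lgi_other")],
    res
  )
  out$estimate <- out$or
  out$or <- NULL
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha & !out$degenerate
  prop_egi <- out$egi_dom / (out$egi_dom + out$egi_other)
  prop_lgi <- out$lgi_dom / (out$lgi_dom + out$lgi_other)
  out$direction <- dplyr::case_when(
    prop_egi > prop_lgi ~ "EGI",
    prop_lgi > prop_egi ~ "LGI",
    TRUE ~ "none"
  )
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1,
#' order-preserving).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  assert_probs(p)
  p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' Family-wise correction: each p multiplied by the family size, capped at 1.
#'
#' @inheritParams bh_adjust
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  assert_probs(p)
  p.adjust(p, method = "bonferroni")
}
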