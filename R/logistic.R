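#' Logistic odds ratio for one feature
#'
#' Fits the single-predictor logistic regression `cluster ~ feature` by
#' iteratively reweighted least squares (the LGI cluster coded 1, so OR > 1
#' means LGI-association and OR < 1 EGI-association), and reports the odds
#' ratio with its Wald confidence interval. Missing feature values are
#' dropped. Quasi-complete separation (diverging slope) is flagged and the
#' estimate reported as the bound reached.
#'
#' @param values Numeric feature vector (native scale).
#' @param labels Character vector (`"EGI"`/`"LGI"`) aligned with `values`.
#' @param feature Feature name carried into the output.
#' @param conf Confidence level for the Wald interval.
#' @return One-row association tibble: `feature`, `estimate` (OR), `ci_lo`,
#'   `ci_hi`, `p_raw`, `method`, `direction`, `n`, `degenerate`, `separated`.
#' @export
logistic_or <- function(values, labels, feature = "feature", conf = 0.95) {
  keep <- !is.na(values) & !is.na(labels)
  v <- values[keep]
  y <- as.integer(labels[keep] == "LGI")
  if (length(unique(y)) < 2) abort("both clusters must be present")
  if (length(unique(v)) < 2) {
    return(tibble::tibble(feature = feature, estimate = 1, ci_lo = NA_real_,
                          ci_hi = NA_real_, p_raw = 1, method = "logistic",
                          direction = "none", n = length(v),
                          degenerate = TRUE, separated = FALSE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ v, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  slope <- coef(fit)[["v"]]
  se <- sqrt(vcov(fit)["v", "v"])
  if (!separated && (abs(slope) > 20 || !fit$converged)) separated <- TRUE
  z <- qnorm(1 - (1 - conf) / 2)
  p <- 2 * pnorm(-abs(slope / se))
  or <- exp(slope)
  tibble::tibble(
    feature = feature, estimate = or,
    ci_lo = exp(slope - z * se), ci_hi = exp(slope + z * se),
    p_raw = p, method = "logistic",
    direction = if (or > 1) "LGI" else if (or < 1) "EGI" else "none",
    n = length(v), degenerate = FALSE, separated = separated
  )
}

#' Per-feature logistic odds-ratio enrichment table
#'
#' Fits [logistic_or()] for every feature column and corrects for multiple
#' testing (Bonferroni by default, matching forest-plot conventions). When
#' `kinds` is supplied (named vector, feature -> family tag), the correction
#' is applied within each family separately.
#'
#' @param features Feature tibble (`sample_id` + numeric columns).
#' @param labels Tibble `sample_id`, `label`.
#' @param kinds Optional named character vector of family tags per feature.
#' @param adjust `"bonferroni"` or `"BH"`.
#' @param alpha Significance level for the `significant` flag.
#' @return Association tibble, one row per feature, with `p_adj`,
#'   `significant` and (when `kinds` given) `kind`.
#' @export
feature_association_table <- function(features, labels, kinds = NULL,
                                      adjust = c("bonferroni", "BH"),
                                      alpha = 0.05) {
  adjust <- match.arg(adjust)
  dat <- dplyr::inner_join(features, labels[, c("sample_id", "label")],
                           by = "sample_id")
  feats <- setdiff(names(features), "sample_id")
  out <- dplyr::bind_rows(lapply(feats, function(f) {
    logistic_or(dat[[f]], dat$label, feature = f)
  }))
  if (!is.null(kinds)) {
    out$kind <- unname(kinds[out$feature])
    fam <- out$kind
  } else {
    fam <- rep("all", nrow(out))
  }
  adj_fun <- if (adjust == "bonferroni") bonferroni_adjust else bh_adjust
  out$p_adj <- NA_real_
  for (g in unique(fam)) {
    idx <- which(fam == g)
    out$p_adj[idx] <- adj_fun(out$p_raw[idx])
  }
  out$significant <- out$p_adj < alpha & !out$degenerate
  out
}
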