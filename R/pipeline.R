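#' Run the full genome-instability-timing pipeline
#'
#' Sequences every stage: hallmark VAF profiles and ranks, PCA, WSS/elbow,
#' k-means, silhouette, EGI/LGI labelling, per-hallmark Mann-Whitney VAF
#' comparison, SBS96 spectra, minimum-mutation filter, signature refitting,
#' dominant SBS/CN calls, per-signature contingency tests with BH, the
#' bootstrap Anderson-Darling comparison with Cohen's d, per-feature logistic
#' odds ratios with Bonferroni, and the substitution-VAF correlation control.
#' Every random stage derives its seed from `seed`, so a re-run reproduces
#' the numeric tables exactly.
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param hallmark_map Tibble `gene`, `hallmark`.
#' @param catalog SBS signature catalog tibble.
#' @param cn_exposures Optional CN exposure tibble (`sample_id` + signatures).
#' @param features Optional feature tibble (`sample_id` + numeric columns).
#' @param feature_kinds Optional named vector of family tags per feature
#'   (correction applied within family).
#' @param k `"auto"` (elbow-selected over `1:k_max`) or a fixed integer.
#' @param k_max Largest k scanned for the WSS curve.
#' @param seed Master integer seed.
#' @param min_mutations Minimum classified SNVs per sample for refitting.
#' @param trim Signature-weight trim threshold.
#' @param R Bootstrap replicates.
#' @param alpha Significance level.
#' @param out_dir Optional directory; when given, every table plus a run
#'   manifest is written as TSV.
#' @return Object of class `hallmark_pipeline`: named list of result tables
#'   (`profiles`, `pca`, `wss`, `labels`, `silhouette`, `hallmark_vaf_tests`,
#'   `spectra`, `sbs_weights`, `sbs_dominant`, `cn_dominant`,
#'   `sbs_cluster_tests`, `cn_cluster_tests`, `sbs_bootstrap`,
#'   `cn_bootstrap`, `feature_associations`, `substitution_correlation`)
#'   plus `manifest`.
#' @export
run_pipeline <- function(mutations, hallmark_map, catalog,
                         cn_exposures = NULL, features = NULL,
                         feature_kinds = NULL,
                         k = "auto", k_max = 10, seed = 123,
                         min_mutations = 50, trim = 0.06, R = 1000,
                         alpha = 0.05, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  manifest <- list(seed = seed, alpha = alpha, min_mutations = min_mutations,
                   trim = trim, R = R,
                   n_input_samples = length(unique(mutations$sample_id)),
                   n_input_mutations = nrow(mutations))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  profiles <- stage("profiles", {
    p <- compute_hallmark_profiles(mutations, hallmark_map, impute = TRUE)
    rank_hallmarks(p)
  })
  manifest$n_profiled <- length(unique(profiles$sample_id))
  manifest$n_excluded_missing_hallmarks <-
    manifest$n_input_samples - manifest$n_profiled

  pm <- stage("profile_matrix", profile_matrix(profiles))
  pca <- stage("pca", run_pca(pm))
  wss <- stage("wss", wss_curve(pca, k_min = 1,
                                k_max = min(k_max, nrow(pm) - 1), seed = seed))
  k_used <- if (identical(k, "auto")) {
    as.integer(stage("elbow", select_k_elbow(wss)))
  } else as.integer(k)
  manifest$k <- k_used

  assignments <- stage("kmeans", kmeans_assign(pca, k_used, seed = seed))
  sil <- stage("silhouette",
               if (k_used >= 2) silhouette_widths(pca, assignments) else NULL)
  labels <- stage("labels",
                  if (k_used == 2) label_egi_lgi(assignments, profiles) else NULL)
  if (!is.null(labels)) {
    manifest$n_egi <- sum(labels$label == "EGI")
    manifest$n_lgi <- sum(labels$label == "LGI")
  }
  hallmark_vaf_tests <- if (!is.null(labels)) {
    stage("hallmark_vaf_tests", compare_hallmark_vaf(profiles, labels, alpha))
  }

  spectra <- stage("spectra", build_spectra(mutations))
  filt <- stage("min_mutation_filter",
                apply_min_mutation_filter(spectra, min_mutations))
  manifest$n_spectra_retained <- nrow(filt$retained)
  manifest$n_spectra_filtered <- length(filt$excluded)
  if (nrow(filt$retained) == 0) {
    abort(sprintf(
      "pipeline stage 'signatures' failed: all samples have fewer than %d classified mutations",
      min_mutations))
  }

  sbs_weights <- stage("refit",
                       fit_cohort_weights(filt$retained, catalog, trim = trim))
  sbs_dominant <- stage("sbs_dominant", dominant_calls(sbs_weights, kind = "SBS"))
  cn_dominant <- if (!is.null(cn_exposures)) {
    stage("cn_dominant", dominant_calls(cn_exposures, kind = "CN"))
  }
  if (!is.null(cn_dominant) && !is.null(labels)) {
    manifest$n_cn_samples <- sum(cn_dominant$sample_id %in% labels$sample_id)
  }

  sbs_cluster_tests <- cn_cluster_tests <- NULL
  sbs_bootstrap <- cn_bootstrap <- NULL
  if (!is.null(labels)) {
    sbs_calls <- sbs_dominant[sbs_dominant$sample_id %in% labels$sample_id, ]
    sbs_cluster_tests <- stage("sbs_tests",
                               signature_cluster_tests(labels, sbs_calls, alpha))
    sbs_bootstrap <- stage("sbs_bootstrap",
                           bootstrap_signature_comparison(labels, sbs_calls,
                                                          R = R, seed = seed + 1,
                                                          alpha = alpha))
    if (!is.null(cn_dominant)) {
      cn_calls <- cn_dominant[cn_dominant$sample_id %in% labels$sample_id, ]
      cn_cluster_tests <- stage("cn_tests",
                                signature_cluster_tests(labels, cn_calls, alpha))
      cn_bootstrap <- stage("cn_bootstrap",
                            bootstrap_signature_comparison(labels, cn_calls,
                                                           R = R, seed = seed + 2,
                                                           alpha = alpha))
    }
  }

  feature_associations <- if (!is.null(features) && !is.null(labels)) {
    stage("logistic", feature_association_table(features, labels,
                                                kinds = feature_kinds,
                                                adjust = "bonferroni",
                                                alpha = alpha))
  }
  substitution_correlation <- stage("correlation",
                                    substitution_vaf_correlation(mutations,
                                                                 hallmark_map,
                                                                 alpha))

  res <- structure(list(
    profiles = profiles, pca = pca, wss = wss, k = k_used,
    assignments = assignments, silhouette = sil, labels = labels,
    hallmark_vaf_tests = hallmark_vaf_tests,
    spectra = filt$retained, excluded_samples = filt$excluded,
    sbs_weights = sbs_weights, sbs_dominant = sbs_dominant,
    cn_dominant = cn_dominant,
    sbs_cluster_tests = sbs_cluster_tests, cn_cluster_tests = cn_cluster_tests,
    sbs_bootstrap = sbs_bootstrap, cn_bootstrap = cn_bootstrap,
    feature_associations = feature_associations,
    substitution_correlation = substitution_correlation,
    manifest = manifest
  ), class = "hallmark_pipeline")

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Write every pipeline table plus the run manifest
#'
#' @param result A `hallmark_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_pipeline <- function(result, out_dir) {
  stopifnot(inherits(result, "hallmark_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    profiles = result$profiles,
    pca_scores = result$pca$scores,
    pca_loadings = result$pca$loadings,
    wss_curve = result$wss,
    assignments = result$assignments,
    silhouette = result$silhouette,
    labels = result$labels,
    hallmark_vaf_tests = result$hallmark_vaf_tests,
    sbs_weights = result$sbs_weights,
    sbs_dominant = result$sbs_dominant,
    cn_dominant = result$cn_dominant,
    sbs_cluster_tests = result$sbs_cluster_tests,
    cn_cluster_tests = result$cn_cluster_tests,
    sbs_bootstrap = result$sbs_bootstrap,
    cn_bootstrap = result$cn_bootstrap,
    feature_associations = result$feature_associations,
    substitution_correlation = result$substitution_correlation
  )
  tables <- tables[!vapply(tables, is.null, logical(1))]
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], p)
    paths[nm] <- p
  }
  mf <- result$manifest
  mf$tables <- paste(names(tables), collapse = ",")
  man_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(tibble::tibble(key = names(mf),
                                  value = vapply(mf, as.character, character(1))),
                   man_path)
  paths["manifest"] <- man_path
  invisible(paths)
}

#' @export
print.hallmark_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("Genome-instability-timing pipeline run\n")
  cat(sprintf("  samples: %d in, %d profiled, %d spectra retained (>= %d mutations)\n",
              m$n_input_samples, m$n_profiled, m$n_spectra_retained,
              m$min_mutations))
  cat(sprintf("  k = %d", x$k))
  if (!is.null(m$n_egi)) {
    cat(sprintf("; EGI = %d, LGI = %d", m$n_egi, m$n_lgi))
  }
  cat(sprintf("\n  seed = %d, R = %d, alpha = %g\n", m$seed, m$R, m$alpha))
  invisible(x)
}
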