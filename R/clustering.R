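#' Principal component analysis of hallmark profiles
#'
#' Mean-centred (not variance-scaled — all ten features share VAF units) PCA
#' retaining every component; the full score matrix feeds k-means, while the
#' first two components serve visualization.
#'
#' @param x Samples-by-hallmarks matrix (see [profile_matrix()]) or a wide
#'   tibble whose first column is `sample_id`.
#' @param scale. Standardize columns before decomposition (default `FALSE`).
#' @return Object of class `hallmark_pca`: `scores` (tibble, `sample_id` +
#'   `PC1..`), `loadings` (tibble, `hallmark` + components), `var_explained`
#'   (fractions summing to 1), `center`, `sdev`.
#' @export
run_pca <- function(x, scale. = FALSE) {
  m <- as_profile_matrix(x)
  if (anyNA(m)) {
    abort("PCA input contains missing values; impute hallmark profiles first (impute = TRUE)")
  }
  if (nrow(m) < 2 || ncol(m) < 2) abort("PCA needs at least 2 samples and 2 hallmarks")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  fit <- prcomp(m, center = TRUE, scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                              tibble::as_tibble(fit$x)),
    loadings = dplyr::bind_cols(tibble::tibble(hallmark = rownames(fit$rotation)),
                                tibble::as_tibble(fit$rotation)),
    var_explained = ve,
    center = fit$center,
    sdev = fit$sdev
  ), class = "hallmark_pca")
}

as_profile_matrix <- function(x) {
  if (inherits(x, "hallmark_pca")) {
    m <- as.matrix(x$scores[, -1, drop = FALSE])
    rownames(m) <- x$scores$sample_id
    return(m)
  }
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    id_col <- if ("sample_id" %in% names(x)) "sample_id" else names(x)[1]
    m <- as.matrix(x[, setdiff(names(x), id_col), drop = FALSE])
    rownames(m) <- as.character(x[[id_col]])
    return(m)
  }
  abort("expected a matrix, a wide tibble, or a hallmark_pca object")
}

#' K-means cluster assignment
#'
#' Best-of-`n_init` k-means (Lloyd-type iterations from random starts, as in
#' `stats::kmeans`), deterministic given `seed`. When the data hold fewer
#' distinct points than `k`, the distinct points become their own clusters,
#' the fit is flagged degenerate and the within-cluster sum of squares is 0.
#'
#' @param x Score matrix, wide tibble, or `hallmark_pca`.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_init Number of restarts (best by within-cluster sum of squares).
#' @param iter_max Maximum Lloyd iterations per start.
#' @return Tibble `sample_id`, `cluster`; attributes `tot_withinss`,
#'   `centers`, `degenerate`.
#' @export
kmeans_assign <- function(x, k, seed = 123, n_init = 25, iter_max = 300) {
  m <- as_profile_matrix(x)
  stopifnot(k >= 1)
  distinct <- unique(m)
  if (nrow(distinct) < k) {
    cl <- match(apply(m, 1, paste, collapse = "\r"),
                apply(distinct, 1, paste, collapse = "\r"))
    out <- tibble::tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                          cluster = cl)
    attr(out, "tot_withinss") <- 0
    attr(out, "centers") <- distinct
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- with_seed(seed, {
    tryCatch(
      suppressWarnings(kmeans(m, centers = k, nstart = n_init, iter.max = iter_max)),
      error = function(e) {
        # rare empty-cluster failure: retry from fresh starts
        inform(sprintf("k-means restart after: %s", conditionMessage(e)))
        suppressWarnings(kmeans(m, centers = k, nstart = n_init,
                                iter.max = iter_max, algorithm = "Lloyd"))
      }
    )
  })
  out <- tibble::tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                        cluster = as.integer(fit$cluster))
  attr(out, "tot_withinss") <- fit$tot.withinss
  attr(out, "centers") <- fit$centers
  attr(out, "degenerate") <- FALSE
  out
}

#' Within-cluster sum-of-squares curve
#'
#' Total within-cluster sum of squares for each k in `k_min:k_max`, each the
#' best of `n_init` k-means restarts — the input of the elbow rule.
#'
#' @inheritParams kmeans_assign
#' @param k_min,k_max Range of cluster numbers (k_max below the sample count).
#' @return Tibble with columns `k`, `wss`.
#' @export
wss_curve <- function(x, k_min = 1, k_max = 10, seed = 123, n_init = 25) {
  m <- as_profile_matrix(x)
  if (k_max >= nrow(m)) abort("k_max must be smaller than the number of samples")
  ks <- k_min:k_max
  wss <- vapply(ks, function(k) {
    attr(kmeans_assign(m, k, seed = seed + k, n_init = n_init), "tot_withinss")
  }, numeric(1))
  if (any(diff(wss) > 1e-8)) {
    warn("WSS curve is not monotone nonincreasing; consider raising n_init")
  }
  tibble::tibble(k = ks, wss = wss)
}

#' Elbow selection of the cluster number
#'
#' Picks the k at which the decrease in WSS diminishes most sharply: the k
#' maximizing the second forward difference `wss(k-1) - 2 wss(k) + wss(k+1)`.
#' Ties resolve to the smallest k. When the curve decays linearly (no
#' curvature anywhere) the smallest interior k is returned with attribute
#' `no_clear_elbow = TRUE`.
#'
#' @param curve Tibble from [wss_curve()] (at least 3 rows, consecutive k).
#' @return Integer k; attribute `no_clear_elbow`.
#' @export
select_k_elbow <- function(curve) {
  if (nrow(curve) < 3) abort("elbow selection needs at least 3 (k, WSS) points")
  curve <- dplyr::arrange(curve, .data$k)
  w <- curve$wss
  d2 <- w[-c(length(w) - 1, length(w))] - 2 * w[-c(1, length(w))] + w[-c(1, 2)]
  scale_ref <- max(abs(w[1]), 1e-12)
  flat <- diff(range(d2)) < 1e-9 * scale_ref
  k <- as.integer(curve$k[which.max(d2) + 1L])
  if (flat) {
    k <- as.integer(curve$k[2])
    inform("no clear elbow: WSS decays linearly; returning the smallest interior k")
  }
  attr(k, "no_clear_elbow") <- flat
  k
}

#' Silhouette widths of a clustering
#'
#' Standard Euclidean silhouette widths per sample (samples in singleton
#' clusters get width 0) and the average width as a clustering quality score.
#'
#' @param x Score matrix, wide tibble, or `hallmark_pca`.
#' @param assignments Tibble from [kmeans_assign()] (or integer vector).
#' @return Tibble `sample_id`, `cluster`, `silhouette`; attribute
#'   `avg_width`.
#' @export
silhouette_widths <- function(x, assignments) {
  m <- as_profile_matrix(x)
  cl <- if (is.data.frame(assignments)) {
    assignments$cluster[match(rownames(m), assignments$sample_id)]
  } else as.integer(assignments)
  if (length(unique(cl)) < 2) abort("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(cl, stats::dist(m))
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(cl))
  out <- tibble::tibble(sample_id = rownames(m), cluster = cl,
                        silhouette = as.numeric(widths))
  attr(out, "avg_width") <- mean(out$silhouette)
  out
}

#' Label the two clusters as early vs late genome instability
#'
#' The cluster whose patients rank the genome-instability hallmark earlier
#' (lower mean rank, i.e. higher relative VAF) is labelled EGI; the other LGI.
#' The margin between the two cluster mean ranks is attached as a confidence
#' diagnostic.
#'
#' @param assignments Tibble `sample_id`, `cluster` with exactly 2 clusters.
#' @param profiles Ranked profile tibble from [rank_hallmarks()].
#' @param gi_hallmark Name of the genome-instability hallmark.
#' @return Tibble `sample_id`, `cluster`, `label` (`"EGI"`/`"LGI"`);
#'   attribute `rank_margin`.
#' @export
label_egi_lgi <- function(assignments, profiles,
                          gi_hallmark = "genome_instability") {
  cls <- sort(unique(assignments$cluster))
  if (length(cls) != 2) abort("EGI/LGI labelling requires exactly 2 clusters")
  gi <- profiles[profiles$hallmark == gi_hallmark & !is.na(profiles$rank), ]
  joined <- dplyr::inner_join(assignments, gi[, c("sample_id", "rank")],
                              by = "sample_id")
  mr <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean_rank = mean(.data$rank), .groups = "drop")
  if (abs(diff(mr$mean_rank)) < 1e-9) {
    abort("indistinguishable clusters: genome-instability mean ranks are equal")
  }
  egi_cluster <- mr$cluster[which.min(mr$mean_rank)]
  out <- assignments
  out$label <- ifelse(out$cluster == egi_cluster, "EGI", "LGI")
  attr(out, "rank_margin") <- abs(diff(mr$mean_rank))
  out
}

#' Per-hallmark Mann-Whitney comparison of VAF between clusters
#'
#' For each hallmark, compares the per-patient mean VAF distributions of the
#' two clusters with a two-sided Mann-Whitney U test (exact enumeration when
#' both groups have at most 8 observations and no ties; otherwise the normal
#' approximation with tie correction), reports the median VAF difference
#' (LGI - EGI), and adjusts p-values across hallmarks by Benjamini-Hochberg.
#'
#' @param profiles Long profile tibble.
#' @param labels Tibble `sample_id`, `label` from [label_egi_lgi()].
#' @param alpha Significance level for the `significant` flag.
#' @return Association tibble: `feature` (hallmark), `estimate` (median VAF
#'   difference, LGI - EGI), `p_raw`, `p_adj`, `method`, `direction`,
#'   `n_egi`, `n_lgi`, `significant`.
#' @export
compare_hallmark_vaf <- function(profiles, labels, alpha = 0.05) {
  dat <- dplyr::inner_join(profiles, labels[, c("sample_id", "label")],
                           by = "sample_id")
  dat <- dat[!is.na(dat$mean_vaf), , drop = FALSE]
  rows <- lapply(canonical_hallmarks(), function(h) {
    x <- dat$mean_vaf[dat$hallmark == h & dat$label == "LGI"]
    y <- dat$mean_vaf[dat$hallmark == h & dat$label == "EGI"]
    if (length(x) < 2 || length(y) < 2) {
      inform(sprintf("hallmark '%s' skipped: fewer than 2 observations per group", h))
      return(NULL)
    }
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = !exact)
    )
    est <- median(x) - median(y)
    tibble::tibble(
      feature = h, estimate = est, p_raw = wt$p.value,
      method = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
      n_egi = length(y), n_lgi = length(x),
      direction = if (est > 0) "LGI" else if (est < 0) "EGI" else "none"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out[, c("feature", "estimate", "p_raw", "p_adj", "method", "direction",
          "n_egi", "n_lgi", "significant")]
}
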