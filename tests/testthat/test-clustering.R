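blob_matrix <- function(n_per = 20, gap = 5, d = 4, seed = 9, sd = 0.3) {
  withr::with_seed(seed, {
    m <- rbind(
      matrix(rnorm(n_per * d, 0, sd), ncol = d),
      matrix(rnorm(n_per * d, gap, sd), ncol = d)
    )
    rownames(m) <- sprintf("S%02d", seq_len(2 * n_per))
    m
  })
}

test_that("PCA is a lossless mean-centred decomposition", {
  withr::with_seed(14, {
    m <- matrix(runif(200, 0.2, 0.4), nrow = 20,
                dimnames = list(sprintf("S%02d", 1:20), canonical_hallmarks()))
    pca <- run_pca(m)
    expect_equal(sum(pca$var_explained), 1, tolerance = 1e-9)
    expect_true(all(diff(pca$var_explained) <= 1e-12))
    scores <- as.matrix(pca$scores[, -1])
    load <- as.matrix(pca$loadings[, -1])
    recon <- scores %*% t(load) + matrix(pca$center, 20, 10, byrow = TRUE)
    expect_equal(unname(recon), unname(m), tolerance = 1e-8)
  })
})

test_that("the first loading aligns with the dominant axis up to sign", {
  m <- cbind(x = c(-2, -1, 0, 1, 2), y = rep(0, 5))
  rownames(m) <- paste0("S", 1:5)
  pca <- run_pca(m)
  l1 <- as.numeric(unlist(pca$loadings[pca$loadings$hallmark == "x", "PC1"]))
  expect_equal(abs(l1), 1, tolerance = 1e-12)
})

test_that("PCA refuses missing values with a pointer to imputation", {
  m <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(run_pca(m), "impute")
})

test_that("WSS boundary values and blob structure behave as expected", {
  m <- blob_matrix()
  curve <- wss_curve(m, k_min = 1, k_max = 6, seed = 1)
  tss <- sum(scale(m, scale = FALSE)^2)
  expect_equal(curve$wss[1], tss, tolerance = 1e-9)
  expect_true(all(diff(curve$wss) <= 1e-8))
  # k = 1 -> 2 collapses almost all the variance for two far blobs
  expect_gt(curve$wss[1] / curve$wss[2], 50)
  expect_error(wss_curve(m[1:4, ], k_min = 1, k_max = 4), "smaller")

  # k = n gives zero WSS
  tiny <- m[1:5, ]
  expect_equal(attr(kmeans_assign(tiny, 5, seed = 2), "tot_withinss"), 0,
               tolerance = 1e-12)
})

test_that("elbow selection maximizes the second difference", {
  curve <- tibble::tibble(k = 1:5, wss = c(100, 20, 18, 17, 16))
  expect_equal(as.integer(select_k_elbow(curve)), 2L)
  lin <- tibble::tibble(k = 1:5, wss = c(50, 40, 30, 20, 10))
  expect_message(k <- select_k_elbow(lin), "no clear elbow")
  expect_equal(as.integer(k), 2L)
  expect_true(attr(k, "no_clear_elbow"))
  expect_error(select_k_elbow(curve[1:2, ]), "3")
})

test_that("k-means recovers planted blobs and handles degeneracies", {
  two <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  asg <- kmeans_assign(two, 2)
  expect_equal(attr(asg, "tot_withinss"), 0)
  expect_equal(length(unique(asg$cluster)), 2)

  same <- matrix(1, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  deg <- kmeans_assign(same, 2)
  expect_true(attr(deg, "degenerate"))
  expect_equal(attr(deg, "tot_withinss"), 0)

  m <- blob_matrix()
  truth <- rep(1:2, each = 20)
  asg2 <- kmeans_assign(m, 2, seed = 4)
  expect_equal(ari(asg2$cluster, truth), 1)
  # determinism
  expect_identical(asg2$cluster, kmeans_assign(m, 2, seed = 4)$cluster)
})

test_that("k-means on all PCA components equals k-means on centred data", {
  m <- blob_matrix(n_per = 15, gap = 3, seed = 17)
  pca <- run_pca(m)
  a <- kmeans_assign(pca, 2, seed = 3)
  b <- kmeans_assign(scale(m, scale = FALSE), 2, seed = 3)
  expect_equal(ari(a$cluster, b$cluster), 1)
  expect_equal(attr(a, "tot_withinss"), attr(b, "tot_withinss"),
               tolerance = 1e-8)
})

test_that("silhouette widths match the brute-force definition", {
  m <- blob_matrix(n_per = 15, gap = 6, seed = 8)
  asg <- kmeans_assign(m, 2, seed = 5)
  sw <- silhouette_widths(m, asg)
  expect_true(all(sw$silhouette > 0.9))

  # O(n^2) definition on a random 30-sample clustering
  withr::with_seed(30, {
    x <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("r", 1:30), NULL))
    cl <- sample(1:3, 30, replace = TRUE)
    got <- silhouette_widths(x, cl)$silhouette
    D <- as.matrix(dist(x))
    oracle <- vapply(1:30, function(i) {
      own <- which(cl == cl[i] & seq_len(30) != i)
      if (length(own) == 0) return(0)
      a <- mean(D[i, own])
      b <- min(vapply(setdiff(unique(cl), cl[i]), function(k)
        mean(D[i, cl == k]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-12)
  })

  # a point exactly midway between two tight clusters has width ~0
  mid <- rbind(matrix(c(0, 0.01, -0.01, 0, 0, 0.01), ncol = 2),
               matrix(c(10, 10.01, 9.99, 0, 0, 0.01), ncol = 2),
               c(5, 0))
  rownames(mid) <- paste0("p", 1:7)
  cl <- c(1, 1, 1, 2, 2, 2, 1)
  w <- silhouette_widths(mid, cl)$silhouette
  expect_lt(abs(w[7]), 0.01)
  expect_error(silhouette_widths(mid, rep(1, 7)), "2 clusters")
})

test_that("EGI/LGI labelling follows the genome-instability mean rank", {
  prof <- tibble::tibble(
    sample_id = rep(c("a", "b", "c", "d"), each = 1),
    hallmark = "genome_instability",
    mean_vaf = 0.3, n_mut = 5L, imputed = FALSE,
    rank = c(1.2, 1.2, 6.6, 6.6)
  )
  asg <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        cluster = c(1L, 1L, 2L, 2L))
  lab <- label_egi_lgi(asg, prof)
  expect_equal(lab$label, c("EGI", "EGI", "LGI", "LGI"))
  expect_equal(attr(lab, "rank_margin"), 5.4)

  # swapping cluster indices swaps nothing biologically
  asg2 <- asg; asg2$cluster <- 3L - asg$cluster
  expect_equal(label_egi_lgi(asg2, prof)$label, lab$label)
  # sample order invariance
  perm <- sample(4)
  expect_equal(
    label_egi_lgi(asg[perm, ], prof)$label[order(asg$sample_id[perm])],
    lab$label[order(asg$sample_id)]
  )

  tie <- prof; tie$rank <- c(3, 3, 3, 3)
  expect_error(label_egi_lgi(asg, tie), "indistinguishable")
})

test_that("per-hallmark Mann-Whitney comparisons match exact enumeration", {
  mk_prof <- function(egi, lgi, hallmark = "inflammation") {
    n <- length(egi) + length(lgi)
    tibble::tibble(
      sample_id = paste0("s", seq_len(n)), hallmark = hallmark,
      mean_vaf = c(egi, lgi), n_mut = 2L, imputed = FALSE
    )
  }
  mk_lab <- function(n_egi, n_lgi) {
    tibble::tibble(sample_id = paste0("s", seq_len(n_egi + n_lgi)),
                   label = c(rep("EGI", n_egi), rep("LGI", n_lgi)))
  }
  res <- compare_hallmark_vaf(mk_prof(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)),
                              mk_lab(3, 3))
  expect_equal(res$p_raw, 0.1)                    # 2/20 extreme rank splits
  expect_equal(res$p_raw, mw_enum_p(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3)))
  expect_equal(res$estimate, 0.3)
  expect_equal(res$direction, "LGI")

  # balanced interleaving (U one step from its null mean): exact p = 1
  same <- compare_hallmark_vaf(mk_prof(c(0.2, 0.3, 0.5), c(0.1, 0.4, 0.6)),
                               mk_lab(3, 3))
  expect_equal(same$p_raw, 1)
  expect_equal(same$p_raw, mw_enum_p(c(0.1, 0.4, 0.6), c(0.2, 0.3, 0.5)))

  # continuity-corrected normal approximation tracks enumeration closely
  # at n = 8 (the approximation's own worst case sits just above 0.01)
  withr::with_seed(77, {
    for (rep in 1:5) {
      x <- round(runif(8), 3); y <- round(runif(8), 3)
      exact <- mw_enum_p(x, y)
      approx <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      expect_lt(abs(exact - approx), 0.02)
    }
  })
})

test_that("planted hallmark shifts are detected only where planted", {
  cfg <- small_cohort_config(n = 40, seed = 3)
  co <- generate_cohort(cfg)
  prof <- suppressMessages(rank_hallmarks(
    compute_hallmark_profiles(co$mutations, co$hallmark_map, impute = TRUE)))
  labels <- co$truth; labels$label <- labels$group
  res <- compare_hallmark_vaf(prof, labels)
  big <- res$feature[res$significant]
  expect_true(all(c("genome_instability", "immune_evasion", "inflammation")
                  %in% big))
  # proliferative signaling sits at the same rank in both orders: no shift
  expect_false("proliferative_signaling" %in% big)
})
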