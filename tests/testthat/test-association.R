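mk_labels <- function(n_egi, n_lgi) {
  tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_egi + n_lgi)),
                 label = c(rep("EGI", n_egi), rep("LGI", n_lgi)))
}
mk_calls <- function(sigs) {
  tibble::tibble(sample_id = sprintf("s%03d", seq_along(sigs)),
                 signature = sigs, value = 0.8, kind = "CN", tie = FALSE)
}

test_that("dominant-count tables have cluster-size margins", {
  lab <- mk_labels(2, 2)
  tabs <- dominant_count_tables(lab, mk_calls(c("S", "S", "T", "T")))
  s <- tabs[tabs$signature == "S", ]
  expect_equal(unlist(s[, -1], use.names = FALSE), c(2L, 0L, 0L, 2L))

  expect_error(
    dominant_count_tables(lab[1:3, ], mk_calls(c("S", "S", "T", "T"))),
    "s004")

  co <- generate_cohort(small_cohort_config(n = 20, seed = 2))
  lab2 <- co$truth; lab2$label <- lab2$group
  tabs2 <- dominant_count_tables(lab2, dominant_calls(co$cn_exposures, "CN"))
  expect_true(all(tabs2$egi_dom + tabs2$egi_other == 20))
  expect_true(all(tabs2$lgi_dom + tabs2$lgi_other == 20))
})

test_that("contingency tests pick chi-square vs Fisher by expected counts", {
  flat <- test_contingency(10, 10, 10, 10)
  expect_equal(flat$method, "chisq")
  expect_equal(flat$p_raw, 1)

  fish <- test_contingency(1, 9, 2, 10)   # expected dominant cells below 5
  expect_equal(fish$method, "fisher")
  expect_equal(fish$p_raw, fisher_enum_p(1, 9, 2, 10), tolerance = 1e-9)

  degen <- test_contingency(0, 0, 5, 5)
  expect_true(degen$degenerate)
  expect_equal(degen$p_raw, 1)

  # same proportions at 1000x the counts: p can only drop
  small <- test_contingency(3, 1, 2, 4)
  big <- test_contingency(3000, 1000, 2000, 4000)
  expect_lte(big$p_raw, small$p_raw)
})

test_that("Fisher p equals hypergeometric enumeration on all small tables", {
  withr::with_seed(41, {
    for (rep in 1:50) {
      tot <- sample(4:40, 1)
      cuts <- sort(sample(0:tot, 3, replace = TRUE))
      a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
      d <- tot - cuts[3]
      if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
      got <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
      expect_equal(got, fisher_enum_p(a, b, c, d), tolerance = 1e-9)
    }
  })
})

test_that("BH and Bonferroni follow their step rules and dominance", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(6, {
    p <- runif(20)
    expect_true(all(bh_adjust(p) >= p))
    expect_true(all(bonferroni_adjust(p) >= bh_adjust(p)))
  })
})

test_that("signature cluster tests adjust across signatures", {
  lab <- mk_labels(30, 30)
  sigs <- c(rep("A", 25), rep("B", 5), rep("B", 25), rep("A", 5))
  res <- signature_cluster_tests(lab, mk_calls(sigs))
  expect_equal(res$p_adj, bh_adjust(res$p_raw))
  expect_true(all(res$significant))
  expect_equal(res$direction[res$feature == "A"], "EGI")
  expect_equal(res$direction[res$feature == "B"], "LGI")
})

test_that("logistic OR on a binary predictor matches the 2x2 cross product", {
  a <- 30; b <- 10; c <- 20; d <- 40   # EGI/LGI x feature 1/0
  vals <- c(rep(1, a), rep(0, c), rep(1, b), rep(0, d))
  labs <- c(rep("EGI", a + c), rep("LGI", b + d))
  res <- logistic_or(vals, labs)
  # LGI coded 1: OR for feature = (b*c)/(a*d)
  expect_equal(res$estimate, (b * c) / (a * d), tolerance = 1e-6)
  expect_equal(res$direction, "EGI")
})

test_that("a permutation-balanced feature yields OR near 1", {
  vals <- rep(c(0.1, 0.2, 0.3, 0.4), times = 50)
  labs <- rep(c("EGI", "LGI"), each = 100)
  res <- logistic_or(vals, labs)
  expect_equal(res$estimate, 1, tolerance = 1e-6)
  expect_gt(res$p_raw, 0.99)
})

test_that("planted feature shifts reach Bonferroni significance with direction", {
  withr::with_seed(91, {
    n <- 500
    feats <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:(2 * n)),
      shifted = c(rnorm(n, 0), rnorm(n, 1)),       # +1 SD in LGI
      null1 = rnorm(2 * n), null2 = rnorm(2 * n)
    )
    lab <- mk_labels(n, n)
    res <- feature_association_table(feats, lab, adjust = "bonferroni")
    sh <- res[res$feature == "shifted", ]
    expect_lt(sh$p_adj, 0.05)
    expect_equal(sh$direction, "LGI")
    expect_gt(sh$estimate, 1)
  })
})

test_that("relabelling EGI/LGI inverts every odds ratio", {
  withr::with_seed(12, {
    feats <- tibble::tibble(sample_id = sprintf("s%03d", 1:80),
                            f1 = rnorm(80, rep(c(0, 0.5), each = 40)),
                            f2 = rnorm(80))
    lab <- mk_labels(40, 40)
    flipped <- lab
    flipped$label <- ifelse(lab$label == "EGI", "LGI", "EGI")
    a <- feature_association_table(feats, lab)
    b <- feature_association_table(feats, flipped)
    expect_equal(a$estimate * b$estimate, rep(1, 2), tolerance = 1e-9)
  })
})

test_that("degenerate logistic inputs are flagged", {
  lab <- mk_labels(10, 10)
  expect_error(logistic_or(rnorm(10), rep("EGI", 10)), "both clusters")
  res <- logistic_or(rep(2, 20), lab$label)
  expect_true(res$degenerate)
  expect_equal(res$estimate, 1)
  sep <- logistic_or(c(rep(0, 20), rep(1, 20)),
                     c(rep("EGI", 20), rep("LGI", 20)))
  expect_true(sep$separated)
})

test_that("substitution-VAF correlation matches the covariance formula", {
  # constructed genes where mean VAF is linear in count -> r = 1
  map <- tibble::tibble(gene = paste0("G", 1:4), hallmark = "inflammation")
  counts <- c(2, 3, 4, 5)
  muts <- dplyr::bind_rows(lapply(1:4, function(i) {
    mutation_fixture(sample_id = "P1", gene = rep(paste0("G", i), counts[i]),
                     vaf = 0.1 * counts[i])
  }))
  res <- suppressMessages(substitution_vaf_correlation(muts, map))
  expect_equal(res$estimate[res$feature == "C>A"], 1, tolerance = 1e-9)

  # 4-gene hand-computable fixture vs direct Pearson formula
  vafs <- list(c(0.2, 0.4), c(0.5, 0.7, 0.3), c(0.9), c(0.25, 0.35, 0.15, 0.45))
  muts2 <- dplyr::bind_rows(lapply(1:4, function(i) {
    mutation_fixture(sample_id = "P1", gene = rep(paste0("G", i),
                                                  length(vafs[[i]])),
                     vaf = vafs[[i]])
  }))
  res2 <- suppressMessages(substitution_vaf_correlation(muts2, map))
  x <- lengths(vafs)
  y <- vapply(vafs, mean, numeric(1))
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$estimate[res2$feature == "C>A"], r_oracle,
               tolerance = 1e-12)
  expect_equal(res2$n_genes[res2$feature == "C>A"], 4L)

  # classes seen in fewer than 3 genes are skipped
  expect_false("T>G" %in% res2$feature)
})

test_that("count-VAF correlation is null when counts are shuffled", {
  withr::with_seed(61, {
    map <- tibble::tibble(gene = paste0("G", 1:60), hallmark = "inflammation")
    counts <- sample(2:30, 60, replace = TRUE)
    muts <- dplyr::bind_rows(lapply(1:60, function(i) {
      mutation_fixture(sample_id = "P1",
                       gene = rep(paste0("G", i), counts[i]),
                       vaf = pmin(pmax(rnorm(counts[i], 0.4, 0.1), 0.01), 0.99))
    }))
    res <- suppressMessages(substitution_vaf_correlation(muts, map))
    expect_lt(abs(res$estimate[res$feature == "C>A"]), 0.3)
  })
})
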