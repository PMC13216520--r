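# two-sample Scholz-Stephens A2akN statistic (midrank tie version)
ad_statistic_2sample <- function(x, y) {
  n <- c(length(x), length(y))
  N <- sum(n)
  pooled <- c(x, y)
  z <- sort(unique(pooled))
  l <- as.numeric(table(factor(pooled, levels = z)))
  f <- rbind(as.numeric(table(factor(x, levels = z))),
             as.numeric(table(factor(y, levels = z))))
  B <- cumsum(l) - l / 2                      # pooled obs < z_j plus half equal
  denom <- B * (N - B) - N * l / 4
  inner <- 0
  for (i in 1:2) {
    M <- cumsum(f[i, ]) - f[i, ] / 2
    term <- (l / N) * (N * M - n[i] * B)^2 / denom
    inner <- inner + sum(term[denom > 0]) / n[i]
  }
  (N - 1) / N * inner
}

ad_variance <- function(n) {
  k <- length(n)
  N <- sum(n)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  i <- seq_len(N - 2)
  g <- sum(vapply(i, function(ii) sum(1 / ((N - ii) * seq(ii + 1, N - 1))),
                  numeric(1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
}

# asymptotic p for the standardized statistic: quadratic interpolation of
# log(significance) against the Scholz-Stephens critical-value curves for m=1;
# outside the tabulated range the p-value is capped at 0.25 / floored at 0.001
# (the quadratic is only trustworthy between the tabulated points)
ad_asymptotic_p <- function(tm, m = 1) {
  sig <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  crit <- b0 + b1 / sqrt(m) + b2 / m
  if (tm <= min(crit)) return(0.25)
  if (tm >= max(crit)) return(0.001)
  fit <- stats::lm.fit(cbind(1, crit, crit^2), log(sig))
  p <- exp(sum(fit$coefficients * c(1, tm, tm^2)))
  min(max(p, 0), 1)
}

#' Two-sample Anderson-Darling k-sample test
#'
#' Rank-based Anderson-Darling comparison of two samples (the k-sample
#' statistic of Scholz and Stephens with midrank tie handling), sensitive to
#' differences in both location and shape. The asymptotic p-value
#' interpolates the published critical-value curves of the standardized
#' statistic; when the combined sample size is at most `exact_max_n`, the
#' exact permutation p-value over all splits is computed instead. A constant
#' pooled sample yields p = 1 with a degenerate flag.
#'
#' @param x,y Numeric samples (each of size at least 2).
#' @param exact_max_n Combined-size ceiling for exact permutation enumeration.
#' @return One-row tibble: `statistic` (A2akN), `t_stat` (standardized),
#'   `p`, `method` (`"exact_permutation"`/`"asymptotic"`/`"degenerate"`),
#'   `degenerate`.
#' @export
ad_ksample_test <- function(x, y, exact_max_n = 12) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(tibble::tibble(statistic = 0, t_stat = NA_real_, p = 1,
                          method = "degenerate", degenerate = TRUE))
  }
  n <- c(length(x), length(y))
  N <- sum(n)
  obs <- ad_statistic_2sample(x, y)
  sigma <- sqrt(ad_variance(n))
  tm <- (obs - 1) / sigma
  if (N <= exact_max_n) {
    splits <- utils::combn(N, n[1])
    stats_perm <- apply(splits, 2, function(idx) {
      ad_statistic_2sample(pooled[idx], pooled[-idx])
    })
    p <- mean(stats_perm >= obs - 1e-12)
    method <- "exact_permutation"
  } else {
    p <- ad_asymptotic_p(tm)
    method <- "asymptotic"
  }
  tibble::tibble(statistic = obs, t_stat = tm, p = p, method = method,
                 degenerate = FALSE)
}

#' Cohen's d with confidence interval and magnitude bin
#'
#' Standardized mean difference `(mean(x) - mean(y)) / pooled SD` (n-1
#' denominators), with the large-sample standard error
#' `sqrt((nx+ny)/(nx*ny) + d^2 / (2(nx+ny-2)))` and a central-t confidence
#' interval. `|d|` is binned as negligible (< 0.2), small (< 0.5), medium
#' (< 0.8) or large (>= 0.8).
#'
#' @param x,y Numeric samples (each of size at least 2).
#' @param confidence Confidence level (default 0.95).
#' @return One-row tibble: `d`, `ci_lo`, `ci_hi`, `bin`, `degenerate`.
#' @export
cohens_d_ci <- function(x, y, confidence = 0.95) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) {
    return(tibble::tibble(d = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          bin = NA_character_, degenerate = TRUE))
  }
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt((nx + ny) / (nx * ny) + d^2 / (2 * (nx + ny - 2)))
  tq <- qt(1 - (1 - confidence) / 2, df = nx + ny - 2)
  bin <- cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
             labels = c("negligible", "small", "medium", "large"))
  tibble::tibble(d = d, ci_lo = d - tq * se, ci_hi = d + tq * se,
                 bin = as.character(bin), degenerate = FALSE)
}

#' Bootstrap replicate dominant-signature counts per cluster
#'
#' For each of `R` replicates, patients are resampled with replacement within
#' each cluster (cluster sizes preserved) and the number whose dominant
#' signature equals each catalog signature is recorded. Deterministic given
#' `seed`.
#'
#' @param labels Tibble `sample_id`, `label`.
#' @param calls Dominant-call tibble from [dominant_calls()].
#' @param R Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (default 123).
#' @return Long tibble: `signature`, `label`, `replicate`, `count`; observed
#'   counts attached as attribute `"observed"`.
#' @export
bootstrap_dominant_counts <- function(labels, calls, R = 1000, seed = 123) {
  if (R < 2) abort("R must be at least 2")
  dat <- dplyr::inner_join(calls, labels[, c("sample_id", "label")],
                           by = "sample_id")
  if (length(unique(dat$label)) < 2) abort("both clusters must be non-empty")
  sigs <- sort(unique(dat$signature))
  out <- with_seed(seed, {
    dplyr::bind_rows(lapply(c("EGI", "LGI"), function(g) {
      code <- match(dat$signature[dat$label == g], sigs)
      n_g <- length(code)
      draws <- matrix(code[sample.int(n_g, n_g * R, replace = TRUE)], nrow = R)
      dplyr::bind_rows(lapply(seq_along(sigs), function(k) {
        tibble::tibble(signature = sigs[k], label = g,
                       replicate = seq_len(R),
                       count = as.integer(rowSums(draws == k)))
      }))
    }))
  })
  attr(out, "observed") <- dat |>
    dplyr::count(.data$signature, .data$label, name = "count")
  out
}

#' Bootstrap Anderson-Darling comparison of dominant-signature counts
#'
#' The full bootstrap procedure: replicate dominant counts per cluster
#' ([bootstrap_dominant_counts()]), an Anderson-Darling comparison of the two
#' replicate distributions per signature, Benjamini-Hochberg adjustment
#' across signatures, and Cohen's d (EGI minus LGI replicate counts) with its
#' confidence interval and magnitude bin.
#'
#' @inheritParams bootstrap_dominant_counts
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble per signature: `feature`, `ad_stat`, `p_raw`, `p_adj`,
#'   `cohen_d`, `d_lo`, `d_hi`, `d_bin`, `significant`; replicate counts kept
#'   as attribute `"replicates"`.
#' @export
bootstrap_signature_comparison <- function(labels, calls, R = 1000,
                                           seed = 123, alpha = 0.05) {
  reps <- bootstrap_dominant_counts(labels, calls, R = R, seed = seed)
  sigs <- unique(reps$signature)
  rows <- lapply(sigs, function(s) {
    e <- reps$count[reps$signature == s & reps$label == "EGI"]
    l <- reps$count[reps$signature == s & reps$label == "LGI"]
    ad <- ad_ksample_test(e, l)
    d <- cohens_d_ci(e, l)
    tibble::tibble(feature = s, ad_stat = ad$statistic, p_raw = ad$p,
                   cohen_d = d$d, d_lo = d$ci_lo, d_hi = d$ci_hi,
                   d_bin = d$bin, degenerate = ad$degenerate | d$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha & !out$degenerate
  out <- out[, c("feature", "ad_stat", "p_raw", "p_adj", "cohen_d",
                 "d_lo", "d_hi", "d_bin", "significant", "degenerate")]
  attr(out, "replicates") <- reps
  out
}
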