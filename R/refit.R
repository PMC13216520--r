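# golden-section minimization of f on [lo, hi]
golden_section <- function(f, lo = 0, hi = 1, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a)
  d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Refit signature weights for one mutation spectrum
#'
#' Greedy forward refitting of per-sample signature exposures against a
#' reference catalog, in the style of deconstructSigs: the observed 96-channel
#' counts are normalized to fractions, and the algorithm repeatedly re-opt-
#' imizes (by golden-section search on \[0, 1\]) the single signature weight
#' whose adjustment most reduces the sum of squared errors between the
#' weighted catalog mix and the observed fractions, stopping when the best
#' achievable SSE improvement falls below `tol`. The raw weights are then
#' normalized against the observed spectrum (fractions summing to one),
#' weights below `trim` are zeroed, and the residual mass `1 - sum(weights)`
#' (floored at 0) is reported as unexplained.
#'
#' @param spectrum Named 96-vector of channel counts, or a one-row spectra
#'   tibble from [build_spectra()].
#' @param catalog Catalog tibble from [read_signature_catalog()] /
#'   [synthetic_signature_catalog()].
#' @param trim Weights below this value are discarded (default 0.06).
#' @param tol Minimum SSE improvement to continue iterating (default 1e-3).
#' @param max_iter Safety cap on greedy iterations.
#' @return Object of class `signature_fit`: `weights` (named, sum <= 1),
#'   `unexplained`, `sse`, `n_mutations`, `sample_id`.
#' @export
fit_signature_weights <- function(spectrum, catalog, trim = 0.06,
                                  tol = 1e-3, max_iter = 100) {
  channels <- sbs96_channels()
  sample_id <- NA_character_
  if (is.data.frame(spectrum)) {
    stopifnot(nrow(spectrum) == 1)
    sample_id <- spectrum$sample_id
    spectrum <- spectrum_counts(spectrum, 1)
  }
  if (is.null(names(spectrum))) names(spectrum) <- channels
  total <- sum(spectrum)
  if (total <= 0) abort("cannot fit signatures to a zero-total spectrum")
  obs <- as.numeric(spectrum[channels]) / total

  sigs <- setdiff(names(catalog), "channel")
  S <- as.matrix(catalog[match(channels, catalog$channel), sigs, drop = FALSE])

  fit_greedy <- function(active) {
    w <- setNames(rep(0, length(active)), active)
    recon <- rep(0, 96)
    sse <- sum((obs - recon)^2)
    for (it in seq_len(max_iter)) {
      best <- list(sig = NULL, w = NA_real_, sse = sse)
      for (s in active) {
        base <- recon - w[s] * S[, s]
        opt <- golden_section(function(v) sum((obs - base - v * S[, s])^2))
        if (opt$value < best$sse) best <- list(sig = s, w = opt$x, sse = opt$value)
      }
      if (is.null(best$sig) || (sse - best$sse) < tol) break
      recon <- recon - w[best$sig] * S[, best$sig] + best$w * S[, best$sig]
      w[best$sig] <- best$w
      sse <- best$sse
    }
    list(w = w, sse = sse)
  }

  fit <- fit_greedy(sigs)
  w_final <- fit$w
  if (sum(w_final) > 0) {
    w_final <- w_final / sum(w_final)   # fractions of the observed spectrum
  }
  w_final[w_final < trim] <- 0

  structure(list(
    sample_id = sample_id,
    weights = w_final,
    unexplained = max(0, 1 - sum(w_final)),
    sse = fit$sse,
    n_mutations = as.integer(total)
  ), class = "signature_fit")
}

#' Refit signature weights for a whole cohort
#'
#' Applies [fit_signature_weights()] to every retained spectrum row.
#'
#' @param spectra Spectra tibble from [build_spectra()] (already filtered with
#'   [apply_min_mutation_filter()] if desired).
#' @inheritParams fit_signature_weights
#' @return Tibble: `sample_id`, `n_mutations`, `unexplained`, `sse`, plus one
#'   weight column per catalog signature.
#' @export
fit_cohort_weights <- function(spectra, catalog, trim = 0.06, tol = 1e-3) {
  rows <- lapply(seq_len(nrow(spectra)), function(i) {
    f <- fit_signature_weights(spectra[i, ], catalog, trim = trim, tol = tol)
    dplyr::bind_cols(
      tibble::tibble(sample_id = f$sample_id, n_mutations = f$n_mutations,
                     unexplained = f$unexplained, sse = f$sse),
      tibble::as_tibble(as.list(f$weights))
    )
  })
  dplyr::bind_rows(rows)
}

#' Dominant signature of a weight or exposure row
#'
#' The signature with the highest fitted weight (SBS) or exposure (CN) in a
#' sample. Exact ties resolve to the lexicographically smallest signature name
#' and are flagged.
#'
#' @param row Named numeric vector of weights/exposures, or a one-row tibble
#'   whose non-id numeric columns are signatures.
#' @param kind `"SBS"` or `"CN"`.
#' @return Tibble: `sample_id`, `signature`, `value`, `kind`, `tie`.
#' @export
dominant_signature <- function(row, kind = c("SBS", "CN")) {
  kind <- match.arg(kind)
  sample_id <- NA_character_
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1)
    if ("sample_id" %in% names(row)) sample_id <- row$sample_id
    drop <- intersect(c("sample_id", "n_mutations", "unexplained", "sse", "total"),
                      names(row))
    row <- unlist(row[, setdiff(names(row), drop)])
  }
  if (length(row) < 1) abort("need at least one signature")
  if (all(row == 0)) abort("no attributable signature: all weights are zero")
  mx <- max(row)
  hits <- sort(names(row)[row == mx])
  tibble::tibble(sample_id = sample_id, signature = hits[1],
                 value = unname(mx), kind = kind, tie = length(hits) > 1)
}

#' Dominant signatures for every sample of a weight/exposure table
#'
#' @param tbl Tibble with `sample_id` plus one numeric column per signature
#'   (fit table from [fit_cohort_weights()] or an exposure matrix).
#' @inheritParams dominant_signature
#' @return Tibble with one row per sample: `sample_id`, `signature`, `value`,
#'   `kind`, `tie`.
#' @export
dominant_calls <- function(tbl, kind = c("SBS", "CN")) {
  kind <- match.arg(kind)
  dplyr::bind_rows(lapply(seq_len(nrow(tbl)), function(i) {
    dominant_signature(tbl[i, ], kind = kind)
  }))
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature refit", if (!is.na(x$sample_id)) paste0("for ", x$sample_id),
      "\n  mutations:", x$n_mutations,
      "\n  SSE:", format(x$sse, digits = 4),
      "\n  unexplained:", format(x$unexplained, digits = 4), "\n")
  w <- x$weights[x$weights > 0]
  if (length(w)) {
    cat("  weights:\n")
    for (s in names(sort(w, decreasing = TRUE))) {
      cat(sprintf("    %-10s %.3f\n", s, w[s]))
    }
  }
  invisible(x)
}
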