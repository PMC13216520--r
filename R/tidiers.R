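#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a signature refit
#'
#' One row per catalog signature with its fitted weight.
#'
#' @param x A `signature_fit` object.
#' @param ... Unused.
#' @return Tibble: `signature`, `weight`.
#' @method tidy signature_fit
#' @export
tidy.signature_fit <- function(x, ...) {
  tibble::tibble(signature = names(x$weights), weight = unname(x$weights))
}

#' @rdname tidy.signature_fit
#' @return `glance()`: one-row tibble with `n_mutations`, `n_signatures`
#'   (nonzero weights), `sse`, `unexplained`.
#' @method glance signature_fit
#' @export
glance.signature_fit <- function(x, ...) {
  tibble::tibble(n_mutations = x$n_mutations,
                 n_signatures = sum(x$weights > 0),
                 sse = x$sse, unexplained = x$unexplained)
}

#' Tidy a hallmark PCA
#'
#' @param x A `hallmark_pca` object.
#' @param matrix `"scores"`, `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @return Tibble of the requested component.
#' @method tidy hallmark_pca
#' @export
tidy.hallmark_pca <- function(x, matrix = c("scores", "loadings",
                                            "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         eigenvalues = tibble::tibble(
           component = seq_along(x$var_explained),
           sdev = x$sdev,
           var_explained = x$var_explained,
           cum_var_explained = cumsum(x$var_explained)
         ))
}

#' Summaries of a pipeline run
#'
#' @param x A `hallmark_pipeline` object.
#' @param ... Unused.
#' @return One-row tibble with sample bookkeeping, selected k, cluster sizes
#'   and average silhouette width.
#' @method glance hallmark_pipeline
#' @export
glance.hallmark_pipeline <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    n_samples = m$n_input_samples,
    n_profiled = m$n_profiled,
    n_spectra_retained = m$n_spectra_retained,
    k = x$k,
    n_egi = m$n_egi %||% NA_integer_,
    n_lgi = m$n_lgi %||% NA_integer_,
    avg_silhouette = if (!is.null(x$silhouette))
      attr(x$silhouette, "avg_width") else NA_real_,
    seed = m$seed
  )
}
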