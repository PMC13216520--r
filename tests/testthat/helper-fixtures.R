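# shared fixtures, built in code at test time

mutation_fixture <- function(sample_id = "S1", gene = "G1", vaf = 0.5,
                             ref = "C", alt = "A", context3 = "ACA") {
  n <- max(lengths(list(sample_id, gene, vaf, ref, alt, context3)))
  tibble::tibble(
    sample_id = rep_len(sample_id, n), gene = rep_len(gene, n),
    chrom = "1", pos = seq_len(n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    vaf = rep_len(vaf, n), context3 = rep_len(context3, n)
  )
}

write_fixture_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

tiny_catalog <- function(n_signatures = 3, seed = 11) {
  synthetic_signature_catalog(n_signatures = n_signatures, seed = seed)
}

small_cohort_config <- function(n = 30, seed = 42, ...) {
  cohort_config(n_egi = n, n_lgi = n, seed = seed, ...)
}

# sample mutations from a fixed channel mixture for one sample
spectrum_mutations <- function(probs, n, sample_id = "S1", seed = 1) {
  channels <- sbs96_channels()
  withr::with_seed(seed, {
    ch <- sample(channels, n, replace = TRUE, prob = probs)
    tibble::tibble(
      sample_id = sample_id, gene = "G1", chrom = "1", pos = seq_len(n),
      ref = substr(ch, 3, 3), alt = substr(ch, 5, 5),
      vaf = 0.5,
      context3 = paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
    )
  })
}

# adjusted Rand index between two label vectors (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent two-sided Fisher p: full hypergeometric enumeration over all
# tables with the observed margins
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent exact two-sided Mann-Whitney p: enumerate all group splits
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_from <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  obs <- u_from(seq_len(nx))
  mu <- nx * (n - nx) / 2
  splits <- utils::combn(n, nx)
  us <- apply(splits, 2, u_from)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}
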