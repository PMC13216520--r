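test_that("pyrimidine-strand normalization maps both strands to one channel", {
  got <- classify_sbs96(tibble::tibble(
    ref = c("C", "G"), alt = c("A", "T"), context3 = c("ACA", "TGT")
  ))
  expect_equal(got$channel, c("A[C>A]A", "A[C>A]A"))
  expect_true(all(is.na(got$reject_reason)))
})

test_that("exhaustive enumeration of substitutions yields exactly 96 channels", {
  grid <- expand.grid(p5 = DNA <- c("A", "C", "G", "T"), ref = DNA,
                      p3 = DNA, alt = DNA, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  muts <- tibble::tibble(ref = grid$ref, alt = grid$alt,
                         context3 = paste0(grid$p5, grid$ref, grid$p3))
  got <- classify_sbs96(muts)
  expect_true(all(!is.na(got$channel)))
  hit <- table(got$channel)
  expect_equal(sort(names(hit)), sort(sbs96_channels()))
  expect_equal(length(unique(got$channel)), 96)
  # each pyrimidine channel is reachable from exactly 2 stranded forms
  expect_true(all(hit == 2))
  # 16 flank contexts per substitution class
  cls <- sub(".*\\[(.+)\\].*", "\\1", sbs96_channels())
  expect_equal(as.integer(table(cls)), rep(16L, 6))
  expect_equal(sort(unique(cls)), substitution_classes())
})

test_that("classification is strand-involutive on random records", {
  withr::with_seed(5, {
    channels <- sbs96_channels()
    ch <- sample(channels, 50, replace = TRUE)
    fwd <- tibble::tibble(
      ref = substr(ch, 3, 3), alt = substr(ch, 5, 5),
      context3 = paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
    )
    rev <- tibble::tibble(
      ref = chartr("ACGT", "TGCA", fwd$ref),
      alt = chartr("ACGT", "TGCA", fwd$alt),
      context3 = vapply(fwd$context3, function(s)
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
        character(1), USE.NAMES = FALSE)
    )
    expect_equal(classify_sbs96(fwd)$channel, ch)
    expect_equal(classify_sbs96(rev)$channel, ch)
  })
})

test_that("indels, complex variants and inconsistent contexts are rejected", {
  got <- classify_sbs96(tibble::tibble(
    ref = c("CT", "-", "C", "C"), alt = c("C", "A", "CA", "A"),
    context3 = c("ACA", "ACA", "ACA", "AGA")
  ))
  expect_equal(got$reject_reason,
               c("indel_or_complex", "indel_or_complex", "indel_or_complex",
                 "context_mismatch"))
  expect_true(all(is.na(got$channel)))
})

test_that("spectra tally per-sample channel counts", {
  empty <- build_spectra(mutation_fixture()[0, ])
  expect_equal(nrow(empty), 0)

  five <- mutation_fixture(sample_id = rep("S1", 5))
  sp <- build_spectra(five)
  expect_equal(sp$total, 5L)
  expect_equal(sp[["A[C>A]A"]], 5L)
  expect_equal(sum(sp[, sbs96_channels()]), 5)

  # hand-tallied mixed fixture across two samples
  mixed <- tibble::tibble(
    sample_id = c(rep("S1", 7), rep("S2", 5)),
    gene = "G1", chrom = "1", pos = 1:12,
    ref      = c("C", "C", "G", "T", "T", "A", "C",  "C", "C", "CT", "T", "G"),
    alt      = c("A", "A", "T", "C", "C", "G", "G",  "T", "T", "C",  "G", "A"),
    vaf = 0.4,
    context3 = c("ACA", "ACA", "TGT", "ATC", "ATC", "CAG", "CCG",
                 "GCG", "GCG", "ACA", "TTT", "AGA")
  )
  sp2 <- build_spectra(mixed)
  s1 <- sp2[sp2$sample_id == "S1", ]
  s2 <- sp2[sp2$sample_id == "S2", ]
  expect_equal(s1$total, 7L)        # all S1 records classify (G>T/A>G revcomp)
  expect_equal(s1[["A[C>A]A"]], 3L) # 2 direct + 1 via TGT revcomp
  expect_equal(s1[["A[T>C]C"]], 2L)
  expect_equal(s1[["C[T>C]G"]], 1L) # A>G @ CAG -> revcomp CTG ctx, T>C
  expect_equal(s1[["C[C>G]G"]], 1L)
  expect_equal(s2$total, 4L)        # the "CT>C" indel is rejected
  expect_equal(s2[["G[C>T]G"]], 2L)
  expect_equal(s2[["T[T>G]T"]], 1L)
  expect_equal(s2[["T[C>T]T"]], 1L) # G>A @ AGA -> revcomp TCT
  expect_equal(attr(sp2, "rejections")$indel_or_complex, 1L)
})

test_that("minimum-mutation filter keeps only adequately mutated samples", {
  sp <- build_spectra(mutation_fixture(
    sample_id = c(rep("A", 49), rep("B", 50), rep("C", 51))
  ))
  filt <- apply_min_mutation_filter(sp, threshold = 50)
  expect_equal(sort(filt$retained$sample_id), c("B", "C"))
  expect_equal(filt$excluded, "A")

  all_kept <- apply_min_mutation_filter(sp, threshold = 1)
  expect_equal(nrow(all_kept$retained), 3)
  expect_warning(none <- apply_min_mutation_filter(sp, threshold = 100),
                 "below")
  expect_equal(nrow(none$retained), 0)

  # monotonicity: raising the threshold never increases retained count
  kept <- vapply(c(1, 10, 50, 51, 100), function(th)
    nrow(suppressWarnings(apply_min_mutation_filter(sp, th))$retained),
    numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("the CN classification scheme has 48 channels and is validated", {
  ch <- cn48_channels()
  expect_equal(length(ch), 48)
  expect_equal(anyDuplicated(ch), 0)
  cat48 <- tibble::tibble(channel = ch, CN1 = 1 / 48, CN2 = 2 / 48)
  expect_invisible(validate_cn_catalog(cat48))
  expect_error(validate_cn_catalog(cat48[-1, ]), "48")
  bad <- cat48; bad$CN1[3] <- -1
  expect_error(validate_cn_catalog(bad), "nonnegative")
})
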