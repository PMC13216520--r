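#' Synthetic SBS signature catalog
#'
#' Builds a synthetic reference catalog of SBS96 spectra for simulation and
#' testing. Signatures are random sparse-ish probability vectors over the 96
#' channels, each concentrated on a distinct subset of channels so that
#' pairwise spectra are well separated in L1. These are synthetic stand-ins,
#' named `sSBS1, sSBS2, ...` to avoid confusion with curated catalogs.
#'
#' @param n_signatures Number of signatures to generate.
#' @param seed Integer seed; the catalog is a deterministic function of it.
#' @param concentration Dirichlet-like concentration of mass on each
#'   signature's preferred channels (smaller = peakier spectra).
#' @return Catalog tibble as from [read_signature_catalog()]: column `channel`
#'   plus one probability column per signature, each summing to 1.
#' @export
synthetic_signature_catalog <- function(n_signatures = 6, seed = 20240901,
                                        concentration = 0.08) {
  channels <- sbs96_channels()
  with_seed(seed, {
    out <- tibble::tibble(channel = channels)
    blocks <- split(seq_len(96), rep(seq_len(n_signatures), length.out = 96))
    for (i in seq_len(n_signatures)) {
      w <- rep(concentration, 96)
      w[blocks[[i]]] <- 1     # preferred channels carry most of the mass
      v <- rgamma(96, shape = w, rate = 1)
      out[[paste0("sSBS", i)]] <- v / sum(v)
    }
    out
  })
}

default_feature_effects <- function() {
  tibble::tribble(
    ~feature,                ~mean_egi, ~mean_lgi, ~sd,   ~kind,
    "mast_cells_resting",    0.020,     0.050,     0.020, "immune_cell",
    "mast_cells_activated",  0.050,     0.020,     0.020, "immune_cell",
    "t_cells_cd8",           0.100,     0.140,     0.040, "immune_cell",
    "macrophages_m0",        0.120,     0.080,     0.040, "immune_cell",
    "nk_cells_resting",      0.040,     0.040,     0.020, "immune_cell",
    "stemness_mrna",         0.450,     0.350,     0.100, "immune_feature",
    "proliferation",         0.300,     0.220,     0.100, "immune_feature",
    "emt_score",             0.000,     0.000,     0.300, "immune_feature"
  )
}

#' Configuration for a synthetic EGI/LGI cohort
#'
#' Collects every generative setting of the simulator: group sizes, the two
#' hallmark acquisition orders (earliest first), the rank-to-mean-VAF base
#' sequence, noise levels, mutation load, group SBS mixture weights, dominant
#' copy-number-signature probabilities, and per-feature group effects.
#'
#' Defaults emulate the study conditions: two latent groups of equal size
#' whose orderings differ chiefly in where genome instability and the
#' immune/inflammation hallmarks sit, with between-group hallmark VAF
#' differences of about 0.05 and ~8 mutations per hallmark per patient.
#'
#' @param n_egi,n_lgi Patients per group.
#' @param hallmark_order_egi,hallmark_order_lgi Permutations of
#'   [canonical_hallmarks()], earliest-acquired first.
#' @param vaf_base Strictly decreasing vector of 10 mean VAFs assigned by rank.
#' @param vaf_noise_sd SD of the Gaussian noise on each patient's per-hallmark
#'   mean VAF (truncated to (0.01, 0.99)).
#' @param muts_per_hallmark Poisson mean mutation count per hallmark per
#'   patient.
#' @param vaf_concentration Beta concentration of per-mutation VAF jitter
#'   around the hallmark mean (larger = tighter).
#' @param genes_per_hallmark Synthetic genes per hallmark (`<HALLMARK>_g<k>`).
#' @param sbs_weights_egi,sbs_weights_lgi Named mixing weights over catalog
#'   signatures; each must sum to 1.
#' @param cn_dominant_probs_egi,cn_dominant_probs_lgi Named probabilities that
#'   each CN signature is a patient's dominant one; each must sum to 1.
#' @param feature_effects Tibble with columns `feature`, `mean_egi`,
#'   `mean_lgi`, `sd`, `kind`.
#' @param seed Integer seed controlling the whole cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_egi = 200,
    n_lgi = 200,
    hallmark_order_egi = c(
      "genome_instability", "growth_suppressor_evasion",
      "proliferative_signaling", "replicative_immortality",
      "apoptosis_resistance", "metabolic_reprogramming", "angiogenesis",
      "invasion_metastasis", "immune_evasion", "inflammation"
    ),
    hallmark_order_lgi = c(
      "immune_evasion", "inflammation", "proliferative_signaling",
      "growth_suppressor_evasion", "replicative_immortality",
      "apoptosis_resistance", "metabolic_reprogramming", "angiogenesis",
      "invasion_metastasis", "genome_instability"
    ),
    vaf_base = seq(0.33, 0.27, length.out = 10),
    vaf_noise_sd = 0.015,
    muts_per_hallmark = 8,
    vaf_concentration = 150,
    genes_per_hallmark = 20,
    sbs_weights_egi = c(sSBS1 = 0.5, sSBS3 = 0.4, sSBS5 = 0.1),
    sbs_weights_lgi = c(sSBS1 = 0.4, sSBS2 = 0.3, sSBS4 = 0.2, sSBS6 = 0.1),
    cn_dominant_probs_egi = c(CN1 = 0.10, CN2 = 0.15, CN3 = 0.25,
                              CN4 = 0.20, CN5 = 0.20, CN6 = 0.10),
    cn_dominant_probs_lgi = c(CN1 = 0.40, CN2 = 0.15, CN3 = 0.10,
                              CN4 = 0.10, CN5 = 0.15, CN6 = 0.10),
    feature_effects = default_feature_effects(),
    seed = 123) {
  hallmarks <- canonical_hallmarks()
  stopifnot(
    n_egi >= 0, n_lgi >= 0,
    setequal(hallmark_order_egi, hallmarks),
    setequal(hallmark_order_lgi, hallmarks),
    !anyDuplicated(hallmark_order_egi), !anyDuplicated(hallmark_order_lgi),
    length(vaf_base) == 10, all(diff(vaf_base) < 0),
    all(vaf_base > 0 & vaf_base < 1),
    vaf_noise_sd > 0
  )
  for (w in list(sbs_weights_egi, sbs_weights_lgi,
                 cn_dominant_probs_egi, cn_dominant_probs_lgi)) {
    if (abs(sum(w) - 1) > 1e-9) abort("mixing weights must sum to 1")
    if (any(w < 0)) abort("mixing weights must be nonnegative")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with planted EGI/LGI structure
#'
#' Simulates a cohort from a [cohort_config()]: per-patient hallmark mean VAFs
#' are the rank-indexed `vaf_base` permuted by the group's acquisition order
#' plus truncated Gaussian noise; per-mutation VAFs are beta-jittered around
#' the hallmark mean; trinucleotide contexts are drawn from the 96-channel
#' distribution implied by the group's SBS mixture against `catalog` (half the
#' records are emitted on the purine strand to exercise strand normalization);
#' each patient receives one dominant CN signature encoded in an exposure row;
#' features are Gaussian with group-specific means. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param catalog Signature catalog tibble; defaults to
#'   [synthetic_signature_catalog()].
#' @return A `synthetic_cohort` list: `mutations`, `hallmark_map`,
#'   `cn_exposures`, `features`, `feature_kinds`, `truth` (sample_id, group),
#'   `truth_weights`, and the `config`.
#' @export
generate_cohort <- function(config, catalog = synthetic_signature_catalog()) {
  stopifnot(inherits(config, "cohort_config"))
  missing_sigs <- setdiff(
    c(names(config$sbs_weights_egi), names(config$sbs_weights_lgi)),
    setdiff(names(catalog), "channel")
  )
  if (length(missing_sigs) > 0) {
    abort(sprintf("config references signatures absent from the catalog: %s",
                  paste(missing_sigs, collapse = ", ")))
  }
  hallmarks <- canonical_hallmarks()
  channels <- sbs96_channels()
  sig_mat <- as.matrix(catalog[, setdiff(names(catalog), "channel")])
  rownames(sig_mat) <- catalog$channel

  hallmark_map <- tibble::tibble(
    gene = unlist(lapply(hallmarks, function(h)
      paste0(toupper(h), "_g", seq_len(config$genes_per_hallmark)))),
    hallmark = rep(hallmarks, each = config$genes_per_hallmark)
  )

  groups <- c(rep("EGI", config$n_egi), rep("LGI", config$n_lgi))
  n <- length(groups)
  ids <- if (n > 0) sprintf("S%04d", seq_len(n)) else character(0)

  group_spectrum <- function(w) {
    p <- as.vector(sig_mat[, names(w), drop = FALSE] %*% w)
    p / sum(p)
  }
  spectra <- list(EGI = group_spectrum(config$sbs_weights_egi),
                  LGI = group_spectrum(config$sbs_weights_lgi))
  orders <- list(EGI = config$hallmark_order_egi,
                 LGI = config$hallmark_order_lgi)
  cn_probs <- list(EGI = config$cn_dominant_probs_egi,
                   LGI = config$cn_dominant_probs_lgi)
  cn_sigs <- names(config$cn_dominant_probs_egi)
  fe <- config$feature_effects

  with_seed(config$seed, {
    mut_list <- vector("list", n)
    cn_mat <- matrix(0, nrow = n, ncol = length(cn_sigs),
                     dimnames = list(ids, cn_sigs))
    feat_mat <- matrix(NA_real_, nrow = n, ncol = nrow(fe),
                       dimnames = list(ids, fe$feature))

    for (i in seq_len(n)) {
      g <- groups[i]
      # per-patient hallmark mean VAFs: base value at the group's rank + noise
      mu <- config$vaf_base[match(hallmarks, orders[[g]])]
      mu <- pmin(pmax(mu + rnorm(10, 0, config$vaf_noise_sd), 0.01), 0.99)
      names(mu) <- hallmarks

      n_h <- rpois(10, config$muts_per_hallmark)
      total <- sum(n_h)
      if (total > 0) {
        hall <- rep(hallmarks, n_h)
        m <- mu[hall]
        nu <- config$vaf_concentration
        vaf <- pmin(pmax(rbeta(total, m * nu, (1 - m) * nu), 0.01), 0.99)
        gene <- paste0(toupper(hall), "_g",
                       sample.int(config$genes_per_hallmark, total, replace = TRUE))
        ch <- channels[sample.int(96, total, replace = TRUE, prob = spectra[[g]])]
        ref <- substr(ch, 3, 3)
        alt <- substr(ch, 5, 5)
        ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
        # report about half of the records on the purine strand, as MAFs do
        flip <- runif(total) < 0.5
        if (any(flip)) {
          ref[flip] <- chartr("CT", "GA", ref[flip])
          alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
          ctx[flip] <- revcomp(ctx[flip])
        }
        mut_list[[i]] <- tibble::tibble(
          sample_id = ids[i], gene = gene,
          chrom = as.character(sample.int(22, total, replace = TRUE)),
          pos = sample.int(1e8, total, replace = TRUE),
          ref = ref, alt = alt, vaf = vaf, context3 = ctx
        )
      }

      # dominant CN exposure >= 0.55 guarantees it is the row argmax
      dom <- sample(cn_sigs, 1, prob = cn_probs[[g]])
      u <- runif(1, 0.55, 0.90)
      rest <- rgamma(length(cn_sigs) - 1, shape = 1)
      row <- numeric(length(cn_sigs))
      row[cn_sigs != dom] <- (1 - u) * rest / sum(rest)
      row[cn_sigs == dom] <- u
      cn_mat[i, ] <- row

      feat_mat[i, ] <- rnorm(nrow(fe),
                             mean = if (g == "EGI") fe$mean_egi else fe$mean_lgi,
                             sd = fe$sd)
    }

    empty_muts <- tibble::tibble(
      sample_id = character(), gene = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      vaf = numeric(), context3 = character()
    )
    mutations <- dplyr::bind_rows(c(list(empty_muts), mut_list))

    truth_weights <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      w <- if (groups[i] == "EGI") config$sbs_weights_egi else config$sbs_weights_lgi
      tibble::tibble(sample_id = ids[i], signature = names(w), weight = unname(w))
    }))
    if (n == 0) truth_weights <- tibble::tibble(
      sample_id = character(), signature = character(), weight = numeric())

    structure(list(
      mutations = mutations,
      hallmark_map = hallmark_map,
      cn_exposures = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                      tibble::as_tibble(cn_mat)),
      features = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                  tibble::as_tibble(feat_mat)),
      feature_kinds = setNames(fe$kind, fe$feature),
      truth = tibble::tibble(sample_id = ids, group = groups),
      truth_weights = truth_weights,
      config = config
    ), class = "synthetic_cohort")
  })
}

#' Generate a null cohort (no group differences)
#'
#' Identical generative settings for both groups — the EGI settings are copied
#' onto the LGI group (hallmark order, SBS weights, CN dominant probabilities,
#' feature means) — while the group labels are still recorded. Used for
#' type-I-error calibration of the association statistics.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort`, as from [generate_cohort()].
#' @export
generate_null_cohort <- function(config, catalog = synthetic_signature_catalog()) {
  stopifnot(inherits(config, "cohort_config"))
  config$hallmark_order_lgi <- config$hallmark_order_egi
  config$sbs_weights_lgi <- config$sbs_weights_egi
  config$cn_dominant_probs_lgi <- config$cn_dominant_probs_egi
  config$feature_effects$mean_lgi <- config$feature_effects$mean_egi
  generate_cohort(config, catalog)
}

#' Write a synthetic cohort to TSV files
#'
#' Emits the tables the pipeline consumes (`mutations.tsv`, `hallmark_map.tsv`,
#' `cn_exposures.tsv`, `features.tsv`) plus the ground truth (`truth.tsv`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    hallmark_map = file.path(dir, "hallmark_map.tsv"),
    cn_exposures = file.path(dir, "cn_exposures.tsv"),
    features = file.path(dir, "features.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(cohort$mutations, paths[["mutations"]])
  readr::write_tsv(cohort$hallmark_map, paths[["hallmark_map"]])
  readr::write_tsv(cohort$cn_exposures, paths[["cn_exposures"]])
  readr::write_tsv(cohort$features, paths[["features"]])
  readr::write_tsv(cohort$truth, paths[["truth"]])
  invisible(paths)
}
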