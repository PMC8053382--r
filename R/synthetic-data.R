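#' Specification for a synthetic EM-fungal survey dataset
#'
#' Describes the generative model used for calibration and power studies:
#' a fixed number of sites with equal sample counts, ranked heavy-tailed base
#' relative abundances shared by all sites, optional per-OTU site affinity,
#' and exact multinomial sampling to a common read depth. The defaults mirror
#' a three-site survey design: 3 sites x 7 root samples, a pool of 122 OTUs
#' and a rarefied depth of 1,038 reads per sample.
#'
#' Site affinity of an OTU with preferred site `a` and strength `s` in
#' \[0, 1\] multiplies its sampling probability by `1 + (S - 1) * s` at `a`
#' and `1 - s` elsewhere (`S` sites). Averaged over sites the multiplier is
#' 1, so the expected whole-dataset relative abundance of an OTU does not
#' depend on its specialization; at `s = 1` the OTU is confined entirely to
#' its preferred site.
#'
#' @param n_sites number of sites (>= 2).
#' @param samples_per_site samples per site (>= 1).
#' @param n_otus size of the OTU pool.
#' @param depth reads per sample after the (emulated) rarefaction.
#' @param base_model ranked base-abundance model: `"geometric"` (default,
#'   abundance proportional to `geometric_ratio^(rank - 1)`) or
#'   `"log-series"` (proportional to `logseries_x^rank / rank`, a much
#'   longer rare tail).
#' @param geometric_ratio decay ratio of the geometric series.
#' @param logseries_x parameter of the log-series model in (0, 1).
#' @param specialization baseline site-affinity strength, recycled over the
#'   OTU pool (preferred sites cycle over 1..n_sites by rank). Use 0 for a
#'   fully site-exchangeable community.
#' @param planted_specialists optional data.frame with columns `otu`
#'   (rank index into the pool), `site` (preferred site index) and
#'   `strength`; overrides the baseline specialization for those OTUs.
#' @param site_covariates optional data.frame of per-site covariate means
#'   (see [default_site_covariates()]).
#' @param covariate_jitter named vector of per-sample SD for the climate and
#'   soil covariates.
#' @param coordinate_jitter SD (degrees) of per-sample coordinate scatter
#'   around the site centre.
#' @param raw_depth if non-NULL, emit unrarefied tables whose per-sample
#'   totals are negative-binomial around this mean (for rarefaction tests)
#'   instead of exactly `depth`.
#' @param raw_dispersion negative-binomial size parameter for `raw_depth`.
#' @param seed default seed used by [generate_dataset()].
#' @return a `synthetic_spec` list.
#' @seealso [generate_dataset()], [null_dataset()]
#' @export
synthetic_spec <- function(n_sites = 3L, samples_per_site = 7L,
                           n_otus = 122L, depth = 1038L,
                           base_model = c("geometric", "log-series"),
                           geometric_ratio = 0.93, logseries_x = 0.80,
                           specialization = 0,
                           planted_specialists = NULL,
                           site_covariates = NULL,
                           covariate_jitter = NULL,
                           coordinate_jitter = 0.01,
                           raw_depth = NULL, raw_dispersion = 5,
                           seed = NULL) {
  base_model <- match.arg(base_model)
  n_sites <- as.integer(n_sites)
  samples_per_site <- as.integer(samples_per_site)
  n_otus <- as.integer(n_otus)
  depth <- as.integer(depth)
  stopifnot(n_sites >= 2L, samples_per_site >= 1L, n_otus >= 1L, depth >= 1L,
            geometric_ratio > 0, geometric_ratio < 1,
            logseries_x > 0, logseries_x < 1)
  specialization <- rep_len(specialization, n_otus)
  if (any(specialization < 0 | specialization > 1))
    stop("specialization strengths must lie in [0, 1]", call. = FALSE)
  if (!is.null(planted_specialists)) {
    ps <- planted_specialists
    need <- c("otu", "site", "strength")
    if (!all(need %in% colnames(ps)))
      stop("planted_specialists needs columns otu, site, strength",
           call. = FALSE)
    if (any(ps$otu < 1 | ps$otu > n_otus))
      stop("planted specialist references an OTU outside the pool",
           call. = FALSE)
    if (any(ps$site < 1 | ps$site > n_sites))
      stop("planted specialist references a site outside 1..n_sites",
           call. = FALSE)
    if (any(ps$strength < 0 | ps$strength > 1))
      stop("planted specialist strengths must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(site_covariates))
    site_covariates <- default_site_covariates(n_sites)
  if (is.null(covariate_jitter))
    covariate_jitter <- c(MAT = 0.15, MAP = 8, pH = 0.1, N = 0.25,
                          P = 0.04, K = 0.8, OM = 4)
  structure(list(n_sites = n_sites, samples_per_site = samples_per_site,
                 n_otus = n_otus, depth = depth, base_model = base_model,
                 geometric_ratio = geometric_ratio, logseries_x = logseries_x,
                 specialization = specialization,
                 planted_specialists = planted_specialists,
                 site_covariates = site_covariates,
                 covariate_jitter = covariate_jitter,
                 coordinate_jitter = coordinate_jitter,
                 raw_depth = raw_depth, raw_dispersion = raw_dispersion,
                 seed = seed),
            class = "synthetic_spec")
}

#' Default per-site covariate means
#'
#' Three template sites loosely patterned on a cold-temperate montane larch
#' survey (MAT between -4.7 and 0.1 degrees C, MAP between 374 and 506 mm;
#' one cold northern site far from two warmer southern sites). Entirely
#' synthetic values — no claim of matching any real soils. Additional sites
#' beyond three are generated by offsetting the templates.
#'
#' @param n_sites number of sites.
#' @return data.frame of per-site means, one row per site.
#' @export
default_site_covariates <- function(n_sites = 3L) {
  template <- data.frame(
    site = c("GH", "HGL", "SHWL"),
    latitude = c(50.90, 43.52, 44.10),
    longitude = c(121.50, 118.30, 118.70),
    MAT = c(-4.7, -0.3, 0.1),
    MAP = c(450, 506, 374),
    pH = c(5.1, 5.9, 6.3),
    N = c(4.2, 3.1, 2.6),
    P = c(0.60, 0.50, 0.45),
    K = c(14, 16, 17),
    OM = c(80, 55, 45),
    stringsAsFactors = FALSE)
  if (n_sites <= 3L) return(template[seq_len(n_sites), , drop = FALSE])
  extra <- lapply(seq_len(n_sites - 3L), function(k) {
    row <- template[((k - 1L) %% 3L) + 1L, ]
    row$site <- paste0("S", k + 3L)
    row$latitude <- row$latitude + 0.5 * k
    row$longitude <- row$longitude + 0.5 * k
    row
  })
  out <- rbind(template, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

## Ranked base relative abundances (sum to one).
base_abundances <- function(spec) {
  k <- seq_len(spec$n_otus)
  p <- switch(spec$base_model,
              "geometric" = spec$geometric_ratio^(k - 1),
              "log-series" = spec$logseries_x^k / k)
  p / sum(p)
}

## Per-OTU preferred site and strength after planting overrides.
resolve_specialists <- function(spec) {
  strength <- spec$specialization
  pref <- ((seq_len(spec$n_otus) - 1L) %% spec$n_sites) + 1L
  if (!is.null(spec$planted_specialists)) {
    ps <- spec$planted_specialists
    strength[ps$otu] <- ps$strength
    pref[ps$otu] <- as.integer(ps$site)
  }
  list(strength = strength, preferred = pref)
}

#' Generate a synthetic survey dataset
#'
#' Draws one dataset from a [synthetic_spec()]: per-sample counts are
#' multinomial of size `depth` over the base abundances modulated by each
#' OTU's site-affinity multiplier (renormalized per sample), and per-sample
#' covariates are site means plus Gaussian jitter. Fully reproducible from
#' the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to the spec's own seed. `NULL` draws
#'   from the current RNG stream.
#' @return an `em_dataset` list with elements `table` ([otu_table()] keeping
#'   the full OTU pool, including never-observed columns), `metadata`,
#'   `taxonomy` (a deterministic synthetic lineage assignment), `truth`
#'   (planted strengths, preferred sites and expected per-site relative
#'   abundance profiles) and `spec`.
#' @export
generate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_if(seed, function() {
    S <- spec$n_sites
    nps <- spec$samples_per_site
    n <- S * nps
    cov <- spec$site_covariates
    site_names <- cov$site
    site_of <- rep(seq_len(S), each = nps)
    sample_ids <- paste0(site_names[site_of], "_",
                         rep(seq_len(nps), times = S))
    otu_ids <- sprintf("OTU_%03d", seq_len(spec$n_otus))

    base <- base_abundances(spec)
    sp <- resolve_specialists(spec)
    ## site x OTU probability profiles (rows sum to 1)
    mult <- matrix(1, S, spec$n_otus)
    hot <- which(sp$strength > 0)
    for (j in hot) {
      mult[, j] <- 1 - sp$strength[j]
      mult[sp$preferred[j], j] <- 1 + (S - 1) * sp$strength[j]
    }
    prof <- sweep(mult, 2, base, `*`)
    prof <- prof / rowSums(prof)

    depths <- if (is.null(spec$raw_depth)) {
      rep(spec$depth, n)
    } else {
      pmax(1L, stats::rnbinom(n, mu = spec$raw_depth,
                              size = spec$raw_dispersion))
    }
    counts <- matrix(0L, n, spec$n_otus,
                     dimnames = list(sample_ids, otu_ids))
    for (i in seq_len(n)) {
      counts[i, ] <- stats::rmultinom(1, depths[i], prof[site_of[i], ])
    }
    table <- otu_table(counts, drop_empty = FALSE)

    jit <- spec$covariate_jitter
    md <- data.frame(
      sample_id = sample_ids,
      site = site_names[site_of],
      latitude = cov$latitude[site_of] +
        stats::rnorm(n, 0, spec$coordinate_jitter),
      longitude = cov$longitude[site_of] +
        stats::rnorm(n, 0, spec$coordinate_jitter),
      stringsAsFactors = FALSE)
    for (v in c("MAT", "MAP", "pH", "N", "P", "K", "OM")) {
      md[[v]] <- cov[[v]][site_of] + stats::rnorm(n, 0, jit[[v]])
    }

    truth <- list(
      specialists = data.frame(otu_id = otu_ids,
                               otu = seq_len(spec$n_otus),
                               preferred_site = site_names[sp$preferred],
                               strength = sp$strength,
                               stringsAsFactors = FALSE),
      expected_profiles = structure(prof,
                                    dimnames = list(site_names, otu_ids)),
      base_abundance = structure(base, names = otu_ids))

    structure(list(table = table, metadata = md,
                   taxonomy = synthetic_taxonomy(otu_ids),
                   truth = truth, spec = spec),
              class = "em_dataset")
  })
}

## Deterministic synthetic lineage assignment: the common EM lineages
## rotate over abundance ranks so that the dominant ranks spread across the
## major lineages. Synthetic labels, not a biological claim.
synthetic_taxonomy <- function(otu_ids) {
  lineages <- c("/tricholoma", "/tomentella-thelephora", "/suillus-rhizopogon",
                "/piloderma", "/wilcoxina", "/russula-lactarius",
                "/cortinarius", "/sebacina")
  genera <- c("Tricholoma", "Tomentella", "Suillus", "Piloderma",
              "Wilcoxina", "Russula", "Cortinarius", "Sebacina")
  idx <- ((seq_along(otu_ids) - 1L) %% length(lineages)) + 1L
  data.frame(otu_id = otu_ids, genus = genera[idx], lineage = lineages[idx],
             stringsAsFactors = FALSE)
}

#' Generate a site-exchangeable null dataset
#'
#' Convenience wrapper for type-I-error suites: forces all specialization to
#' zero and removes planted specialists, so site labels are exchangeable by
#' construction.
#'
#' @inheritParams generate_dataset
#' @return an `em_dataset`.
#' @export
null_dataset <- function(spec = synthetic_spec(), seed = spec$seed) {
  spec$specialization <- rep(0, spec$n_otus)
  spec$planted_specialists <- NULL
  generate_dataset(spec, seed = seed)
}

#' Planted-specialist design used by the package's power studies
#'
#' Places specialists at moderate abundance ranks of the geometric series
#' (defaults: ranks 45 to 53), cycling the preferred site. The band is
#' chosen so that a specialist is abundant enough to be kept by the >0.1%
#' abundance filter yet rare enough that binarized presence still carries a
#' site signal; see the methods vignette for the design-stage power
#' analysis behind it.
#'
#' @param spec a [synthetic_spec()].
#' @param strength affinity strength given to every planted OTU.
#' @param ranks abundance ranks (pool indices) to plant.
#' @return data.frame suitable for `planted_specialists`.
#' @export
plant_specialists <- function(spec, strength = 0.9,
                              ranks = 45:53) {
  stopifnot(all(ranks >= 1L), all(ranks <= spec$n_otus))
  data.frame(otu = as.integer(ranks),
             site = ((seq_along(ranks) - 1L) %% spec$n_sites) + 1L,
             strength = strength)
}

#' Write a synthetic dataset to TSV files
#'
#' Emits `table.tsv`, `metadata.tsv`, `taxonomy.tsv` and `truth.tsv` under
#' `dir`.
#'
#' @param dataset an `em_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "em_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(dataset$table, file.path(dir, "table.tsv"))
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$specialists, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
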