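#' Configuration for a full pipeline run
#'
#' Exactly one of `input` (paths to table/metadata/taxonomy TSVs) or
#' `synthetic` (a [synthetic_spec()]) must be given.
#'
#' @param input named list with `table`, `metadata` and optionally
#'   `taxonomy` file paths.
#' @param synthetic a [synthetic_spec()] to generate the inputs instead.
#' @param out_dir output directory for TSV results and the manifest.
#' @param depth rarefaction depth.
#' @param dominant_threshold,rare_threshold,abundant_threshold abundance
#'   class cutoffs (fractions of total reads), ordered
#'   rare < abundant < dominant.
#' @param distance `"both"`, `"bray"` or `"sorensen"`.
#' @param n_permutations named list of permutation counts per test.
#' @param alpha FDR level for occurrence calls.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param scores optional path to a TSV of external ordination scores
#'   (`sample_id` + axis columns) for environmental fitting.
#' @param occurrence_input binarize the `"rarefied"` (default) or `"raw"`
#'   table for the occurrence analysis.
#' @param p_mode p-value mode for the occurrence analysis.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, out_dir,
                            depth = 1038,
                            dominant_threshold = 0.01,
                            rare_threshold = 1e-4,
                            abundant_threshold = 1e-3,
                            distance = c("both", "bray", "sorensen"),
                            n_permutations = list(mantel = 999,
                                                  permanova = 999,
                                                  envfit = 999,
                                                  occurrence = 1000),
                            alpha = 0.05, seed = 1, scores = NULL,
                            occurrence_input = c("rarefied", "raw"),
                            p_mode = c("normal", "empirical")) {
  distance <- match.arg(distance)
  occurrence_input <- match.arg(occurrence_input)
  p_mode <- match.arg(p_mode)
  if (is.null(input) == is.null(synthetic))
    stop("provide exactly one of input paths or a synthetic spec",
         call. = FALSE)
  if (!(rare_threshold < abundant_threshold &&
        abundant_threshold < dominant_threshold))
    stop("thresholds must satisfy rare < abundant < dominant", call. = FALSE)
  if (!is.null(input) &&
      !all(c("table", "metadata") %in% names(input)))
    stop("input needs at least table and metadata paths", call. = FALSE)
  defaults <- list(mantel = 999, permanova = 999, envfit = 999,
                   occurrence = 1000)
  n_permutations <- utils::modifyList(defaults, as.list(n_permutations))
  structure(list(input = input, synthetic = synthetic, out_dir = out_dir,
                 depth = depth, dominant_threshold = dominant_threshold,
                 rare_threshold = rare_threshold,
                 abundant_threshold = abundant_threshold,
                 distance = distance, n_permutations = n_permutations,
                 alpha = alpha, seed = as.integer(seed), scores = scores,
                 occurrence_input = occurrence_input, p_mode = p_mode),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_dist <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(id = rownames(m), round(m, 10), check.names = FALSE)
  write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Stage order: load/validate, rarefy, alpha diversity (+ per-index site
#' ANOVA), accumulation curves, abundance classes, Venn partition, lineage
#' aggregation, dissimilarity (Hellinger/Bray-Curtis and/or Sorensen) with
#' Mantel, PerMANOVA, PCNM and optional environmental fitting, and the
#' site/fungus occurrence analysis. All tabular results are written as TSV
#' under `out_dir`; the run manifest (config snapshot, derived seeds,
#' per-stage row/column counts and warnings) is written last as
#' `manifest.yaml`. Identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6,
                        labels = c("synthetic", "rarefy", "accumulation",
                                   "mantel", "permanova", "occurrence"))
  manifest <- list(package = "emoccur",
                   version = as.character(utils::packageVersion("emoccur")),
                   seed = config$seed, seeds = as.list(seeds),
                   config = config[setdiff(names(config),
                                           c("input", "synthetic"))],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], list(...))
  }
  warnings_log <- character(0)
  capture <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  ## ---- load ----
  if (!is.null(config$synthetic)) {
    ds <- capture("load", generate_dataset(config$synthetic,
                                           seed = seeds[["synthetic"]]))
    table <- ds$table; metadata <- ds$metadata; taxonomy <- ds$taxonomy
    write_dataset(ds, file.path(out, "inputs"))
    note("load", source = "synthetic")
  } else {
    table <- capture("load", read_otu_table(config$input$table))
    metadata <- read_sample_metadata(config$input$metadata)
    taxonomy <- if (!is.null(config$input$taxonomy))
      read_taxonomy(config$input$taxonomy) else NULL
    note("load", source = "files")
  }
  metadata <- validate_sample_metadata(metadata, table)
  note("load", samples = nrow(table), otus = ncol(table))

  ## ---- rarefy ----
  raw_table <- table
  table <- tryCatch(
    capture("rarefaction", rarefy_table(table, depth = config$depth,
                                        seed = seeds[["rarefy"]])),
    error = function(e) stop_stage("rarefaction", conditionMessage(e)))
  metadata_r <- metadata[metadata$sample_id %in% rownames(table), ,
                         drop = FALSE]
  note("rarefaction", depth = config$depth, samples = nrow(table),
       otus = ncol(table))

  ## ---- diversity ----
  div <- alpha_diversity(table)
  div$site <- metadata_r$site[match(div$sample_id, metadata_r$sample_id)]
  write_tsv(div, file.path(out, "diversity.tsv"))
  ## site effect per index, delegated to classical one-way ANOVA
  tests <- do.call(rbind, lapply(c("richness", "shannon", "simpson"),
    function(v) {
      fit <- stats::aov(div[[v]] ~ factor(div$site))
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      data.frame(index = v, anova_p = p)
    }))
  write_tsv(tests, file.path(out, "diversity_anova.tsv"))

  ## ---- accumulation ----
  acc <- capture("accumulation",
    do.call(rbind, lapply(unique(metadata_r$site), function(s) {
      sub <- table[metadata_r$sample_id[metadata_r$site == s], , drop = FALSE]
      if (nrow(sub) < 2) return(NULL)
      a <- accumulation_curve(otu_table(unclass(sub), drop_empty = TRUE),
                              seed = seeds[["accumulation"]])
      cbind(site = s, a)
    })))
  if (!is.null(acc)) write_tsv(acc, file.path(out, "accumulation.tsv"))

  ## ---- abundance / venn / lineages ----
  ab <- classify_abundance(table, dominant = config$dominant_threshold,
                           rare = config$rare_threshold,
                           abundant = config$abundant_threshold)
  write_tsv(ab, file.path(out, "abundance_classes.tsv"))
  vp <- venn_partition(binarize(table), metadata_r)
  write_tsv(data.frame(region = names(vp$counts), n_otus = vp$counts,
                       percent = round(vp$percentages, 4)),
            file.path(out, "venn.tsv"))
  if (!is.null(taxonomy)) {
    lin <- aggregate_by_lineage(table, taxonomy, metadata_r, by = "site")
    write_tsv(data.frame(lineage = rownames(lin$relative),
                         round(lin$relative, 6), check.names = FALSE),
              file.path(out, "lineage_abundance.tsv"))
  }

  ## ---- dissimilarity & association ----
  geo <- geographic_distance(metadata_r)
  res_rows <- list()
  run_block <- function(dmat, label, mseed, pseed) {
    man <- mantel_test(dmat, geo,
                       n_permutations = config$n_permutations$mantel,
                       seed = mseed)
    pmv <- permanova(dmat, metadata_r$site,
                     n_permutations = config$n_permutations$permanova,
                     seed = pseed)
    write_dist(dmat, file.path(out, paste0("distance_", label, ".tsv")))
    rbind(data.frame(distance = label, test = "mantel_geographic",
                     statistic = man$statistic, R2 = NA_real_,
                     p_value = man$p_value,
                     n_permutations = man$n_permutations),
          data.frame(distance = label, test = "permanova_site",
                     statistic = pmv$statistic, R2 = pmv$R2,
                     p_value = pmv$p_value,
                     n_permutations = pmv$n_permutations))
  }
  if (config$distance %in% c("both", "bray")) {
    bray <- bray_curtis(hellinger_transform(table))
    res_rows$bray <- run_block(bray, "bray", seeds[["mantel"]],
                               seeds[["permanova"]])
  }
  if (config$distance %in% c("both", "sorensen")) {
    sor <- sorensen(binarize(table))
    res_rows$sorensen <- run_block(sor, "sorensen",
                                   seeds[["mantel"]] + 1L,
                                   seeds[["permanova"]] + 1L)
  }
  write_tsv(do.call(rbind, res_rows), file.path(out, "association_tests.tsv"))

  site_coords <- unique(data.frame(
    site = metadata_r$site,
    latitude = tapply(metadata_r$latitude, metadata_r$site,
                      mean)[metadata_r$site],
    longitude = tapply(metadata_r$longitude, metadata_r$site,
                       mean)[metadata_r$site]))
  pc <- pcnm_vectors(site_coords[, c("latitude", "longitude")])
  write_tsv(data.frame(site = site_coords$site, pc$vectors,
                       check.names = FALSE),
            file.path(out, "pcnm.tsv"))
  note("pcnm", positive_eigenvectors = ncol(pc$vectors))

  if (!is.null(config$scores)) {
    sc <- utils::read.delim(config$scores, check.names = FALSE)
    rn <- sc$sample_id
    sc <- as.matrix(sc[, setdiff(colnames(sc), "sample_id"), drop = FALSE])
    rownames(sc) <- rn
    sc <- sc[metadata_r$sample_id, , drop = FALSE]
    vars <- metadata_r[, c("MAT", "MAP", "pH", "N", "P", "K", "OM")]
    ef <- env_fit(sc, vars,
                  n_permutations = config$n_permutations$envfit,
                  seed = seeds[["mantel"]] + 2L)
    write_tsv(ef, file.path(out, "envfit.tsv"))
  }

  ## ---- occurrence ----
  occ_table <- if (config$occurrence_input == "rarefied") table else
    raw_table[rownames(table), , drop = FALSE]
  occ <- occurrence_analysis(occ_table, metadata_r,
                             n_permutations =
                               config$n_permutations$occurrence,
                             seed = seeds[["occurrence"]],
                             p_mode = config$p_mode)
  rep <- occurrence_report(occ, alpha = config$alpha,
                           abundant_filter = TRUE,
                           abundant_threshold = config$abundant_threshold)
  write_tsv(rep$otus, file.path(out, "occurrence_otus.tsv"))
  write_tsv(rep$sites, file.path(out, "occurrence_sites.tsv"))
  write_tsv(rep$cells, file.path(out, "occurrence_cells.tsv"))
  write_tsv(data.frame(measure = names(rep$summary),
                       value = as.integer(rep$summary)),
            file.path(out, "occurrence_summary.tsv"))
  note("occurrence", n_permutations = config$n_permutations$occurrence,
       p_mode = config$p_mode,
       cells_tested = unname(rep$summary[["cells_tested"]]),
       cells_significant = unname(rep$summary[["cells_significant"]]))

  manifest$warnings <- warnings_log
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

#' Simulation-based validation of the pipeline's occurrence calls
#'
#' Runs replicate synthetic datasets through the occurrence machinery and
#' reports (a) the type-I behaviour of raw empirical per-cell p-values on
#' site-exchangeable null data, (b) PerMANOVA and Mantel null p-value
#' uniformity, and (c) detection power for planted site specialists as a
#' function of affinity strength (detection = the planted site-OTU cell is
#' FDR-significant among abundant OTUs).
#'
#' @param spec a [synthetic_spec()] describing the community.
#' @param replicates null replicates for calibration.
#' @param n_permutations ensemble size for the calibration replicates.
#' @param strengths specialist strengths for the power sweep.
#' @param power_replicates replicates per strength.
#' @param power_permutations ensemble size for the power replicates.
#' @param alpha FDR level for detection.
#' @param seed master seed.
#' @param uniformity also run PerMANOVA/Mantel on each null replicate.
#' @return a `calibration_report` list; see Details in the vignette.
#' @export
simulate_and_validate <- function(spec = synthetic_spec(),
                                  replicates = 100,
                                  n_permutations = 200,
                                  strengths = c(0.3, 0.6, 0.9),
                                  power_replicates = 20,
                                  power_permutations = 1000,
                                  alpha = 0.05, seed = 1,
                                  uniformity = TRUE) {
  if (replicates < 10)
    warning("fewer than 10 replicates: estimates will be unstable",
            call. = FALSE)
  seeds <- derive_seeds(seed, replicates +
                          length(strengths) * power_replicates + 1L)
  ## ---- null calibration ----
  null_p <- vector("list", replicates)
  perm_p <- mantel_p <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    ds <- null_dataset(spec, seed = seeds[r])
    presence <- binarize(ds$table)
    sm <- build_site_matrix(presence, ds$metadata)
    ens <- shuffle_sample_null(presence, ds$metadata,
                               n_permutations = n_permutations,
                               seed = seeds[r] + 1L)
    tdo <- two_dimensional_occurrence(sm, ens, p_mode = "empirical")
    null_p[[r]] <- tdo$p_raw[tdo$defined]
    if (uniformity) {
      keep <- rowSums(ds$table) > 0
      tab <- suppressWarnings(
        otu_table(unclass(ds$table)[keep, , drop = FALSE],
                  drop_empty = TRUE))
      md <- ds$metadata[ds$metadata$sample_id %in% rownames(tab), ]
      bc <- bray_curtis(hellinger_transform(tab))
      geo <- geographic_distance(md)
      mantel_p[r] <- mantel_test(bc, geo, n_permutations = 199,
                                 seed = seeds[r] + 2L,
                                 exhaustive = FALSE)$p_value
      perm_p[r] <- permanova(bc, md$site, n_permutations = 199,
                             seed = seeds[r] + 3L,
                             exhaustive = FALSE)$p_value
    }
  }
  pooled <- unlist(null_p)
  calibration <- list(
    n_cells = length(pooled),
    rejection_rate = mean(pooled <= 0.05),
    per_dataset = vapply(null_p, function(p) mean(p <= 0.05), numeric(1)))

  ## ---- power sweep ----
  power <- data.frame(strength = strengths, power = NA_real_,
                      cells = NA_integer_)
  sidx <- replicates + 1L
  for (k in seq_along(strengths)) {
    hits <- 0L; tries <- 0L
    for (r in seq_len(power_replicates)) {
      sp <- spec
      sp$planted_specialists <- plant_specialists(spec,
                                                  strength = strengths[k])
      ds <- generate_dataset(sp, seed = seeds[sidx])
      sidx <- sidx + 1L
      occ <- occurrence_analysis(ds$table, ds$metadata,
                                 n_permutations = power_permutations,
                                 seed = seeds[sidx - 1L] + 7L,
                                 p_mode = "normal", dprime_axes = character(0))
      rep_ <- occurrence_report(occ, alpha = alpha, abundant_filter = TRUE)
      plants <- sp$planted_specialists
      truth_sites <- ds$spec$site_covariates$site[plants$site]
      otu_ids <- sprintf("OTU_%03d", plants$otu)
      idx <- match(paste(truth_sites, otu_ids),
                   paste(rep_$cells$site, rep_$cells$otu_id))
      found <- rep_$cells$significant[idx[!is.na(idx)]]
      hits <- hits + sum(found, na.rm = TRUE)
      tries <- tries + length(otu_ids)
    }
    power$power[k] <- hits / tries
    power$cells[k] <- tries
  }

  out <- list(calibration = calibration, power = power, alpha = alpha,
              spec = spec, replicates = replicates,
              n_permutations = n_permutations)
  if (uniformity) {
    out$uniformity <- list(
      mantel_rate = mean(mantel_p <= 0.05, na.rm = TRUE),
      permanova_rate = mean(perm_p <= 0.05, na.rm = TRUE),
      mantel_p = mantel_p, permanova_p = perm_p)
  }
  structure(out, class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration over %d null datasets (%d permutations each):\n",
              x$replicates, x$n_permutations))
  cat(sprintf("  raw empirical P <= 0.05 in %.2f%% of %d cells\n",
              100 * x$calibration$rejection_rate, x$calibration$n_cells))
  if (!is.null(x$uniformity))
    cat(sprintf("  Mantel / PerMANOVA null rejection at 0.05: %.3f / %.3f\n",
                x$uniformity$mantel_rate, x$uniformity$permanova_rate))
  cat("Power (planted specialists, FDR-significant planted cells):\n")
  print(x$power, row.names = FALSE)
  invisible(x)
}
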