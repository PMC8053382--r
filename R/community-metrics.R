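#' Rarefy an OTU table to a common depth
#'
#' Each retained sample's counts are subsampled uniformly at random without
#' replacement to exactly `depth` reads (one-shot draw, the usual survey
#' practice). Samples with fewer reads than `depth` are dropped with a
#' warning by default; OTU columns emptied everywhere by the subsampling are
#' dropped with a warning.
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample.
#' @param seed optional seed for the draw.
#' @param below_depth `"drop"` (default) or `"error"` for samples whose
#'   total is below `depth`.
#' @return a rarefied [otu_table()].
#' @export
rarefy_table <- function(x, depth = 1038, seed = NULL,
                         below_depth = c("drop", "error")) {
  below_depth <- match.arg(below_depth)
  totals <- rowSums(x)
  short <- totals < depth
  if (any(short)) {
    if (below_depth == "error")
      stop("sample total below rarefaction depth: ",
           paste(rownames(x)[short], collapse = ", "), call. = FALSE)
    warning(sprintf("dropping %d sample(s) with fewer than %d reads: %s",
                    sum(short), depth,
                    paste(rownames(x)[short], collapse = ", ")),
            call. = FALSE)
    x <- x[!short, , drop = FALSE]
  }
  if (nrow(x) == 0)
    stop("no sample reaches the rarefaction depth", call. = FALSE)
  ## vegan::rrarefy emits a heuristic warning when no count equals 1;
  ## irrelevant for valid integer tables, so it is muffled here
  m <- with_seed_if(seed, function()
    withCallingHandlers(vegan::rrarefy(unclass(x), depth),
                        warning = function(w) {
                          if (grepl("observed counts", conditionMessage(w)))
                            invokeRestart("muffleWarning")
                        }))
  otu_table(m, drop_empty = TRUE)
}

#' Exact expected richness after rarefaction
#'
#' Closed-form hypergeometric expectation of the number of OTUs retained
#' when a sample with counts `counts` (total N) is subsampled without
#' replacement to `depth` reads:
#' `sum_i [1 - choose(N - n_i, depth) / choose(N, depth)]`.
#' Used as the independent oracle for [rarefy_table()].
#'
#' @param counts integer vector of reads per OTU for one sample.
#' @param depth subsample size (<= sum(counts)).
#' @return expected number of OTUs with at least one read retained.
#' @export
expected_rarefied_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  stopifnot(depth >= 1, depth <= N)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Per-sample alpha diversity
#'
#' Richness (observed OTUs), Shannon entropy (nats) and the Simpson
#' concentration complement `1 - sum(p^2)`, computed on per-sample
#' proportions. Intended for rarefied tables.
#'
#' @param x an [otu_table()].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(x) {
  m <- unclass(x)
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  data.frame(sample_id = rownames(m),
             richness = as.integer(rowSums(m > 0)),
             shannon = as.numeric(vegan::diversity(m, index = "shannon")),
             simpson = as.numeric(vegan::diversity(m, index = "simpson")),
             stringsAsFactors = FALSE)
}

#' OTU accumulation curve
#'
#' Mean (and SD) of the number of distinct OTUs observed in the first
#' `k = 1..n` samples over random sample orderings, alongside the exact
#' expectation `sum_i [1 - choose(n - f_i, k) / choose(n, k)]` where `f_i`
#' is the occupancy of OTU i.
#'
#' @param x an [otu_table()] with at least two samples.
#' @param n_permutations number of random orderings.
#' @param seed optional seed.
#' @return data.frame with columns `samples`, `mean`, `sd`, `exact`.
#' @export
accumulation_curve <- function(x, n_permutations = 100, seed = NULL) {
  m <- unclass(x)
  if (nrow(m) < 2) stop("need at least two samples", call. = FALSE)
  acc <- with_seed_if(seed, function()
    suppressMessages(vegan::specaccum(m, method = "random",
                                      permutations = n_permutations)))
  n <- nrow(m)
  f <- occupancy(x)
  exact <- vapply(seq_len(n), function(k)
    sum(1 - exp(lchoose(n - f, k) - lchoose(n, k))), numeric(1))
  data.frame(samples = seq_len(n), mean = as.numeric(acc$richness),
             sd = as.numeric(acc$sd), exact = exact)
}

#' Classify OTUs by whole-dataset relative abundance
#'
#' Relative abundance is the OTU's read total over the grand total.
#' Thresholds follow common survey practice: dominant at >= 1%, rare at
#' < 0.01%, everything between is intermediate; independently, OTUs above
#' 0.1% are flagged "abundant" (the subset usually retained for
#' occurrence testing).
#'
#' @param x an [otu_table()].
#' @param dominant,rare,abundant thresholds as fractions of total reads.
#' @return data.frame with columns `otu_id`, `relative_abundance`, `class`
#'   (factor: dominant/intermediate/rare) and `abundant_flag`.
#' @export
classify_abundance <- function(x, dominant = 0.01, rare = 1e-4,
                               abundant = 1e-3) {
  stopifnot(rare < abundant, abundant < dominant)
  rel <- colSums(x) / sum(x)
  cls <- ifelse(rel >= dominant, "dominant",
                ifelse(rel < rare, "rare", "intermediate"))
  data.frame(otu_id = colnames(x),
             relative_abundance = as.numeric(rel),
             class = factor(cls, levels = c("dominant", "intermediate",
                                            "rare")),
             abundant_flag = rel > abundant,
             stringsAsFactors = FALSE)
}

#' Venn partition of OTUs by site membership
#'
#' An OTU belongs to a site when it is present in at least one of that
#' site's samples. The `2^s - 1` membership regions are disjoint and
#' together cover every observed OTU.
#'
#' @param presence a presence table from [binarize()] (counts are accepted
#'   and binarized).
#' @param metadata per-sample metadata with `sample_id` and `site`.
#' @return a `venn_partition` list: `regions` (named list of OTU id
#'   vectors, names like `"GH"` or `"GH&HGL"`), `counts`, `percentages`
#'   (of the observed OTU total) and `total`.
#' @export
venn_partition <- function(presence, metadata) {
  p <- binarize(presence)
  metadata <- validate_sample_metadata(metadata)
  site <- metadata$site[match(rownames(p), metadata$sample_id)]
  if (anyNA(site))
    stop("samples without a site assignment: ",
         paste(rownames(p)[is.na(site)], collapse = ", "), call. = FALSE)
  sites <- unique(metadata$site)
  counts_per_site <- table(factor(site, levels = sites))
  if (any(counts_per_site == 0))
    stop("site without samples: ",
         paste(names(counts_per_site)[counts_per_site == 0], collapse = ", "),
         call. = FALSE)
  by_site <- rowsum(unclass(p) * 1, group = factor(site, levels = sites)) > 0
  observed <- colSums(by_site) > 0
  by_site <- by_site[, observed, drop = FALSE]
  membership <- apply(by_site, 2, function(col)
    paste(sites[col], collapse = "&"))
  region_names <- unlist(lapply(seq_along(sites), function(k)
    apply(utils::combn(sites, k), 2, paste, collapse = "&")))
  regions <- lapply(region_names, function(r)
    colnames(by_site)[membership == r])
  names(regions) <- region_names
  counts <- vapply(regions, length, integer(1))
  total <- sum(counts)
  structure(list(regions = regions, counts = counts,
                 percentages = 100 * counts / total, total = total,
                 sites = sites),
            class = "venn_partition")
}

#' Aggregate OTU abundances by lineage
#'
#' Sums reads over OTUs of each EM lineage (OTUs without a taxonomy record
#' fall into an `"unassigned"` bucket) and normalises per sample or per
#' site. Lineages above `dominant_threshold` of all reads are flagged
#' dominant.
#'
#' @param x an [otu_table()].
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param metadata required when `by = "site"`.
#' @param by aggregate per `"sample"` (default) or `"site"`.
#' @param dominant_threshold fraction of total reads above which a lineage
#'   is flagged dominant.
#' @return list with `relative` (lineage x sample/site matrix of fractions
#'   summing to 1 per column), `total_relative` (lineage fractions of all
#'   reads) and `dominant` (character vector of dominant lineages).
#' @export
aggregate_by_lineage <- function(x, taxonomy, metadata = NULL,
                                 by = c("sample", "site"),
                                 dominant_threshold = 0.01) {
  by <- match.arg(by)
  lineage <- taxonomy$lineage[match(colnames(x), taxonomy$otu_id)]
  lineage[is.na(lineage) | lineage == ""] <- "unassigned"
  m <- unclass(x)
  if (by == "site") {
    if (is.null(metadata)) stop("metadata required for by = 'site'",
                                call. = FALSE)
    metadata <- validate_sample_metadata(metadata, x)
    site <- metadata$site[match(rownames(m), metadata$sample_id)]
    m <- rowsum(m, group = site)
  }
  agg <- t(rowsum(t(m), group = lineage))  # samples x lineages
  rel <- t(agg / rowSums(agg))             # lineages x samples
  total_rel <- colSums(agg) / sum(agg)
  list(relative = rel,
       total_relative = total_rel,
       dominant = names(total_rel)[total_rel > dominant_threshold])
}
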