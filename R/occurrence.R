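#' Build the site-level occurrence matrix
#'
#' Transforms a sample-level presence/absence table into a site x OTU
#' matrix whose cell (i, j) counts the samples at site i in which OTU j is
#' present. This matrix is the substrate of the whole occurrence analysis.
#'
#' @param presence a presence table from [binarize()] (counts are accepted
#'   and binarized).
#' @param metadata per-sample metadata with `sample_id` and `site`.
#' @return a `site_fungus_matrix`: integer matrix with a `samples_per_site`
#'   attribute.
#' @export
build_site_matrix <- function(presence, metadata) {
  p <- binarize(presence)
  metadata <- validate_sample_metadata(metadata)
  site <- metadata$site[match(rownames(p), metadata$sample_id)]
  if (anyNA(site))
    stop("samples without a site assignment: ",
         paste(rownames(p)[is.na(site)], collapse = ", "), call. = FALSE)
  site <- factor(site, levels = unique(metadata$site))
  m <- rowsum(unclass(p) * 1L, group = site)
  storage.mode(m) <- "integer"
  attr(m, "samples_per_site") <- as.integer(table(site))
  names(attr(m, "samples_per_site")) <- levels(site)
  class(m) <- c("site_fungus_matrix", "matrix", "array")
  m
}

## ---- d' machinery -------------------------------------------------------
## The d statistic for a focal interaction vector n (over partners with
## availabilities q, sum(q) = 1) is the Kullback-Leibler divergence
##   d = sum_j p'_j log(p'_j / q_j),  p'_j = n_j / sum(n), 0 log 0 = 0.
## Over integer reallocations of the focal total T across partners, d is a
## separable convex function of the allocation, so:
##   * its maximum over the integer simplex sits at a vertex: all T
##     interactions on the partner with the smallest availability,
##     d_max = log(1 / min(q));
##   * its minimum is found exactly by the greedy incremental allocation
##     (standard result for separable convex resource allocation).
## Exhaustive enumeration over all compositions is kept as an oracle.

d_of_allocation <- function(n_alloc, q) {
  total <- sum(n_alloc)
  p <- n_alloc / total
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

d_max_exact <- function(total, q) log(1 / min(q))

d_min_greedy <- function(total, q) {
  k <- length(q)
  g <- function(x, qq) if (x == 0) 0 else (x / total) * log(x / (total * qq))
  n <- integer(k)
  delta <- vapply(seq_len(k), function(j) g(1L, q[j]), numeric(1))
  for (step in seq_len(total)) {
    j <- which.min(delta)
    n[j] <- n[j] + 1L
    delta[j] <- g(n[j] + 1L, q[j]) - g(n[j], q[j])
  }
  n
}

#' Exact range of the d statistic by exhaustive enumeration
#'
#' Enumerates every integer allocation of `total` interactions over the
#' partners and returns the minimum and maximum of the d statistic. Used as
#' the independent oracle for the closed-form/greedy range in [dprime()];
#' practical only for small totals and few partners.
#'
#' @param total focal interaction total.
#' @param q partner availabilities (positive, summing to 1).
#' @return named numeric vector `c(d_min, d_max)`.
#' @export
dprime_range_exact <- function(total, q) {
  stopifnot(total >= 1, all(q > 0))
  comps <- integer_compositions(as.integer(total), length(q))
  vals <- apply(comps, 1, d_of_allocation, q = q)
  c(d_min = min(vals), d_max = max(vals))
}

d_range <- function(total, q, method = c("direct", "exhaustive")) {
  method <- match.arg(method)
  if (method == "exhaustive") return(dprime_range_exact(total, q))
  c(d_min = d_of_allocation(d_min_greedy(as.integer(total), q), q),
    d_max = d_max_exact(total, q))
}

#' Interaction specialization index d' per row or column
#'
#' For each focal OTU (columns; computed on the transposed matrix) or site
#' (rows), the Kullback-Leibler divergence `d` of its interaction
#' distribution against partner availability
#' (`q_j` = partner marginal / grand total), normalised to
#' `d' = (d - d_min) / (d_max - d_min)` in \[0, 1\] where `d_min`/`d_max`
#' range over integer reallocations of the focal total with all other rows
#' fixed. A focal unit exactly proportional to the partner marginals has
#' `d' = 0`; a single available partner gives `d' = 0` by convention.
#' Partners with zero marginal are excluded; focal units with zero total
#' are returned as `NA` with a warning.
#'
#' @param m a `site_fungus_matrix` (or any non-negative integer matrix).
#' @param axis `"otus"` (focal = columns, default) or `"sites"`
#'   (focal = rows).
#' @param method `"direct"` (closed-form maximum + greedy minimum, both
#'   exact for this objective) or `"exhaustive"` enumeration.
#' @return data.frame with columns `id`, `total`, `d`, `d_min`, `d_max`,
#'   `d_prime`.
#' @export
dprime <- function(m, axis = c("otus", "sites"),
                   method = c("direct", "exhaustive")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  w <- unclass(m)
  if (axis == "otus") w <- t(w)
  if (is.null(rownames(w)))
    rownames(w) <- paste0(if (axis == "otus") "otu" else "site",
                          seq_len(nrow(w)))
  ## rows of w are focal units, columns are partners
  partner_tot <- colSums(w)
  grand <- sum(w)
  if (grand == 0) stop("matrix grand total is zero", call. = FALSE)
  keep <- partner_tot > 0
  q <- partner_tot[keep] / grand
  totals <- rowSums(w)
  if (any(totals == 0))
    warning("focal unit(s) with zero total excluded: ",
            paste(rownames(w)[totals == 0], collapse = ", "), call. = FALSE)
  out <- data.frame(id = rownames(w), total = as.integer(totals),
                    d = NA_real_, d_min = NA_real_, d_max = NA_real_,
                    d_prime = NA_real_, stringsAsFactors = FALSE)
  range_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(w))) {
    total <- totals[i]
    if (total == 0) next
    n_i <- w[i, keep]
    d <- d_of_allocation(n_i, q)
    key <- as.character(total)
    rng <- range_cache[[key]]
    if (is.null(rng)) {
      rng <- d_range(total, q, method)
      range_cache[[key]] <- rng
    }
    spread <- rng[["d_max"]] - rng[["d_min"]]
    dp <- if (spread < 1e-12) 0 else (d - rng[["d_min"]]) / spread
    out$d[i] <- d
    out$d_min[i] <- rng[["d_min"]]
    out$d_max[i] <- rng[["d_max"]]
    out$d_prime[i] <- min(max(dp, 0), 1)
  }
  out
}

## fast path used on null-ensemble members: d' for every focal unit of one
## matrix, ranges cached by focal total (q is shared within a matrix)
dprime_values <- function(w_focal_by_partner) {
  w <- w_focal_by_partner
  partner_tot <- colSums(w)
  grand <- sum(w)
  keep <- partner_tot > 0
  q <- partner_tot[keep] / grand
  totals <- rowSums(w)
  dp <- rep(NA_real_, nrow(w))
  rngs <- list()
  dmax1 <- log(1 / min(q))
  for (i in which(totals > 0)) {
    total <- totals[i]
    key <- as.character(total)
    rng <- rngs[[key]]
    if (is.null(rng)) {
      rng <- c(d_of_allocation(d_min_greedy(as.integer(total), q), q), dmax1)
      rngs[[key]] <- rng
    }
    d <- d_of_allocation(w[i, keep], q)
    spread <- rng[2] - rng[1]
    dp[i] <- if (spread < 1e-12) 0 else
      min(max((d - rng[1]) / spread, 0), 1)
  }
  names(dp) <- rownames(w)
  dp
}

#' Shuffle-sample null ensemble
#'
#' Randomizes the sample-to-site assignment (site sample counts fixed,
#' each sample's OTU content untouched) and rebuilds the site-level matrix
#' for every permutation. Column sums (OTU occupancies) and the
#' `samples_per_site` vector are conserved in every member by construction.
#'
#' @inheritParams build_site_matrix
#' @param n_permutations ensemble size.
#' @param seed optional seed.
#' @param exhaustive enumerate all `n!` sample-label permutations instead
#'   (small n only).
#' @return a `null_ensemble`: list with `matrices` (site x OTU x member
#'   array), `n_permutations`, `samples_per_site`, `exhaustive`.
#' @export
shuffle_sample_null <- function(presence, metadata, n_permutations = 1000,
                                seed = NULL, exhaustive = FALSE) {
  if (!exhaustive && n_permutations < 1)
    stop("n_permutations must be at least 1", call. = FALSE)
  p <- binarize(presence)
  metadata <- validate_sample_metadata(metadata)
  site <- metadata$site[match(rownames(p), metadata$sample_id)]
  if (anyNA(site))
    stop("samples without a site assignment", call. = FALSE)
  site <- factor(site, levels = unique(metadata$site))
  n <- nrow(p)
  pm <- unclass(p) * 1
  sites <- levels(site)
  build <- function(assign) {
    m <- rowsum(pm, group = factor(assign, levels = sites))
    m
  }
  if (exhaustive) {
    perms <- all_permutations(n)
  } else {
    perms <- with_seed_if(seed, function()
      t(vapply(seq_len(n_permutations), function(i) sample.int(n),
               integer(n))))
  }
  arr <- array(0, dim = c(length(sites), ncol(p), nrow(perms)),
               dimnames = list(sites, colnames(p), NULL))
  for (b in seq_len(nrow(perms))) {
    arr[, , b] <- build(site[perms[b, ]])
  }
  structure(list(matrices = arr, n_permutations = nrow(perms),
                 samples_per_site = as.integer(table(site)),
                 sites = sites, exhaustive = exhaustive, seed = seed),
            class = "null_ensemble")
}

## raw p for a z-like score / empirical counts
score_pvalue <- function(z, obs, null_mat, p_mode, two_sided = FALSE) {
  if (p_mode == "normal") {
    p <- stats::pnorm(z, lower.tail = FALSE)
    if (two_sided) p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
  } else {
    m <- ncol(null_mat)
    ge <- rowSums(null_mat >= obs - 1e-12)
    p <- (1 + ge) / (1 + m)
    if (two_sided) {
      le <- rowSums(null_mat <= obs + 1e-12)
      p <- pmin(1, 2 * pmin((1 + ge) / (1 + m), (1 + le) / (1 + m)))
    }
  }
  p
}

#' Standardized d' against the null ensemble
#'
#' `z = (d'_observed - mean(d'_randomized)) / sd(d'_randomized)` per OTU
#' (or per site). Focal units whose null SD is zero are flagged undefined
#' rather than silently set to 0.
#'
#' @param m the observed `site_fungus_matrix`.
#' @param ensemble a `null_ensemble` from [shuffle_sample_null()].
#' @param axis `"otus"` or `"sites"`.
#' @param p_mode `"normal"` (upper-tail standard-normal approximation,
#'   default) or `"empirical"` (rank against the ensemble,
#'   `(1 + b) / (1 + m)`).
#' @param two_sided report two-tailed p-values instead of upper-tailed.
#' @return data.frame with `id`, `d_prime_obs`, `null_mean`, `null_sd`,
#'   `z`, `p_raw`, `p_fdr` (Benjamini-Hochberg over the defined entries),
#'   `defined`.
#' @export
standardized_dprime <- function(m, ensemble, axis = c("otus", "sites"),
                                p_mode = c("normal", "empirical"),
                                two_sided = FALSE) {
  axis <- match.arg(axis)
  p_mode <- match.arg(p_mode)
  stopifnot(inherits(ensemble, "null_ensemble"))
  orient <- function(mat) if (axis == "otus") t(unclass(mat)) else
    unclass(mat)
  obs <- dprime_values(orient(m))
  B <- ensemble$n_permutations
  null_mat <- matrix(NA_real_, length(obs), B, dimnames = list(names(obs)))
  for (b in seq_len(B)) {
    null_mat[, b] <- dprime_values(orient(ensemble$matrices[, , b]))
  }
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1, stats::sd)
  defined <- !is.na(obs) & !is.na(sdv) & sdv > 1e-12
  z <- ifelse(defined, (obs - mu) / sdv, NA_real_)
  p <- rep(NA_real_, length(obs))
  p[defined] <- score_pvalue(z[defined], obs[defined],
                             null_mat[defined, , drop = FALSE],
                             p_mode, two_sided)
  p_fdr <- rep(NA_real_, length(obs))
  p_fdr[defined] <- fdr_adjust(p[defined])
  data.frame(id = names(obs), d_prime_obs = as.numeric(obs),
             null_mean = mu, null_sd = sdv, z = z,
             p_raw = p, p_fdr = p_fdr, defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-dimensional occurrence (2DO) scores
#'
#' Per site-OTU cell,
#' `2DO(i, j) = [N_obs(i, j) - mean(N_rand(i, j))] / sd(N_rand(i, j))`,
#' the z-like score of the observed sample count against the shuffle-sample
#' null. Raw p-values are upper-tailed (is the pair observed more often
#' than chance?): standard-normal approximation by default, or the
#' empirical rank `(1 + b) / (1 + m)` in empirical mode. Cells with null
#' SD zero are flagged undefined.
#'
#' @inheritParams standardized_dprime
#' @return an `occurrence_2do` list with matrices `n_obs`, `null_mean`,
#'   `null_sd`, `z`, `p_raw`, and `defined`, plus `p_mode`.
#' @export
two_dimensional_occurrence <- function(m, ensemble,
                                       p_mode = c("normal", "empirical"),
                                       two_sided = FALSE) {
  p_mode <- match.arg(p_mode)
  stopifnot(inherits(ensemble, "null_ensemble"))
  arr <- ensemble$matrices
  B <- ensemble$n_permutations
  n_obs <- unclass(m) * 1
  sum1 <- rowSums(arr, dims = 2)
  sum2 <- rowSums(arr^2, dims = 2)
  mu <- sum1 / B
  v <- pmax((sum2 - sum1^2 / B) / (B - 1), 0)
  sdv <- sqrt(v)
  defined <- sdv > 1e-12
  z <- matrix(NA_real_, nrow(n_obs), ncol(n_obs), dimnames = dimnames(n_obs))
  z[defined] <- (n_obs[defined] - mu[defined]) / sdv[defined]
  p <- matrix(NA_real_, nrow(n_obs), ncol(n_obs), dimnames = dimnames(n_obs))
  if (any(defined)) {
    null_flat <- matrix(arr, nrow = nrow(n_obs) * ncol(n_obs), ncol = B)
    p[defined] <- score_pvalue(z[defined], n_obs[defined],
                               null_flat[which(defined), , drop = FALSE],
                               p_mode, two_sided)
  }
  structure(list(n_obs = n_obs, null_mean = mu, null_sd = sdv, z = z,
                 p_raw = p, defined = defined, p_mode = p_mode),
            class = "occurrence_2do")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1. Input p-values must
#' lie in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Full site/fungus occurrence analysis
#'
#' Runs the whole chain on one table: binarization (when given counts),
#' site-level matrix, shuffle-sample null ensemble, standardized d' per OTU
#' and per site, and per-cell 2DO scores with raw p-values. FDR adjustment
#' is applied separately across OTU-level scores, site-level scores, and
#' jointly across all defined site-OTU cells.
#'
#' @param x an [otu_table()] (binarized internally; whether to pass the
#'   rarefied or the raw table is the caller's choice — the pipeline default
#'   is the rarefied table) or a presence table.
#' @param metadata per-sample metadata.
#' @param n_permutations ensemble size (survey convention: 1,000).
#' @param seed seed for the ensemble.
#' @param p_mode `"normal"` or `"empirical"` (see
#'   [two_dimensional_occurrence()]).
#' @param dprime_axes which standardized d' tables to compute; any subset
#'   of `c("otus", "sites")`. Skipping them (e.g. in large simulation
#'   sweeps that only need 2DO) saves most of the runtime.
#' @param two_sided two-tailed p-values.
#' @return an `occurrence_result` with elements `site_matrix`, `otus`,
#'   `sites`, `cells` (the 2DO object plus a joint `p_fdr` matrix),
#'   `rel_abundance` (when counts were supplied), and the run settings.
#' @export
occurrence_analysis <- function(x, metadata, n_permutations = 1000,
                                seed = NULL,
                                p_mode = c("normal", "empirical"),
                                dprime_axes = c("otus", "sites"),
                                two_sided = FALSE) {
  p_mode <- match.arg(p_mode)
  rel <- NULL
  if (inherits(x, "otu_table")) {
    rel <- colSums(x) / sum(x)
  }
  presence <- binarize(x)
  sm <- build_site_matrix(presence, metadata)
  ens <- shuffle_sample_null(presence, metadata,
                             n_permutations = n_permutations, seed = seed)
  otus <- if ("otus" %in% dprime_axes)
    standardized_dprime(sm, ens, "otus", p_mode, two_sided) else NULL
  sites <- if ("sites" %in% dprime_axes)
    standardized_dprime(sm, ens, "sites", p_mode, two_sided) else NULL
  cells <- two_dimensional_occurrence(sm, ens, p_mode, two_sided)
  cells$p_fdr <- matrix(NA_real_, nrow(sm), ncol(sm), dimnames = dimnames(sm))
  if (any(cells$defined))
    cells$p_fdr[cells$defined] <- fdr_adjust(cells$p_raw[cells$defined])
  structure(list(site_matrix = sm, otus = otus, sites = sites,
                 cells = cells, rel_abundance = rel,
                 settings = list(n_permutations = ens$n_permutations,
                                 seed = seed, p_mode = p_mode,
                                 two_sided = two_sided)),
            class = "occurrence_result")
}

#' @export
print.occurrence_result <- function(x, ...) {
  cat(sprintf("Occurrence analysis: %d sites x %d OTUs, %d permutations (%s p)\n",
              nrow(x$site_matrix), ncol(x$site_matrix),
              x$settings$n_permutations, x$settings$p_mode))
  invisible(x)
}

#' Summarise an occurrence analysis
#'
#' Counts and fractions of significant OTUs, sites and site-OTU cells at a
#' given FDR level. When `abundant_filter` is on (the usual reporting
#' choice — standardized d' is unreliable for rare OTUs), the analysis is
#' restricted to OTUs above `abundant_threshold` relative abundance and the
#' FDR correction is re-applied within that family. The number of cells
#' actually tested (defined null SD) is reported explicitly.
#'
#' @param result an `occurrence_result`.
#' @param alpha FDR significance level; `alpha >= 1` marks every defined
#'   entry significant (bound case).
#' @param abundant_filter restrict to abundant OTUs.
#' @param abundant_threshold relative-abundance cutoff for "abundant".
#' @return an `occurrence_report` list with `summary` (named numbers),
#'   `otus`, `sites` and `cells` data.frames (cells in long format keyed by
#'   site and OTU).
#' @export
occurrence_report <- function(result, alpha = 0.05, abundant_filter = TRUE,
                              abundant_threshold = 1e-3) {
  stopifnot(inherits(result, "occurrence_result"))
  sm <- result$site_matrix
  keep_otus <- colnames(sm)
  if (abundant_filter) {
    if (is.null(result$rel_abundance))
      stop("abundant_filter requires an analysis run on a count table",
           call. = FALSE)
    keep_otus <- names(result$rel_abundance)[
      result$rel_abundance > abundant_threshold]
    keep_otus <- intersect(colnames(sm), keep_otus)
  }
  sig_at <- function(p_fdr, defined) {
    if (alpha >= 1) defined else (!is.na(p_fdr) & p_fdr < alpha)
  }

  ## cells, re-adjusted within the reported family
  cells <- result$cells
  jdx <- match(keep_otus, colnames(sm))
  long <- expand.grid(site = rownames(sm), otu_id = keep_otus,
                      stringsAsFactors = FALSE)
  long$n_obs <- as.vector(cells$n_obs[, jdx, drop = FALSE])
  long$null_mean <- as.vector(cells$null_mean[, jdx, drop = FALSE])
  long$null_sd <- as.vector(cells$null_sd[, jdx, drop = FALSE])
  long$two_do <- as.vector(cells$z[, jdx, drop = FALSE])
  long$p_raw <- as.vector(cells$p_raw[, jdx, drop = FALSE])
  long$defined <- as.vector(cells$defined[, jdx, drop = FALSE])
  long$p_fdr <- NA_real_
  long$p_fdr[long$defined] <- fdr_adjust(long$p_raw[long$defined])
  long$significant <- sig_at(long$p_fdr, long$defined)

  otus <- result$otus
  if (!is.null(otus)) {
    otus <- otus[otus$id %in% keep_otus, , drop = FALSE]
    otus$p_fdr <- NA_real_
    otus$p_fdr[otus$defined] <- fdr_adjust(otus$p_raw[otus$defined])
    otus$significant <- sig_at(otus$p_fdr, otus$defined)
  }
  sites <- result$sites
  if (!is.null(sites)) {
    sites$significant <- sig_at(sites$p_fdr, sites$defined)
  }

  summary <- c(
    otus_tested = if (is.null(otus)) NA_integer_ else sum(otus$defined),
    otus_significant = if (is.null(otus)) NA_integer_ else
      sum(otus$significant, na.rm = TRUE),
    sites_tested = if (is.null(sites)) NA_integer_ else sum(sites$defined),
    sites_significant = if (is.null(sites)) NA_integer_ else
      sum(sites$significant, na.rm = TRUE),
    cells_tested = sum(long$defined),
    cells_significant = sum(long$significant, na.rm = TRUE))
  fr <- function(k, n) if (is.na(k) || n == 0) NA_real_ else k / n
  fractions <- c(
    otu_fraction = fr(summary[["otus_significant"]],
                      summary[["otus_tested"]]),
    site_fraction = fr(summary[["sites_significant"]],
                       summary[["sites_tested"]]),
    cell_fraction = fr(summary[["cells_significant"]],
                       summary[["cells_tested"]]))
  structure(list(summary = summary, fractions = fractions,
                 otus = otus, sites = sites, cells = long,
                 alpha = alpha, abundant_filter = abundant_filter,
                 abundant_threshold = abundant_threshold),
            class = "occurrence_report")
}

#' @export
print.occurrence_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Occurrence report (FDR < %g%s):\n", x$alpha,
              if (x$abundant_filter) ", abundant OTUs only" else ""))
  if (!is.na(s[["otus_significant"]]))
    cat(sprintf("  OTUs: %d of %d significant (%.0f%%)\n",
                s[["otus_significant"]], s[["otus_tested"]],
                100 * x$fractions[["otu_fraction"]]))
  if (!is.na(s[["sites_significant"]]))
    cat(sprintf("  sites: %d of %d significant\n",
                s[["sites_significant"]], s[["sites_tested"]]))
  cat(sprintf("  site-OTU cells: %d of %d tested significant (%.1f%%)\n",
              s[["cells_significant"]], s[["cells_tested"]],
              100 * x$fractions[["cell_fraction"]]))
  invisible(x)
}
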