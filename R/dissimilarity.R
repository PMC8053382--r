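#' Hellinger transformation
#'
#' Square root of per-sample relative abundances,
#' `cell = sqrt(count / row total)`; makes Bray-Curtis/Euclidean-type
#' distances well behaved for abundance data.
#'
#' @param x an [otu_table()] or non-negative matrix without all-zero rows.
#' @return numeric matrix of the same shape.
#' @export
hellinger_transform <- function(x) {
  m <- unclass(x)
  if (any(rowSums(m) == 0))
    stop("all-zero row(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  vegan::decostand(m, method = "hellinger")
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between rows.
#'
#' @param x non-negative matrix, rows = entities (samples or sites).
#' @return a `dist` object.
#' @export
bray_curtis <- function(x) {
  m <- unclass(x)
  if (any(m < 0)) stop("negative entries", call. = FALSE)
  if (sum(rowSums(m) == 0) >= 2)
    stop("two all-zero rows make their dissimilarity undefined",
         call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Sorensen dissimilarity on presence/absence data
#'
#' `d = 1 - 2a / (2a + b + c)` with `a` shared and `b`, `c` unique
#' presences; identical to Bray-Curtis applied to the binary matrix.
#'
#' @param presence binary matrix (a presence table from [binarize()]).
#' @return a `dist` object.
#' @export
sorensen <- function(presence) {
  m <- unclass(presence)
  if (!all(m %in% c(0, 1)))
    stop("sorensen() needs a binary matrix; use binarize()", call. = FALSE)
  if (sum(rowSums(m) == 0) >= 2)
    stop("two empty rows make their dissimilarity undefined", call. = FALSE)
  vegan::vegdist(m, method = "bray", binary = TRUE)
}

#' Geographic distance among samples or sites
#'
#' @param metadata data.frame with `latitude` and `longitude` (decimal
#'   degrees) and, for `by = "site"`, a `site` column; site coordinates are
#'   the means over the site's samples.
#' @param mode `"euclidean-degrees"` (plain Euclidean distance on the
#'   coordinate plane, the convention of small-extent surveys) or
#'   `"haversine-km"` (great-circle distance, mean Earth radius 6371 km).
#' @param by distances among `"sample"` rows (default) or aggregated
#'   `"site"` centres.
#' @return a `dist` object labelled by sample or site.
#' @export
geographic_distance <- function(metadata,
                                mode = c("euclidean-degrees", "haversine-km"),
                                by = c("sample", "site")) {
  mode <- match.arg(mode)
  by <- match.arg(by)
  if (anyNA(metadata$latitude) || anyNA(metadata$longitude))
    stop("missing coordinate(s)", call. = FALSE)
  if (by == "site") {
    lat <- tapply(metadata$latitude, metadata$site, mean)
    lon <- tapply(metadata$longitude, metadata$site, mean)
    ids <- names(lat)
  } else {
    lat <- metadata$latitude
    lon <- metadata$longitude
    ids <- metadata$sample_id %||% rownames(metadata)
  }
  if (mode == "euclidean-degrees") {
    d <- dist(cbind(lat, lon))
  } else {
    n <- length(lat)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      m[i, (i + 1):n] <- geosphere::distHaversine(
        c(lon[i], lat[i]), cbind(lon[(i + 1):n], lat[(i + 1):n]),
        r = 6371000) / 1000
    }
    d <- stats::as.dist(m + t(m))
  }
  attr(d, "Labels") <- as.character(ids)
  d
}

## lower-triangle vector with id check
dist_vec <- function(d, other = NULL) {
  d <- stats::as.dist(d)
  if (!is.null(other)) {
    l1 <- attr(d, "Labels"); l2 <- attr(other, "Labels")
    if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
      stop("distance matrices are labelled differently", call. = FALSE)
    if (attr(d, "Size") != attr(other, "Size"))
      stop("distance matrices differ in size", call. = FALSE)
  }
  as.vector(d)
}

perm_test_result <- function(statistic, p_value, n_permutations, exhaustive,
                             what, extra = NULL) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   n_permutations = n_permutations, exhaustive = exhaustive,
                   what = what), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s, %d permutations)\n",
              x$what, x$statistic, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' Mantel test
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices; significance by simultaneous row/column permutation of the
#' second matrix. Exhaustive enumeration of all `n!` permutations is used
#' automatically when the permutation space is at most 10,000 (p is then
#' the exact fraction of permutations, identity included, with a
#' correlation at least as large); otherwise Monte-Carlo with the
#' `(1 + b) / (1 + m)` convention.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) over the same
#'   entities.
#' @param n_permutations Monte-Carlo permutation count.
#' @param seed optional seed.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) enumeration;
#'   `NULL` = automatic.
#' @return a `perm_test` with the correlation as statistic.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = NULL,
                        exhaustive = NULL) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  n <- attr(d1, "Size")
  if (n < 4) stop("mantel test needs at least 4 entities", call. = FALSE)
  v1 <- dist_vec(d1, d2)
  m2 <- as.matrix(d2)
  v2 <- as.vector(stats::as.dist(m2))
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a distance matrix", call. = FALSE)
  obs <- cor(v1, v2)
  stat_for <- function(idx) cor(v1, as.vector(stats::as.dist(m2[idx, idx])))
  if (is.null(exhaustive)) exhaustive <- factorial(n) <= 10000
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_all <- apply(perms, 1, stat_for)
    p <- mean(stats_all >= obs - 1e-12)
    return(perm_test_result(obs, p, nrow(perms), TRUE, "Mantel r"))
  }
  permuted <- with_seed_if(seed, function()
    vapply(seq_len(n_permutations),
           function(i) stat_for(sample.int(n)), numeric(1)))
  perm_test_result(obs, mc_pvalue(obs - 1e-12, permuted), n_permutations,
                   FALSE, "Mantel r")
}

## distance-based sums of squares for one grouping
permanova_stats <- function(d2mat, groups) {
  n <- nrow(d2mat)
  lev <- unique(groups)
  k <- length(lev)
  lower <- lower.tri(d2mat)
  ss_total <- sum(d2mat[lower]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    sub <- d2mat[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  c(F = f, R2 = ss_between / ss_total)
}

#' PerMANOVA (distance-based multivariate analysis of variance)
#'
#' Partitions the squared-dissimilarity sum of squares between and within
#' groups: `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, with
#' `pseudo-F = [SS_between / (k - 1)] / [SS_within / (n - k)]` and
#' `R2 = SS_between / SS_total`. Significance by permuting group labels;
#' exhaustive enumeration as in [mantel_test()]. With Euclidean distances
#' on one coordinate the pseudo-F equals the classical one-way ANOVA F.
#'
#' @param d a `dist` object (or symmetric matrix).
#' @param groups group label per entity; at least 2 groups with at least 2
#'   members each.
#' @inheritParams mantel_test
#' @return a `perm_test` with pseudo-F as statistic and an `R2` element.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      exhaustive = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("one group label per entity required", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  d2mat <- as.matrix(d)^2
  if (sum(d2mat) == 0)
    stop("all entities identical: no variance to partition", call. = FALSE)
  obs <- permanova_stats(d2mat, groups)
  if (is.null(exhaustive)) exhaustive <- factorial(n) <= 10000
  if (exhaustive) {
    perms <- all_permutations(n)
    fs <- apply(perms, 1, function(idx)
      permanova_stats(d2mat, groups[idx])[["F"]])
    p <- mean(fs >= obs[["F"]] - 1e-12)
    return(perm_test_result(obs[["F"]], p, nrow(perms), TRUE,
                            "PerMANOVA pseudo-F",
                            extra = list(R2 = obs[["R2"]])))
  }
  fs <- with_seed_if(seed, function()
    vapply(seq_len(n_permutations), function(i)
      permanova_stats(d2mat, groups[sample.int(n)])[["F"]], numeric(1)))
  perm_test_result(obs[["F"]], mc_pvalue(obs[["F"]] - 1e-12, fs),
                   n_permutations, FALSE, "PerMANOVA pseudo-F",
                   extra = list(R2 = obs[["R2"]]))
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: pairwise distances above a
#' truncation threshold (default: the longest edge of the minimum spanning
#' tree) are replaced by four times the threshold, the truncated matrix is
#' Gower double-centred and eigen-decomposed, and the eigenvectors with
#' positive eigenvalues are returned as spatial predictors.
#'
#' @param coords two-column matrix/data.frame of coordinates (or a `dist`).
#' @param threshold optional truncation distance.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are treated as zero.
#' @return list with `vectors` (entities x axes), `values` (positive
#'   eigenvalues) and `threshold`.
#' @export
pcnm_vectors <- function(coords, threshold = NULL, tol = 1e-8) {
  d <- if (inherits(coords, "dist")) coords else dist(as.matrix(coords))
  n <- attr(d, "Size")
  if (n < 2) stop("need at least two points", call. = FALSE)
  if (max(d) == 0) stop("all points identical", call. = FALSE)
  if (is.null(threshold)) {
    ## longest edge of the minimum spanning tree
    threshold <- max(vegan::spantree(d)$dist)
  }
  m <- as.matrix(d)
  m[m > threshold] <- 4 * threshold
  ## Gower double-centring of -d^2/2
  g <- -0.5 * m^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))  # successive sweeps add the grand mean back
  ## numerical symmetrisation before eigen
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  vectors <- e$vectors[, keep, drop = FALSE]
  colnames(vectors) <- paste0("PCNM", seq_len(ncol(vectors)))
  rownames(vectors) <- attr(d, "Labels")
  list(vectors = vectors, values = e$values[keep], threshold = threshold)
}

#' Fit environmental vectors onto ordination scores
#'
#' For each variable, a least-squares fit of the (centred) variable on the
#' (centred) score axes gives an arrow direction (unit-normalised
#' coefficients) and `R^2`, the squared correlation between fitted and
#' observed values. Significance by permuting the variable across
#' entities; exhaustive enumeration as in [mantel_test()].
#'
#' @param scores entities x axes matrix of ordination coordinates (e.g. two
#'   NMDS axes from any external embedding).
#' @param variables data.frame/matrix of one value per entity per variable.
#' @inheritParams mantel_test
#' @return data.frame with one row per variable: arrow components, `r2`,
#'   `p_value`, `n_permutations`.
#' @export
env_fit <- function(scores, variables, n_permutations = 999, seed = NULL,
                    exhaustive = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3) stop("need at least three entities", call. = FALSE)
  variables <- as.data.frame(variables)
  s <- scale(scores, center = TRUE, scale = FALSE)
  r2_of <- function(v) {
    vc <- v - mean(v)
    fit <- s %*% solve(crossprod(s), crossprod(s, vc))
    denom <- sum(vc^2)
    sum(fit^2) / denom  # == squared correlation of fitted vs observed
  }
  if (is.null(exhaustive)) exhaustive <- factorial(n) <= 10000
  rows <- lapply(names(variables), function(nm) {
    v <- as.numeric(variables[[nm]])
    if (stats::sd(v) == 0)
      stop("constant variable: ", nm, call. = FALSE)
    vc <- v - mean(v)
    b <- solve(crossprod(s), crossprod(s, vc))
    arrow <- as.numeric(b / sqrt(sum(b^2)))
    r2 <- r2_of(v)
    if (exhaustive) {
      perms <- all_permutations(n)
      r2s <- apply(perms, 1, function(idx) r2_of(v[idx]))
      p <- mean(r2s >= r2 - 1e-12)
      m <- nrow(perms)
    } else {
      r2s <- with_seed_if(seed, function()
        vapply(seq_len(n_permutations),
               function(i) r2_of(v[sample.int(n)]), numeric(1)))
      p <- mc_pvalue(r2 - 1e-12, r2s)
      m <- n_permutations
    }
    out <- data.frame(variable = nm, r2 = r2, p_value = p,
                      n_permutations = m, stringsAsFactors = FALSE)
    for (a in seq_along(arrow)) out[[paste0("axis", a)]] <- arrow[a]
    out
  })
  do.call(rbind, rows)
}
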