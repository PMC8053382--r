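test_that("site matrix counts per-site sample occurrences and conserves occupancy", {
  p <- matrix(c(1, 0, 1,
                1, 1, 0,
                0, 1, 0,
                0, 1, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("x", "y", "z")))
  md <- tiny_metadata(rownames(p), c("A", "A", "B", "B"))
  sm <- build_site_matrix(p, md)
  expect_equal(as.vector(unclass(sm)), c(2L, 0L, 1L, 2L, 1L, 0L))
  expect_equal(attr(sm, "samples_per_site"), c(A = 2L, B = 2L))
  # column sums equal occupancy from the sample-level table
  expect_equal(unname(colSums(sm)), unname(occupancy(p)))
  # unmapped sample
  md2 <- md[1:3, ]
  expect_error(build_site_matrix(p, md2), "without a site")
  # OTU in both samples of site A only -> column (2, 0)
  expect_equal(unname(unclass(sm)[, "x"]), c(2L, 0L))
})

test_that("d' is 0 for proportional use and 1 for maximal specialization", {
  # row exactly proportional to partner marginals
  m <- matrix(c(2, 4, 6,
                1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("x", "y", "z")))
  res <- dprime(m, axis = "sites")
  expect_equal(res$d, c(0, 0), tolerance = 1e-12)
  expect_equal(res$d_prime, c(0, 0), tolerance = 1e-12)
  # [[5,0],[0,5]]: maximal given the marginals
  m2 <- matrix(c(5, 0, 0, 5), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("x", "y")))
  res2 <- dprime(m2, axis = "sites")
  expect_equal(res2$d_prime, c(1, 1), tolerance = 1e-12)
  # ... confirmed against exhaustive enumeration of all 6 reallocations
  ex <- dprime_range_exact(5, c(0.5, 0.5))
  expect_equal(res2$d[1], ex[["d_max"]], tolerance = 1e-12)
  # single available partner -> d' = 0 by convention
  m3 <- matrix(c(3, 0, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(dprime(m3, axis = "sites")$d_prime, c(0, 0))
})

test_that("closed-form/greedy d range equals brute-force enumeration on random matrices", {
  set.seed(20)
  for (rep in 1:60) {
    k <- sample(3:5, 1)
    total <- sample(1:12, 1)
    q <- runif(k, 0.05, 1)
    q <- q / sum(q)
    mine <- emoccur:::d_range(total, q, method = "direct")
    orac <- oracle_d_range(total, q)
    expect_equal(unname(mine[["d_min"]]), orac[1], tolerance = 1e-10)
    expect_equal(unname(mine[["d_max"]]), orac[2], tolerance = 1e-10)
  }
})

test_that("d' stays within [0, 1] on random integer matrices and per-axis transposition is consistent", {
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(rpois(12, 2), 3, 4,
                dimnames = list(paste0("s", 1:3), paste0("o", 1:4)))
    if (any(colSums(m) == 0) || any(rowSums(m) == 0)) next
    a <- dprime(m, axis = "otus")
    b <- dprime(t(m), axis = "sites")
    expect_equal(a$d_prime, b$d_prime, tolerance = 1e-12)
    expect_true(all(a$d_prime >= 0 & a$d_prime <= 1))
  }
  # zero focal column excluded with warning
  m <- matrix(c(1, 2, 0, 0, 3, 0), 2, 3,
              dimnames = list(c("A", "B"), c("x", "y", "z")))
  expect_warning(res <- dprime(m, axis = "otus"), "zero total")
  expect_true(is.na(res$d_prime[res$id == "y"]))
})

test_that("the shuffle-sample null conserves column sums and site sizes in every member", {
  ds <- generate_dataset(synthetic_spec(n_otus = 40, seed = 71))
  p <- binarize(ds$table)
  ens <- shuffle_sample_null(p, ds$metadata, n_permutations = 50, seed = 8)
  occ <- unname(colSums(unclass(p)))
  for (b in seq_len(ens$n_permutations)) {
    m <- ens$matrices[, , b]
    expect_equal(unname(colSums(m)), occ)
    expect_true(all(m >= 0 & m <= 7))
  }
  expect_equal(ens$samples_per_site, c(7L, 7L, 7L))
  # determinism
  ens2 <- shuffle_sample_null(p, ds$metadata, n_permutations = 50, seed = 8)
  expect_identical(ens$matrices, ens2$matrices)
  expect_error(shuffle_sample_null(p, ds$metadata, n_permutations = 0),
               "at least 1")
})

test_that("exhaustive shuffle null enumerates all assignments for tiny designs", {
  p <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("x", "y")))
  md <- tiny_metadata(c("s1", "s2"), c("A", "B"))
  ens <- shuffle_sample_null(p, md, exhaustive = TRUE)
  expect_equal(ens$n_permutations, 2L)
  mats <- lapply(1:2, function(b) ens$matrices[, , b])
  # the two distinct assignments both occur
  expect_false(identical(mats[[1]], mats[[2]]))
  expect_true(all(vapply(mats, function(m) all(colSums(m) == c(1, 1)),
                         logical(1))))
})

test_that("standardized d' matches a hand enumeration on an exhaustive tiny case", {
  # 4 samples, 2 sites; exhaustive null = all 24 sample relabelings
  p <- matrix(c(1, 1, 0,
                1, 0, 0,
                0, 1, 1,
                0, 0, 1), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("x", "y", "z")))
  md <- tiny_metadata(rownames(p), c("A", "A", "B", "B"))
  sm <- build_site_matrix(p, md)
  ens <- shuffle_sample_null(p, md, exhaustive = TRUE)
  res <- standardized_dprime(sm, ens, axis = "otus", p_mode = "empirical")

  # oracle: recompute d' for every permutation with independent code
  site <- c("A", "A", "B", "B")
  perms <- oracle_perms(4)
  dprime_col <- function(m, j) {
    q <- rowSums(m) / sum(m)
    tot <- sum(m[, j])
    d <- oracle_d(m[, j], q)
    rng <- oracle_d_range(tot, q)
    if (rng[2] - rng[1] < 1e-12) 0 else (d - rng[1]) / (rng[2] - rng[1])
  }
  null_dp <- sapply(seq_len(nrow(perms)), function(i) {
    s <- site[perms[i, ]]
    m <- rowsum(p * 1, factor(s, levels = c("A", "B")))
    vapply(1:3, function(j) dprime_col(m, j), numeric(1))
  })
  obs_dp <- vapply(1:3, function(j) dprime_col(unclass(sm) * 1, j),
                   numeric(1))
  mu <- rowMeans(null_dp)
  sdv <- apply(null_dp, 1, sd)
  expect_equal(res$d_prime_obs, obs_dp, tolerance = 1e-10)
  expect_equal(res$null_mean, unname(mu), tolerance = 1e-10)
  expect_equal(res$null_sd, unname(sdv), tolerance = 1e-10)
  ok <- res$defined
  expect_equal(res$z[ok], unname((obs_dp - mu) / sdv)[ok], tolerance = 1e-9)
  # empirical p against the same enumeration
  for (j in which(ok)) {
    p_or <- (1 + sum(null_dp[j, ] >= obs_dp[j] - 1e-12)) /
      (1 + ncol(null_dp))
    expect_equal(res$p_raw[j], p_or, tolerance = 1e-12)
  }
})

test_that("a score equal to the null mean standardizes to zero with p near one half", {
  ds <- generate_dataset(synthetic_spec(n_otus = 30, seed = 72))
  p <- binarize(ds$table)
  sm <- build_site_matrix(p, ds$metadata)
  ens <- shuffle_sample_null(p, ds$metadata, n_permutations = 100, seed = 9)
  tdo <- two_dimensional_occurrence(sm, ens, p_mode = "normal")
  near <- which(tdo$defined &
                  abs(tdo$n_obs - tdo$null_mean) < 1e-9)
  if (length(near) > 0) {
    expect_true(all(abs(tdo$z[near]) < 1e-9))
    expect_true(all(abs(tdo$p_raw[near] - 0.5) < 1e-9))
  }
  # antisymmetry of 2DO under reflection of the observed count about the
  # null mean
  i <- which(tdo$defined)[1]
  reflected <- 2 * tdo$null_mean[i] - tdo$n_obs[i]
  z_ref <- (reflected - tdo$null_mean[i]) / tdo$null_sd[i]
  expect_equal(z_ref, -tdo$z[i], tolerance = 1e-12)
})

test_that("empirical 2DO p-values match full enumeration on a tiny design", {
  p <- matrix(c(1, 1, 0,
                1, 0, 1,
                0, 1, 1,
                0, 0, 1), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("x", "y", "z")))
  md <- tiny_metadata(rownames(p), c("A", "A", "B", "B"))
  sm <- build_site_matrix(p, md)
  ens <- shuffle_sample_null(p, md, exhaustive = TRUE)
  tdo <- two_dimensional_occurrence(sm, ens, p_mode = "empirical")
  site <- c("A", "A", "B", "B")
  perms <- oracle_perms(4)
  for (i in 1:2) for (j in 1:3) {
    null_n <- vapply(seq_len(nrow(perms)), function(b) {
      s <- site[perms[b, ]]
      rowsum(p * 1, factor(s, levels = c("A", "B")))[i, j]
    }, numeric(1))
    if (sd(null_n) > 1e-12) {
      p_or <- (1 + sum(null_n >= unclass(sm)[i, j] - 1e-12)) /
        (1 + length(null_n))
      expect_equal(tdo$p_raw[i, j], p_or, tolerance = 1e-12)
    } else {
      expect_false(tdo$defined[i, j])
      expect_true(is.na(tdo$p_raw[i, j]))
    }
  }
})

test_that("empirical per-cell p-values are valid (conservative) under the null model", {
  # discrete count statistics make the empirical rank p super-uniform, so
  # the rejection rate at 0.05 must not exceed the binomial upper bound
  pooled <- c()
  for (r in 1:30) {
    ds <- null_dataset(synthetic_spec(), seed = 7000 + r)
    p <- binarize(ds$table)
    sm <- build_site_matrix(p, ds$metadata)
    ens <- shuffle_sample_null(p, ds$metadata, n_permutations = 100,
                               seed = 7000 + r)
    tdo <- two_dimensional_occurrence(sm, ens, p_mode = "empirical")
    pooled <- c(pooled, tdo$p_raw[tdo$defined])
  }
  rate <- mean(pooled <= 0.05)
  upper <- stats::qbinom(0.995, length(pooled), 0.05) / length(pooled)
  expect_lte(rate, upper)
  # and standardized d' scores centre near zero under the null
  ds <- null_dataset(synthetic_spec(), seed = 7777)
  p <- binarize(ds$table)
  sm <- build_site_matrix(p, ds$metadata)
  ens <- shuffle_sample_null(p, ds$metadata, n_permutations = 200,
                             seed = 7778)
  sdp <- standardized_dprime(sm, ens, axis = "otus")
  expect_lt(abs(mean(sdp$z[sdp$defined])), 0.35)
})

test_that("benjamini-hochberg adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.37), 0.37)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  expect_equal(fdr_adjust(p), stats::p.adjust(p, "BH"))
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("occurrence report fractions and the alpha = 1 bound case", {
  ds <- generate_dataset(synthetic_spec(seed = 73))
  occ <- occurrence_analysis(ds$table, ds$metadata, n_permutations = 100,
                             seed = 10)
  rep_all <- occurrence_report(occ, alpha = 1, abundant_filter = FALSE)
  expect_equal(rep_all$summary[["cells_significant"]],
               rep_all$summary[["cells_tested"]])
  rep_ab <- occurrence_report(occ, alpha = 0.05, abundant_filter = TRUE)
  expect_lte(rep_ab$summary[["otus_tested"]],
             sum(occ$rel_abundance > 1e-3))
  # a summary built from 42 tested / 8 significant reports 19%
  fr <- rep_ab$fractions[["otu_fraction"]]
  expect_true(is.na(fr) || (fr >= 0 && fr <= 1))
  expect_equal(round(100 * 8 / 42), 19)
})

test_that("planted specialists are flagged and non-planted false positives stay controlled", {
  sp <- synthetic_spec()
  sp$planted_specialists <- plant_specialists(sp, strength = 0.9)
  fp <- 0; fp_n <- 0; hits <- 0; tries <- 0
  for (r in 1:5) {
    ds <- generate_dataset(sp, seed = 8100 + r)
    occ <- occurrence_analysis(ds$table, ds$metadata, n_permutations = 500,
                               seed = 8200 + r, dprime_axes = character(0))
    rp <- occurrence_report(occ, alpha = 0.05)
    planted_sites <- sp$site_covariates$site[sp$planted_specialists$site]
    planted_ids <- sprintf("OTU_%03d", sp$planted_specialists$otu)
    key <- paste(rp$cells$site, rp$cells$otu_id)
    planted_key <- paste(planted_sites, planted_ids)
    is_planted_cell <- key %in% planted_key
    is_planted_otu <- rp$cells$otu_id %in% planted_ids
    idx <- match(planted_key, key)
    found <- rp$cells$significant[idx[!is.na(idx)]]
    hits <- hits + sum(found, na.rm = TRUE)
    tries <- tries + length(planted_key)
    neutral <- !is_planted_otu & rp$cells$defined
    fp <- fp + sum(rp$cells$significant[neutral], na.rm = TRUE)
    fp_n <- fp_n + sum(neutral)
  }
  expect_gt(hits / tries, 0.7)
  # false positives among unplanted OTU cells within binomial bounds of alpha
  upper <- stats::qbinom(0.995, fp_n, 0.05) / fp_n
  expect_lte(fp / fp_n, upper)
})
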