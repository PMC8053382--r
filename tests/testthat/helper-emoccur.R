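# Fixtures and independent oracles shared across the suite.

# small deterministic count table: 4 samples x 5 OTUs
tiny_table <- function() {
  m <- matrix(c(5, 3, 2, 0, 0,
                0, 4, 0, 1, 0,
                2, 2, 2, 2, 2,
                7, 0, 0, 0, 3),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("o", 1:5)))
  otu_table(m)
}

tiny_metadata <- function(sample_ids, sites) {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids, site = sites,
             latitude = 50 + seq_len(n) / 10,
             longitude = 120 + seq_len(n) / 10,
             MAT = -2 + seq_len(n) / 5, MAP = 400 + 2 * seq_len(n),
             pH = 5.5, N = 3, P = 0.5, K = 15, OM = 60,
             stringsAsFactors = FALSE)
}

# metadata matching a generated em_dataset
dataset_metadata <- function(ds) ds$metadata

# independent d statistic (plain formula, no shared code paths)
oracle_d <- function(n_vec, q) {
  tot <- sum(n_vec)
  p <- n_vec / tot
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# exhaustive d range by direct composition enumeration (written against
# oracle_d, independent of the package internals)
oracle_d_range <- function(total, q) {
  k <- length(q)
  grid <- expand.grid(rep(list(0:total), k))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  vals <- apply(grid, 1, oracle_d, q = q)
  c(min(vals), max(vals))
}

# all permutations of seq_len(n) via recursion (test-side, independent)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

make_site_matrix <- function(m, sites_per_row = NULL) {
  class(m) <- c("site_fungus_matrix", "matrix", "array")
  m
}
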