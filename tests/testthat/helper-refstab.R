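# Shared fixtures and independent oracles for the test suite.

# Random complete Cq matrix in a plausible cycle range.
random_cq <- function(n = 10, G = 5, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * G, mean = 26, sd = sd), n, G,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", sprintf("%02d", seq_len(G)))))
  m
}

# Brute-force comparative delta-Ct oracle: explicit double loop over gene
# pairs, independent of the vectorised implementation.
oracle_delta_ct <- function(m) {
  G <- ncol(m)
  out <- numeric(G)
  for (g in seq_len(G)) {
    sds <- c()
    for (k in seq_len(G)) {
      if (k == g) next
      d <- m[, g] - m[, k]
      mu <- sum(d) / length(d)
      sds <- c(sds, sqrt(sum((d - mu)^2) / (length(d) - 1)))
    }
    out[g] <- mean(sds)
  }
  names(out) <- colnames(m)
  out
}

# Hand-rolled n-1 standard deviation for tiny fixtures.
sd1 <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

# Long-format replicate table for a dense design.
make_replicates <- function(samples, genes, cq_fun, replicates = 3) {
  grid <- expand.grid(replicate = seq_len(replicates), gene = genes,
                      sample_id = samples, stringsAsFactors = FALSE)
  grid <- grid[c("sample_id", "gene", "replicate")]
  grid$cq <- mapply(cq_fun, grid$sample_id, grid$gene, grid$replicate)
  grid
}

beluga_rank_columns <- function(samples) {
  tab <- beluga_stability_table(samples)
  r <- as.matrix(tab[c("delta_ct_rank", "bestkeeper_rank",
                       "normfinder_rank", "genorm_rank")])
  rownames(r) <- tab$gene
  r
}
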