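# shared fixtures and independent oracles used across test files

# draw one Dirichlet-multinomial sample
rdirmult <- function(n_i, pi, gamma) {
  p <- rgamma(length(pi), shape = gamma * pi)
  rmultinom(1, n_i, p / sum(p))[, 1]
}

# a DTUDataset of DM-distributed null genes (no group difference)
make_null_dm_dataset <- function(n_genes, n_samples = 12, gamma = 20,
                                 total = 800, K_range = 2:4, seed = 1) {
  set.seed(seed)
  genes <- lapply(seq_len(n_genes), function(g) {
    K <- if (length(K_range) > 1) sample(K_range, 1) else K_range
    pi <- rgamma(K, 2); pi <- pi / sum(pi)
    sapply(seq_len(n_samples), function(i)
      rdirmult(rpois(1, total), pi, gamma))
  })
  cts <- do.call(rbind, genes)
  gids <- rep(sprintf("SIMG%011d.1", seq_len(n_genes)),
              vapply(genes, nrow, 1L))
  tids <- sprintf("SIMT%011d.1", seq_len(nrow(cts)))
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(n_samples)),
                        condition = rep(c("1", "2"), each = n_samples / 2))
  dtu_dataset(cts, gids, tids, samples)
}

# write a small TranscriptQuantSet-shaped set of quant.sf files by hand
write_toy_quants <- function(dir, tpm, eff_len, reads, len,
                             tx = rownames(tpm), reorder_sample = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(tpm))
  for (i in seq_len(ncol(tpm))) {
    sdir <- file.path(dir, colnames(tpm)[i])
    dir.create(sdir, showWarnings = FALSE)
    ord <- seq_along(tx)
    if (!is.null(reorder_sample) && i == reorder_sample)
      ord <- rev(ord)
    df <- data.frame(Name = tx[ord], Length = len[ord],
                     EffectiveLength = eff_len[ord, i],
                     TPM = tpm[ord, i], NumReads = reads[ord, i])
    paths[i] <- file.path(sdir, "quant.sf")
    write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  setNames(paths, colnames(tpm))
}

# independent step-up BH oracle: literal enumeration of the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(p[o][k:m] * m / (k:m)))
  }
  adj
}

# independent direct DM pmf oracle (with multinomial coefficient)
dm_pmf_oracle <- function(y, pi, gamma) {
  n <- sum(y)
  coef <- lgamma(n + 1) - sum(lgamma(y + 1))
  exp(coef + lgamma(gamma) - lgamma(n + gamma) +
        sum(lgamma(y + gamma * pi) - lgamma(gamma * pi)))
}

# beta-binomial log-pmf (two-category DM), for one-vs-rest oracles
bb_logpmf <- function(x, n, p, gamma) {
  a <- gamma * p; b <- gamma * (1 - p)
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}
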