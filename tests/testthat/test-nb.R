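nb_samples <- function(n_per_group = 6) {
  data.frame(sample_id = sprintf("s%d", seq_len(2 * n_per_group)),
             condition = rep(c("1", "2"), each = n_per_group))
}

test_that("augmented one-vs-rest counts reconstruct the gene totals", {
  # gene with transcripts at (3, 7): pairs (3,7) and (7,3)
  ds <- dtu_dataset(rbind(c(3, 5), c(7, 2)), c("G1", "G1"), c("T1", "T2"),
                    data.frame(sample_id = c("a", "b"),
                               condition = c("1", "2")))
  aug <- build_augmented_counts(ds)
  expect_equal(unname(aug$this[, 1]), c(3, 7))
  expect_equal(unname(aug$others[, 1]), c(7, 3))
  # single-transcript gene: others all zero
  ds1 <- dtu_dataset(rbind(c(4, 9)), "G1", "T1",
                     data.frame(sample_id = c("a", "b"),
                                condition = c("1", "2")))
  expect_true(all(build_augmented_counts(ds1)$others == 0))
  # random fixture: this + others equals the per-sample gene total
  set.seed(41)
  cts <- matrix(rnbinom(60, mu = 30, size = 3), 10)
  gids <- rep(c("G1", "G2", "G3"), c(4, 3, 3))
  ds <- dtu_dataset(cts, gids, sprintf("T%02d", 1:10), nb_samples(3))
  aug <- build_augmented_counts(ds)
  tot <- rowsum(round(ds$counts), ds$gene_ids)
  expect_equal(aug$this + aug$others,
               tot[match(ds$gene_ids, rownames(tot)), ],
               ignore_attr = TRUE)
})

test_that("size factors follow median-of-ratios with geometric mean 1", {
  # identical columns: all factors 1
  m <- matrix(rep(c(10, 20, 35, 50), 3), 4)
  expect_equal(unname(estimate_size_factors(m)), rep(1, 3))
  # one column doubled: its factor is twice the others after renormalizing
  m2 <- cbind(a = c(10, 20, 35, 50), b = c(20, 40, 70, 100),
              c = c(10, 20, 35, 50))
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # explicit hand computation on a 5 x 3 matrix (odd row count, so the
  # ratio-scale and log-scale medians coincide)
  m3 <- matrix(c(4, 10, 20, 40, 12,
                 8, 10, 10, 80, 18,
                 2, 10, 40, 20, 9), 5)
  geo <- exp(rowMeans(log(m3)))
  raw <- apply(m3 / geo, 2, median)
  expect_equal(unname(estimate_size_factors(m3)),
               unname(raw / exp(mean(log(raw)))))
  # a zero in every row leaves nothing to anchor the ratios
  mz <- matrix(c(0, 5, 5, 0), 2)
  expect_error(estimate_size_factors(mz), "all-positive")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(80, mu = 100, size = 5) + 1, 20)
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same up to the geometric-mean-1 normalization we apply
  expect_equal(unname(ours), unname(ref / exp(mean(log(ref)))),
               tolerance = 1e-10)
})

sim_aug_dataset <- function(n_genes, mu = 500, size = 10, n_per_group = 6,
                            seed = 1, switch_first = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_group
  cts <- matrix(0, 2 * n_genes, n)
  for (g in seq_len(n_genes)) {
    m1 <- mu * runif(1, 0.5, 1.5); m2 <- mu * runif(1, 0.5, 1.5)
    r1 <- rnbinom(n, mu = m1, size = size)
    r2 <- rnbinom(n, mu = m2, size = size)
    if (switch_first && g == 1) {
      r1 <- c(rnbinom(n_per_group, mu = 1000, size = size),
              rnbinom(n_per_group, mu = 5, size = size))
      r2 <- c(rnbinom(n_per_group, mu = 5, size = size),
              rnbinom(n_per_group, mu = 1000, size = size))
    }
    cts[2 * g - 1, ] <- r1
    cts[2 * g, ] <- r2
  }
  dtu_dataset(cts, rep(sprintf("G%03d", seq_len(n_genes)), each = 2),
              sprintf("T%04d", seq_len(2 * n_genes)),
              nb_samples(n_per_group))
}

test_that("dispersion estimation recovers the truth and shrinks sensibly", {
  # NB data with dispersion 0.1 at mean ~500, 12 samples
  ds <- sim_aug_dataset(40, mu = 500, size = 10, seed = 43)
  aug <- build_augmented_counts(ds)
  sf <- estimate_size_factors(round(ds$counts))
  disp <- estimate_dispersions(aug, sf)
  expect_true(all(disp$disp_map >= 1e-8))
  expect_gt(median(disp$disp_mle), 0.05)
  expect_lt(median(disp$disp_mle), 0.2)
  # Poisson data: shrunken dispersions collapse toward zero
  set.seed(44)
  cts <- matrix(rpois(80 * 12, lambda = 400), 80)
  dsp <- dtu_dataset(cts, rep(sprintf("G%03d", 1:40), each = 2),
                     sprintf("T%04d", 1:80), nb_samples())
  augp <- build_augmented_counts(dsp)
  dispp <- estimate_dispersions(augp, estimate_size_factors(round(cts)))
  expect_lt(median(dispp$disp_map), 0.01)
  # a transcript with one extreme outlier keeps its high dispersion
  ds_o <- sim_aug_dataset(30, mu = 500, size = 50, seed = 45)
  ds_o$counts[1, 1] <- 20000
  aug_o <- build_augmented_counts(ds_o)
  disp_o <- estimate_dispersions(aug_o,
                                 estimate_size_factors(round(ds_o$counts)))
  expect_gt(disp_o$disp_map[1], 2 * disp_o$disp_trend[1])
})

test_that("the interaction LRT has df 1, detects switches, and is sample-
           order invariant", {
  ds <- sim_aug_dataset(30, seed = 46, switch_first = TRUE)
  aug <- build_augmented_counts(ds)
  sf <- estimate_size_factors(round(ds$counts))
  disp <- estimate_dispersions(aug, sf)
  res <- test_interaction_lrt(aug, sf, disp$disp_map)
  expect_true(all(res$df == 1))
  # simulated two-isoform switch: overwhelming evidence
  expect_lt(res$pvalue[1], 1e-8)
  # permuting the sample order leaves the statistics unchanged
  perm <- c(3, 1, 2, 6, 5, 4, 9, 7, 8, 12, 11, 10)
  ds2 <- dtu_dataset(ds$counts[, perm], ds$gene_ids, ds$transcript_ids,
                     ds$samples[perm, ])
  aug2 <- build_augmented_counts(ds2)
  res2 <- test_interaction_lrt(aug2, sf[perm], disp$disp_map)
  expect_equal(res2$lr, res$lr, tolerance = 1e-6)
})

test_that("null NB data gives a calibrated interaction test", {
  ds <- sim_aug_dataset(150, mu = 400, size = 8, seed = 47)
  aug <- build_augmented_counts(ds)
  sf <- estimate_size_factors(round(ds$counts))
  disp <- estimate_dispersions(aug, sf)
  res <- test_interaction_lrt(aug, sf, disp$disp_map)
  # rejection rate at 0.05 within the exact binomial 99% band; each gene
  # contributes two mirrored transcripts, so test one per gene
  p <- res$pvalue[seq(1, nrow(res), by = 2)]
  n <- sum(!is.na(p))
  band <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(sum(p < 0.05, na.rm = TRUE), band[1])
  expect_lte(sum(p < 0.05, na.rm = TRUE), band[2])
  # and no gene reaches q < 0.05: false positives within Poisson bounds
  q <- per_gene_qvalue(res$pvalue, res$gene_id)
  expect_lte(sum(q$qval < 0.05), 3)
})

test_that("per-gene aggregation uses the Sidak minimum-p formula", {
  expect_equal(per_gene_qvalue(0.07, "G1")$pvalue, 0.07)
  expect_equal(per_gene_qvalue(c(0.05, 0.8), c("G1", "G1"))$pvalue,
               1 - 0.95^2)
  expect_equal(per_gene_qvalue(c(1, 1, 1), rep("G1", 3))$pvalue, 1)
  # Sidak-vs-Bonferroni sandwich: min p <= gene p <= K * min p
  set.seed(48)
  for (rep in 1:10) {
    K <- sample(1:6, 1)
    p <- runif(K)
    gp <- per_gene_qvalue(p, rep("G", K))$pvalue
    expect_gte(gp, min(p) - 1e-12)
    expect_lte(gp, K * min(p) + 1e-12)
  }
})
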