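# Count-level benchmark generator with DGE/DTE/DTU ground truth.
#
# Genes carry 1..7 isoforms; per-transcript baseline abundances (TPM) are
# drawn log-normally with structural zeros, and transcripts whose expected
# baseline fragment count falls below a threshold are set to abundance 0
# ("non-expressed"). Genes are assigned to truth categories:
#   DGE - all expressed isoforms multiplied by a common fold change in one
#         (randomly chosen) group;
#   DTE - a single randomly chosen expressed isoform multiplied by a fold
#         change in one group;
#   DTU - the TPMs of two expressed isoforms with distinct abundances are
#         exchanged in one group (or the sole expressed isoform exchanged
#         with a non-expressed one), leaving the gene total unchanged.
# Effective truth labels follow the category semantics: DGE genes are also
# DTE-true but never DTU-true (proportions unchanged); DTE genes are always
# DGE-true (the total changed) and DTU-true exactly when the gene has other
# expressed isoforms; DTU genes are DTE-true but not DGE-true.
#
# Fragment counts have expectation proportional to TPM x effective length,
# scaled to the per-sample library size, with negative-binomial noise;
# dispersion comes from a mean-dispersion function with log-normal jitter,
# either per transcript ("main") or shared within a gene matched on the
# gene-level mean ("fixed_per_gene").

#' Simulation parameters
#'
#' @param n_genes number of genes (all carry at least one expressed
#'   isoform).
#' @param frac_dge,frac_dte,frac_dtu fractions of genes per differential
#'   category (defaults 0.1 each); each category receives exactly
#'   `floor(frac * n_genes)` genes and the remainder are null.
#' @param n_per_group samples per condition group (default 6).
#' @param isoform_probs probabilities for 1..7 isoforms per gene.
#' @param baseline_meanlog,baseline_sdlog log2-TPM normal parameters for the
#'   expressed baseline abundances.
#' @param zero_prob probability that a transcript is structurally
#'   unexpressed at baseline.
#' @param expressed_count_threshold transcripts whose expected baseline
#'   count falls below this are thresholded to abundance 0 (default 10).
#' @param lfc_range log2 fold-change range for DGE/DTE effects (default
#'   `c(1, 2.58)`, i.e. fold changes 2 to 6).
#' @param library_sizes per-sample library sizes; default `NULL` draws
#'   uniformly from 31.4 to 38.5 million reads scaled by `n_genes / 15017`,
#'   keeping per-gene depth at the level of a genome-wide experiment.
#' @param dispersion_mode `"main"` (per-transcript dispersion) or
#'   `"fixed_per_gene"` (one dispersion per gene, matched on the gene-level
#'   mean).
#' @param mean_dispersion_fn function mu -> dispersion alpha; default
#'   `4/mu + 0.05`.
#' @param dispersion_sdlog log-normal jitter sdlog on dispersions (default
#'   0.3; 0 disables jitter).
#' @param seed integer seed.
#' @return list of class `SimParams`.
#' @export
sim_params <- function(n_genes = 1000,
                       frac_dge = 0.1, frac_dte = 0.1, frac_dtu = 0.1,
                       n_per_group = 6,
                       isoform_probs = c(0.35, 0.30, 0.18, 0.09,
                                         0.05, 0.02, 0.01),
                       baseline_meanlog = 2.5, baseline_sdlog = 2,
                       zero_prob = 0.3,
                       expressed_count_threshold = 10,
                       lfc_range = c(1, 2.58),
                       library_sizes = NULL,
                       dispersion_mode = c("main", "fixed_per_gene"),
                       mean_dispersion_fn = function(mu) 4 / mu + 0.05,
                       dispersion_sdlog = 0.3,
                       seed = 1) {
  if (frac_dge + frac_dte + frac_dtu > 1)
    stop("differential fractions sum above 1")
  if (any(lfc_range <= 0)) stop("lfc_range must be positive")
  p <- list(n_genes = n_genes, frac_dge = frac_dge, frac_dte = frac_dte,
            frac_dtu = frac_dtu, n_per_group = n_per_group,
            isoform_probs = isoform_probs / sum(isoform_probs),
            baseline_meanlog = baseline_meanlog,
            baseline_sdlog = baseline_sdlog, zero_prob = zero_prob,
            expressed_count_threshold = expressed_count_threshold,
            lfc_range = lfc_range, library_sizes = library_sizes,
            dispersion_mode = match.arg(dispersion_mode),
            mean_dispersion_fn = mean_dispersion_fn,
            dispersion_sdlog = dispersion_sdlog, seed = seed)
  class(p) <- "SimParams"
  p
}

#' Simulate ground truth abundances and labels
#'
#' Generates the per-transcript baseline abundances, assigns genes to
#' categories with exact `floor(frac * n_genes)` counts, applies the
#' category constructions, and records per-gene and per-transcript truth
#' labels. Gene and transcript identifiers follow a GENCODE-like shape with
#' a 15-character stem plus version suffix.
#'
#' @param params a `SimParams`.
#' @return A `SimTruth`: list with data.frames `genes` (gene_id, label,
#'   dge_true, dte_true, dtu_true) and `transcripts` (transcript_id,
#'   gene_id, length, eff_length, tpm_g1, tpm_g2, expressed, dge_tx, dte_tx,
#'   dtu_tx).
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  nG <- params$n_genes
  ntx <- sample(seq_along(params$isoform_probs), nG, replace = TRUE,
                prob = params$isoform_probs)
  nT <- sum(ntx)
  gene_ids <- sprintf("SIMG%011d.%d", seq_len(nG),
                      sample(1:15, nG, replace = TRUE))
  tx_gene_idx <- rep(seq_len(nG), ntx)
  tx_ids <- sprintf("SIMT%011d.%d", seq_len(nT),
                    sample(1:15, nT, replace = TRUE))
  len <- pmax(300L, as.integer(round(exp(stats::rnorm(nT, log(1800), 0.6)))))
  eff_len <- pmax(50, len - 200)
  tpm <- 2^stats::rnorm(nT, params$baseline_meanlog, params$baseline_sdlog)
  tpm[stats::runif(nT) < params$zero_prob] <- 0
  # expected baseline count at the mean library size; threshold low ones
  lib0 <- if (is.null(params$library_sizes))
    mean(c(31.4e6, 38.5e6)) * nG / 15017 else mean(params$library_sizes)
  expected_counts <- function(tpm_vec) {
    w <- tpm_vec * eff_len
    tot <- sum(w)
    if (tot <= 0) rep(0, length(w)) else w / tot * lib0
  }
  tpm[expected_counts(tpm) < params$expressed_count_threshold] <- 0
  # guarantee one expressed isoform per gene: lift one transcript of each
  # empty gene above the threshold
  for (rep_pass in 1:5) {
    cnt <- expected_counts(tpm)
    empty <- setdiff(seq_len(nG), unique(tx_gene_idx[cnt >=
      params$expressed_count_threshold & tpm > 0]))
    if (length(empty) == 0) break
    tot_w <- sum(tpm * eff_len)
    if (tot_w <= 0) tot_w <- lib0
    for (g in empty) {
      k <- which(tx_gene_idx == g)
      k <- if (length(k) > 1) sample(k, 1) else k
      # TPM level whose expected count sits at the threshold, then lifted
      tau <- params$expressed_count_threshold * tot_w / (eff_len[k] * lib0)
      tpm[k] <- tau * 2^(1 + abs(stats::rnorm(1)))
    }
  }
  expressed <- tpm > 0
  # category assignment with exact floor counts; DTU genes need >= 2
  # annotated isoforms
  n_dge <- floor(params$frac_dge * nG)
  n_dte <- floor(params$frac_dte * nG)
  n_dtu <- floor(params$frac_dtu * nG)
  pool <- sample(seq_len(nG))
  multi <- ntx[pool] >= 2
  dtu_genes <- pool[multi][seq_len(n_dtu)]
  rest <- setdiff(pool, dtu_genes)
  dge_genes <- rest[seq_len(n_dge)]
  dte_genes <- rest[n_dge + seq_len(n_dte)]
  label <- rep("null", nG)
  label[dge_genes] <- "DGE"; label[dte_genes] <- "DTE"
  label[dtu_genes] <- "DTU"
  tpm_g1 <- tpm
  tpm_g2 <- tpm
  dge_tx <- dte_tx <- dtu_tx <- logical(nT)
  gene_dge <- gene_dte <- gene_dtu <- logical(nG)
  draw_fc <- function() 2^stats::runif(1, params$lfc_range[1],
                                       params$lfc_range[2])
  for (g in dge_genes) {
    k <- which(tx_gene_idx == g & expressed)
    fc <- draw_fc()
    if (stats::runif(1) < 0.5) tpm_g2[k] <- tpm_g2[k] * fc
    else tpm_g1[k] <- tpm_g1[k] * fc
    dge_tx[k] <- TRUE; dte_tx[k] <- TRUE
    gene_dge[g] <- TRUE; gene_dte[g] <- TRUE
  }
  for (g in dte_genes) {
    k <- which(tx_gene_idx == g & expressed)
    chosen <- if (length(k) > 1) sample(k, 1) else k
    fc <- draw_fc()
    if (stats::runif(1) < 0.5) tpm_g2[chosen] <- tpm_g2[chosen] * fc
    else tpm_g1[chosen] <- tpm_g1[chosen] * fc
    dte_tx[chosen] <- TRUE
    gene_dte[g] <- TRUE
    gene_dge[g] <- TRUE  # the gene total changed
    if (length(k) > 1) {
      # scaling one isoform shifts the proportions of every expressed
      # isoform of the gene, so all of them participate in the usage change
      gene_dtu[g] <- TRUE
      dtu_tx[k] <- TRUE
    } else {
      dge_tx[chosen] <- TRUE
    }
  }
  for (g in dtu_genes) {
    k_exp <- which(tx_gene_idx == g & expressed)
    k_all <- which(tx_gene_idx == g)
    if (length(k_exp) >= 2) {
      # two expressed isoforms with distinct abundances
      pair <- NULL
      for (try in 1:20) {
        cand <- sample(k_exp, 2)
        if (abs(tpm[cand[1]] - tpm[cand[2]]) > 1e-8) { pair <- cand; break }
      }
      if (is.null(pair)) pair <- sample(k_exp, 2)
    } else {
      k_non <- setdiff(k_all, k_exp)
      pair <- c(k_exp, if (length(k_non) > 1) sample(k_non, 1) else k_non)
    }
    tpm_g2[pair] <- tpm_g2[rev(pair)]
    dtu_tx[pair] <- TRUE; dte_tx[pair] <- TRUE
    gene_dtu[g] <- TRUE; gene_dte[g] <- TRUE
  }
  truth <- list(
    genes = data.frame(gene_id = gene_ids, label = label,
                       dge_true = gene_dge, dte_true = gene_dte,
                       dtu_true = gene_dtu, stringsAsFactors = FALSE),
    transcripts = data.frame(
      transcript_id = tx_ids, gene_id = gene_ids[tx_gene_idx],
      length = len, eff_length = eff_len,
      tpm_g1 = tpm_g1, tpm_g2 = tpm_g2, expressed = expressed,
      dge_tx = dge_tx, dte_tx = dte_tx, dtu_tx = dtu_tx,
      stringsAsFactors = FALSE),
    params = params)
  class(truth) <- "SimTruth"
  truth
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d genes, %d transcripts\n",
              nrow(x$genes), nrow(x$transcripts)))
  print(table(x$genes$label))
  invisible(x)
}

#' Simulate negative-binomial fragment counts from truth abundances
#'
#' Expected fragment counts are proportional to group TPM times effective
#' length, scaled so each sample's expectations sum to its library size.
#' Counts are drawn NB with dispersion from the mean-dispersion function
#' times log-normal jitter, per transcript (`main`) or shared within genes
#' matched on gene-level mean (`fixed_per_gene`). A Salmon-like
#' quantification set (TPM recomputed from realized counts) is returned
#' alongside the true count matrix so the counts-from-abundance import path
#' can be exercised end to end.
#'
#' @param truth a `SimTruth`.
#' @param params a `SimParams` (defaults to the one stored in `truth`).
#' @return list with `quants` (a `TranscriptQuantSet`), `counts` (the
#'   realized count matrix, transcripts x samples), `samples` (sample
#'   table), and `mu` (expectation matrix).
#' @export
simulate_counts <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(params$seed + 1L)
  tx <- truth$transcripts
  nT <- nrow(tx)
  n <- params$n_per_group
  sample_ids <- c(sprintf("s%d_1", seq_len(n)), sprintf("s%d_2", seq_len(n)))
  condition <- rep(c("1", "2"), each = n)
  lib <- params$library_sizes
  if (is.null(lib))
    lib <- stats::runif(2 * n, 31.4e6, 38.5e6) * params$n_genes / 15017
  if (length(lib) == 1) lib <- rep(lib, 2 * n)
  stopifnot(length(lib) == 2 * n)
  w1 <- tx$tpm_g1 * tx$eff_length
  w2 <- tx$tpm_g2 * tx$eff_length
  mu <- matrix(0, nT, 2 * n, dimnames = list(tx$transcript_id, sample_ids))
  for (i in seq_len(2 * n)) {
    w <- if (condition[i] == "1") w1 else w2
    mu[, i] <- w / sum(w) * lib[i]
  }
  jitter <- function(m) {
    if (params$dispersion_sdlog > 0)
      stats::rlnorm(m, -params$dispersion_sdlog^2 / 2,
                    params$dispersion_sdlog)
    else rep(1, m)
  }
  mu_bar <- rowMeans(mu)
  if (params$dispersion_mode == "main") {
    alpha <- params$mean_dispersion_fn(pmax(mu_bar, 1e-8)) * jitter(nT)
  } else {
    gmu <- rowsum(mu_bar, tx$gene_id)
    galpha <- params$mean_dispersion_fn(pmax(gmu[, 1], 1e-8)) *
      jitter(nrow(gmu))
    alpha <- galpha[match(tx$gene_id, rownames(gmu))]
  }
  counts <- matrix(0, nT, 2 * n, dimnames = dimnames(mu))
  for (i in seq_len(2 * n)) {
    pos <- mu[, i] > 0
    counts[pos, i] <- stats::rnbinom(sum(pos), mu = mu[pos, i],
                                     size = 1 / alpha[pos])
  }
  # Salmon-style TPM from realized counts and effective lengths
  dens <- counts / tx$eff_length
  tpm_mat <- sweep(dens, 2, colSums(dens), `/`) * 1e6
  q <- list(transcript_ids = tx$transcript_id,
            sample_ids = sample_ids,
            tpm = tpm_mat,
            eff_length = matrix(tx$eff_length, nT, 2 * n,
                                dimnames = dimnames(mu)),
            est_reads = counts,
            length = stats::setNames(tx$length, tx$transcript_id))
  class(q) <- "TranscriptQuantSet"
  list(quants = q, counts = counts,
       samples = data.frame(sample_id = sample_ids, condition = condition,
                            stringsAsFactors = FALSE),
       mu = mu, dispersion = alpha)
}

#' Write Salmon-format quantification files
#'
#' One `quant.sf`-style TSV per sample, with the standard header
#' `Name Length EffectiveLength TPM NumReads`.
#'
#' @param q a `TranscriptQuantSet`.
#' @param dir output directory; one subdirectory per sample is created
#'   containing `quant.sf`.
#' @return named vector of file paths.
#' @export
write_quant_files <- function(q, dir) {
  stopifnot(inherits(q, "TranscriptQuantSet"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", dir))
  paths <- character(length(q$sample_ids))
  for (i in seq_along(q$sample_ids)) {
    sdir <- file.path(dir, q$sample_ids[i])
    dir.create(sdir, showWarnings = FALSE)
    f <- file.path(sdir, "quant.sf")
    # %.17g preserves doubles exactly across the write/read round trip
    df <- data.frame(Name = q$transcript_ids,
                     Length = q$length,
                     EffectiveLength = sprintf("%.17g", q$eff_length[, i]),
                     TPM = sprintf("%.17g", q$tpm[, i]),
                     NumReads = sprintf("%.17g", q$est_reads[, i]))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[i] <- f
  }
  stats::setNames(paths, q$sample_ids)
}
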