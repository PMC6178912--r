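#' Assemble a DTU dataset
#'
#' Bundles a transcript-level count matrix with its gene grouping and the
#' sample design. Rows are reordered so that transcripts of a gene are
#' contiguous (gene order follows first appearance).
#'
#' @param counts numeric matrix, transcripts x samples.
#' @param gene_ids character vector aligned to rows of `counts`.
#' @param transcript_ids character vector aligned to rows of `counts`.
#' @param samples data.frame with at least `sample_id` and `condition`;
#'   `condition` is coerced to factor.
#' @return A `DTUDataset`.
#' @export
dtu_dataset <- function(counts, gene_ids, transcript_ids, samples) {
  counts <- as.matrix(counts)
  if (length(gene_ids) != nrow(counts) ||
      length(transcript_ids) != nrow(counts))
    stop("gene_ids/transcript_ids must align with rows of counts")
  if (!all(c("sample_id", "condition") %in% colnames(samples)))
    stop("samples must have columns 'sample_id' and 'condition'")
  if (nrow(samples) != ncol(counts))
    stop("samples table does not match the number of count columns")
  samples$condition <- factor(samples$condition)
  ord <- order(match(gene_ids, unique(gene_ids)))
  ds <- list(counts = counts[ord, , drop = FALSE],
             gene_ids = gene_ids[ord],
             transcript_ids = transcript_ids[ord],
             samples = samples)
  colnames(ds$counts) <- samples$sample_id
  rownames(ds$counts) <- ds$transcript_ids
  class(ds) <- "DTUDataset"
  ds
}

#' @export
print.DTUDataset <- function(x, ...) {
  cat(sprintf("DTUDataset: %d transcripts in %d genes, %d samples\n",
              nrow(x$counts), length(unique(x$gene_ids)), ncol(x$counts)))
  invisible(x)
}

#' Filter configuration for DTU pre-filtering
#'
#' The three pre-modeling filters: a transcript is retained when it has a
#' count of at least `min_feature_expr` in at least `min_samps_feature_expr`
#' samples and a within-gene proportion of at least `min_feature_prop` in at
#' least `min_samps_feature_prop` samples; a gene is retained when its total
#' count is at least `min_gene_expr` in at least `min_samps_gene_expr`
#' samples and at least two of its transcripts survive. The conventional
#' choice sets the sample-count thresholds for the transcript rules to the
#' size of the smallest condition group and the gene rule to the total
#' sample number.
#'
#' @param min_samps_feature_expr,min_samps_feature_prop,min_samps_gene_expr
#'   integer sample-count thresholds.
#' @param min_feature_expr,min_gene_expr count thresholds (default 10).
#' @param min_feature_prop proportion threshold in `[0, 1]` (default 0.1).
#' @return list of class `FilterConfig`.
#' @export
filter_config <- function(min_samps_feature_expr,
                          min_feature_expr = 10,
                          min_samps_feature_prop = min_samps_feature_expr,
                          min_feature_prop = 0.1,
                          min_samps_gene_expr,
                          min_gene_expr = 10) {
  cfg <- list(min_samps_feature_expr = as.integer(min_samps_feature_expr),
              min_feature_expr = min_feature_expr,
              min_samps_feature_prop = as.integer(min_samps_feature_prop),
              min_feature_prop = min_feature_prop,
              min_samps_gene_expr = as.integer(min_samps_gene_expr),
              min_gene_expr = min_gene_expr)
  if (cfg$min_feature_prop < 0 || cfg$min_feature_prop > 1)
    stop("min_feature_prop must be in [0, 1]")
  class(cfg) <- "FilterConfig"
  cfg
}

#' Default filter configuration for a sample table
#'
#' Sets the transcript-rule sample thresholds to the smallest group size and
#' the gene-rule threshold to the total sample number.
#'
#' @param samples data.frame with a `condition` column.
#' @export
default_filter_config <- function(samples) {
  n <- nrow(samples)
  n_small <- min(table(samples$condition))
  filter_config(min_samps_feature_expr = n_small,
                min_samps_feature_prop = n_small,
                min_samps_gene_expr = n)
}

#' Pre-modeling filter on counts and within-gene proportions
#'
#' Applies the three filter rules of [filter_config()] in a single pass.
#' Within-gene proportions are computed against the gene total over all
#' transcripts present before any removal; samples with a zero gene total
#' contribute proportion 0. Genes left with fewer than two surviving
#' transcripts are dropped entirely.
#'
#' @param ds a `DTUDataset`.
#' @param cfg a `FilterConfig`.
#' @param report logical; attach a per-transcript filter report as attribute
#'   `"report"` (columns transcript_id, gene_id, pass_count_filter,
#'   pass_prop_filter, gene_pass, final_keep).
#' @return the filtered `DTUDataset`.
#' @export
dm_style_filter <- function(ds, cfg, report = FALSE) {
  stopifnot(inherits(ds, "DTUDataset"), inherits(cfg, "FilterConfig"))
  n <- ncol(ds$counts)
  if (cfg$min_samps_feature_expr > n || cfg$min_samps_feature_prop > n ||
      cfg$min_samps_gene_expr > n)
    stop("sample-count threshold exceeds the number of samples")
  cts <- ds$counts
  gene_tot <- rowsum(cts, ds$gene_ids)
  tot <- gene_tot[match(ds$gene_ids, rownames(gene_tot)), , drop = FALSE]
  props <- cts / tot
  props[tot == 0] <- 0
  pass_count <- rowSums(cts >= cfg$min_feature_expr) >=
    cfg$min_samps_feature_expr
  pass_prop <- rowSums(props >= cfg$min_feature_prop) >=
    cfg$min_samps_feature_prop
  gene_keep_expr <- rowSums(gene_tot >= cfg$min_gene_expr) >=
    cfg$min_samps_gene_expr
  gene_pass <- gene_keep_expr[match(ds$gene_ids, rownames(gene_tot))]
  tx_keep <- pass_count & pass_prop & gene_pass
  surv <- table(ds$gene_ids[tx_keep])
  multi <- names(surv)[surv >= 2]
  final <- tx_keep & ds$gene_ids %in% multi
  out <- dtu_dataset(cts[final, , drop = FALSE], ds$gene_ids[final],
                     ds$transcript_ids[final], ds$samples)
  if (report) {
    attr(out, "report") <- data.frame(
      transcript_id = ds$transcript_ids,
      gene_id = ds$gene_ids,
      pass_count_filter = pass_count,
      pass_prop_filter = pass_prop,
      gene_pass = unname(gene_pass),
      final_keep = unname(final),
      stringsAsFactors = FALSE)
  }
  out
}

#' Post-hoc mask on the standard deviation of per-sample proportions
#'
#' For each transcript the per-sample within-gene proportion is computed
#' (count over per-sample gene total; 0 when the gene total is 0) and its
#' standard deviation across all samples taken with the unbiased (n-1)
#' denominator. Transcripts whose proportion SD falls below `threshold` are
#' masked. This statistic ignores the condition grouping; callers set the
#' p-value and adjusted p-value of masked transcripts to 1 without
#' recomputing the adjustment. Intended for the Dirichlet-multinomial test
#' path, where it tightens false discovery control.
#'
#' @param ds a `DTUDataset`.
#' @param threshold SD threshold (default 0.1).
#' @return logical vector over transcripts; `TRUE` = mask (small SD).
#' @export
proportion_sd_mask <- function(ds, threshold = 0.1) {
  stopifnot(inherits(ds, "DTUDataset"))
  cts <- ds$counts
  gene_tot <- rowsum(cts, ds$gene_ids)
  tot <- gene_tot[match(ds$gene_ids, rownames(gene_tot)), , drop = FALSE]
  props <- cts / tot
  props[tot == 0] <- 0
  sds <- apply(props, 1, stats::sd)
  unname(sds < threshold)
}
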