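# Scoring of DTU calls against simulated truth: FDR/TPR at nominal
# thresholds, observed OFDR with confirmation sensitivity, and breakdown of
# false positives by simulated gene category.

#' FDR and TPR at nominal thresholds
#'
#' Calls are adjusted p-values at or below each threshold. The empty-call
#' convention reports FDR 0 when nothing is called
#' (`FDR = FP / max(1, FP + TP)`).
#'
#' @param adj_p numeric vector of adjusted p-values (`NA` = never called).
#' @param truth logical vector, `TRUE` for true positives.
#' @param thresholds nominal thresholds (default 0.01, 0.05, 0.10).
#' @return data.frame: `threshold`, `called`, `tp`, `fp`, `fdr`, `tpr`.
#' @export
fdr_tpr <- function(adj_p, truth, thresholds = c(0.01, 0.05, 0.10)) {
  if (length(adj_p) != length(truth))
    stop("adj_p and truth must have equal length")
  truth <- as.logical(truth)
  pos <- sum(truth)
  rows <- lapply(thresholds, function(t) {
    called <- !is.na(adj_p) & adj_p <= t
    tp <- sum(called & truth)
    fp <- sum(called & !truth)
    data.frame(threshold = t, called = tp + fp, tp = tp, fp = fp,
               fdr = fp / max(1, fp + tp),
               tpr = if (pos > 0) tp / pos else 0)
  })
  do.call(rbind, rows)
}

#' Observed OFDR and DTU-transcript sensitivity of a stage-wise result
#'
#' A screened gene counts as an overall false discovery when it is not
#' DTU-true, or when any of its confirmed transcripts (transcript-level
#' adjusted p at or below `alpha`) does not participate in DTU. Sensitivity
#' is the fraction of true DTU transcripts in the evaluation universe that
#' were confirmed. Identifiers are compared after 15-character truncation.
#' Screened genes absent from the truth tables are excluded from both
#' numerator and denominator and counted in `n_unmatched`.
#'
#' @param result a `StageWiseResult`.
#' @param truth a `SimTruth`.
#' @param alpha target OFDR (default: the alpha stored in `result`).
#' @param universe_tx optional transcript ids delimiting the evaluation
#'   universe for sensitivity (default: all transcripts in `truth`).
#' @return list: `ofdr`, `sensitivity`, `n_screened`, `n_false_screened`,
#'   `n_false_confirmation`, `n_unmatched`, `empty` (flag: no screened
#'   genes).
#' @export
ofdr_sensitivity <- function(result, truth, alpha = NULL,
                             universe_tx = NULL) {
  stopifnot(inherits(result, "StageWiseResult"), inherits(truth, "SimTruth"))
  if (is.null(alpha)) alpha <- attr(result, "alpha")
  g_truth <- truth$genes
  t_truth <- truth$transcripts
  gkey <- strip_version(g_truth$gene_id)
  tkey <- strip_version(t_truth$transcript_id)
  dtu_genes <- gkey[g_truth$dtu_true]
  dtu_tx <- tkey[t_truth$dtu_tx]
  screened <- unique(result$geneID)
  matched <- screened %in% gkey
  n_unmatched <- sum(!matched)
  screened <- screened[matched]
  confirmed <- result[!is.na(result$transcript) &
                        result$transcript <= alpha, , drop = FALSE]
  bad_conf <- unique(confirmed$geneID[!(confirmed$txID %in% dtu_tx)])
  false_screen <- !(screened %in% dtu_genes)
  false_conf <- screened %in% bad_conf
  n_s <- length(screened)
  ofdr <- if (n_s == 0) 0 else sum(false_screen | false_conf) / n_s
  if (is.null(universe_tx)) universe_tx <- tkey
  universe_tx <- strip_version(universe_tx)
  dtu_universe <- intersect(dtu_tx, universe_tx)
  sens <- if (length(dtu_universe) == 0) 0 else
    length(intersect(confirmed$txID, dtu_universe)) / length(dtu_universe)
  list(ofdr = ofdr, sensitivity = sens, n_screened = n_s,
       n_false_screened = sum(false_screen),
       n_false_confirmation = sum(false_conf),
       n_unmatched = n_unmatched, empty = n_s == 0)
}

#' Break down false positives by simulated gene category
#'
#' @param calls logical vector of calls (gene-level or transcript-level).
#' @param truth_positive logical vector: which units are true positives for
#'   the analysis being scored.
#' @param category character vector of the simulated category of each
#'   unit's gene (`"DGE"`, `"DTE"`, `"DTU"`, `"null"`).
#' @return named integer vector of false-positive counts per category
#'   (always includes the four categories), with the total as attribute
#'   `"total"`.
#' @export
fp_breakdown <- function(calls, truth_positive, category) {
  if (length(calls) != length(truth_positive) ||
      length(calls) != length(category))
    stop("calls, truth_positive and category must align")
  fp <- calls & !truth_positive
  lev <- c("DGE", "DTE", "DTU", "null")
  out <- table(factor(category[fp], levels = lev))
  out <- stats::setNames(as.integer(out), lev)
  attr(out, "total") <- sum(fp)
  out
}

#' Full evaluation report for a DTU analysis on simulated data
#'
#' Computes gene- and transcript-level FDR/TPR tables at the nominal
#' thresholds, the observed OFDR and sensitivity of the stage-wise result,
#' and false-positive breakdowns, restricted to the post-filter evaluation
#' universe.
#'
#' @param gene_adj named vector of gene-level adjusted p-values (names =
#'   gene ids, version suffixes allowed).
#' @param tx_adj named vector of transcript-level adjusted p-values.
#' @param stagewise a `StageWiseResult` (or `NULL` to skip OFDR).
#' @param truth a `SimTruth`.
#' @param thresholds nominal FDR thresholds.
#' @return list of class `EvalReport`.
#' @export
evaluate_dtu <- function(gene_adj, tx_adj, stagewise, truth,
                         thresholds = c(0.01, 0.05, 0.10)) {
  g_truth <- truth$genes
  t_truth <- truth$transcripts
  gkey <- strip_version(g_truth$gene_id)
  tkey <- strip_version(t_truth$transcript_id)
  gid <- strip_version(names(gene_adj))
  tid <- strip_version(names(tx_adj))
  gi <- match(gid, gkey)
  ti <- match(tid, tkey)
  gene_ok <- !is.na(gi)
  tx_ok <- !is.na(ti)
  gene_tab <- fdr_tpr(gene_adj[gene_ok], g_truth$dtu_true[gi[gene_ok]],
                      thresholds)
  tx_tab <- fdr_tpr(tx_adj[tx_ok], t_truth$dtu_tx[ti[tx_ok]], thresholds)
  brk <- lapply(thresholds, function(t) {
    calls <- !is.na(gene_adj[gene_ok]) & gene_adj[gene_ok] <= t
    fp_breakdown(calls, g_truth$dtu_true[gi[gene_ok]],
                 g_truth$label[gi[gene_ok]])
  })
  names(brk) <- sprintf("t%g", thresholds)
  ofdr <- if (!is.null(stagewise))
    ofdr_sensitivity(stagewise, truth, universe_tx = tid) else NULL
  rep <- list(gene = gene_tab, transcript = tx_tab,
              fp_by_category = brk, ofdr = ofdr)
  class(rep) <- "EvalReport"
  rep
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("Gene-level FDR/TPR:\n"); print(x$gene)
  cat("Transcript-level FDR/TPR:\n"); print(x$transcript)
  if (!is.null(x$ofdr))
    cat(sprintf("Observed OFDR %.4f, DTU-transcript sensitivity %.4f (%d screened genes)\n",
                x$ofdr$ofdr, x$ofdr$sensitivity, x$ofdr$n_screened))
  invisible(x)
}
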