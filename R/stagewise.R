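# Stage-wise testing: screen genes for any differential transcript usage,
# then confirm which transcripts participate, controlling the overall false
# discovery rate (OFDR) across the gene/transcript pairs at a fixed target.
# Unlike independently adjusted p-values, results must be interpreted at the
# alpha fixed before running; re-thresholding at other levels is invalid.

#' Truncate identifiers to 15 characters
#'
#' Drops Ensembl/GENCODE-style version suffixes by keeping only the first 15
#' characters of each identifier, the convention used to join gene- and
#' transcript-level results before stage-wise adjustment.
#'
#' @param id character vector.
#' @export
strip_version <- function(id) {
  substr(id, 1, 15)
}

# within-gene step-down adjustment over K ordered p-values; multiplier for
# the j-th smallest is max(K-j, 1): the global null on a simplex implies at
# least two changed transcripts, so the smallest p faces only K-1
# alternatives (Shaffer reduction), and subsequent p-values continue the
# Holm sequence. Running maximum enforces monotonicity; capped at 1.
.holm_shaffer <- function(p) {
  K <- length(p)
  o <- order(p)
  mult <- pmax(K - seq_len(K), 1)
  adj <- pmin(1, cummax(p[o] * mult))
  out <- numeric(K)
  out[o] <- adj
  out
}

#' Stage-wise adjustment with OFDR control
#'
#' Screening: gene-level p-values are BH-adjusted (skipped when
#' `screen_adjusted`) and genes with adjusted p at or below `alpha` pass.
#' Confirmation: within each screened gene, transcript p-values receive a
#' Holm correction with the Shaffer reduction (smallest p multiplied by
#' K-1); genes with exactly two transcripts therefore keep both transcripts
#' at their raw p-value. The within-gene adjusted p-values are scaled by
#' G/|S| (total screened-universe genes over screened genes) and capped at
#' 1, so that comparing the reported transcript-level value against `alpha`
#' enacts the confirmation level alpha*|S|/G. Gene and transcript
#' identifiers are truncated to 15 characters before joining.
#'
#' With this procedure, in expectation no more than `alpha` of the genes
#' passing screening either contain no differential usage at all or contain
#' a falsely confirmed transcript.
#'
#' @param p_screen named numeric vector of per-gene screening p-values
#'   (names are gene ids), or unnamed with `tx2gene` supplying the universe.
#' @param p_confirmation numeric vector of per-transcript confirmation
#'   p-values, aligned with `tx2gene`.
#' @param tx2gene data.frame with transcript ids in column 1 and gene ids in
#'   column 2, aligned to `p_confirmation`.
#' @param alpha target OFDR in (0, 1), fixed before running.
#' @param screen_adjusted logical; `TRUE` when `p_screen` already holds
#'   FDR-adjusted values (q-values), as in the NB path.
#' @return A `StageWiseResult`: data.frame (`geneID`, `txID`, `gene`,
#'   `transcript`) restricted to screened genes, ordered by geneID then
#'   txID, with the `alpha` used as an attribute.
#' @export
stage_wise_adjust <- function(p_screen, p_confirmation, tx2gene,
                              alpha = 0.05, screen_adjusted = FALSE) {
  if (anyNA(p_screen) || anyNA(p_confirmation))
    stop("missing p-values; sanitize upstream (see sanitize_pvalues)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(p_confirmation) != nrow(tx2gene))
    stop("p_confirmation and tx2gene must align")
  gene_ids <- strip_version(names(p_screen))
  tx <- strip_version(as.character(tx2gene[[1]]))
  txg <- strip_version(as.character(tx2gene[[2]]))
  if (!all(txg %in% gene_ids))
    stop("confirmation transcripts map outside the screened universe")
  G <- length(p_screen)
  gene_adj <- if (screen_adjusted) as.numeric(p_screen)
    else adjust_bh(as.numeric(p_screen))
  names(gene_adj) <- gene_ids
  screened <- gene_ids[gene_adj <= alpha]
  res <- data.frame(geneID = character(0), txID = character(0),
                    gene = numeric(0), transcript = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(screened) > 0) {
    S <- length(screened)
    keep <- txg %in% screened
    adj_within <- unsplit(lapply(split(p_confirmation[keep], txg[keep]),
                                 .holm_shaffer), txg[keep])
    res <- data.frame(geneID = txg[keep], txID = tx[keep],
                      gene = unname(gene_adj[txg[keep]]),
                      transcript = pmin(1, adj_within * G / S),
                      stringsAsFactors = FALSE)
    res <- res[order(res$geneID, res$txID), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "alpha") <- alpha
  class(res) <- c("StageWiseResult", "data.frame")
  res
}
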