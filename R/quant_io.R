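#' Read Salmon-format quantification files
#'
#' Reads one `quant.sf`-style TSV per sample (columns `Name`, `Length`,
#' `EffectiveLength`, `TPM`, `NumReads`) and assembles per-transcript,
#' per-sample matrices of abundances (TPM), effective lengths and estimated
#' fragment counts. All samples must quantify the same set of transcripts;
#' transcript order is taken from the first file and the remaining files are
#' realigned by `Name`.
#'
#' @param paths named character vector of file paths; names are sample ids.
#' @return A `TranscriptQuantSet`: list with `transcript_ids`, `sample_ids`,
#'   matrices `tpm`, `eff_length`, `est_reads` (transcripts x samples) and the
#'   integer vector `length` of annotated transcript lengths.
#' @export
read_salmon_quant <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("'paths' must be a named vector; names are sample ids")
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  tabs <- lapply(seq_along(paths), function(i) {
    f <- paths[[i]]
    tab <- utils::read.delim(f, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(required, colnames(tab))
    if (length(missing) > 0)
      stop(sprintf("file '%s' is missing required column(s): %s",
                   f, paste(missing, collapse = ", ")))
    if (anyDuplicated(tab$Name))
      stop(sprintf("file '%s' lists duplicated transcript names", f))
    tab
  })
  ref_ids <- tabs[[1]]$Name
  for (i in seq_along(tabs)) {
    if (!setequal(tabs[[i]]$Name, ref_ids))
      stop(sprintf(
        "transcript sets differ between '%s' and '%s'",
        paths[[1]], paths[[i]]))
    tabs[[i]] <- tabs[[i]][match(ref_ids, tabs[[i]]$Name), , drop = FALSE]
    if (any(tabs[[i]]$EffectiveLength <= 0))
      stop(sprintf("file '%s' contains non-positive EffectiveLength values",
                   paths[[i]]))
  }
  grab <- function(col) {
    m <- vapply(tabs, function(t) as.numeric(t[[col]]),
                numeric(length(ref_ids)))
    m <- matrix(m, nrow = length(ref_ids),
                dimnames = list(ref_ids, names(paths)))
    m
  }
  q <- list(
    transcript_ids = ref_ids,
    sample_ids = names(paths),
    tpm = grab("TPM"),
    eff_length = grab("EffectiveLength"),
    est_reads = grab("NumReads"),
    length = stats::setNames(as.integer(tabs[[1]]$Length), ref_ids)
  )
  class(q) <- "TranscriptQuantSet"
  tpm_sums <- colSums(q$tpm)
  off <- abs(tpm_sums - 1e6) / 1e6
  if (any(off > 1e-3))
    warning(sprintf(
      "TPM columns deviate from 1e6 by up to %.3g relative: %s",
      max(off), paste(names(paths)[off > 1e-3], collapse = ", ")))
  q
}

#' @export
print.TranscriptQuantSet <- function(x, ...) {
  cat(sprintf("TranscriptQuantSet: %d transcripts x %d samples\n",
              length(x$transcript_ids), length(x$sample_ids)))
  invisible(x)
}

#' Build a transcript-to-gene table from a GTF annotation
#'
#' Parses the `transcript_id`/`gene_id` attributes of transcript records
#' (falling back to exon records when a GTF carries no transcript lines) and
#' returns one row per distinct transcript together with `ntx`, the number of
#' annotated transcripts of the gene. Version suffixes on identifiers are
#' retained verbatim.
#'
#' @param gtf_path path to a GTF file.
#' @return data.frame with columns `transcript_id`, `gene_id`, `ntx`.
#' @export
build_tx2gene <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (!"transcript_id" %in% colnames(meta))
    stop("GTF has no 'transcript_id' attribute on any record")
  if (!"gene_id" %in% colnames(meta))
    stop("GTF has no 'gene_id' attribute on any record")
  keep <- if ("type" %in% colnames(meta) && any(meta$type == "transcript"))
    meta$type == "transcript" else !is.na(meta$transcript_id)
  tab <- meta[keep, c("transcript_id", "gene_id"), drop = FALSE]
  tab <- tab[!is.na(tab$transcript_id), , drop = FALSE]
  if (any(is.na(tab$gene_id)))
    stop("GTF record with transcript_id but no gene_id attribute")
  tab <- unique(tab)
  dup <- duplicated(tab$transcript_id)
  if (any(dup))
    stop(sprintf("transcript(s) mapped to more than one gene: %s",
                 paste(unique(tab$transcript_id[dup]), collapse = ", ")))
  ntx_tab <- table(tab$gene_id)
  data.frame(
    transcript_id = tab$transcript_id,
    gene_id = tab$gene_id,
    ntx = as.integer(ntx_tab[tab$gene_id]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Counts from abundance
#'
#' Converts a `TranscriptQuantSet` into a count matrix under one of three
#' conventions: `raw` returns the estimated fragment counts unchanged;
#' `scaledTPM` rescales each sample's TPM vector so that the column sums to
#' that sample's total mapped reads (taken as the column sum of `NumReads`);
#' `lengthScaledTPM` first multiplies each transcript's TPM by its average
#' effective length over samples and then applies the same per-sample
#' rescaling. scaledTPM counts do not scale with transcript length within a
#' gene and are the recommended input for DTU testing. Rows that are zero
#' across all samples are dropped.
#'
#' @param q a `TranscriptQuantSet`.
#' @param mode one of `"raw"`, `"scaledTPM"`, `"lengthScaledTPM"`.
#' @return A `CountMatrix`: list with `row_ids`, `sample_ids`, numeric matrix
#'   `counts` and the `mode` used.
#' @export
counts_from_abundance <- function(q,
                                  mode = c("scaledTPM", "raw",
                                           "lengthScaledTPM")) {
  mode <- match.arg(mode)
  stopifnot(inherits(q, "TranscriptQuantSet"))
  cts <- .cfa_matrix(q, mode)
  keep <- rowSums(cts) > 0
  cm <- list(row_ids = q$transcript_ids[keep],
             sample_ids = q$sample_ids,
             counts = cts[keep, , drop = FALSE],
             mode = mode, offsets = NULL)
  class(cm) <- "CountMatrix"
  cm
}

# shared kernel: full (undroppped) count matrix for a given mode
.cfa_matrix <- function(q, mode) {
  if (mode == "raw") return(q$est_reads)
  mapped <- colSums(q$est_reads)
  ab <- q$tpm
  if (mode == "lengthScaledTPM")
    ab <- ab * rowMeans(q$eff_length)
  tot <- colSums(ab)
  if (any(tot <= 0))
    stop(sprintf("sample(s) with zero total TPM: %s",
                 paste(q$sample_ids[tot <= 0], collapse = ", ")))
  sweep(ab, 2, mapped / tot, `*`)
}

#' Summarize transcript quantifications to the gene level
#'
#' Gene counts are sums of member-transcript counts under the selected
#' counts-from-abundance mode. For gene-level count modeling an
#' abundance-weighted average effective transcript length is returned as an
#' offset matrix: `offset[g, i] = sum_t w_ti * efflen_ti` with weights
#' `w_ti = TPM_ti / sum_{t in g} TPM_ti`; when a gene's TPM total is zero in
#' a sample the unweighted mean effective length is used instead.
#'
#' @param q a `TranscriptQuantSet`.
#' @param map data.frame from [build_tx2gene()] (columns `transcript_id`,
#'   `gene_id`).
#' @param mode counts-from-abundance mode, see [counts_from_abundance()].
#' @return A gene-level `CountMatrix` with an `offsets` matrix.
#' @export
summarize_to_gene <- function(q, map, mode = c("raw", "scaledTPM",
                                               "lengthScaledTPM")) {
  mode <- match.arg(mode)
  stopifnot(inherits(q, "TranscriptQuantSet"))
  missing <- setdiff(q$transcript_ids, map$transcript_id)
  if (length(missing) > 0)
    stop("transcript(s) absent from tx2gene map: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ..." else "")
  gene <- map$gene_id[match(q$transcript_ids, map$transcript_id)]
  cts <- .cfa_matrix(q, mode)
  gcts <- rowsum(cts, gene)
  gene_tpm <- rowsum(q$tpm, gene)
  # abundance-weighted mean effective length per gene and sample
  wlen <- rowsum(q$tpm * q$eff_length, gene)
  nlen <- rowsum(q$eff_length, gene)
  ntx <- as.vector(table(gene)[rownames(nlen)])
  off <- wlen / gene_tpm
  fallback <- nlen / ntx
  zero <- !(gene_tpm > 0)
  off[zero] <- fallback[zero]
  cm <- list(row_ids = rownames(gcts),
             sample_ids = q$sample_ids,
             counts = gcts,
             mode = mode,
             offsets = off)
  class(cm) <- "CountMatrix"
  cm
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix (%s): %d rows x %d samples%s\n", x$mode,
              length(x$row_ids), length(x$sample_ids),
              if (!is.null(x$offsets)) ", with length offsets" else ""))
  invisible(x)
}

#' Write a count matrix as TSV
#'
#' @param cm a `CountMatrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(row_id = cm$row_ids, cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
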