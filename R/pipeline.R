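# Orchestration: one call from quantifications (or a simulated dataset) to
# filtered counts, DTU tests, stage-wise results and, when truth is
# available, an evaluation report. The defaults reproduce the recommended
# path: scaledTPM counts for DTU, the three pre-filters at their default
# thresholds, and the post-hoc proportion-SD filter on the DM path only.

#' Run configuration
#'
#' @param quant_dir directory holding `<sample_id>/quant.sf` files (or
#'   `NULL` when `quants` passed directly to [run_pipeline()]).
#' @param gtf path to a GTF annotation (or `NULL` when `tx2gene` passed
#'   directly).
#' @param samples_csv CSV with columns `sample_id`, `condition` (or `NULL`).
#' @param out_dir output directory for result TSVs (`NULL` = no files).
#' @param counts_mode counts-from-abundance mode for DTU (default
#'   `"scaledTPM"`).
#' @param method `"dm"`, `"nb"` or `"both"`.
#' @param alpha target OFDR for stage-wise testing (default 0.05).
#' @param sd_filter apply the post-hoc proportion-SD filter on the DM path
#'   (default `TRUE`; never applied to the NB path).
#' @param sd_threshold proportion-SD threshold (default 0.1).
#' @param filter_cfg optional `FilterConfig`; default derives thresholds
#'   from the sample table.
#' @param seed integer seed.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(quant_dir = NULL, gtf = NULL, samples_csv = NULL,
                       out_dir = NULL, counts_mode = "scaledTPM",
                       method = c("dm", "nb", "both"), alpha = 0.05,
                       sd_filter = TRUE, sd_threshold = 0.1,
                       filter_cfg = NULL, seed = 1) {
  cfg <- list(quant_dir = quant_dir, gtf = gtf, samples_csv = samples_csv,
              out_dir = out_dir, counts_mode = counts_mode,
              method = match.arg(method), alpha = alpha,
              sd_filter = sd_filter, sd_threshold = sd_threshold,
              filter_cfg = filter_cfg, seed = seed)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s (check the inputs to this stage)", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the DTU pipeline
#'
#' Stages: import quantifications, build scaledTPM counts, map transcripts
#' to genes, pre-filter, test (DM and/or NB), stage-wise adjust at the
#' configured alpha, and (when `truth` is supplied) evaluate. Deterministic
#' given `cfg$seed`. When `cfg$out_dir` is set, writes per-method gene and
#' transcript result TSVs and the stage-wise table.
#'
#' @param cfg a `RunConfig`.
#' @param quants optional `TranscriptQuantSet` (bypasses `quant_dir`).
#' @param tx2gene optional transcript-to-gene data.frame (bypasses `gtf`).
#' @param samples optional sample table (bypasses `samples_csv`).
#' @param truth optional `SimTruth` for evaluation.
#' @return list with `dataset` (filtered `DTUDataset`) and per-method
#'   entries `dm` / `nb`, each holding `results`, `stagewise` and (with
#'   truth) `evaluation`.
#' @export
run_pipeline <- function(cfg, quants = NULL, tx2gene = NULL, samples = NULL,
                         truth = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  set.seed(cfg$seed)
  if (is.null(samples)) {
    if (is.null(cfg$samples_csv)) stop("[import] no sample table provided")
    samples <- utils::read.csv(cfg$samples_csv, stringsAsFactors = FALSE)
  }
  if (is.null(quants)) {
    if (is.null(cfg$quant_dir)) stop("[import] no quantifications provided")
    paths <- stats::setNames(
      file.path(cfg$quant_dir, samples$sample_id, "quant.sf"),
      samples$sample_id)
    quants <- .stage("import", read_salmon_quant(paths))
  }
  if (is.null(tx2gene)) {
    if (is.null(cfg$gtf)) stop("[tx2gene] no annotation provided")
    tx2gene <- .stage("tx2gene", build_tx2gene(cfg$gtf))
  }
  cm <- .stage("counts", counts_from_abundance(quants, cfg$counts_mode))
  gene_of <- tx2gene$gene_id[match(cm$row_ids, tx2gene$transcript_id)]
  if (anyNA(gene_of))
    stop("[tx2gene] transcripts missing from the annotation: ",
         paste(utils::head(cm$row_ids[is.na(gene_of)], 5), collapse = ", "))
  ds <- dtu_dataset(cm$counts, gene_of, cm$row_ids, samples)
  fcfg <- if (is.null(cfg$filter_cfg)) default_filter_config(samples)
    else cfg$filter_cfg
  ds <- .stage("filter", dm_style_filter(ds, fcfg))
  out <- list(dataset = ds, config = cfg)
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cfg$method %in% c("dm", "both"))
    out$dm <- .run_dm_path(ds, cfg, truth)
  if (cfg$method %in% c("nb", "both"))
    out$nb <- .run_nb_path(ds, cfg, truth)
  out
}

.run_dm_path <- function(ds, cfg, truth) {
  res <- .stage("dtu-dm", dm_test(ds, seed = cfg$seed))
  gene <- res$gene
  txp <- res$transcript
  if (cfg$sd_filter) {
    mask <- proportion_sd_mask(ds, cfg$sd_threshold)
    mask <- mask[match(txp$feature_id, ds$transcript_ids)]
    txp$pvalue[mask] <- 1
    txp$adj_pvalue[mask] <- 1
  }
  p_screen <- stats::setNames(sanitize_pvalues(gene$pvalue), gene$gene_id)
  p_conf <- sanitize_pvalues(txp$pvalue)
  sw <- .stage("stagewise", stage_wise_adjust(
    p_screen, p_conf, txp[, c("feature_id", "gene_id")],
    alpha = cfg$alpha, screen_adjusted = FALSE))
  path <- list(results = res, transcript_filtered = txp, stagewise = sw)
  if (!is.null(truth))
    path$evaluation <- evaluate_dtu(
      stats::setNames(gene$adj_pvalue, gene$gene_id),
      stats::setNames(txp$adj_pvalue, txp$feature_id), sw, truth)
  if (!is.null(cfg$out_dir)) .write_path_results(path, cfg$out_dir, "dm")
  path
}

.run_nb_path <- function(ds, cfg, truth) {
  res <- .stage("dtu-nb", nb_test(ds))
  txp <- res$transcript
  gene <- res$gene
  p_screen <- stats::setNames(sanitize_pvalues(gene$qval), gene$gene_id)
  p_conf <- sanitize_pvalues(txp$pvalue)
  sw <- .stage("stagewise", stage_wise_adjust(
    p_screen, p_conf, txp[, c("feature_id", "gene_id")],
    alpha = cfg$alpha, screen_adjusted = TRUE))
  path <- list(results = res, stagewise = sw)
  if (!is.null(truth))
    path$evaluation <- evaluate_dtu(
      stats::setNames(gene$qval, gene$gene_id),
      stats::setNames(txp$adj_pvalue, txp$feature_id), sw, truth)
  if (!is.null(cfg$out_dir)) .write_path_results(path, cfg$out_dir, "nb")
  path
}

.write_path_results <- function(path, out_dir, tag) {
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(path$results$gene, sprintf("%s_gene_results.tsv", tag))
  tx <- if (!is.null(path$transcript_filtered)) path$transcript_filtered
    else path$results$transcript
  wt(tx, sprintf("%s_transcript_results.tsv", tag))
  wt(as.data.frame(path$stagewise), sprintf("%s_stagewise.tsv", tag))
  if (!is.null(path$evaluation)) {
    ev <- path$evaluation
    wt(ev$gene, sprintf("%s_eval_gene.tsv", tag))
    wt(ev$transcript, sprintf("%s_eval_transcript.tsv", tag))
    jsonlite::write_json(
      list(ofdr = ev$ofdr$ofdr, sensitivity = ev$ofdr$sensitivity,
           n_screened = ev$ofdr$n_screened),
      file.path(out_dir, sprintf("%s_eval_ofdr.json", tag)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
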