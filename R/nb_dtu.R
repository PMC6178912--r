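# Per-transcript negative-binomial GLM test of differential usage.
#
# Each transcript's counts are paired with the summed counts of the other
# transcripts of its gene ("one vs rest"), giving 2n observations per
# transcript. The full model
#
#   ~ sample + feature + condition:feature
#
# allows the focal-feature proportion to depend on condition; the reduced
# model drops the interaction. NB dispersions are per-transcript: Cox-Reid
# adjusted profile likelihood MLEs, a parametric trend a1/mu + a0, and MAP
# shrinkage toward the trend.

#' Build one-vs-rest augmented counts
#'
#' For each transcript, pairs its per-sample counts with the per-sample sum
#' of the remaining transcripts of the same gene. Counts are rounded to
#' integers.
#'
#' @param ds a `DTUDataset`.
#' @return An `AugmentedCounts`: list with integer matrices `this` and
#'   `others` (transcripts x samples), `feature_id`, `gene_id`, `samples`.
#' @export
build_augmented_counts <- function(ds) {
  stopifnot(inherits(ds, "DTUDataset"))
  cts <- round(ds$counts)
  gene_tot <- rowsum(cts, ds$gene_ids)
  tot <- gene_tot[match(ds$gene_ids, rownames(gene_tot)), , drop = FALSE]
  aug <- list(this = cts, others = tot - cts,
              feature_id = ds$transcript_ids, gene_id = ds$gene_ids,
              samples = ds$samples)
  class(aug) <- "AugmentedCounts"
  aug
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over rows of the ratio of its count to the
#' row geometric mean, restricted to rows with a positive geometric mean;
#' factors are then normalized to geometric mean 1.
#'
#' @param counts numeric matrix (rows x samples).
#' @return positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("size-factor estimation needs at least one row with all-positive counts")
  lsf <- apply(log(counts[use, , drop = FALSE]) - loggeo[use], 2,
               stats::median)
  sf <- exp(lsf - mean(lsf))
  stats::setNames(sf, colnames(counts))
}

# design matrices for the stacked (this, others) response of one transcript:
# observations are ordered c(this_1..this_n, others_1..others_n).
# full:    intercept + sample + feature("this") + condition:feature
# reduced: drop the interaction column(s)
.nb_designs <- function(samples) {
  n <- nrow(samples)
  sample_f <- factor(rep(seq_len(n), 2))
  feat <- rep(c(1, 0), each = n)           # 1 = focal feature
  cond <- factor(rep(samples$condition, 2))
  Xs <- stats::model.matrix(~sample_f)
  inter <- stats::model.matrix(~cond)[, -1, drop = FALSE] * feat
  colnames(inter) <- paste0("cond", levels(cond)[-1], ":this")
  X_full <- cbind(Xs, this = feat, inter)
  X_red <- cbind(Xs, this = feat)
  list(full = X_full, reduced = X_red, n_inter = ncol(inter))
}

# NB GLM fit with fixed dispersion alpha via glm.fit and the
# MASS negative.binomial family; returns fitted means and log-likelihood.
.nb_glm <- function(y, X, offset, alpha) {
  theta <- 1 / alpha
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = MASS::negative.binomial(theta = theta),
                   offset = offset,
                   control = list(maxit = 500, epsilon = 1e-8)))
  mu <- pmax(fit$fitted.values, 1e-10)
  list(mu = mu,
       loglik = sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)),
       converged = fit$converged)
}

# Cox-Reid adjusted profile log-likelihood of alpha for one transcript.
.nb_cr_apl <- function(alpha, y, X, offset) {
  f <- .nb_glm(y, X, offset, alpha)
  W <- f$mu / (1 + alpha * f$mu)
  XtWX <- crossprod(X, W * X)
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  f$loglik - 0.5 * as.numeric(ld)
}

.NB_LOG_ALPHA_BOUNDS <- log(c(1e-8, 30))

# parametric trend alpha(mu) = a1/mu + a0 by iterated gamma-family
# regression over per-transcript dispersion MLEs (outlier ratios trimmed
# each round). Falls back to a flat trend at the median when the fit fails.
.nb_fit_trend <- function(means, disps) {
  ok <- is.finite(disps) & disps > 1e-7 & is.finite(means) & means > 0
  x <- means[ok]; d <- disps[ok]
  if (length(d) < 10)
    return(list(a0 = stats::median(disps, na.rm = TRUE), a1 = 0))
  a <- c(stats::median(d), 0)
  for (it in 1:10) {
    fit <- try(suppressWarnings(
      stats::glm(d ~ I(1 / x), family = Gamma(link = "identity"),
                 start = c(a[1], max(a[2], 1e-4)))), silent = TRUE)
    if (inherits(fit, "try-error")) break
    anew <- unname(stats::coef(fit))
    pred <- pmax(anew[1] + anew[2] / x, 1e-8)
    ratio <- d / pred
    keep <- ratio > 1e-4 & ratio < 15
    if (all(abs(anew - a) < 1e-3 * pmax(abs(a), 1e-3))) {
      a <- anew; break
    }
    a <- anew
    if (sum(keep) >= 10) { x <- x[keep]; d <- d[keep] }
  }
  list(a0 = max(a[1], 1e-8), a1 = max(a[2], 0))
}

#' Estimate per-transcript NB dispersions on augmented counts
#'
#' Three stages: (1) per-transcript dispersion MLE by maximizing the
#' Cox-Reid adjusted profile likelihood under the full design; (2) a
#' parametric mean-dispersion trend `alpha(mu) = a1/mu + a0` fit by iterated
#' gamma-family regression; (3) maximum-a-posteriori shrinkage of each MLE
#' toward the trend under a log-normal prior whose variance is estimated
#' from the spread of log residuals (floored at 0.25). Transcripts whose
#' MLE lies far above the trend (log residual beyond twice the residual
#' spread) are dispersion outliers and keep their unshrunken MLE.
#'
#' @param aug an `AugmentedCounts`.
#' @param size_factors per-sample size factors (from
#'   [estimate_size_factors()]).
#' @return data.frame per transcript: `mean` (base mean of the focal
#'   counts), `disp_mle`, `disp_trend`, `disp_map`.
#' @export
estimate_dispersions <- function(aug, size_factors) {
  stopifnot(inherits(aug, "AugmentedCounts"))
  des <- .nb_designs(aug$samples)
  X <- des$full
  n <- nrow(aug$samples)
  if (2 * n <= ncol(X))
    stop("fewer observations than design coefficients")
  offset <- rep(log(size_factors), 2)
  T <- nrow(aug$this)
  disp_mle <- numeric(T)
  means <- numeric(T)
  for (t in seq_len(T)) {
    y <- c(aug$this[t, ], aug$others[t, ])
    means[t] <- mean(aug$this[t, ] / size_factors)
    opt <- try(stats::optimize(function(la) .nb_cr_apl(exp(la), y, X, offset),
                               interval = .NB_LOG_ALPHA_BOUNDS,
                               maximum = TRUE, tol = 1e-3), silent = TRUE)
    disp_mle[t] <- if (inherits(opt, "try-error")) NA_real_
      else exp(opt$maximum)
  }
  disp_mle <- pmax(disp_mle, 1e-8)
  trend <- .nb_fit_trend(means, disp_mle)
  disp_trend <- pmax(trend$a0 + trend$a1 / pmax(means, 1e-8), 1e-8)
  lr <- log(disp_mle) - log(disp_trend)
  spread <- stats::mad(lr[is.finite(lr)], na.rm = TRUE)
  # subtract the expected sampling variance of a log dispersion estimate
  m <- 2 * n; p <- ncol(X)
  samp_var <- trigamma((m - p) / 2)
  prior_var <- max(spread^2 - samp_var, 0.25)
  outlier <- is.finite(lr) & lr > 2 * pmax(spread, sqrt(samp_var))
  disp_map <- numeric(T)
  for (t in seq_len(T)) {
    if (outlier[t] || !is.finite(disp_mle[t])) {
      disp_map[t] <- disp_mle[t]
      next
    }
    y <- c(aug$this[t, ], aug$others[t, ])
    post <- function(la) {
      .nb_cr_apl(exp(la), y, X, offset) -
        (la - log(disp_trend[t]))^2 / (2 * prior_var)
    }
    opt <- try(stats::optimize(post, interval = .NB_LOG_ALPHA_BOUNDS,
                               maximum = TRUE, tol = 1e-3), silent = TRUE)
    disp_map[t] <- if (inherits(opt, "try-error")) disp_trend[t]
      else exp(opt$maximum)
  }
  disp_map <- pmax(disp_map, 1e-8)
  data.frame(feature_id = aug$feature_id, gene_id = aug$gene_id,
             mean = means, disp_mle = disp_mle, disp_trend = disp_trend,
             disp_map = disp_map, stringsAsFactors = FALSE)
}

#' Likelihood-ratio test of the condition:feature interaction
#'
#' Fits the full (`~ sample + feature + condition:feature`) and reduced
#' (`~ sample + feature`) NB GLMs to each transcript's stacked
#' (focal, rest-of-gene) counts with log size factors as offsets and fixed
#' per-transcript dispersion, and computes the chi-squared likelihood-ratio
#' p-value. Non-converged fits yield a missing p-value.
#'
#' @param aug an `AugmentedCounts`.
#' @param size_factors per-sample size factors.
#' @param dispersions per-transcript dispersions (e.g. column `disp_map`
#'   from [estimate_dispersions()]).
#' @return data.frame per transcript: `feature_id`, `gene_id`, `lr`, `df`,
#'   `pvalue`.
#' @export
test_interaction_lrt <- function(aug, size_factors, dispersions) {
  stopifnot(inherits(aug, "AugmentedCounts"))
  des <- .nb_designs(aug$samples)
  offset <- rep(log(size_factors), 2)
  T <- nrow(aug$this)
  stopifnot(length(dispersions) == T)
  df <- des$n_inter
  lr <- numeric(T); pv <- numeric(T)
  for (t in seq_len(T)) {
    y <- c(aug$this[t, ], aug$others[t, ])
    res <- tryCatch({
      full <- .nb_glm(y, des$full, offset, dispersions[t])
      red <- .nb_glm(y, des$reduced, offset, dispersions[t])
      if (!full$converged || !red$converged) stop("no convergence")
      s <- max(0, 2 * (full$loglik - red$loglik))
      c(s, chisq_lr_pvalue(s, df))
    }, error = function(e) c(NA_real_, NA_real_))
    lr[t] <- res[1]; pv[t] <- res[2]
  }
  data.frame(feature_id = aug$feature_id, gene_id = aug$gene_id,
             lr = lr, df = df, pvalue = pv, stringsAsFactors = FALSE)
}

#' Aggregate transcript p-values to gene-level q-values
#'
#' Per gene, the minimum transcript p-value is corrected for within-gene
#' multiplicity by the Sidak formula `1 - (1 - min p)^K` over the gene's K
#' tested transcripts, and the resulting gene p-values are BH-adjusted
#' across genes. Missing transcript p-values are ignored; a gene with no
#' finite p-value gets p = 1.
#'
#' @param transcript_p numeric vector of per-transcript p-values.
#' @param gene_ids aligned gene identifiers.
#' @return data.frame: `gene_id`, `pvalue`, `qval`.
#' @export
per_gene_qvalue <- function(transcript_p, gene_ids) {
  stopifnot(length(transcript_p) == length(gene_ids))
  sp <- split(transcript_p, gene_ids)
  gene_p <- vapply(sp, function(p) {
    K <- length(p)
    p <- p[is.finite(p)]
    if (length(p) == 0) return(1)
    1 - (1 - min(p))^K
  }, numeric(1))
  data.frame(gene_id = names(gene_p), pvalue = unname(gene_p),
             qval = unname(adjust_bh(gene_p)), stringsAsFactors = FALSE)
}

#' Negative-binomial DTU testing across a dataset
#'
#' Runs the full NB interaction path: augmented one-vs-rest counts, size
#' factors on the transcript count matrix, per-transcript dispersion
#' estimation, interaction likelihood-ratio tests, and per-gene q-value
#' aggregation.
#'
#' @param ds a filtered `DTUDataset`.
#' @param verbose print progress.
#' @return An `NBResults`: list with data.frames `transcript` (feature_id,
#'   gene_id, lr, df, pvalue, adj_pvalue) and `gene` (gene_id, pvalue,
#'   qval), plus `size_factors` and the `dispersions` table.
#' @export
nb_test <- function(ds, verbose = FALSE) {
  aug <- build_augmented_counts(ds)
  sf <- estimate_size_factors(round(ds$counts))
  if (verbose) message("estimating dispersions")
  disp <- estimate_dispersions(aug, sf)
  if (verbose) message("testing interaction terms")
  txp <- test_interaction_lrt(aug, sf, disp$disp_map)
  txp$adj_pvalue <- adjust_bh(txp$pvalue)
  gene <- per_gene_qvalue(txp$pvalue, txp$gene_id)
  out <- list(transcript = txp, gene = gene, size_factors = sf,
              dispersions = disp)
  class(out) <- "NBResults"
  out
}
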