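#' Build a covariate design matrix for residualization
#'
#' Assembles the nuisance design used before the paired perturbation test
#' and the case-control analyses: intercept, sex, age, sequencing-batch
#' indicators (first level dropped), EBV load, ATP level and viable cell
#' count, and genotypic ancestry PCs 1-5. Cell count and ATP level are
#' cell-harvest measurements and exist per condition; by default both
#' conditions' values enter the design (`both_condition_covariates`).
#' Affection status is included only for the paired perturbation analysis
#' (where it must be removed from the residuals) and excluded for
#' case-control analyses (where it is the predictor of interest).
#'
#' `condition = "pooled"` builds one design over all baseline and stimulated
#' samples together (without any condition term). This is the design for
#' the paired perturbation test: residualizing each condition separately
#' would zero every gene's mean per condition and destroy exactly the
#' baseline-versus-stimulated contrast the paired test measures, so
#' covariates are removed jointly and the condition contrast survives into
#' the residuals.
#'
#' Aliased columns are dropped with a warning; a design that remains
#' rank-deficient is an error.
#'
#' @param samples Sample sheet (all samples, both conditions).
#' @param pairs A [paired_design()] of the sample sheet.
#' @param condition `"baseline"`, `"stimulated"`, or `"pooled"` (both
#'   conditions stacked, baseline first).
#' @param include_affection Include affection status as a nuisance column
#'   (TRUE for the paired perturbation test, FALSE for case-control
#'   analyses).
#' @param both_condition_covariates Use cell count and ATP level measured at
#'   both conditions (default) or only at the sample's own condition.
#' @return An object of class `covariate_design`: list with the model matrix
#'   `X`, `sample_id` and `subject_id` (row-aligned).
#' @export
covariate_design <- function(samples, pairs,
                             condition = c("baseline", "stimulated",
                                           "pooled"),
                             include_affection = FALSE,
                             both_condition_covariates = TRUE) {
  condition <- match.arg(condition)
  samples <- validate_sample_sheet(samples)
  stopifnot(inherits(pairs, "paired_design"))
  if (condition == "pooled") {
    own_ids <- c(pairs$baseline, pairs$stimulated)
    other_ids <- c(pairs$stimulated, pairs$baseline)
    subject_id <- c(pairs$subject_id, pairs$subject_id)
  } else {
    own_ids <- pairs[[condition]]
    other <- if (condition == "baseline") "stimulated" else "baseline"
    other_ids <- pairs[[other]]
    subject_id <- pairs$subject_id
  }
  own <- samples[match(own_ids, samples$sample_id), ]
  oth <- samples[match(other_ids, samples$sample_id), ]
  df <- data.frame(sex = factor(own$sex, levels = c("male", "female")),
                   age = own$age,
                   batch = factor(own$batch),
                   ebv_load = own$ebv_load,
                   atp_level = own$atp_level,
                   cell_count = own$cell_count)
  if (both_condition_covariates) {
    df$atp_level_other <- oth$atp_level
    df$cell_count_other <- oth$cell_count
  }
  df[paste0("pc", 1:5)] <- own[paste0("pc", 1:5)]
  if (include_affection)
    df$affection <- factor(own$affection, levels = c("control", "case"))
  X <- stats::model.matrix(~ ., data = df)
  rownames(X) <- own_ids
  X <- drop_aliased(X)
  structure(list(X = X, sample_id = own_ids, subject_id = subject_id),
            class = "covariate_design")
}

# drop linearly dependent columns (keeping the intercept) with a warning;
# error if the pivoted rank check still fails afterwards
drop_aliased <- function(X, tol = 1e-10) {
  qx <- qr(X, tol = tol)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[drop], collapse = ", "), call. = FALSE)
    X <- X[, -drop, drop = FALSE]
    if (qr(X, tol = tol)$rank < ncol(X))
      stop("design matrix is rank-deficient after dropping aliased columns",
           call. = FALSE)
  }
  X
}

#' Regress covariates out of an expression matrix
#'
#' Per gene, ordinary least squares residuals
#' `y - X (X'X)^{-1} X' y` against the design; the residuals are orthogonal
#' to every design column. The design rows must align with the matrix
#' columns (matching `sample_id` for a `covariate_design`, rownames for a
#' plain matrix).
#'
#' @param m An `expr_matrix` (genes x samples).
#' @param design A [covariate_design()] or a numeric design matrix with
#'   sample rownames.
#' @return An `expr_matrix` at stage `residual`.
#' @export
residualize <- function(m, design) {
  stopifnot(inherits(m, "expr_matrix"))
  if (inherits(design, "covariate_design")) {
    idx <- match(colnames(m), design$sample_id)
    if (anyNA(idx))
      stop("design does not cover sample(s): ",
           paste(utils::head(colnames(m)[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    X <- design$X[idx, , drop = FALSE]
  } else {
    X <- as.matrix(design)
    if (!is.null(rownames(X))) {
      idx <- match(colnames(m), rownames(X))
      if (anyNA(idx))
        stop("design rownames do not cover all samples", call. = FALSE)
      X <- X[idx, , drop = FALSE]
    } else if (nrow(X) != ncol(m)) {
      stop("design rows must align with matrix samples", call. = FALSE)
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient", call. = FALSE)
  qx <- qr(X)
  res <- t(qr.resid(qx, t(em_values(m))))
  dimnames(res) <- dimnames(m)
  expr_matrix(res, stage = "residual")
}

#' Paired baseline-versus-stimulated test
#'
#' One-sample Student t-test on the within-subject differences
#' `d_i = stimulated_i - baseline_i` of covariate-adjusted expression, per
#' gene: `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-sided
#' p-value. Genes whose differences have zero variance are flagged
#' (`degenerate`) and reported with missing statistics; q-values are
#' Benjamini-Hochberg over all non-degenerate genes.
#'
#' @param baseline_resid,stim_resid Residual-stage `expr_matrix` objects for
#'   the two conditions.
#' @param pairs A [paired_design()] mapping subjects to their two samples.
#' @return A data.frame with one row per gene: `gene_id`, `mean_baseline`,
#'   `mean_stimulated`, `t_stat`, `df`, `p`, `q`, `degenerate`.
#' @export
paired_da_test <- function(baseline_resid, stim_resid, pairs) {
  stopifnot(inherits(baseline_resid, "expr_matrix"),
            inherits(stim_resid, "expr_matrix"),
            inherits(pairs, "paired_design"))
  if (!identical(rownames(baseline_resid), rownames(stim_resid)))
    stop("matrices must share the same gene index", call. = FALSE)
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  b <- em_values(baseline_resid)[, pairs$baseline, drop = FALSE]
  s <- em_values(stim_resid)[, pairs$stimulated, drop = FALSE]
  d <- s - b
  n <- ncol(d)
  mean_d <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mean_d)^2) / (n - 1L))
  degenerate <- sd_d == 0
  t_stat <- ifelse(degenerate, NA_real_, mean_d / (sd_d / sqrt(n)))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  q <- rep(NA_real_, length(p))
  q[!degenerate] <- bh_fdr(p[!degenerate])
  data.frame(gene_id = rownames(d),
             mean_baseline = rowMeans(b),
             mean_stimulated = rowMeans(s),
             t_stat = t_stat, df = n - 1L, p = p, q = q,
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Perturbation fold change
#'
#' Per gene, the ratio of mean expression in the stimulated condition to mean
#' expression at baseline, on quantile-normalized RPKM, plus its log2.
#' Genes with zero baseline mean get `fc = NA` and are flagged `undefined`.
#'
#' @param baseline,stim RPKM-stage `expr_matrix` objects sharing genes.
#' @param per_subject If TRUE, compute instead the mean over paired subjects
#'   of the per-subject ratios (requires `pairs`).
#' @param pairs [paired_design()], required when `per_subject = TRUE`.
#' @return data.frame: `gene_id`, `fc`, `log2fc`, `undefined`.
#' @export
fold_change <- function(baseline, stim, per_subject = FALSE, pairs = NULL) {
  stopifnot(inherits(baseline, "expr_matrix"), inherits(stim, "expr_matrix"))
  if (!identical(rownames(baseline), rownames(stim)))
    stop("matrices must share the same gene index", call. = FALSE)
  if (per_subject) {
    if (is.null(pairs)) stop("per_subject = TRUE requires `pairs`",
                             call. = FALSE)
    b <- em_values(baseline)[, pairs$baseline, drop = FALSE]
    s <- em_values(stim)[, pairs$stimulated, drop = FALSE]
    ratio <- s / b
    ratio[!is.finite(ratio)] <- NA
    fc <- rowMeans(ratio, na.rm = TRUE)
    undefined <- !is.finite(fc)
  } else {
    mb <- rowMeans(em_values(baseline))
    ms <- rowMeans(em_values(stim))
    undefined <- mb == 0
    fc <- ifelse(undefined, NA_real_, ms / mb)
  }
  data.frame(gene_id = rownames(baseline), fc = fc,
             log2fc = log2(fc), undefined = undefined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select genes by a standard-deviation cutoff on log2 fold change
#'
#' Computes `mean(log2fc) +/- k_sd * sd(log2fc)` and selects genes strictly
#' outside the closed interval. Used to pick the larger-magnitude responders
#' from a near-universal small-effect fold-change distribution for
#' enrichment analysis.
#'
#' @param log2fc Named numeric vector of per-gene log2 fold changes
#'   (non-finite entries are ignored).
#' @param k_sd Width of the retained interval in SD units, default 1.
#' @return List with `selected` (gene names), `lower`/`upper` (log2 cutoffs)
#'   and `fc_lower`/`fc_upper` (the same cutoffs on the FC scale).
#' @export
select_by_fc_sd <- function(log2fc, k_sd = 1) {
  keep <- is.finite(log2fc)
  x <- log2fc[keep]
  if (length(x) < 2L) stop("need at least 2 finite log2 fold changes",
                           call. = FALSE)
  mu <- mean(x)
  s <- stats::sd(x)
  lower <- mu - k_sd * s
  upper <- mu + k_sd * s
  sel <- names(x)[x < lower | x > upper]
  list(selected = sel, lower = lower, upper = upper,
       fc_lower = 2^lower, fc_upper = 2^upper)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles of their ranks with the Blom offset:
#' `qnorm((r - 3/8) / (n + 1/4))`, ties receiving their mean rank. The
#' output depends on the input only through its ranks, so any strictly
#' increasing transform of the input yields the identical result. Applied to
#' a matrix, the transform acts per gene (row) across samples and returns a
#' `rank_normal`-stage matrix.
#'
#' @param x Numeric vector (length >= 2) or an `expr_matrix`.
#' @return Transformed vector, or `expr_matrix` at stage `rank_normal`.
#' @export
rank_normalize <- function(x) {
  if (inherits(x, "expr_matrix")) {
    v <- em_values(x)
    if (ncol(v) < 2L) stop("need at least 2 samples", call. = FALSE)
    out <- t(apply(v, 1L, rank_normalize_vec))
    dimnames(out) <- dimnames(v)
    return(expr_matrix(out, stage = "rank_normal"))
  }
  rank_normalize_vec(x)
}

rank_normalize_vec <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Case-control association of expression
#'
#' Per gene, simple linear regression of expression on affection status
#' coded control = 0, case = 1:
#' `E(y) = beta0 + beta1 * status`, so `beta1` is the case-minus-control mean
#' difference, tested two-sided with `df = n - 2`. The expression input is
#' expected to be covariate-adjusted and rank-normalized (or a perturbation
#' response built from such values). Zero-variance genes are flagged
#' `degenerate` and excluded from the Benjamini-Hochberg adjustment.
#'
#' @param expr `expr_matrix` at stage `rank_normal` or `response`; columns
#'   may be sample IDs or subject IDs.
#' @param samples Sample sheet used to look up affection status (by
#'   `sample_id` first, falling back to `subject_id` for response matrices).
#' @param analysis Label stored in the result: `"baseline"`, `"stimulated"`
#'   or `"response"`.
#' @return data.frame per gene: `gene_id`, `beta0`, `beta1`, `se1`, `p`,
#'   `q`, `analysis`, `degenerate`.
#' @export
case_control_assoc <- function(expr, samples,
                               analysis = c("baseline", "stimulated",
                                            "response")) {
  stopifnot(inherits(expr, "expr_matrix"))
  analysis <- match.arg(analysis)
  samples <- validate_sample_sheet(samples)
  ids <- colnames(expr)
  aff <- samples$affection[match(ids, samples$sample_id)]
  if (anyNA(aff)) {
    by_subj <- samples$affection[match(ids, samples$subject_id)]
    aff[is.na(aff)] <- by_subj[is.na(aff)]
  }
  if (anyNA(aff))
    stop("affection status not found for: ",
         paste(utils::head(ids[is.na(aff)], 5L), collapse = ", "),
         call. = FALSE)
  status <- as.numeric(aff == "case")
  if (length(unique(status)) < 2L)
    stop("both affection groups must be present", call. = FALSE)
  y <- em_values(expr)
  n <- ncol(y)
  xc <- status - mean(status)
  sxx <- sum(xc^2)
  beta1 <- drop(y %*% xc) / sxx
  beta0 <- rowMeans(y) - beta1 * mean(status)
  yc <- y - rowMeans(y)
  rss <- rowSums(yc^2) - beta1^2 * sxx
  rss[rss < 0] <- 0
  degenerate <- rowSums(yc^2) == 0
  sigma2 <- rss / (n - 2L)
  se1 <- sqrt(sigma2 / sxx)
  t_stat <- beta1 / se1
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2L)
  p[degenerate | !is.finite(p)] <- NA_real_
  degenerate <- degenerate | !is.finite(t_stat)
  q <- rep(NA_real_, length(p))
  q[!degenerate] <- bh_fdr(p[!degenerate])
  data.frame(gene_id = rownames(y), beta0 = beta0, beta1 = beta1,
             se1 = se1, p = p, q = q, analysis = analysis,
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subject perturbation response
#'
#' Subtracts the covariate-adjusted, rank-normalized baseline expression from
#' its stimulated counterpart, per subject:
#' `response(g, subject) = stim(g, subject) - baseline(g, subject)`.
#' The result has one column per subject and is the phenotype of the
#' differential-response case-control analysis.
#'
#' @param baseline_adj,stim_adj `rank_normal`-stage `expr_matrix` objects.
#' @param pairs A [paired_design()].
#' @return `expr_matrix` at stage `response`, columns named by subject.
#' @export
da_response <- function(baseline_adj, stim_adj, pairs) {
  stopifnot(inherits(baseline_adj, "expr_matrix"),
            inherits(stim_adj, "expr_matrix"),
            inherits(pairs, "paired_design"))
  if (!identical(rownames(baseline_adj), rownames(stim_adj)))
    stop("matrices must share the same gene index", call. = FALSE)
  miss <- setdiff(c(pairs$baseline, pairs$stimulated),
                  c(colnames(baseline_adj), colnames(stim_adj)))
  if (length(miss))
    stop("sample(s) missing from the adjusted matrices: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  b <- em_values(baseline_adj)[, pairs$baseline, drop = FALSE]
  s <- em_values(stim_adj)[, pairs$stimulated, drop = FALSE]
  out <- s - b
  colnames(out) <- pairs$subject_id
  expr_matrix(out, stage = "response")
}

#' Regress out top expression principal components
#'
#' Computes the top `k` principal components of the gene-centered residual
#' matrix in sample space and regresses their score vectors (plus an
#' intercept) out of every gene. This is a robustness device against
#' confounders not captured by the measured covariates; the output is
#' orthogonal to the removed components. `k = 0` returns the input
#' unchanged.
#'
#' @param resid `expr_matrix` at stage `residual` (or `rank_normal`).
#' @param k Number of leading components to remove, default 5; must be
#'   smaller than the number of samples.
#' @return `expr_matrix` at the input's stage.
#' @export
expression_pc_adjust <- function(resid, k = 5) {
  stopifnot(inherits(resid, "expr_matrix"))
  if (k == 0) return(resid)
  v <- em_values(resid)
  if (k >= ncol(v))
    stop("k must be smaller than the number of samples", call. = FALSE)
  centered <- v - rowMeans(v)
  sv <- svd(centered, nu = 0L, nv = k)
  scores <- sv$v[, seq_len(k), drop = FALSE]
  X <- cbind(1, scores)
  out <- t(qr.resid(qr(X), t(v)))
  dimnames(out) <- dimnames(v)
  expr_matrix(out, stage = expr_stage(resid))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * n / j`, clipped at 1 and
#' mapped back to input order (delegated to [stats::p.adjust()]). Inputs
#' must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
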