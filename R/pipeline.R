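#' Control parameters for the perturbation-response pipeline
#'
#' @param min_fraction Expressed-gene threshold: minimum fraction of samples
#'   with a positive value in either condition (default 0.5).
#' @param fdr Benjamini-Hochberg FDR threshold used to call significant
#'   genes (default 0.05).
#' @param fc_sd SD cutoff on log2 fold change for selecting the
#'   larger-magnitude perturbation responders (default 1).
#' @param pc_adjust Number of expression PCs to regress out in the
#'   robustness repeat of the case-control analyses; 0 disables the repeat
#'   (default 5).
#' @param qc Run the sample-level QC stage and exclude flagged outliers
#'   (default TRUE).
#' @param z_cut Outlier threshold passed to [detect_outliers()].
#' @param outlier_policy Combine the correlation and PCA outlier screens by
#'   `"union"` (default) or `"intersection"`.
#' @param both_condition_covariates Include harvest covariates (cell count,
#'   ATP) from both conditions in every design (default TRUE).
#' @param query_in_background Fisher 2x2 construction for enrichment, see
#'   [fisher_two_sided()].
#' @param keep_matrices Keep the adjusted expression matrices in the fitted
#'   object (needed by [residuals.da_fit()]; default TRUE).
#' @return A list of class `da_control`.
#' @export
da_control <- function(min_fraction = 0.5, fdr = 0.05, fc_sd = 1,
                       pc_adjust = 5, qc = TRUE, z_cut = 4,
                       outlier_policy = "union",
                       both_condition_covariates = TRUE,
                       query_in_background = TRUE, keep_matrices = TRUE) {
  stopifnot(min_fraction >= 0, min_fraction <= 1, fdr > 0, fdr < 1,
            fc_sd >= 0, pc_adjust >= 0)
  structure(list(min_fraction = min_fraction, fdr = fdr, fc_sd = fc_sd,
                 pc_adjust = pc_adjust, qc = qc, z_cut = z_cut,
                 outlier_policy = outlier_policy,
                 both_condition_covariates = both_condition_covariates,
                 query_in_background = query_in_background,
                 keep_matrices = keep_matrices),
            class = "da_control")
}

#' Fit the paired perturbation-response analysis
#'
#' The package's central fitting function. Starting from gene-level counts
#' (or RPKM) for paired baseline and stimulated samples, it runs the full
#' analysis chain:
#' sample QC with outlier exclusion; expressed-gene filtering; quantile
#' normalization across all samples; the paired perturbation test on
#' covariate residuals with fold changes and the SD-cutoff selection;
#' log2(RPKM + 1) transformation, covariate residualization and rank-based
#' inverse-normal transformation; case-control association of expression at
#' baseline and under stimulation; the per-subject perturbation response and
#' its case-control association; an optional repeat of the three
#' case-control analyses after removing the top expression PCs; gene-set
#' enrichment of every significant gene list; and a three-way overlap
#' summary with direction concordance. The pipeline is a pure function of
#' its inputs and control settings: repeated runs yield identical results.
#'
#' @param counts_baseline,counts_stimulated Counts- or RPKM-stage
#'   [expr_matrix()] objects sharing a gene index.
#' @param samples Sample sheet covering all columns of both matrices.
#' @param annotation Gene annotation (required for counts-stage input).
#' @param gene_sets Optional named list of gene-ID vectors to test for
#'   enrichment (background = the run's expressed genes).
#' @param control A [da_control()] list.
#' @return An object of class `da_fit`; see [summary.da_fit()],
#'   [coef.da_fit()], [residuals.da_fit()], [plot.da_fit()].
#' @export
da_perturb <- function(counts_baseline, counts_stimulated, samples,
                       annotation = NULL, gene_sets = NULL,
                       control = da_control()) {
  stopifnot(inherits(counts_baseline, "expr_matrix"),
            inherits(counts_stimulated, "expr_matrix"),
            inherits(control, "da_control"))
  samples <- validate_sample_sheet(samples)
  stages <- list()
  note_stage <- function(name, genes, samples_n) {
    stages[[name]] <<- c(genes = genes, samples = samples_n)
  }
  note_stage("input", nrow(counts_baseline),
             ncol(counts_baseline) + ncol(counts_stimulated))

  ## RPKM
  if (expr_stage(counts_baseline) == "counts") {
    if (is.null(annotation))
      stop("counts-stage input requires `annotation`", call. = FALSE)
    rpkm_b <- rpkm_from_counts(counts_baseline, annotation)
    rpkm_s <- rpkm_from_counts(counts_stimulated, annotation)
  } else {
    rpkm_b <- counts_baseline
    rpkm_s <- counts_stimulated
  }

  ## QC and outlier exclusion (one-shot, before the expressed-gene filter)
  qc <- NULL
  if (control$qc) {
    all_rpkm <- expr_matrix(cbind(em_values(rpkm_b), em_values(rpkm_s)),
                            "rpkm")
    qc <- qc_report(all_rpkm, samples, z_cut = control$z_cut,
                    outlier_policy = control$outlier_policy)
    rm(all_rpkm)
    if (length(qc$excluded)) {
      bad_subjects <- unique(samples$subject_id[samples$sample_id %in%
                                                  qc$excluded])
      keep <- !(samples$subject_id %in% bad_subjects)
      samples <- samples[keep, , drop = FALSE]
      rpkm_b <- rpkm_b[, intersect(colnames(rpkm_b), samples$sample_id)]
      rpkm_s <- rpkm_s[, intersect(colnames(rpkm_s), samples$sample_id)]
    }
  }
  pairs <- paired_design(samples)
  note_stage("post_qc", nrow(rpkm_b), ncol(rpkm_b) + ncol(rpkm_s))

  ## expressed-gene filter, then quantile normalization over all samples
  expressed <- expressed_gene_filter(rpkm_b, rpkm_s,
                                     min_fraction = control$min_fraction)
  rpkm_b <- rpkm_b[expressed, ]
  rpkm_s <- rpkm_s[expressed, ]
  note_stage("expressed", length(expressed), ncol(rpkm_b) + ncol(rpkm_s))
  nb <- ncol(rpkm_b)
  qn_all <- quantile_normalize(
    expr_matrix(cbind(em_values(rpkm_b), em_values(rpkm_s)), "rpkm"))
  qn_b <- qn_all[, seq_len(nb)]
  qn_s <- qn_all[, nb + seq_len(ncol(rpkm_s))]

  ## paired perturbation test on covariate residuals (affection included,
  ## covariates removed jointly across conditions so the condition contrast
  ## survives residualization)
  des_pooled <- covariate_design(samples, pairs, "pooled",
    include_affection = TRUE,
    both_condition_covariates = control$both_condition_covariates)
  resid_pooled <- residualize(qn_all, des_pooled)
  de <- paired_da_test(resid_pooled[, seq_len(nb)],
                       resid_pooled[, nb + seq_len(ncol(qn_s))], pairs)
  rm(resid_pooled)
  fc <- fold_change(qn_b, qn_s)
  de <- merge(de, fc, by = "gene_id", sort = FALSE)
  de <- de[match(expressed, de$gene_id), ]
  rownames(de) <- NULL
  lfc <- stats::setNames(de$log2fc, de$gene_id)
  fc_selection <- select_by_fc_sd(lfc, k_sd = control$fc_sd)

  ## case-control analyses on rank-normalized covariate residuals
  des_b <- covariate_design(samples, pairs, "baseline",
    include_affection = FALSE,
    both_condition_covariates = control$both_condition_covariates)
  des_s <- covariate_design(samples, pairs, "stimulated",
    include_affection = FALSE,
    both_condition_covariates = control$both_condition_covariates)
  resid_b <- residualize(log2p1(qn_b), des_b)
  resid_s <- residualize(log2p1(qn_s), des_s)
  adj_b <- rank_normalize(resid_b)
  adj_s <- rank_normalize(resid_s)
  resp <- da_response(adj_b, adj_s, pairs)
  assoc <- list(baseline = case_control_assoc(adj_b, samples, "baseline"),
                stimulated = case_control_assoc(adj_s, samples,
                                                "stimulated"),
                response = case_control_assoc(resp, samples, "response"))

  ## robustness repeat with top expression PCs removed (per condition)
  assoc_pc <- NULL
  if (control$pc_adjust > 0) {
    pcadj_b <- rank_normalize(expression_pc_adjust(resid_b,
                                                   control$pc_adjust))
    pcadj_s <- rank_normalize(expression_pc_adjust(resid_s,
                                                   control$pc_adjust))
    resp_pc <- da_response(pcadj_b, pcadj_s, pairs)
    assoc_pc <- list(
      baseline = case_control_assoc(pcadj_b, samples, "baseline"),
      stimulated = case_control_assoc(pcadj_s, samples, "stimulated"),
      response = case_control_assoc(resp_pc, samples, "response"))
  }

  sig <- lapply(assoc, function(a)
    a$gene_id[!a$degenerate & !is.na(a$q) & a$q < control$fdr])
  beta_of <- function(a) stats::setNames(a$beta1, a$gene_id)
  overlap <- overlap_summary(sig$baseline, sig$stimulated, sig$response,
                             beta_baseline = beta_of(assoc$baseline),
                             beta_stimulated = beta_of(assoc$stimulated))

  ## gene-set enrichment of every selected list
  enrichment <- NULL
  if (!is.null(gene_sets)) {
    collection <- gene_set_collection(gene_sets, background = expressed)
    queries <- c(list(perturbation_fc = fc_selection$selected), sig)
    if (!is.null(assoc_pc)) {
      sig_pc <- lapply(assoc_pc, function(a)
        a$gene_id[!a$degenerate & !is.na(a$q) & a$q < control$fdr])
      names(sig_pc) <- paste0(names(sig_pc), "_pc")
      queries <- c(queries, sig_pc)
    }
    queries <- queries[vapply(queries, length, 1L) > 0L]
    enrichment <- table1_report(lapply(queries, enrich,
      collection = collection,
      query_in_background = control$query_in_background))
  }

  manifest <- list(control = unclass(control),
                   stages = stages,
                   n_subjects = nrow(pairs),
                   n_cases = sum(pairs$affection == "case"),
                   n_controls = sum(pairs$affection == "control"),
                   excluded_samples = if (is.null(qc)) character(0)
                                      else qc$excluded,
                   n_expressed = length(expressed),
                   n_da_responsive_fdr = sum(!de$degenerate &
                                               de$q < control$fdr,
                                             na.rm = TRUE),
                   n_fc_selected = length(fc_selection$selected),
                   n_significant = vapply(sig, length, 1L))

  out <- list(qc = qc, pairs = pairs, samples = samples,
              expressed = expressed, de = de, fc_selection = fc_selection,
              assoc = assoc, assoc_pc = assoc_pc, significant = sig,
              overlap = overlap, enrichment = enrichment,
              manifest = manifest, control = control)
  if (control$keep_matrices)
    out$matrices <- list(rpkm_baseline = qn_b, rpkm_stimulated = qn_s,
                         residual_baseline = resid_b,
                         residual_stimulated = resid_s,
                         adjusted_baseline = adj_b,
                         adjusted_stimulated = adj_s,
                         response = resp)
  class(out) <- "da_fit"
  out
}

#' Three-way overlap of significant gene sets
#'
#' Counts the 7 regions of the Venn decomposition of the baseline,
#' stimulated and response significant sets (region counts sum exactly to
#' the size of the union), and the direction-concordance rate: the fraction
#' of genes significant at both baseline and stimulation whose case-control
#' effect signs agree.
#'
#' @param sig_baseline,sig_stimulated,sig_response Character vectors of
#'   significant gene IDs over a common gene universe.
#' @param beta_baseline,beta_stimulated Optional named per-gene effect
#'   vectors used for the concordance rate.
#' @return List with `regions` (named integer vector of the 7 Venn region
#'   counts), `union_size` and `concordance` (NA when betas are absent or
#'   the intersection is empty).
#' @export
overlap_summary <- function(sig_baseline, sig_stimulated, sig_response,
                            beta_baseline = NULL, beta_stimulated = NULL) {
  b <- unique(sig_baseline); s <- unique(sig_stimulated)
  r <- unique(sig_response)
  in_b <- function(g) g %in% b
  in_s <- function(g) g %in% s
  in_r <- function(g) g %in% r
  u <- union(union(b, s), r)
  regions <- c(
    baseline_only = sum(in_b(u) & !in_s(u) & !in_r(u)),
    stimulated_only = sum(!in_b(u) & in_s(u) & !in_r(u)),
    response_only = sum(!in_b(u) & !in_s(u) & in_r(u)),
    baseline_stimulated = sum(in_b(u) & in_s(u) & !in_r(u)),
    baseline_response = sum(in_b(u) & !in_s(u) & in_r(u)),
    stimulated_response = sum(!in_b(u) & in_s(u) & in_r(u)),
    all_three = sum(in_b(u) & in_s(u) & in_r(u)))
  bs <- intersect(b, s)
  concordance <- NA_real_
  if (length(bs) && !is.null(beta_baseline) && !is.null(beta_stimulated)) {
    sign_b <- sign(beta_baseline[bs])
    sign_s <- sign(beta_stimulated[bs])
    ok <- !is.na(sign_b) & !is.na(sign_s)
    if (any(ok)) concordance <- mean(sign_b[ok] == sign_s[ok])
  }
  list(regions = regions, union_size = length(u), concordance = concordance)
}

#' @export
print.da_fit <- function(x, ...) {
  m <- x$manifest
  cat("Paired perturbation-response fit\n")
  cat(sprintf("  %d subjects (%d cases, %d controls), %d expressed genes\n",
              m$n_subjects, m$n_cases, m$n_controls, m$n_expressed))
  if (length(m$excluded_samples))
    cat(sprintf("  excluded %d outlier sample(s): %s\n",
                length(m$excluded_samples),
                paste(m$excluded_samples, collapse = ", ")))
  cat(sprintf("  perturbation-responsive genes (FDR < %g): %d\n",
              x$control$fdr, m$n_da_responsive_fdr))
  cat(sprintf("  |log2 FC| beyond %g SD: %d genes (FC < %.2f or > %.2f)\n",
              x$control$fc_sd, m$n_fc_selected,
              x$fc_selection$fc_lower, x$fc_selection$fc_upper))
  cat(sprintf("  case-control significant (FDR < %g): baseline %d, stimulated %d, response %d\n",
              x$control$fdr, m$n_significant["baseline"],
              m$n_significant["stimulated"], m$n_significant["response"]))
  invisible(x)
}

#' Summarize a fitted perturbation-response analysis
#'
#' @param object A `da_fit`.
#' @param n_top Number of top response genes to list.
#' @param ... Unused.
#' @return A list of class `summary.da_fit`.
#' @export
summary.da_fit <- function(object, n_top = 10, ...) {
  resp <- object$assoc$response
  resp <- resp[!resp$degenerate & !is.na(resp$p), ]
  top <- resp[order(resp$p), c("gene_id", "beta1", "p", "q")]
  top <- utils::head(top, n_top)
  rownames(top) <- NULL
  out <- list(manifest = object$manifest, control = object$control,
              fc_selection = object$fc_selection[c("fc_lower", "fc_upper")],
              overlap = object$overlap, top_response = top,
              enrichment = object$enrichment)
  class(out) <- "summary.da_fit"
  out
}

#' @export
print.summary.da_fit <- function(x, ...) {
  m <- x$manifest
  cat("Paired perturbation-response analysis\n")
  cat(sprintf("  subjects: %d cases + %d controls; expressed genes: %d\n",
              m$n_cases, m$n_controls, m$n_expressed))
  cat(sprintf("  perturbation-responsive at FDR < %g: %d (%.1f%% of expressed)\n",
              x$control$fdr, m$n_da_responsive_fdr,
              100 * m$n_da_responsive_fdr / m$n_expressed))
  cat(sprintf("  case-control significant: baseline %d, stimulated %d, response %d\n",
              m$n_significant["baseline"], m$n_significant["stimulated"],
              m$n_significant["response"]))
  cat("  overlap regions:\n")
  print(x$overlap$regions)
  if (!is.na(x$overlap$concordance))
    cat(sprintf("  baseline/stimulated direction concordance: %.3f\n",
                x$overlap$concordance))
  cat("  top differential-response genes:\n")
  print(x$top_response, row.names = FALSE)
  if (!is.null(x$enrichment)) {
    cat("  enrichment:\n")
    df <- x$enrichment[, c("analysis", "set_name", "total", "count",
                           "percent_fmt", "fold_fmt", "p_fmt")]
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Extract case-control regression coefficients
#'
#' @param object A `da_fit`.
#' @param analysis `"baseline"`, `"stimulated"` or `"response"`.
#' @param pc_adjusted Use the expression-PC-adjusted repeat.
#' @param ... Unused.
#' @return data.frame of per-gene `beta0`, `beta1`, `se1`, `p`, `q`.
#' @export
coef.da_fit <- function(object, analysis = "response", pc_adjusted = FALSE,
                        ...) {
  analysis <- match.arg(analysis, c("baseline", "stimulated", "response"))
  src <- if (pc_adjusted) {
    if (is.null(object$assoc_pc))
      stop("fit was run without PC adjustment", call. = FALSE)
    object$assoc_pc
  } else object$assoc
  src[[analysis]]
}

#' Extract adjusted expression matrices from a fit
#'
#' @param object A `da_fit` run with `keep_matrices = TRUE`.
#' @param stage One of `"residual"`, `"rank_normal"`, `"response"`,
#'   `"rpkm"` (quantile-normalized).
#' @param condition `"baseline"` or `"stimulated"` (ignored for
#'   `"response"`).
#' @param ... Unused.
#' @return The requested `expr_matrix`.
#' @export
residuals.da_fit <- function(object, stage = "response",
                             condition = "baseline", ...) {
  if (is.null(object$matrices))
    stop("fit was run with keep_matrices = FALSE", call. = FALSE)
  stage <- match.arg(stage, c("residual", "rank_normal", "response", "rpkm"))
  condition <- match.arg(condition, c("baseline", "stimulated"))
  key <- switch(stage,
                response = "response",
                residual = paste0("residual_", condition),
                rank_normal = paste0("adjusted_", condition),
                rpkm = paste0("rpkm_", condition))
  object$matrices[[key]]
}

#' Plot the fold-change distribution of a fit
#'
#' Histogram of per-gene log2 fold changes with the SD-cutoff selection
#' boundaries marked.
#'
#' @param x A `da_fit`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.da_fit <- function(x, ...) {
  lfc <- x$de$log2fc[is.finite(x$de$log2fc)]
  graphics::hist(lfc, breaks = 80, main = "Perturbation fold changes",
                 xlab = "log2 fold change (stimulated / baseline)", ...)
  graphics::abline(v = c(x$fc_selection$lower, x$fc_selection$upper),
                   col = "red", lty = 2)
  invisible(x)
}
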