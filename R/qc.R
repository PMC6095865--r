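#' Sex-marker concordance check
#'
#' Compares reported sex against sex predicted from expression of the X-linked
#' marker XIST and a panel of Y-chromosome genes. A sample is predicted female
#' when XIST RPKM exceeds `t_x` while the mean Y-marker RPKM stays below
#' `t_y`, male in the reverse situation, and indeterminate otherwise (both
#' margins low or both high). Marker genes absent from the matrix are dropped
#' with a warning; if all markers of one side are missing every sample is
#' flagged indeterminate.
#'
#' @param m An `expr_matrix` of RPKM values.
#' @param samples Sample sheet covering the matrix columns.
#' @param x_marker X-linked female marker gene, default `"XIST"`.
#' @param y_markers Y-linked male marker genes; the default panel is
#'   RPS4Y1, ZFY, USP9Y, DDX3Y, UTY, KDM5D and EIF1AY.
#' @param t_x,t_y RPKM thresholds for the X and Y margins (default 1).
#' @return Named character vector over samples with values
#'   `"concordant"`, `"discordant"` or `"indeterminate"`.
#' @export
sex_concordance <- function(m, samples, x_marker = "XIST",
                            y_markers = c("RPS4Y1", "ZFY", "USP9Y", "DDX3Y",
                                          "UTY", "KDM5D", "EIF1AY"),
                            t_x = 1, t_y = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  samples <- validate_sample_sheet(samples)
  ids <- intersect(colnames(m), samples$sample_id)
  v <- em_values(m)[, ids, drop = FALSE]
  reported <- samples$sex[match(ids, samples$sample_id)]
  miss_x <- !(x_marker %in% rownames(v))
  y_have <- intersect(y_markers, rownames(v))
  if (miss_x || length(y_have) < length(y_markers))
    warning("missing sex marker gene(s): ",
            paste(c(if (miss_x) x_marker, setdiff(y_markers, y_have)),
                  collapse = ", "), call. = FALSE)
  if (miss_x || length(y_have) == 0L) {
    flags <- rep("indeterminate", length(ids))
    names(flags) <- ids
    return(flags)
  }
  x_expr <- v[x_marker, ]
  y_expr <- colMeans(v[y_have, , drop = FALSE])
  predicted <- ifelse(x_expr > t_x & y_expr < t_y, "female",
                      ifelse(x_expr < t_x & y_expr > t_y, "male", NA))
  flags <- ifelse(is.na(predicted), "indeterminate",
                  ifelse(predicted == reported, "concordant", "discordant"))
  names(flags) <- ids
  flags
}

#' Genotype concordance between RNA-seq calls and array genotypes
#'
#' Compares pre-called genotype tables (coded 0/1/2 with NA for missing) over
#' a shared SNP panel, sample by sample. Concordance is the fraction of
#' matching calls among SNPs non-missing in both tables; samples whose
#' concordance falls below `threshold` are flagged as possible swaps. A
#' sample with no jointly non-missing SNP is indeterminate (NA), not zero.
#'
#' @param rnaseq_calls,array_calls Numeric matrices (SNPs x samples) coded
#'   0/1/2/NA, sharing SNP rownames.
#' @param snp_panel Optional character vector restricting to a SNP panel.
#' @param threshold Flagging threshold on concordance, default 0.8.
#' @return A data.frame with `sample_id`, `concordance`, `n_compared`,
#'   `flagged`.
#' @export
genotype_concordance <- function(rnaseq_calls, array_calls, snp_panel = NULL,
                                 threshold = 0.8) {
  if (is.null(rownames(rnaseq_calls)) || is.null(rownames(array_calls)))
    stop("genotype matrices need SNP rownames", call. = FALSE)
  snps <- intersect(rownames(rnaseq_calls), rownames(array_calls))
  if (!is.null(snp_panel)) snps <- intersect(snps, snp_panel)
  if (length(snps) == 0L) stop("no shared SNPs to compare", call. = FALSE)
  ids <- intersect(colnames(rnaseq_calls), colnames(array_calls))
  a <- rnaseq_calls[snps, ids, drop = FALSE]
  b <- array_calls[snps, ids, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  n_cmp <- colSums(ok)
  n_match <- colSums(ok & (a == b), na.rm = TRUE)
  conc <- ifelse(n_cmp > 0, n_match / n_cmp, NA_real_)
  data.frame(sample_id = ids, concordance = conc, n_compared = n_cmp,
             flagged = !is.na(conc) & conc < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene completion rates by affection group
#'
#' The completion rate of a gene in a group is the fraction of that group's
#' samples with a positive expression value. Near-identical case and control
#' completion profiles (Pearson correlation close to 1) indicate the absence
#' of systematic case/control detection bias.
#'
#' @param m An `expr_matrix` (typically RPKM).
#' @param samples Sample sheet covering the matrix columns.
#' @return A list with `rates` (data.frame: gene_id, case, control) and
#'   `correlation` (Pearson correlation of the two rate vectors).
#' @export
completion_rates <- function(m, samples) {
  stopifnot(inherits(m, "expr_matrix"))
  samples <- validate_sample_sheet(samples)
  aff <- samples$affection[match(colnames(m), samples$sample_id)]
  if (anyNA(aff))
    stop("sample(s) missing from the sample sheet: ",
         paste(utils::head(colnames(m)[is.na(aff)], 5L), collapse = ", "),
         call. = FALSE)
  v <- em_values(m)
  if (sum(aff == "case") < 2L || sum(aff == "control") < 2L)
    stop("need at least two samples per affection group", call. = FALSE)
  rate_case <- rowMeans(v[, aff == "case", drop = FALSE] > 0)
  rate_ctrl <- rowMeans(v[, aff == "control", drop = FALSE] > 0)
  r <- if (stats::sd(rate_case) == 0 || stats::sd(rate_ctrl) == 0) NA_real_
       else stats::cor(rate_case, rate_ctrl)
  list(rates = data.frame(gene_id = rownames(v), case = rate_case,
                          control = rate_ctrl, row.names = NULL,
                          stringsAsFactors = FALSE),
       correlation = r)
}

# column-wise Pearson correlation via BLAS (much faster than stats::cor
# for wide matrices); columns with zero variance yield NA
fast_cor <- function(x) {
  x <- scale(x, center = TRUE, scale = FALSE)
  s <- sqrt(colSums(x^2))
  s[s == 0] <- NA_real_
  x <- sweep(x, 2L, s, "/")
  crossprod(x)
}

#' Expression-based outlier detection
#'
#' Two complementary sample-level screens:
#' \describe{
#'   \item{correlation}{each sample's mean pairwise Spearman correlation with
#'     all other samples is z-scored across samples; samples with
#'     z < `-z_cut` are flagged. Spearman is used for robustness to the
#'     heavy-tailed expression scale.}
#'   \item{pca}{samples are scored on the top 2 principal components of the
#'     gene-centered matrix; a sample is flagged when |score| exceeds `z_cut`
#'     standard deviations on either component.}
#' }
#' The returned list is ordered by severity (most extreme first). Flags are
#' deterministic and invariant to sample ordering.
#'
#' @param m An `expr_matrix`.
#' @param method `"correlation"` or `"pca"`.
#' @param z_cut Flagging threshold in standard deviations, default 4.
#' @return Character vector of flagged sample IDs (possibly empty).
#' @export
detect_outliers <- function(m, method = c("correlation", "pca"), z_cut = 4) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  v <- em_values(m)
  if (ncol(v) < 10L)
    stop("need at least 10 samples for outlier detection", call. = FALSE)
  if (method == "correlation") {
    rk <- apply(v, 2L, rank, ties.method = "average")
    cc <- fast_cor(rk)
    diag(cc) <- NA
    mean_cor <- colMeans(cc, na.rm = TRUE)
    z <- (mean_cor - mean(mean_cor)) / stats::sd(mean_cor)
    flagged <- colnames(v)[!is.na(z) & z < -z_cut]
    flagged[order(z[match(flagged, colnames(v))])]
  } else {
    centered <- v - rowMeans(v)
    # sample scores on the top 2 right singular vectors of the centered matrix
    sv <- svd(centered, nu = 0L, nv = 2L)
    scores <- sv$v %*% diag(sv$d[1:2], 2L)
    zs <- scale(scores)
    zs[!is.finite(zs)] <- 0  # zero-variance component: nothing to flag
    worst <- apply(abs(zs), 1L, max)
    flagged <- colnames(v)[worst > z_cut]
    flagged[order(-worst[match(flagged, colnames(v))])]
  }
}

#' Assemble a sample-level QC report
#'
#' Bundles the individual QC screens into one report: sex-marker flags,
#' optional genotype concordance, per-gene completion rates with their
#' case/control correlation, and outlier lists from both the correlation and
#' the PCA screen. `outlier_policy` chooses how the two screens are combined
#' into the exclusion list. The outlier screens run on the log2(RPKM + 1)
#' scale: the Spearman correlation screen is rank-based and unaffected,
#' while PCA on the raw RPKM scale would be dominated by a handful of
#' highly expressed genes and flag their sampling noise as outliers.
#'
#' @param m RPKM `expr_matrix`.
#' @param samples Sample sheet.
#' @param rnaseq_calls,array_calls Optional genotype matrices for
#'   [genotype_concordance()].
#' @param z_cut Outlier threshold passed to [detect_outliers()].
#' @param outlier_policy `"union"` (default) or `"intersection"` of the two
#'   outlier screens.
#' @return A list of class `qc_report`.
#' @export
qc_report <- function(m, samples, rnaseq_calls = NULL, array_calls = NULL,
                      z_cut = 4, outlier_policy = c("union", "intersection")) {
  outlier_policy <- match.arg(outlier_policy)
  sex <- suppressWarnings(sex_concordance(m, samples))
  geno <- if (!is.null(rnaseq_calls) && !is.null(array_calls))
    genotype_concordance(rnaseq_calls, array_calls) else NULL
  comp <- completion_rates(m, samples)
  logm <- if (expr_stage(m) == "rpkm") log2p1(m) else m
  out_cor <- detect_outliers(logm, "correlation", z_cut = z_cut)
  out_pca <- detect_outliers(logm, "pca", z_cut = z_cut)
  excluded <- if (outlier_policy == "union") union(out_cor, out_pca)
              else intersect(out_cor, out_pca)
  structure(list(sex_flags = sex,
                 genotype = geno,
                 completion = comp$rates,
                 completion_correlation = comp$correlation,
                 outliers_correlation = out_cor,
                 outliers_pca = out_pca,
                 outlier_policy = outlier_policy,
                 excluded = excluded),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Sample QC report\n")
  cat(sprintf("  sex flags: %d concordant, %d discordant, %d indeterminate\n",
              sum(x$sex_flags == "concordant"),
              sum(x$sex_flags == "discordant"),
              sum(x$sex_flags == "indeterminate")))
  if (!is.null(x$genotype))
    cat(sprintf("  genotype concordance: %d/%d samples flagged\n",
                sum(x$genotype$flagged), nrow(x$genotype)))
  cat(sprintf("  case/control completion-rate correlation: %.3f\n",
              x$completion_correlation))
  cat(sprintf("  outliers: %d by correlation, %d by PCA; %d excluded (%s)\n",
              length(x$outliers_correlation), length(x$outliers_pca),
              length(x$excluded), x$outlier_policy))
  invisible(x)
}

#' Write a QC report to disk
#'
#' Serializes the scalar/flag parts of the report as JSON and the per-gene
#' completion rates as TSV.
#'
#' @param report A `qc_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "qc_report.json")
  tsv_path <- file.path(dir, "completion_rates.tsv")
  jsonlite::write_json(
    list(sex_flags = as.list(report$sex_flags),
         genotype = report$genotype,
         completion_correlation = report$completion_correlation,
         outliers_correlation = report$outliers_correlation,
         outliers_pca = report$outliers_pca,
         outlier_policy = report$outlier_policy,
         excluded = report$excluded),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$completion, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
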