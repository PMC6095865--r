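#' RPKM from raw gene-level counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM(g, s) = counts(g, s) * 1e9 / (exonic_length(g) * library_size(s))`,
#' with the exonic length taken from the longest-transcript exon model of the
#' gene and the library size taken as the column sum of the count matrix.
#'
#' @param counts An `expr_matrix` at stage `counts`.
#' @param annot Gene annotation data.frame with `gene_id` and `exonic_length`
#'   covering every counted gene (see [read_gene_annotation()]).
#' @return An `expr_matrix` at stage `rpkm`.
#' @export
rpkm_from_counts <- function(counts, annot) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_stage(counts) != "counts")
    stop("rpkm_from_counts() expects a counts-stage matrix", call. = FALSE)
  annot <- validate_gene_annotation(annot)
  idx <- match(rownames(counts), annot$gene_id)
  if (anyNA(idx))
    stop("no annotation for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  len <- annot$exonic_length[idx]
  v <- em_values(counts)
  lib <- colSums(v)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(v)[lib == 0], collapse = ", "), call. = FALSE)
  out <- v * 1e9 / len
  out <- sweep(out, 2L, lib, "/")
  expr_matrix(out, stage = "rpkm")
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) onto a common reference distribution, the
#' per-rank mean of the sorted per-sample vectors, preserving each sample's
#' within-column rank order. Tied values within a sample receive the mean of
#' the reference values at their tied ranks, which makes the transform
#' idempotent. Used on gene-level RPKM to absorb batch/run-level distribution
#' shifts before any statistics are computed.
#'
#' @param m An `expr_matrix` (any stage; the stage tag is preserved).
#' @return An `expr_matrix` of the same shape and stage.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- em_values(m)
  if (ncol(v) < 1L) stop("need at least one sample", call. = FALSE)
  ref <- rowMeans(apply(v, 2L, sort, method = "radix"))
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    assigned <- numeric(length(x))
    assigned[order(x, method = "radix")] <- ref
    # ties: mean of the reference values occupying the tied ranks
    out[, j] <- stats::ave(assigned, match(x, x), FUN = mean)
  }
  expr_matrix(out, stage = expr_stage(m))
}

#' Expressed-gene filter
#'
#' A gene is called expressed when it has a positive value in at least
#' `min_fraction` of the baseline samples or at least `min_fraction` of the
#' stimulated samples (inclusive threshold). The permissive either-condition
#' rule keeps genes that are near-silent in one condition but induced or
#' repressed in the other.
#'
#' @param baseline,stimulated `expr_matrix` objects sharing the same gene
#'   index (typically RPKM).
#' @param min_fraction Minimum fraction of positive samples, default 0.5.
#' @return Character vector of expressed gene IDs, in matrix order.
#' @export
expressed_gene_filter <- function(baseline, stimulated, min_fraction = 0.5) {
  stopifnot(inherits(baseline, "expr_matrix"),
            inherits(stimulated, "expr_matrix"))
  if (!identical(rownames(baseline), rownames(stimulated)))
    stop("baseline and stimulated matrices must share the same gene index",
         call. = FALSE)
  frac_b <- rowMeans(em_values(baseline) > 0)
  frac_s <- rowMeans(em_values(stimulated) > 0)
  rownames(baseline)[frac_b >= min_fraction | frac_s >= min_fraction]
}

#' log2(x + 1) transform
#'
#' Elementwise `log2(x + 1)` of an RPKM matrix; monotone, maps 0 to 0.
#'
#' @param m An `expr_matrix` at stage `rpkm` (non-negative values).
#' @return An `expr_matrix` at stage `log2rpkm`.
#' @export
log2p1 <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- em_values(m)
  if (any(v < 0)) stop("log2p1() requires non-negative values", call. = FALSE)
  expr_matrix(log2(v + 1), stage = "log2rpkm")
}
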