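#' Expression matrix with a processing-stage tag
#'
#' An expression matrix is a numeric genes x samples matrix carrying a `stage`
#' attribute that records where in the processing chain its values live:
#' raw `counts`, `rpkm`, `log2rpkm` (log2(RPKM + 1)), covariate `residual`,
#' `rank_normal` (inverse-normal transformed residuals) or `response`
#' (per-subject stimulated minus baseline differences). Stages `counts` and
#' `rpkm` must be non-negative; later stages are unconstrained reals.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene IDs) and
#'   colnames (sample or subject IDs). No missing cells are allowed.
#' @param stage Character scalar, one of
#'   `c("counts", "rpkm", "log2rpkm", "residual", "rank_normal", "response")`.
#' @return An object of class `expr_matrix`: the matrix with a `stage` attribute.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                    paste0("s", 1:2))),
#'                  stage = "counts")
#' expr_stage(m)
#' @export
expr_matrix <- function(values, stage) {
  stage <- match.arg(stage, expr_stages())
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("expression matrix must not contain missing cells", call. = FALSE)
  if (stage %in% c("counts", "rpkm") && any(values < 0))
    stop("stage '", stage, "' requires non-negative values", call. = FALSE)
  structure(values, stage = stage, class = c("expr_matrix", class(values)))
}

expr_stages <- function() {
  c("counts", "rpkm", "log2rpkm", "residual", "rank_normal", "response")
}

#' @rdname expr_matrix
#' @param m An `expr_matrix`.
#' @export
expr_stage <- function(m) {
  s <- attr(m, "stage")
  if (is.null(s)) stop("not an expr_matrix: no stage attribute", call. = FALSE)
  s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              expr_stage(x), nrow(x), ncol(x)))
  v <- unclass(x)
  attr(v, "stage") <- NULL
  print(utils::head(v[, seq_len(min(ncol(v), 6L)), drop = FALSE], 5L), ...)
  if (nrow(x) > 5L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, stage = expr_stage(x),
                     class = c("expr_matrix", class(out)))
  out
}

# strip class/attribute for internal numeric work
em_values <- function(m) {
  v <- unclass(m)
  attr(v, "stage") <- NULL
  v
}

#' Read and write expression matrices as TSV
#'
#' Tab-separated, UTF-8, header row of sample IDs with leading column
#' `gene_id`, no quoting. Gene order is preserved on write. Malformed rows,
#' non-numeric cells and duplicate gene or sample IDs are rejected with an
#' error naming the offending line.
#'
#' @param path Path to a TSV file.
#' @param stage Processing stage to declare for the values read
#'   (see [expr_matrix()]).
#' @return [read_expression_tsv()] returns an `expr_matrix`;
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, stage) {
  stage <- match.arg(stage, expr_stages())
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty expression file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("line 1: header must contain gene_id plus at least one sample",
         call. = FALSE)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("line 1: duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": expected ", length(header),
         " fields, found ", nf[bad[1L]], call. = FALSE)
  gene_ids <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(gene_ids))
  if (length(dup))
    stop("line ", dup[1L] + 1L, ": duplicate gene ID '", gene_ids[dup[1L]],
         "'", call. = FALSE)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(length(sample_ids))))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(sample_ids))
  if (anyNA(vals)) {
    bad_row <- which(apply(is.na(vals), 1L, any))[1L]
    stop("line ", bad_row + 1L, ": non-numeric expression value for gene '",
         gene_ids[bad_row], "'", call. = FALSE)
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  expr_matrix(vals, stage = stage)
}

#' @rdname read_expression_tsv
#' @param m An `expr_matrix` to write.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- em_values(m)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1L, function(row)
    paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `symbol`, `exonic_length` and
#' `chromosome`. Exonic length is the summed exon length (bp) of the longest
#' transcript of the gene and must be a positive integer; it is the length
#' term of the RPKM formula.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  validate_gene_annotation(df)
}

validate_gene_annotation <- function(df) {
  need <- c("gene_id", "symbol", "exonic_length", "chromosome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("annotation has duplicate gene_id entries", call. = FALSE)
  if (any(is.na(df$exonic_length)) || any(df$exonic_length < 1))
    stop("exonic_length must be a positive integer (bp)", call. = FALSE)
  df
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with one row per sequenced sample and columns
#' `sample_id`, `subject_id`, `condition` (baseline/stimulated), `affection`
#' (case/control), `sex` (male/female), `age`, `batch`, `ebv_load`,
#' `atp_level`, `cell_count` and ancestry principal components `pc1`..`pc5`.
#' Each subject contributes one baseline and one stimulated sample.
#'
#' @param path Path to the sample sheet TSV.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "subject_id", "condition", "affection", "sex", "age",
            "batch", "ebv_load", "atp_level", "cell_count",
            paste0("pc", 1:5))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("sample sheet has duplicate sample_id entries", call. = FALSE)
  if (!all(df$condition %in% c("baseline", "stimulated")))
    stop("condition must be 'baseline' or 'stimulated'", call. = FALSE)
  if (!all(df$affection %in% c("case", "control")))
    stop("affection must be 'case' or 'control'", call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (any(df$age < 0)) stop("age must be non-negative", call. = FALSE)
  df
}

#' Baseline/stimulated pairing of a sample sheet
#'
#' Builds the subject-level pairing used by the paired test and the response
#' analysis: each subject must appear exactly once per condition, and the two
#' samples of a subject must agree on affection, sex, age and ancestry PCs.
#'
#' @param samples A sample sheet (see [read_sample_sheet()]).
#' @return A data.frame of class `paired_design` with columns `subject_id`,
#'   `baseline`, `stimulated` and subject-level covariates.
#' @export
paired_design <- function(samples) {
  samples <- validate_sample_sheet(samples)
  base <- samples[samples$condition == "baseline", ]
  stim <- samples[samples$condition == "stimulated", ]
  if (anyDuplicated(base$subject_id) || anyDuplicated(stim$subject_id))
    stop("a subject has more than one sample in a condition", call. = FALSE)
  subj <- sort(unique(samples$subject_id))
  if (!setequal(base$subject_id, subj) || !setequal(stim$subject_id, subj))
    stop("unpaired subject(s): ",
         paste(utils::head(setdiff(subj, intersect(base$subject_id,
                                                   stim$subject_id)), 5L),
               collapse = ", "), call. = FALSE)
  base <- base[match(subj, base$subject_id), ]
  stim <- stim[match(subj, stim$subject_id), ]
  shared <- c("affection", "sex", "age", paste0("pc", 1:5))
  for (col in shared)
    if (!isTRUE(all.equal(base[[col]], stim[[col]], check.attributes = FALSE)))
      stop("paired samples disagree on subject-level covariate '", col, "'",
           call. = FALSE)
  out <- data.frame(subject_id = subj,
                    baseline = base$sample_id,
                    stimulated = stim$sample_id,
                    affection = base$affection,
                    sex = base$sex,
                    age = base$age,
                    stringsAsFactors = FALSE)
  out[paste0("pc", 1:5)] <- base[paste0("pc", 1:5)]
  class(out) <- c("paired_design", "data.frame")
  out
}

#' Gene set collections
#'
#' A gene set collection holds named gene sets together with the background
#' gene universe against which enrichment is evaluated. Every named set is
#' intersected with the background before counting, so set sizes reported by
#' [enrich()] always refer to background members ("expressed" genes).
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param background Character vector: the background gene universe.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named", call. = FALSE)
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, background of %d genes\n",
              length(x$sets), length(x$background)))
  for (nm in utils::head(names(x$sets), 10L))
    cat(sprintf("  %s: %d genes (%d in background)\n", nm,
                length(x$sets[[nm]]),
                length(intersect(x$sets[[nm]], x$background))))
  invisible(x)
}

#' Read and write gene sets in GMT format
#'
#' GMT is one line per gene set: set name, description, then member gene IDs,
#' tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return [read_gmt()] returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("line ", short[1L], ": GMT lines need name, description and >= 1 gene",
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names in GMT", call. = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
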