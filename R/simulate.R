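#' Configuration for the paired case-control expression simulator
#'
#' Defaults mirror the study design the analysis targets: 514 cases and 690
#' controls, each contributing one baseline and one stimulated sample, five
#' sequencing batches, near-universal small perturbation effects
#' (`frac_da_responsive = 0.9`, effect SD 0.3 log2 units) and a small planted
#' subset of genes (5%) whose perturbation response differs between cases
#' and controls by 0.5 log2 units. Counts are negative binomial with a
#' single shared dispersion; a subject-level random intercept (SD 0.2 log2
#' units) induces the within-subject baseline/stimulated correlation the
#' paired design exploits.
#'
#' @param n_cases,n_controls Numbers of case and control subjects.
#' @param n_genes Number of simulated genes (sex-marker genes, when enabled,
#'   are appended on top of this).
#' @param frac_da_responsive Fraction of genes with a nonzero perturbation
#'   effect.
#' @param frac_diff_response Fraction of genes with a case-specific
#'   perturbation-response shift.
#' @param da_effect_sd SD of the per-gene perturbation effect (log2 units).
#' @param diff_response_effect Magnitude of the planted case-specific
#'   response shift (log2 units; sign randomized per gene).
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param covariate_effect_sd SD of per-gene coefficients on the
#'   standardized nuisance covariates and batch offsets (log2 units).
#' @param subject_sd SD of the per-gene subject-level random intercept
#'   (log2 units).
#' @param batch_count Number of sequencing batches.
#' @param outlier_count Number of stimulated samples planted as outliers
#'   (their count vector is permuted across genes).
#' @param base_log2_mean,base_log2_sd Distribution of per-gene baseline
#'   log2 mean counts.
#' @param depth_sdlog Log-normal SD of per-sample depth factors.
#' @param sex_markers Append an XIST + Y-marker block wired to the simulated
#'   sex, so the sex-concordance QC screen is exercisable.
#' @param seed Integer seed governing all draws.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 514, n_controls = 690, n_genes = 21043,
                       frac_da_responsive = 0.9, frac_diff_response = 0.05,
                       da_effect_sd = 0.3, diff_response_effect = 0.5,
                       dispersion = 0.1, covariate_effect_sd = 0.1,
                       subject_sd = 0.2, batch_count = 5, outlier_count = 0,
                       base_log2_mean = 4, base_log2_sd = 2,
                       depth_sdlog = 0.15, sex_markers = TRUE, seed = 1) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
              frac_da_responsive = frac_da_responsive,
              frac_diff_response = frac_diff_response,
              da_effect_sd = da_effect_sd,
              diff_response_effect = diff_response_effect,
              dispersion = dispersion,
              covariate_effect_sd = covariate_effect_sd,
              subject_sd = subject_sd, batch_count = batch_count,
              outlier_count = outlier_count,
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              depth_sdlog = depth_sdlog, sex_markers = sex_markers,
              seed = seed)
  if (cfg$n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (cfg$n_cases < 0 || cfg$n_controls < 0)
    stop("subject counts must be >= 0", call. = FALSE)
  for (f in c("frac_da_responsive", "frac_diff_response"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$batch_count < 1) stop("batch_count must be >= 1", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a paired baseline/stimulated case-control expression dataset
#'
#' Generates gene-level counts for every subject under both conditions from
#' a negative binomial model. On the log2 scale, the expected expression of
#' gene g in subject i under condition c is
#' `base_g + x_i(c)' beta_g + batch_g(i) + u_gi +
#'  1[c = stim] * (da_g + 1[case_i] * delta_g)`,
#' where `x_i(c)` collects standardized nuisance covariates (sex, age, EBV
#' load, ATP level, cell count at condition c, ancestry PCs 1-5), `u_gi` is
#' the subject-level random intercept shared between conditions, `da_g` the
#' perturbation effect and `delta_g` the planted case-specific response
#' shift. Counts are `NB(mean = depth_s * 2^eta, dispersion)`; gene exonic
#' lengths are log-uniform in [500, 20000] bp. All draws follow
#' deterministically from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `da_sim` with elements `counts_baseline`,
#'   `counts_stimulated` (counts-stage [expr_matrix()]s), `samples` (sample
#'   sheet), `pairs` ([paired_design()]), `annotation`, `truth` (per-gene
#'   data.frame with `baseline_mean` = realized mean of the NB mean over
#'   baseline samples, effect sizes and labels), `outlier_samples` and
#'   `config`.
#' @export
simulate_da_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_cases + cfg$n_controls
  if (S < 2L) stop("need at least 2 subjects", call. = FALSE)

  ## subjects and covariates
  subject_id <- sprintf("SUBJ%04d", seq_len(S))
  affection <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  sex <- ifelse(stats::runif(S) < 0.5, "male", "female")
  age <- stats::runif(S, 18, 80)
  batch <- sprintf("b%d", sample.int(cfg$batch_count, S, replace = TRUE))
  pcs <- matrix(stats::rnorm(S * 5), S, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  ## harvest covariates per condition, moderately correlated across
  ## conditions (log-scale r = 0.6) as observed for such assays
  corr_pair <- function(r, sdlog) {
    z1 <- stats::rnorm(S)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(S)
    cbind(exp(sdlog * z1), exp(sdlog * z2))
  }
  ebv <- corr_pair(0.6, 0.5)
  atp <- corr_pair(0.6, 0.3)
  cells <- corr_pair(0.6, 0.3)

  ## genes
  G0 <- cfg$n_genes
  n_mark <- if (cfg$sex_markers) 8L else 0L
  G <- G0 + n_mark
  gene_id <- sprintf("GENE%05d", seq_len(G))
  symbol <- gene_id
  marker_symbols <- c("XIST", "RPS4Y1", "ZFY", "USP9Y", "DDX3Y", "UTY",
                      "KDM5D", "EIF1AY")
  if (n_mark > 0L) symbol[G0 + seq_len(n_mark)] <- marker_symbols
  exonic_length <- round(exp(stats::runif(G, log(500), log(20000))))
  base <- stats::rnorm(G, cfg$base_log2_mean, cfg$base_log2_sd)

  da_responsive <- stats::runif(G) < cfg$frac_da_responsive
  da_effect <- ifelse(da_responsive,
                      stats::rnorm(G, 0, cfg$da_effect_sd), 0)
  diff_response <- stats::runif(G) < cfg$frac_diff_response
  diff_effect <- ifelse(diff_response,
                        cfg$diff_response_effect *
                          sample(c(-1, 1), G, replace = TRUE), 0)
  if (n_mark > 0L) {
    idx <- G0 + seq_len(n_mark)
    da_responsive[idx] <- FALSE
    da_effect[idx] <- 0
    diff_response[idx] <- FALSE
    diff_effect[idx] <- 0
    exonic_length[idx] <- 2000L
  }

  ## log2 expected expression
  zscale <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                        else x - mean(x)
  X_base <- cbind(sexF = as.numeric(sex == "female") - 0.5,
                  age = zscale(age),
                  ebv = zscale(log(ebv[, 1])), atp = zscale(log(atp[, 1])),
                  cells = zscale(log(cells[, 1])), pcs)
  X_stim <- X_base
  X_stim[, "ebv"] <- zscale(log(ebv[, 2]))
  X_stim[, "atp"] <- zscale(log(atp[, 2]))
  X_stim[, "cells"] <- zscale(log(cells[, 2]))
  B <- matrix(stats::rnorm(G * ncol(X_base), 0, cfg$covariate_effect_sd),
              G, ncol(X_base))
  batch_off <- matrix(stats::rnorm(G * cfg$batch_count, 0,
                                   cfg$covariate_effect_sd),
                      G, cfg$batch_count)
  batch_idx <- as.integer(sub("^b", "", batch))
  U <- matrix(stats::rnorm(G * S, 0, cfg$subject_sd), G, S)

  eta_base <- base + B %*% t(X_base) + batch_off[, batch_idx] + U
  eta_stim <- base + B %*% t(X_stim) + batch_off[, batch_idx] + U +
    da_effect + outer(diff_effect, as.numeric(affection == "case"))
  if (n_mark > 0L) {
    fem <- as.numeric(sex == "female")
    idx_x <- G0 + 1L
    idx_y <- G0 + 2L:n_mark
    eta_base[idx_x, ] <- -2 + 8 * fem
    eta_stim[idx_x, ] <- eta_base[idx_x, ]
    eta_base[idx_y, ] <- rep(-3 + 8 * (1 - fem), each = n_mark - 1L)
    eta_stim[idx_y, ] <- eta_base[idx_y, ]
  }

  depth_base <- exp(stats::rnorm(S, 0, cfg$depth_sdlog))
  depth_stim <- exp(stats::rnorm(S, 0, cfg$depth_sdlog))
  mu_base <- sweep(2^eta_base, 2L, depth_base, "*")
  mu_stim <- sweep(2^eta_stim, 2L, depth_stim, "*")

  draw <- function(mu) {
    cnt <- if (cfg$dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    else stats::rpois(length(mu), mu)
    matrix(cnt, nrow(mu), ncol(mu))
  }
  counts_base <- draw(mu_base)
  counts_stim <- draw(mu_stim)

  sample_base <- paste0(subject_id, "_B")
  sample_stim <- paste0(subject_id, "_D")
  dimnames(counts_base) <- list(gene_id, sample_base)
  dimnames(counts_stim) <- list(gene_id, sample_stim)

  ## planted outliers: permute the count vector of chosen stimulated samples
  outlier_samples <- character(0)
  if (cfg$outlier_count > 0L) {
    pick <- sample.int(S, min(cfg$outlier_count, S))
    outlier_samples <- sample_stim[pick]
    for (j in pick) counts_stim[, j] <- counts_stim[sample.int(G, G), j]
  }

  sheet <- function(ids, condition, harvest_col) {
    data.frame(sample_id = ids, subject_id = subject_id,
               condition = condition, affection = affection, sex = sex,
               age = age, batch = batch,
               ebv_load = ebv[, harvest_col], atp_level = atp[, harvest_col],
               cell_count = cells[, harvest_col],
               pcs, stringsAsFactors = FALSE)
  }
  samples <- rbind(sheet(sample_base, "baseline", 1L),
                   sheet(sample_stim, "stimulated", 2L))
  rownames(samples) <- NULL

  annotation <- data.frame(gene_id = gene_id, symbol = symbol,
                           exonic_length = exonic_length,
                           chromosome = ifelse(symbol == "XIST", "chrX",
                                        ifelse(symbol %in% marker_symbols,
                                               "chrY", "chr1")),
                           stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id,
                      baseline_mean = rowMeans(mu_base),
                      da_effect = da_effect,
                      diff_response_effect = diff_effect,
                      da_responsive = da_responsive,
                      diff_response = diff_response,
                      sex_marker = seq_len(G) > G0,
                      stringsAsFactors = FALSE)

  structure(list(counts_baseline = expr_matrix(counts_base, "counts"),
                 counts_stimulated = expr_matrix(counts_stim, "counts"),
                 samples = samples,
                 pairs = paired_design(samples),
                 annotation = annotation,
                 truth = truth,
                 outlier_samples = outlier_samples,
                 config = cfg),
            class = "da_sim")
}

#' @export
print.da_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("simulated paired dataset: %d genes x %d subjects ",
                     "(%d cases, %d controls), 2 conditions\n"),
              nrow(x$counts_baseline), nrow(x$pairs),
              cfg$n_cases, cfg$n_controls))
  cat(sprintf("  planted: %d perturbation-responsive, %d differential-response, %d outlier sample(s)\n",
              sum(x$truth$da_responsive), sum(x$truth$diff_response),
              length(x$outlier_samples)))
  invisible(x)
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Writes the two count matrices, the sample sheet, the gene annotation and
#' the ground-truth table as TSV, plus a JSON manifest holding the full
#' configuration (including the seed) and the file list.
#'
#' @param dataset A `da_sim` from [simulate_da_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "da_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(counts_baseline = "counts_baseline.tsv",
             counts_stimulated = "counts_stimulated.tsv",
             samples = "samples.tsv", annotation = "annotation.tsv",
             truth = "truth.tsv")
  write_expression_tsv(dataset$counts_baseline,
                       file.path(out_dir, files["counts_baseline"]))
  write_expression_tsv(dataset$counts_stimulated,
                       file.path(out_dir, files["counts_stimulated"]))
  for (nm in c("samples", "annotation", "truth"))
    utils::write.table(dataset[[nm]], file.path(out_dir, files[nm]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(dataset$config),
                   outlier_samples = dataset$outlier_samples,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
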