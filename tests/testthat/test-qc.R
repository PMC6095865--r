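marker_panel <- c("RPS4Y1", "ZFY", "USP9Y", "DDX3Y", "UTY", "KDM5D",
                  "EIF1AY")

test_that("sex concordance compares XIST / Y-marker expression to reported sex", {
  expect_equal(eval(formals(sex_concordance)$y_markers), marker_panel)

  genes <- c("XIST", marker_panel)
  sheet <- make_sheet(2)
  base <- sheet[sheet$condition == "baseline", ]
  base$sex <- c("female", "female")
  # s1: clear female signal; s2: clear male signal but reported female
  v <- cbind(c(50, rep(0.01, 7)), c(0.02, rep(30, 7)))
  m <- make_em(v, "rpkm", genes = genes, samples = base$sample_id)
  flags <- sex_concordance(m, base)
  expect_equal(unname(flags), c("concordant", "discordant"))

  # both margins high -> indeterminate
  amb <- make_em(cbind(c(50, rep(30, 7)), c(50, rep(30, 7))), "rpkm",
                 genes = genes, samples = base$sample_id)
  expect_true(all(sex_concordance(amb, base) == "indeterminate"))

  # all markers absent -> warning and all indeterminate
  blank <- make_em(matrix(1, 2, 2), "rpkm", genes = c("gA", "gB"),
                   samples = base$sample_id)
  expect_warning(flags2 <- sex_concordance(blank, base), "missing sex marker")
  expect_true(all(flags2 == "indeterminate"))
})

test_that("genotype concordance counts matches over jointly called SNPs", {
  snps <- sprintf("rs%d", 1:10)
  a <- matrix(rep(c(0, 1, 2, 1, 0), 2), 10, 3,
              dimnames = list(snps, c("s1", "s2", "s3")))
  b <- a
  b[1:3, 2] <- c(2, 0, 0)          # 7 of 10 match for s2
  b[, 3] <- NA                     # no joint calls for s3
  res <- genotype_concordance(a, b, threshold = 0.8)
  expect_equal(res$concordance[res$sample_id == "s1"], 1.0)
  expect_equal(res$concordance[res$sample_id == "s2"], 0.7)
  expect_true(res$flagged[res$sample_id == "s2"])
  expect_true(is.na(res$concordance[res$sample_id == "s3"]))
  expect_false(res$flagged[res$sample_id == "s3"])
  # restriction to a SNP panel changes the denominator
  res5 <- genotype_concordance(a, b, snp_panel = snps[4:10])
  expect_equal(res5$concordance[res5$sample_id == "s2"], 1.0)
})

test_that("completion rates are per-group positive fractions", {
  sheet <- make_sheet(4, n_cases = 2)
  base <- sheet[sheet$condition == "baseline", ]
  # cases: sub01, sub02; controls: sub03, sub04
  v <- rbind(c(1, 1, 1, 1),
             c(1, 0, 0, 0),
             c(0, 0, 2, 2))
  m <- make_em(v, "rpkm", samples = base$sample_id)
  cr <- completion_rates(m, base)
  expect_equal(cr$rates$case, c(1, 0.5, 0))
  expect_equal(cr$rates$control, c(1, 0, 1))

  # identical case and control submatrices -> correlation exactly 1
  v2 <- rbind(c(1, 0, 1, 0), c(1, 1, 1, 1), c(0, 0, 0, 0), c(1, 0, 1, 0))
  cr2 <- completion_rates(make_em(v2, "rpkm", samples = base$sample_id),
                          base)
  expect_equal(cr2$rates$case, cr2$rates$control)
  expect_equal(cr2$correlation, 1.0)
})

test_that("outlier detection flags a planted permuted sample and only it", {
  set.seed(21)
  n <- 51
  shared <- rexp(400, 0.05)
  v <- matrix(shared + rnorm(400 * n, sd = 2), 400, n)
  v[v < 0] <- 0
  v[, n] <- sample(v[, n])         # destroy the shared structure
  m <- make_em(v, "rpkm")
  bad <- colnames(m)[n]
  expect_identical(detect_outliers(m, "correlation"), bad)
  expect_identical(detect_outliers(m, "pca"), bad)

  # infinite threshold flags nothing
  expect_length(detect_outliers(m, "correlation", z_cut = Inf), 0)
  # identical samples: no structure to flag
  flat <- make_em(matrix(rep(rexp(50), 12), 50, 12), "rpkm")
  expect_length(detect_outliers(flat, "correlation"), 0)
  expect_length(detect_outliers(flat, "pca"), 0)
  expect_error(detect_outliers(make_em(matrix(1, 5, 5), "rpkm")),
               "at least 10 samples")
})

test_that("outlier flags are invariant to sample ordering", {
  set.seed(22)
  v <- matrix(rexp(300 * 30, 0.1) + rnorm(300 * 30, sd = 0.5), 300, 30)
  v[v < 0] <- 0
  v[, 7] <- sample(v[, 7])
  m <- make_em(v, "rpkm")
  perm <- sample(30)
  mp <- m[, perm]
  for (meth in c("correlation", "pca"))
    expect_setequal(detect_outliers(m, meth, z_cut = 3),
                    detect_outliers(mp, meth, z_cut = 3))
})

test_that("null simulations rarely trip the outlier screens", {
  # no planted outliers, n >= 100 samples: expected flags < 1 per screen
  n_flags <- c(correlation = 0, pca = 0)
  for (s in 1:20) {
    d <- simulate_da_dataset(sim_config(n_cases = 50, n_controls = 50,
                                        n_genes = 300, seed = 400 + s,
                                        frac_diff_response = 0,
                                        sex_markers = FALSE))
    m <- log2p1(rpkm_from_counts(d$counts_baseline, d$annotation))
    n_flags["correlation"] <- n_flags["correlation"] +
      length(detect_outliers(m, "correlation"))
    n_flags["pca"] <- n_flags["pca"] + length(detect_outliers(m, "pca"))
  }
  expect_lt(n_flags[["correlation"]] / 20, 1)
  expect_lt(n_flags[["pca"]] / 20, 1)
})

test_that("qc_report bundles screens and honours the outlier policy", {
  set.seed(30)
  d <- simulate_da_dataset(sim_config(n_cases = 15, n_controls = 15,
                                      n_genes = 300, seed = 31,
                                      outlier_count = 1))
  m <- rpkm_from_counts(d$counts_stimulated, d$annotation)
  rep_u <- qc_report(m, d$samples[d$samples$condition == "stimulated", ])
  expect_s3_class(rep_u, "qc_report")
  expect_true(d$outlier_samples %in% rep_u$excluded)
  expect_true(all(rep_u$excluded %in% d$samples$sample_id))
  expect_true(all(rep_u$completion$case >= 0 & rep_u$completion$case <= 1))
  out <- withr::local_tempdir()
  paths <- write_qc_report(rep_u, out)
  expect_true(all(file.exists(paths)))
  expect_silent(jsonlite::read_json(paths[1]))
})
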