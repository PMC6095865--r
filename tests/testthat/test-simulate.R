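test_that("simulation is reproducible and internally consistent", {
  cfg <- sim_config(n_cases = 10, n_controls = 12, n_genes = 80, seed = 71)
  d1 <- simulate_da_dataset(cfg)
  d2 <- simulate_da_dataset(cfg)
  expect_identical(d1, d2)

  # truth labels consistent with nonzero effects
  tr <- d1$truth
  expect_true(all((tr$da_effect != 0) == tr$da_responsive |
                    tr$da_effect == 0))
  expect_true(all((tr$diff_response_effect != 0) == tr$diff_response))
  expect_equal(sum(tr$sex_marker), 8L)

  # sample sheet and pairing cover every subject in both conditions
  expect_equal(nrow(d1$pairs), 22L)
  expect_equal(ncol(d1$counts_baseline), 22L)
  expect_setequal(d1$samples$condition, c("baseline", "stimulated"))
  expect_equal(expr_stage(d1$counts_baseline), "counts")

  # different seed changes the data
  d3 <- simulate_da_dataset(sim_config(n_cases = 10, n_controls = 12,
                                       n_genes = 80, seed = 72))
  expect_false(identical(unclass(d1$counts_baseline),
                         unclass(d3$counts_baseline)))

  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_diff_response = 1.5), "frac_diff_response")
  expect_error(sim_config(dispersion = -1), "dispersion")
})

test_that("empirical count means track the negative binomial means", {
  d <- simulate_da_dataset(sim_config(n_cases = 500, n_controls = 500,
                                      n_genes = 60, seed = 73,
                                      sex_markers = FALSE))
  emp <- rowMeans(unclass(d$counts_baseline)[, ])
  expected <- d$truth$baseline_mean
  rel_err <- abs(emp - expected) / expected
  keep <- expected >= 1
  expect_gt(sum(keep), 40)
  expect_lt(stats::median(rel_err[keep]), 0.02)
  expect_lt(stats::quantile(rel_err[keep], 0.95), 0.05)
})

test_that("with all effects off the two conditions are exchangeable", {
  ps <- c()
  for (s in 1:3) {
    d <- simulate_da_dataset(sim_config(n_cases = 25, n_controls = 25,
                                        n_genes = 300, seed = 730 + s,
                                        frac_da_responsive = 0,
                                        frac_diff_response = 0,
                                        sex_markers = FALSE))
    pd <- d$pairs
    rb <- rpkm_from_counts(d$counts_baseline, d$annotation)
    rs <- rpkm_from_counts(d$counts_stimulated, d$annotation)
    des <- covariate_design(d$samples, pd, "pooled",
                            include_affection = TRUE)
    pooled <- expr_matrix(cbind(unclass(rb)[, ], unclass(rs)[, ]), "rpkm")
    r <- residualize(pooled, des)
    de <- paired_da_test(r[, seq_len(ncol(rb))],
                         r[, ncol(rb) + seq_len(ncol(rs))], pd)
    ps <- c(ps, de$p[!is.na(de$p)])
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted perturbation effects are recovered in fold changes", {
  d <- simulate_da_dataset(sim_config(n_cases = 100, n_controls = 100,
                                      n_genes = 800, seed = 74,
                                      frac_diff_response = 0,
                                      da_effect_sd = 0.3,
                                      sex_markers = FALSE))
  rb <- rpkm_from_counts(d$counts_baseline, d$annotation)
  rs <- rpkm_from_counts(d$counts_stimulated, d$annotation)
  qn <- quantile_normalize(expr_matrix(cbind(unclass(rb)[, ],
                                             unclass(rs)[, ]), "rpkm"))
  nb <- ncol(rb)
  fc <- fold_change(qn[, seq_len(nb)], qn[, nb + seq_len(nb)])
  ok <- is.finite(fc$log2fc)
  expect_gt(cor(fc$log2fc[ok], d$truth$da_effect[ok]), 0.9)
})

test_that("planted outlier samples are permuted stimulated columns", {
  d <- simulate_da_dataset(sim_config(n_cases = 20, n_controls = 20,
                                      n_genes = 200, seed = 75,
                                      outlier_count = 2))
  expect_length(d$outlier_samples, 2L)
  expect_true(all(d$outlier_samples %in% colnames(d$counts_stimulated)))
})

test_that("fixtures round-trip through disk including the manifest seed", {
  d <- simulate_da_dataset(sim_config(n_cases = 4, n_controls = 4,
                                      n_genes = 30, seed = 76))
  dir <- withr::local_tempdir()
  manifest <- write_fixture(d, dir)
  expect_equal(manifest$config$seed, 76)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$config$seed, 76)

  cb <- read_expression_tsv(file.path(dir, "counts_baseline.tsv"), "counts")
  expect_equal(unclass(cb)[, ], unclass(d$counts_baseline)[, ])
  ss <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(ss$sample_id, d$samples$sample_id)
  expect_equal(ss$ebv_load, d$samples$ebv_load, tolerance = 1e-9)
  an <- read_gene_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(an$exonic_length, d$annotation$exonic_length)
})
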