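test_that("residualize reproduces closed-form OLS residuals", {
  # single binary covariate: residuals are within-group deviations
  m <- make_em(matrix(c(1, 2, 3, 4), 1, 4), "log2rpkm")
  X <- cbind(1, c(0, 0, 1, 1))
  rownames(X) <- colnames(m)
  r <- residualize(m, X)
  expect_equal(unname(unclass(r)[1, ]), c(-0.5, 0.5, -0.5, 0.5))
  expect_equal(expr_stage(r), "residual")

  # intercept-only design: centering
  X0 <- matrix(1, 4, 1, dimnames = list(colnames(m), NULL))
  r0 <- residualize(m, X0)
  expect_equal(unname(unclass(r0)[1, ]), c(1, 2, 3, 4) - 2.5)

  # covariate orthogonal to centered y leaves the centered y unchanged
  y <- c(1, 2, 3, 4)
  x_orth <- c(1, -1, -1, 1)  # orthogonal to y - mean(y)
  Xo <- cbind(1, x_orth)
  rownames(Xo) <- colnames(m)
  ro <- residualize(m, Xo)
  expect_equal(unname(unclass(ro)[1, ]), y - mean(y))
})

test_that("residuals are orthogonal to every design column", {
  set.seed(51)
  sheet <- make_sheet(20)
  pd <- paired_design(sheet)
  des <- covariate_design(sheet, pd, "baseline", include_affection = TRUE)
  m <- make_em(matrix(rnorm(50 * 20), 50, 20), "log2rpkm",
               samples = pd$baseline)
  r <- unclass(residualize(m, des))[, ]
  X <- des$X
  for (g in 1:10) for (j in seq_len(ncol(X))) {
    bound <- 1e-8 * sqrt(sum(r[g, ]^2)) * sqrt(sum(X[, j]^2)) + 1e-12
    expect_lt(abs(sum(r[g, ] * X[, j])), bound)
  }
  expect_error(residualize(m, cbind(X, X[, 2])), "rank-deficient")
})

test_that("pooled covariate design keeps the condition contrast testable", {
  set.seed(50)
  sheet <- make_sheet(20)
  pd <- paired_design(sheet)
  des <- covariate_design(sheet, pd, "pooled", include_affection = TRUE)
  expect_equal(des$sample_id, c(pd$baseline, pd$stimulated))
  # plant a pure condition shift; pooled residualization must not absorb it
  v <- matrix(rnorm(40 * 5), 5, 40)
  v[, 21:40] <- v[, 21:40] + 3
  m <- make_em(v, "residual", samples = des$sample_id)
  r <- residualize(m, des)
  de <- paired_da_test(r[, 1:20], r[, 21:40], pd)
  expect_true(all(de$p < 1e-4))
  expect_true(all(de$t_stat > 0))
})

test_that("paired test equals the closed-form one-sample t on differences", {
  sheet <- make_sheet(3)
  pd <- paired_design(sheet)
  base <- make_em(matrix(0, 2, 3), "residual", samples = pd$baseline)
  stim <- make_em(rbind(c(1, 2, 3), c(-1, 0, 1)), "residual",
                  samples = pd$stimulated)
  de <- paired_da_test(base, stim, pd)
  expect_equal(de$t_stat[1], 2 / (1 / sqrt(3)), tolerance = 1e-6) # 3.4641
  expect_equal(de$df[1], 2L)
  expect_equal(de$t_stat[2], 0)
  expect_equal(de$p[2], 1)

  # identical matrices -> all-zero differences, flagged not tested
  de0 <- paired_da_test(stim_as_base <- make_em(rbind(c(1, 2, 3)),
                                                "residual",
                                                samples = pd$baseline),
                        make_em(rbind(c(1, 2, 3)), "residual",
                                samples = pd$stimulated), pd)
  expect_true(de0$degenerate[1])
  expect_true(is.na(de0$p[1]))

  # random property: match t.test on the difference vector
  set.seed(52)
  sheet2 <- make_sheet(12)
  pd2 <- paired_design(sheet2)
  b2 <- make_em(matrix(rnorm(8 * 12), 8, 12), "residual",
                samples = pd2$baseline)
  s2 <- make_em(matrix(rnorm(8 * 12), 8, 12), "residual",
                samples = pd2$stimulated)
  de2 <- paired_da_test(b2, s2, pd2)
  for (g in 1:8) {
    d <- unclass(s2)[g, ] - unclass(b2)[g, ]
    tt <- t.test(d)
    expect_equal(de2$t_stat[g], unname(tt$statistic))
    expect_equal(de2$p[g], tt$p.value)
  }
})

test_that("fold change is the ratio of per-gene means", {
  base <- make_em(rbind(c(2, 2), c(1, 3), c(0, 0)), "rpkm")
  stim <- make_em(rbind(c(4, 4), c(3, 5), c(1, 1)), "rpkm")
  fc <- fold_change(base, stim)
  expect_equal(fc$fc[1], 2)
  expect_equal(fc$log2fc[1], 1)
  expect_equal(fc$fc[2], 2)
  expect_true(fc$undefined[3])
  expect_true(is.na(fc$fc[3]))
  same <- fold_change(base, base)
  expect_equal(same$fc[1:2], c(1, 1))
})

test_that("SD selection on log2 FC uses mean +/- k*sd cutoffs", {
  x <- c(a = -2, b = 0, c = 2)
  sel <- select_by_fc_sd(x, k_sd = 1)
  expect_length(sel$selected, 0)          # none strictly outside [-2, 2]
  expect_equal(sel$lower, -2)
  expect_equal(sel$upper, 2)
  expect_equal(sel$fc_lower, 0.25)
  sel0 <- select_by_fc_sd(x, k_sd = 0)
  expect_setequal(sel0$selected, c("a", "c"))
  expect_error(select_by_fc_sd(c(a = 1)), "at least 2")
})

test_that("rank normalization follows the Blom convention", {
  x <- c(10, 3, 7)
  z <- rank_normalize(x)
  expect_equal(z[3], 0)                          # middle value -> median
  expect_equal(z[2], qnorm((1 - 3 / 8) / 3.25))  # qnorm(0.19231)
  expect_equal(z[1], qnorm((3 - 3 / 8) / 3.25))  # qnorm(0.80769)

  # invariance under strictly increasing transforms
  set.seed(53)
  y <- rnorm(40)
  expect_equal(rank_normalize(exp(y)), rank_normalize(y))
  expect_equal(rank_normalize(y^3), rank_normalize(y))

  # matrix form works per gene and tags the stage
  m <- make_em(matrix(rnorm(30), 3, 10), "residual")
  rn <- rank_normalize(m)
  expect_equal(expr_stage(rn), "rank_normal")
  expect_equal(unclass(rn)[2, ], rank_normalize(unclass(m)[2, ]))
  expect_error(rank_normalize(c(1)), "at least 2")
})

test_that("case-control regression matches closed-form and lm", {
  sheet <- make_sheet(4, n_cases = 2)
  base <- sheet[sheet$condition == "baseline", ]
  # cases are sub01, sub02 -> status 1; y = status exactly
  m <- make_em(matrix(c(1, 1, 0, 0), 1, 4), "rank_normal",
               samples = base$sample_id)
  a <- case_control_assoc(m, base, "baseline")
  expect_equal(a$beta0, 0)
  expect_equal(a$beta1, 1)
  expect_equal(a$analysis, "baseline")

  # label swap negates beta1, keeps p
  swapped <- base
  swapped$affection <- ifelse(base$affection == "case", "control", "case")
  a2 <- case_control_assoc(m, swapped, "baseline")
  expect_equal(a2$beta1, -a$beta1)
  expect_equal(a2$p, a$p)

  # random data: agree with lm()
  set.seed(54)
  sheet2 <- make_sheet(16, n_cases = 7)
  b2 <- sheet2[sheet2$condition == "baseline", ]
  m2 <- make_em(matrix(rnorm(5 * 16), 5, 16), "rank_normal",
                samples = b2$sample_id)
  res <- case_control_assoc(m2, b2, "baseline")
  status <- as.numeric(b2$affection == "case")
  for (g in 1:5) {
    fit <- summary(lm(unclass(m2)[g, ] ~ status))
    expect_equal(res$beta1[g], unname(coef(fit)[2, 1]))
    expect_equal(res$se1[g], unname(coef(fit)[2, 2]))
    expect_equal(res$p[g], unname(coef(fit)[2, 4]))
  }
  one_group <- b2; one_group$affection <- "case"
  expect_error(case_control_assoc(m2, one_group, "baseline"),
               "both affection groups")
})

test_that("response matrix is the per-subject adjusted difference", {
  sheet <- make_sheet(5)
  pd <- paired_design(sheet)
  b <- make_em(matrix(rnorm(20), 4, 5), "rank_normal",
               samples = pd$baseline)
  s_same <- make_em(unclass(b)[, ], "rank_normal", samples = pd$stimulated)
  r0 <- da_response(b, s_same, pd)
  expect_true(all(unclass(r0) == 0))
  expect_equal(colnames(r0), pd$subject_id)
  expect_equal(expr_stage(r0), "response")

  s_plus <- make_em(unclass(b)[, ] + 1, "rank_normal",
                    samples = pd$stimulated)
  expect_equal(unname(unclass(da_response(b, s_plus, pd))[, ]),
               matrix(1, 4, 5), tolerance = 1e-12)
})

test_that("expression-PC adjustment removes planted latent structure", {
  m <- make_em(matrix(rnorm(200), 20, 10), "residual")
  expect_identical(expression_pc_adjust(m, k = 0), m)

  # rank-1 matrix vanishes after removing one component
  u <- rnorm(20); v <- rnorm(10)
  r1 <- make_em(outer(u, v), "residual")
  out1 <- expression_pc_adjust(r1, k = 1)
  expect_lt(max(abs(unclass(out1))), 1e-8)

  # planted sample-wide factor: loadings shrink below 5% of original
  set.seed(55)
  load <- rnorm(100, sd = 1)
  scores <- rnorm(40)
  noisy <- outer(load, scores) + matrix(rnorm(4000, sd = 0.05), 100, 40)
  mf <- make_em(noisy, "residual")
  adj <- expression_pc_adjust(mf, k = 1)
  recovered <- drop(unclass(adj) %*% scores) / sum(scores^2)
  expect_lt(max(abs(recovered)), 0.05 * max(abs(load)))
  expect_error(expression_pc_adjust(mf, k = 40), "smaller than")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(56)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
})

test_that("case-control p-values are uniform under the null", {
  # no planted effects: pooled fraction below 0.05 stays near nominal
  ps <- c()
  for (s in 1:10) {
    set.seed(600 + s)
    sheet <- make_sheet(40, n_cases = 20, seed = 600 + s)
    b <- sheet[sheet$condition == "baseline", ]
    m <- make_em(matrix(rnorm(500 * 40), 500, 40), "rank_normal",
                 samples = b$sample_id)
    ps <- c(ps, case_control_assoc(m, b, "baseline")$p)
  }
  expect_gt(mean(ps < 0.05), 0.04)
  expect_lt(mean(ps < 0.05), 0.06)
})
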