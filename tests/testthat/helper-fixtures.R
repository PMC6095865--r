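# small builders used across test files

make_em <- function(values, stage = "rpkm", genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expr_matrix(m, stage = stage)
}

# minimal valid sample sheet: one row per sample id, paired per subject
make_sheet <- function(n_subjects, n_cases = floor(n_subjects / 2),
                       seed = 1) {
  set.seed(seed)
  subject <- sprintf("sub%02d", seq_len(n_subjects))
  aff <- rep(c("case", "control"),
             c(n_cases, n_subjects - n_cases))
  pcs <- matrix(rnorm(n_subjects * 5), n_subjects, 5)
  one <- function(cond, suffix) {
    df <- data.frame(sample_id = paste0(subject, suffix),
                     subject_id = subject,
                     condition = cond, affection = aff,
                     sex = rep(c("male", "female"),
                               length.out = n_subjects),
                     age = seq(20, 60, length.out = n_subjects),
                     batch = rep(c("b1", "b2", "b2", "b1"),
                                 length.out = n_subjects),
                     ebv_load = runif(n_subjects, 0.5, 2),
                     atp_level = runif(n_subjects, 0.5, 2),
                     cell_count = runif(n_subjects, 0.5, 2),
                     stringsAsFactors = FALSE)
    df[paste0("pc", 1:5)] <- pcs
    df
  }
  rbind(one("baseline", "_B"), one("stimulated", "_D"))
}

# draw one integer from lo:hi without the scalar-range pitfall
pick <- function(lo, hi) {
  xs <- lo:hi
  xs[sample.int(length(xs), 1)]
}

# brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1)
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# enumeration oracle for the minimum-likelihood two-sided Fisher p of the
# 2x2 [a, b; c, d]: hypergeometric probabilities from choose(), no dhyper
fisher_enum_2x2 <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; kk <- a + b
  support <- max(0, kk - nn):min(kk, m)
  probs <- choose(m, support) * choose(nn, kk - support) / choose(m + nn, kk)
  obs <- probs[support == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}
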