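test_that("moderation disabled reproduces the pooled two-sample t exactly", {
  set.seed(41)
  n <- 200
  x <- matrix(rnorm(n * 8, 20, 1), n, 8,
              dimnames = list(sprintf("P%03d", 1:n), paste0("S", 1:8)))
  m <- protein_matrix(x, scale = "log2")
  g1 <- paste0("S", 1:4); g2 <- paste0("S", 5:8)
  f <- moderated_fit(m, groups = list(g1, g2), df_prior = 0)
  t_ref <- vapply(seq_len(n), function(i)
    pooled_t_oracle(x[i, g1], x[i, g2]), numeric(1))
  expect_lt(max(abs(f$t_mod - t_ref)), 1e-10)
  expect_equal(f$df_prior[1], 0)
  # and p-values match the t reference with n1+n2-2 df
  expect_equal(f$p, 2 * pt(-abs(t_ref), df = 6), tolerance = 1e-12)
})

test_that("moderated fit matches limma's eBayes on both variance regimes", {
  suppressMessages(library(limma))
  design <- cbind(1, rep(c(0, 1), each = 4))
  for (het in c(FALSE, TRUE)) {
    set.seed(42 + het)
    n <- 300
    s <- if (het) sqrt(0.05 * 4 / rchisq(n, 4)) else rep(1, n)
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(sprintf("P%03d", 1:n), paste0("S", 1:8))) * s + 20
    f <- moderated_fit(protein_matrix(x, scale = "log2"),
                       groups = list(paste0("S", 1:4), paste0("S", 5:8)))
    fl <- eBayes(lmFit(x, design))
    expect_equal(f$df_prior[1], fl$df.prior, tolerance = 1e-8)
    expect_equal(f$s2_prior[1], fl$s2.prior, tolerance = 1e-8)
    expect_lt(max(abs(f$t_mod - fl$t[, 2])), 1e-10)
    expect_lt(max(abs(f$p - fl$p.value[, 2])), 1e-10)
  }
})

test_that("identical groups give log2fc 0, t 0, p 1", {
  x <- matrix(rep(c(18, 20, 22), each = 8), 3, 8, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), paste0("S", 1:8)))
  x[2, ] <- x[2, ] + rep(c(-0.5, 0.5), 4)  # within-group spread, same means
  m <- protein_matrix(x, scale = "log2")
  f <- moderated_fit(m, groups = list(paste0("S", 1:4), paste0("S", 5:8)))
  expect_equal(f$log2fc, rep(0, 3))
  expect_equal(f$t_mod, rep(0, 3))
  expect_equal(f$p, rep(1, 3))
})

test_that("infinite prior df with fixed prior variance is the closed form", {
  set.seed(43)
  n <- 50
  x <- matrix(rnorm(n * 8, 20, 1), n, 8,
              dimnames = list(sprintf("P%02d", 1:n), paste0("S", 1:8)))
  m <- protein_matrix(x, scale = "log2")
  g <- list(paste0("S", 1:4), paste0("S", 5:8))
  f <- moderated_fit(m, groups = g, df_prior = Inf, s2_prior = 0.8)
  expect_equal(f$t_mod, f$log2fc / sqrt(0.8 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(f$p, 2 * pnorm(-abs(f$t_mod)), tolerance = 1e-12)
})

test_that("DAP calling applies inclusive FC and exclusive p boundaries", {
  cfg <- analysis_config()
  fits <- data.frame(
    protein_id = paste0("P", 1:6),
    log2fc = log2(c(1.5, 1.29, 0.76, 1.3, 1.5, 0.5)),
    p = c(0.01, 0.001, 0.049, 0.049, 0.05, 0.05),
    p_adj = NA_real_)
  calls <- call_daps(fits, cfg)
  expect_equal(calls$label,
               c("increased",   # fc 1.5, p 0.01
                 "unchanged",   # fc 1.29 below threshold despite tiny p
                 "decreased",   # fc exactly 0.76 qualifies (inclusive)
                 "increased",   # fc exactly 1.30 qualifies (inclusive)
                 "unchanged",   # p exactly at cutoff does not (exclusive)
                 "unchanged"))
  expect_equal(calls$fc_raw[1], 1.5)
  expect_equal(calls$neg_log10_p, -log10(fits$p))
})

test_that("label-swap symmetry holds with a reciprocal FC config", {
  cfg <- analysis_config(fc_up = 1.3, fc_down = 1 / 1.3)
  set.seed(44)
  n <- 400
  x <- matrix(rnorm(n * 8, 20, 0.5), n, 8,
              dimnames = list(sprintf("P%03d", 1:n), paste0("S", 1:8)))
  x[1:80, 5:8] <- x[1:80, 5:8] + rep(c(1, -1), 40)
  m <- protein_matrix(x, scale = "log2")
  g1 <- paste0("S", 1:4); g2 <- paste0("S", 5:8)
  fwd <- call_daps(moderated_fit(m, groups = list(g1, g2)), cfg)
  rev <- call_daps(moderated_fit(m, groups = list(g2, g1)), cfg)
  expect_equal(fwd$label == "increased", rev$label == "decreased")
  expect_equal(fwd$label == "decreased", rev$label == "increased")
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(45)
  p <- sort(runif(50))
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))            # never decreases any p-value
  expect_true(all(diff(adj) >= 0))      # non-decreasing on sorted input
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pooled Student's t matches the worked example and t.test", {
  tt <- student_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(abs(tt$t), 1.224745, tolerance = 1e-6)
  # frozen from the textbook formula: 2 * pt(-sqrt(3/2), df = 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-6)
  expect_gt(tt$t, 0)  # mean(y) > mean(x) -> positive
  # swapping negates t, preserves p
  rev <- student_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p, tt$p)
  # cross-check against stats::t.test on random data
  set.seed(46)
  x <- rnorm(6); y <- rnorm(8, 0.5)
  ref <- t.test(y, x, var.equal = TRUE)
  mine <- student_ttest(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # degenerate contracts
  expect_equal(student_ttest(c(1, 1), c(1, 1)), list(t = 0, p = 1, df = 2))
  expect_error(student_ttest(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(student_ttest(1, c(1, 2)), "at least 2")
})
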