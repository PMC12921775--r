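test_that("detection filter applies the >=3-of-4 rule per scope", {
  x <- 2^matrix(20, 3, 8)
  dimnames(x) <- list(c("both_ok", "one_group", "neither"),
                      paste0(rep(c("A", "B"), each = 4), 1:4))
  x["one_group", 5:8] <- NA           # 4/4 in A, 0/4 in B
  x["one_group", 4] <- NA             # 3/4 in A
  x["neither", c(3, 4, 7, 8)] <- NA   # 2/4 in both
  m <- protein_matrix(x, scale = "raw")
  grp <- list(paste0("A", 1:4), paste0("B", 1:4))
  any_cfg <- analysis_config(detection_scope = "any_group")
  all_cfg <- analysis_config(detection_scope = "all_groups")
  kept_any <- rownames(filter_by_detection(m, NULL, any_cfg, grp)$intensity)
  kept_all <- rownames(filter_by_detection(m, NULL, all_cfg, grp)$intensity)
  expect_setequal(kept_any, c("both_ok", "one_group"))
  expect_setequal(kept_all, "both_ok")
  expect_error(
    filter_by_detection(m, NULL, any_cfg, list(paste0("A", 1:2), paste0("B", 1:4))),
    "fewer samples than min_detect")
})

test_that("log2 transform maps values exactly and preserves missingness", {
  x <- matrix(c(8, 1, NA, 4), 2, 2,
              dimnames = list(c("P1", "P2"), c("S1", "S2")))
  m <- log2_transform(protein_matrix(x, scale = "raw"))
  expect_equal(m$scale, "log2")
  expect_equal(m$intensity["P1", "S1"], 3)
  expect_equal(m$intensity["P2", "S1"], 0)
  expect_true(is.na(m$intensity["P1", "S2"]))
  expect_error(log2_transform(m), "raw-scale")  # one-way scale transition
})

test_that("vsn calibration removes an exact 2x scale difference", {
  set.seed(11)
  x1 <- 2^rnorm(80, 20, 2)
  x <- cbind(S1 = x1, S2 = 2 * x1)
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  v <- vsn_normalize(protein_matrix(x, scale = "raw"))
  d <- v$matrix$intensity[, 2] - v$matrix$intensity[, 1]
  expect_lt(abs(median(d)), 1e-6)
  expect_equal(v$matrix$scale, "normalized")
  expect_true(all(v$model$scale > 0))
})

test_that("vsn leaves identical samples identical and preserves ranks", {
  set.seed(12)
  x1 <- 2^rnorm(50, 20, 2)
  x <- cbind(S1 = x1, S2 = x1, S3 = x1)
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  v <- vsn_normalize(protein_matrix(x, scale = "raw"))
  expect_lt(max(abs(v$matrix$intensity[, 2] - v$matrix$intensity[, 1])),
            1e-10)
  expect_lt(max(abs(v$matrix$intensity[, 3] - v$matrix$intensity[, 1])),
            1e-10)
  # monotonicity: arsinh calibration is strictly increasing per sample
  for (s in 1:3) {
    o <- order(x[, s])
    expect_true(all(diff(v$matrix$intensity[o, s]) > 0))
  }
})

test_that("vsn refuses samples sharing <3 quantified proteins", {
  x <- 2^matrix(rnorm(20, 20, 1), 10, 2,
                dimnames = list(sprintf("P%02d", 1:10), c("S1", "S2")))
  x[1:8, 2] <- NA
  expect_error(vsn_normalize(protein_matrix(x, scale = "raw")),
               "fewer than 3")
})

test_that("vsn recovers planted fold changes under 4x sample scaling", {
  cfg <- sim_config(seed = 21, n_proteins = 400, pi_dap = 0.1,
                    effect_log2fc = 1.5, protein_sd_scale = 0.002,
                    sample_scale_sd = 0.5, mnar_threshold = -Inf)
  sim <- generate_matrix(cfg)
  # about a 4x multiplicative spread across samples
  expect_gt(diff(range(sim$truth$samples$shift)), 1.5)
  v <- vsn_normalize(sim$matrix)
  a_cols <- sim$design$sample_id[sim$design$diet == "A"]
  b_cols <- sim$design$sample_id[sim$design$diet == "B"]
  fc_hat <- rowMeans(v$matrix$intensity[, b_cols]) -
    rowMeans(v$matrix$intensity[, a_cols])
  err <- fc_hat - sim$truth$proteins$true_log2fc
  expect_lt(max(abs(err)), 0.05)
})

test_that("EM imputation is the identity on complete matrices", {
  m <- toy_matrix(n_proteins = 30, n_samples = 4, seed = 5)
  ml <- log2_transform(m)
  out <- mle_impute(ml)
  expect_identical(out$matrix$intensity, ml$intensity)
  expect_equal(out$model$n_iterations, 0L)
  expect_true(out$model$converged)
  expect_equal(out$model$mu, colMeans(ml$intensity))
})

test_that("imputation equals the closed-form conditional mean on the
           perfectly correlated two-sample toy", {
  set.seed(6)
  a <- rnorm(12, 20, 1)
  x <- cbind(S1 = a, S2 = a + 1)
  rownames(x) <- sprintf("P%02d", seq_len(nrow(x)))
  x[12, 2] <- NA
  out <- mle_impute(protein_matrix(x, scale = "log2"))
  expect_equal(out$matrix$intensity[12, 2], x[12, 1] + 1, tolerance = 1e-8)
  # observed cells are never altered
  obs <- !is.na(x)
  expect_identical(out$matrix$intensity[obs], x[obs])
})

test_that("EM drops all-missing rows, converges monotonically on MNAR data", {
  cfg <- sim_config(seed = 31, n_proteins = 300, n_per_group = 4,
                    mnar_threshold = 19, mnar_slope = 1.5)
  sim <- generate_matrix(cfg)
  ml <- log2_transform(sim$matrix)
  n_allna <- sum(rowSums(!is.na(ml$intensity)) == 0)
  out <- mle_impute(ml)
  expect_equal(out$model$n_dropped, n_allna)
  expect_equal(nrow(out$matrix$intensity), nrow(ml$intensity) - n_allna)
  expect_false(anyNA(out$matrix$intensity))
  ll <- out$model$loglik
  expect_true(all(diff(ll) >= -1e-6 * (abs(ll[-length(ll)]) + 1)))
  expect_true(out$model$converged)
})

test_that("scale tags enforce the filter -> normalize -> impute order", {
  m <- toy_matrix(n_proteins = 15, n_samples = 4, seed = 8)
  expect_error(mle_impute(m), "log2 or normalized")
  v <- vsn_normalize(m)
  expect_error(vsn_normalize(v$matrix), "raw-scale")
  expect_error(log2_transform(v$matrix), "raw-scale")
})
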