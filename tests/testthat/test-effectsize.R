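test_that("an 8+8 design yields three 4-vs-4 plans with disjoint halves", {
  d <- toy_design()
  cfg <- analysis_config(seed = 9)
  plans <- build_plan(d, cfg)
  expect_length(plans, 3)
  expect_equal(vapply(plans, `[[`, character(1), "label"),
               c("within_g1", "within_g2", "between"))
  for (p in plans) {
    expect_length(p$left, 4)
    expect_length(p$right, 4)
    expect_length(intersect(p$left, p$right), 0)
  }
  a_ids <- d$sample_id[d$diet == "A"]
  b_ids <- d$sample_id[d$diet == "B"]
  expect_setequal(c(plans[[1]]$left, plans[[1]]$right), a_ids)
  expect_setequal(c(plans[[2]]$left, plans[[2]]$right), b_ids)
  expect_true(all(plans[[3]]$left %in% a_ids))
  expect_true(all(plans[[3]]$right %in% b_ids))
  # between comparison reuses half 1 of each diet
  expect_identical(plans[[3]]$left, plans[[1]]$left)
  expect_identical(plans[[3]]$right, plans[[2]]$left)
})

test_that("half-splitting is deterministic given the seed", {
  d <- toy_design()
  p1 <- build_plan(d, analysis_config(seed = 123))
  p2 <- build_plan(d, analysis_config(seed = 123))
  expect_identical(p1, p2)
  # the by_replicate mode is the fixed reproducible split
  p3 <- build_plan(d, analysis_config(seed = 1), method = "by_replicate")
  expect_identical(p3[[1]]$left, paste0("A", 1:4))
  expect_identical(p3[[1]]$right, paste0("A", 5:8))
})

test_that("unequal replicate counts are refused at planning", {
  d <- suppressWarnings(sample_design(as.data.frame(toy_design())[-1, ]))
  expect_error(build_plan(d, analysis_config()), "plan error")
})

test_that("comparison summaries compute the DAP percentage from counts", {
  s <- comparison_summary("between", 3901, 205, 302)
  expect_equal(s$n_changed, 507L)
  expect_equal(s$pct_changed, 13.00, tolerance = 1e-9)
  expect_equal(comparison_summary("between", 3660, 235, 231)$pct_changed,
               12.73)
  expect_equal(comparison_summary("within_g1", 500, 0, 0)$pct_changed, 0)
  expect_error(comparison_summary("x", 10, 8, 8), "exceeds total")
})

test_that("run_comparison counts totals from this comparison's filter only", {
  cfg <- sim_config(seed = 51, n_proteins = 250, mnar_threshold = 17)
  acfg <- analysis_config(seed = 51)
  sim <- generate_matrix(cfg)
  plans <- build_plan(sim$design, acfg, method = "by_replicate")
  s <- run_comparison(sim$matrix, plans[[3]], acfg, keep_details = TRUE)
  filt <- filter_by_detection(sim$matrix, NULL, acfg,
                              list(plans[[3]]$left, plans[[3]]$right))
  expect_equal(s$total, nrow(filt$intensity))
  expect_lte(s$n_changed, s$total)
  calls <- attr(s, "calls")
  expect_equal(sum(calls$label == "increased"), s$n_increased)
  expect_equal(sum(calls$label == "decreased"), s$n_decreased)
  # with detection disabled-by-construction data the total is every protein
  cfg2 <- sim_config(seed = 52, n_proteins = 120, mnar_threshold = -Inf)
  sim2 <- generate_matrix(cfg2)
  plans2 <- build_plan(sim2$design, acfg, method = "by_replicate")
  s2 <- run_comparison(sim2$matrix, plans2[[1]], acfg)
  expect_equal(s2$total, 120L)
})

test_that("effect-size aggregation reproduces the tissue-table means", {
  within_pct <- c(6.01, 2.41, 7.86, 5.77, 2.20, 5.21)
  between_pct <- c(12.99, 12.73, 16.59)
  mk <- function(label, pct)
    comparison_summary(label, 10000, round(pct * 100), 0)
  summaries <- c(
    lapply(within_pct, function(p) mk("within_g1", p)),
    lapply(between_pct, function(p) mk("between", p)))
  rep <- summarize_effect_size(summaries)
  expect_equal(round(rep$mean_within, 1), 4.9)
  expect_equal(round(rep$mean_between, 1), 14.1)
  expect_gt(rep$ratio, 2.8)
  expect_lt(rep$ratio, 3)
  expect_error(summarize_effect_size(lapply(within_pct, function(p)
    mk("within_g1", p))), "no between-group")
})

test_that("the whole-study driver aggregates per-tissue comparisons", {
  cfg <- sim_config(seed = 53, n_proteins = 150, tissues = c("brain", "liver"))
  acfg <- analysis_config(seed = 53)
  study <- generate_study(cfg)
  matrices <- lapply(study, `[[`, "matrix")
  rep <- effect_size_analysis(matrices, attr(study, "design"), acfg,
                              method = "by_replicate")
  expect_s3_class(rep, "effect_size_report")
  expect_equal(nrow(rep$comparisons), 6)
  expect_length(attr(rep, "by_tissue"), 2)
  expect_true(rep$ratio > 0)
})
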