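# Within-diet vs between-diet comparison planning, the full per-comparison
# pipeline, and the empirical-null effect-size report.

#' Build within-diet and between-diet comparison plans
#'
#' For a tissue with two diets of `2 * cfg$group_size` replicates each,
#' splits each diet's replicates into two disjoint halves and returns three
#' plans: `within_g1` (half 1 vs half 2 of the first diet), `within_g2`
#' (same for the second diet) and `between` (half 1 of each diet). The
#' within-diet comparisons are an empirical null -- the same treatment on
#' both sides -- against which the between-diet differential-abundance
#' percentage is judged.
#'
#' Halves come from the design's `half` column when assigned; otherwise
#' they are assigned here, either by a seeded shuffle (`method = "seeded"`,
#' using `cfg$seed`, deterministic for a given seed) or by replicate number
#' (`method = "by_replicate"`, replicates 1..group_size form half 1).
#'
#' @param d A `sample_design`.
#' @param cfg An [analysis_config()].
#' @param tissue Tissue to plan for (defaults to the only tissue present).
#' @param method Half-assignment rule when the design has none.
#' @return A list of three `comparison_plan` objects, each with `label`,
#'   `left` and `right` sample-id vectors of length `cfg$group_size`.
#' @export
build_plan <- function(d, cfg, tissue = NULL,
                       method = c("seeded", "by_replicate")) {
  stopifnot(inherits(d, "sample_design"), inherits(cfg, "analysis_config"))
  method <- match.arg(method)
  if (is.null(tissue)) {
    tissue <- unique(d$tissue)
    if (length(tissue) != 1)
      stop("multiple tissues in design; specify `tissue`")
  }
  dd <- d[d$tissue == tissue, , drop = FALSE]
  diets <- sort(unique(dd$diet))
  if (length(diets) != 2) stop("plan error: need exactly two diets")
  gs <- cfg$group_size
  halves <- list()
  need_shuffle <- method == "seeded" &&
    any(is.na(dd$half))
  shuffle_draws <- if (need_shuffle) {
    stats::setNames(
      .with_seed(cfg$seed, lapply(diets, function(d_) sample.int(2 * gs))),
      diets)
  } else NULL
  for (diet in diets) {
    di <- dd[dd$diet == diet, , drop = FALSE]
    if (nrow(di) != 2 * gs)
      stop(sprintf(
        "plan error: diet '%s' has %d replicates in tissue '%s', need %d",
        diet, nrow(di), tissue, 2 * gs))
    di <- di[order(di$replicate), , drop = FALSE]
    if (all(!is.na(di$half))) {
      h1 <- di$sample_id[di$half == 1L]
      h2 <- di$sample_id[di$half == 2L]
      if (length(h1) != gs || length(h2) != gs)
        stop("plan error: assigned halves are not equal-sized")
    } else if (method == "by_replicate") {
      h1 <- di$sample_id[seq_len(gs)]
      h2 <- di$sample_id[gs + seq_len(gs)]
    } else {
      idx <- shuffle_draws[[diet]][seq_len(gs)]
      h1 <- di$sample_id[sort(idx)]
      h2 <- setdiff(di$sample_id, h1)
    }
    halves[[diet]] <- list(h1 = h1, h2 = h2)
  }
  mkplan <- function(label, left, right)
    structure(list(label = label, left = left, right = right,
                   tissue = tissue),
              class = "comparison_plan")
  list(
    mkplan("within_g1", halves[[diets[1]]]$h1, halves[[diets[1]]]$h2),
    mkplan("within_g2", halves[[diets[2]]]$h1, halves[[diets[2]]]$h2),
    mkplan("between",   halves[[diets[1]]]$h1, halves[[diets[2]]]$h1)
  )
}

#' Summarize DAP counts for one comparison
#'
#' @param label Comparison label (e.g. `"between"`, `"within_g1"`, or a
#'   display label such as `"A vs. B"`).
#' @param total Proteins surviving the detection filter in this comparison.
#' @param n_increased,n_decreased DAP counts by direction.
#' @return A `comparison_summary` list with `n_changed` and `pct_changed`
#'   (= 100 * n_changed / total, rounded half-even to 2 decimals).
#' @export
comparison_summary <- function(label, total, n_increased, n_decreased) {
  stopifnot(total >= 0, n_increased >= 0, n_decreased >= 0)
  n_changed <- n_increased + n_decreased
  if (n_changed > total) stop("changed count exceeds total")
  pct <- if (total == 0) 0 else round(100 * n_changed / total, 2)
  structure(list(label = label, total = as.integer(total),
                 n_increased = as.integer(n_increased),
                 n_decreased = as.integer(n_decreased),
                 n_changed = as.integer(n_changed),
                 pct_changed = pct),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("%-10s total %5d | up %4d | down %4d | changed %4d | %.2f%%\n",
              x$label, x$total, x$n_increased, x$n_decreased, x$n_changed,
              x$pct_changed))
  invisible(x)
}

#' Run the full pipeline on one comparison plan
#'
#' Restricted to the plan's samples: detection filter, variance-stabilizing
#' normalization, EM imputation, moderated fit, DAP calling, summary. The
#' `total` is the post-filter protein count of this comparison, so totals
#' differ across plans only through the detection filter.
#'
#' @param m A raw-scale [protein_matrix()] containing the plan's samples.
#' @param plan A `comparison_plan` from [build_plan()].
#' @param cfg An [analysis_config()].
#' @param keep_details If `TRUE`, attach the fit and call tables as
#'   attributes `fits` and `calls`.
#' @return A `comparison_summary`.
#' @export
run_comparison <- function(m, plan, cfg, keep_details = FALSE) {
  stopifnot(inherits(plan, "comparison_plan"))
  groups <- list(plan$left, plan$right)
  filtered <- filter_by_detection(m, NULL, cfg, groups)
  norm <- vsn_normalize(filtered)
  imp <- mle_impute(norm$matrix)
  total <- nrow(imp$matrix$intensity)
  fits <- moderated_fit(imp$matrix, NULL, groups)
  calls <- call_daps(fits, cfg)
  s <- comparison_summary(plan$label, total,
                          sum(calls$label == "increased"),
                          sum(calls$label == "decreased"))
  if (keep_details) {
    attr(s, "fits") <- fits
    attr(s, "calls") <- calls
  }
  s
}

#' Aggregate comparison summaries into an effect-size report
#'
#' Averages the DAP percentages of all within-diet comparisons (the
#' empirical-null level, i.e. systemic noise) and of all between-diet
#' comparisons, across however many tissues are supplied, and reports
#' their ratio: how many times larger the dietary signal is than the
#' null. Means are reported to 1 decimal.
#'
#' @param summaries A list of `comparison_summary` objects (or a list of
#'   such lists, one per tissue).
#' @return An `effect_size_report` with `mean_within`, `mean_between`,
#'   `ratio`, and the per-comparison table `comparisons`.
#' @export
summarize_effect_size <- function(summaries) {
  if (length(summaries) && !inherits(summaries[[1]], "comparison_summary"))
    summaries <- unlist(summaries, recursive = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1),
                       "comparison_summary")))
  labels <- vapply(summaries, `[[`, character(1), "label")
  pct <- vapply(summaries, `[[`, numeric(1), "pct_changed")
  within <- grepl("^within", labels)
  between <- labels == "between"
  if (!any(within)) stop("no within-group comparison supplied")
  if (!any(between)) stop("no between-group comparison supplied")
  mean_within <- mean(pct[within])
  mean_between <- mean(pct[between])
  tab <- data.frame(label = labels, total = vapply(summaries, `[[`,
                                                   integer(1), "total"),
                    n_increased = vapply(summaries, `[[`, integer(1),
                                         "n_increased"),
                    n_decreased = vapply(summaries, `[[`, integer(1),
                                         "n_decreased"),
                    n_changed = vapply(summaries, `[[`, integer(1),
                                       "n_changed"),
                    pct_changed = pct, row.names = NULL)
  structure(list(mean_within = mean_within, mean_between = mean_between,
                 ratio = mean_between / mean_within, comparisons = tab),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("effect-size report over %d comparisons\n",
              nrow(x$comparisons)))
  cat(sprintf("  mean within-group DAP%%:  %.1f\n", x$mean_within))
  cat(sprintf("  mean between-group DAP%%: %.1f\n", x$mean_between))
  cat(sprintf("  between/within ratio:    %.2f\n", x$ratio))
  invisible(x)
}

#' Effect-size analysis of one or more tissues
#'
#' Convenience driver: for each tissue, build the three comparison plans
#' and run them, then aggregate everything into one report.
#'
#' @param matrices A named list of raw-scale matrices, one per tissue
#'   (names are tissue labels), or a single `protein_matrix` for a
#'   single-tissue design.
#' @param d A `sample_design` covering all samples.
#' @param cfg An [analysis_config()].
#' @param method Half-assignment rule passed to [build_plan()].
#' @return An `effect_size_report`; per-tissue summaries in attribute
#'   `by_tissue`.
#' @export
effect_size_analysis <- function(matrices, d, cfg,
                                 method = c("seeded", "by_replicate")) {
  method <- match.arg(method)
  if (inherits(matrices, "protein_matrix"))
    matrices <- stats::setNames(list(matrices), unique(d$tissue)[1])
  by_tissue <- lapply(names(matrices), function(tis) {
    plans <- build_plan(d, cfg, tissue = tis, method = method)
    lapply(plans, function(p) run_comparison(matrices[[tis]], p, cfg))
  })
  names(by_tissue) <- names(matrices)
  rep <- summarize_effect_size(unlist(by_tissue, recursive = FALSE))
  attr(rep, "by_tissue") <- by_tissue
  rep
}
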