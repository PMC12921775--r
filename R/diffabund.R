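# Empirical-Bayes moderated two-group testing, dual p/fold-change DAP
# calling, BH adjustment and the plain pooled Student's t-test.

# Invert the trigamma function by Newton iteration on 1/x (monotone,
# convex parameterization), as used for moment-matching the scaled-F model
# of the per-protein sample variances.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

# Moment-match log sample variances to the scaled-F (log chi-square) model:
# s2_g ~ s2_prior * F(df_g, df_prior). Returns df_prior (possibly Inf) and
# s2_prior. Zero variances are excluded from the moments.
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("hyperparameter estimation error: no positive sample variances")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  if (sum(ok) < 2) return(list(df_prior = Inf, s2_prior = mean(s2[ok])))
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: all true variances
    # equal; the pooled (arithmetic mean) variance is their MLE
    df_prior <- Inf
    s2_prior <- mean(s2[ok])
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated two-group fit
#'
#' Per protein: group means on the log2-like scale, their difference
#' (`log2fc = mean_g2 - mean_g1`), the pooled residual variance `s2` with
#' `n1 + n2 - 2` degrees of freedom, and a moderated t-statistic in which
#' `s2` is shrunk toward an ensemble prior. The prior (`s2_prior`,
#' `df_prior`) is estimated from the distribution of log sample variances
#' by moment matching on the scaled-F model (trigamma inversion);
#' `s2_post = (df_prior*s2_prior + df*s2) / (df_prior + df)` and
#' `t_mod = log2fc / sqrt(s2_post * (1/n1 + 1/n2))` is referred to a
#' Student-t distribution with `df + df_prior` degrees of freedom
#' (a normal reference when `df_prior` is infinite).
#'
#' Setting `df_prior = 0` disables moderation (ordinary pooled t-test);
#' setting `df_prior = Inf` with a fixed `s2_prior` uses that variance for
#' every protein.
#'
#' @param m A complete (imputed) [protein_matrix()] on `log2` or
#'   `normalized` scale.
#' @param d A `sample_design` or `NULL` when `groups` lists sample ids.
#' @param groups Pair of diet labels, or list of two sample-id vectors
#'   (group 1, group 2); each group needs >= 2 samples.
#' @param df_prior,s2_prior Optional overrides of the estimated
#'   hyperparameters.
#' @return A data.frame of class `fit_result` with columns `protein_id`,
#'   `mean_g1`, `mean_g2`, `log2fc`, `s2`, `df_resid`, `s2_prior`,
#'   `df_prior`, `s2_post`, `t_mod`, `p`, `p_adj`.
#' @export
moderated_fit <- function(m, d = NULL, groups, df_prior = NULL,
                          s2_prior = NULL) {
  stopifnot(inherits(m, "protein_matrix"))
  if (m$scale == "raw")
    stop("moderated_fit expects a log2-like (imputed) matrix")
  if (anyNA(m$intensity))
    stop("moderated_fit expects a complete matrix; run mle_impute first")
  g <- .resolve_groups(m, d, groups)
  x1 <- m$intensity[, g$g1, drop = FALSE]
  x2 <- m$intensity[, g$g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  df <- n1 + n2 - 2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / df
  if (all(s2 == 0))
    stop("hyperparameter estimation error: zero variance in every protein")
  if (is.null(df_prior)) {
    prior <- .fit_variance_prior(s2, df)
    d0 <- prior$df_prior
    s0 <- if (is.null(s2_prior)) prior$s2_prior else s2_prior
  } else {
    d0 <- df_prior
    if (d0 > 0 && is.null(s2_prior))
      stop("s2_prior must be supplied with a forced positive df_prior")
    s0 <- if (is.null(s2_prior)) NA_real_ else s2_prior
  }
  s2_post <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(s0, length(s2))
  else (d0 * s0 + df * s2) / (d0 + df)
  fc <- m2 - m1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, Inf * sign(fc)))
  df_total <- df + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
  else 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0 & fc == 0] <- 1
  res <- data.frame(protein_id = rownames(m$intensity),
                    mean_g1 = m1, mean_g2 = m2, log2fc = fc,
                    s2 = s2, df_resid = df,
                    s2_prior = if (d0 == 0) NA_real_ else s0,
                    df_prior = d0, s2_post = s2_post,
                    t_mod = t_mod, p = p,
                    p_adj = bh_adjust(p),
                    row.names = NULL)
  class(res) <- c("fit_result", "data.frame")
  res
}

#' Classify proteins as differentially abundant
#'
#' Applies the dual rule to a [moderated_fit()] table: `increased` when the
#' raw-scale fold change `2^log2fc` is at least `cfg$fc_up` and
#' `p < cfg$p_cut`; `decreased` when the fold change is at most
#' `cfg$fc_down` and `p < cfg$p_cut`; otherwise `unchanged`. Fold-change
#' boundaries are inclusive, the p boundary is exclusive, and the
#' unadjusted p-value is used (the BH-adjusted value is carried along for
#' reporting only). Volcano-plot coordinates (`log2fc`, `-log10 p`) are
#' included.
#'
#' @param fits A `fit_result` data.frame.
#' @param cfg An [analysis_config()].
#' @return A data.frame of class `dap_call` with columns `protein_id`,
#'   `log2fc`, `fc_raw`, `p`, `p_adj`, `label`, `neg_log10_p`.
#' @export
call_daps <- function(fits, cfg) {
  stopifnot(is.data.frame(fits), inherits(cfg, "analysis_config"))
  fc_raw <- 2^fits$log2fc
  sig <- fits$p < cfg$p_cut
  label <- ifelse(sig & fc_raw >= cfg$fc_up, "increased",
                  ifelse(sig & fc_raw <= cfg$fc_down, "decreased",
                         "unchanged"))
  res <- data.frame(protein_id = fits$protein_id,
                    log2fc = fits$log2fc, fc_raw = fc_raw,
                    p = fits$p, p_adj = fits$p_adj, label = label,
                    neg_log10_p = -log10(fits$p),
                    row.names = NULL)
  class(res) <- c("dap_call", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: input order
#' preserved, adjusted values monotone in the p-value ranks and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided pooled (equal-variance) Student's t-test
#'
#' Sign convention: `t > 0` when `mean(y) > mean(x)`. Degenerate inputs
#' follow the reporting contract used for PRM comparisons: zero pooled
#' variance with equal means gives `t = 0, p = 1`; zero pooled variance
#' with unequal means is an error (an infinite statistic has no finite
#' p-value under the model).
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A list with elements `t`, `p` and `df`.
#' @export
student_ttest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 values")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  delta <- mean(y) - mean(x)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, p = 1, df = df))
    stop("zero pooled variance with unequal means")
  }
  t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df = df), df = df)
}
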