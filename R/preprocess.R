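# Detection filtering, log2 transform, variance-stabilizing normalization
# (per-sample affine + glog) and EM maximum-likelihood imputation.

# Resolve a two-group specification into two disjoint sample-id vectors.
# `groups` is either a pair of diet labels (resolved through the design) or
# a list of two sample_id character vectors.
.resolve_groups <- function(m, d, groups) {
  sids <- colnames(m$intensity)
  if (is.list(groups)) {
    g1 <- groups[[1L]]; g2 <- groups[[2L]]
  } else {
    if (is.null(d)) stop("a design is required when groups are diet labels")
    stopifnot(length(groups) == 2)
    g1 <- d$sample_id[d$diet == groups[[1L]]]
    g2 <- d$sample_id[d$diet == groups[[2L]]]
  }
  g1 <- intersect(g1, sids); g2 <- intersect(g2, sids)
  if (length(g1) == 0 || length(g2) == 0)
    stop("group not present among matrix samples")
  if (length(intersect(g1, g2)))
    stop("groups share samples")
  list(g1 = g1, g2 = g2)
}

#' Filter proteins by per-group detection count
#'
#' Keeps proteins quantified (non-missing) in at least `cfg$min_detect`
#' replicates of at least one group (`detection_scope = "any_group"`, the
#' default) or of every group (`"all_groups"`). The number of retained rows
#' is the "Total" of the comparison the filter was run for.
#'
#' @param m A [protein_matrix()] (any scale).
#' @param d A `sample_design`, or `NULL` when `groups` lists sample ids.
#' @param cfg An [analysis_config()].
#' @param groups Pair of diet labels, or a list of two sample-id vectors.
#' @return The row-filtered `protein_matrix`, restricted to the two groups'
#'   columns.
#' @export
filter_by_detection <- function(m, d, cfg, groups) {
  stopifnot(inherits(m, "protein_matrix"), inherits(cfg, "analysis_config"))
  g <- .resolve_groups(m, d, groups)
  if (length(g$g1) < cfg$min_detect || length(g$g2) < cfg$min_detect)
    stop("config error: a group has fewer samples than min_detect")
  n1 <- rowSums(!is.na(m$intensity[, g$g1, drop = FALSE]))
  n2 <- rowSums(!is.na(m$intensity[, g$g2, drop = FALSE]))
  keep <- switch(cfg$detection_scope,
                 any_group = n1 >= cfg$min_detect | n2 >= cfg$min_detect,
                 all_groups = n1 >= cfg$min_detect & n2 >= cfg$min_detect)
  subset_matrix(m, proteins = keep, samples = c(g$g1, g$g2))
}

#' Log2-transform a raw-scale matrix
#'
#' @param m A raw-scale [protein_matrix()]; all non-missing values must be
#'   strictly positive. Missing cells stay missing.
#' @return The matrix on `log2` scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  if (m$scale != "raw")
    stop("log2_transform expects a raw-scale matrix (got ", m$scale, ")")
  if (any(m$intensity <= 0, na.rm = TRUE))
    stop("non-positive intensity cannot be log2-transformed")
  protein_matrix(log2(m$intensity), m$annotation, scale = "log2")
}

# glog on the log2-like scale used throughout: strictly increasing in x
# for a > 0, asymptotically log2(x) + log2(2a) at high intensity.
.glog2 <- function(x, a, b) asinh(a * x + b) / log(2)

# Trimmed profile-likelihood objective of one calibrated sample against the
# reference profile: (keep_n/2) * log(trimmed RSS) minus the log-Jacobian
# of the transform over the kept rows. The Jacobian term is what makes this
# a variance-stabilizing fit rather than plain least squares -- without it,
# inflating the offset squashes the low-intensity range, shrinking
# residuals towards an offset-drift degeneracy. theta = (log a, beta) with
# offset b = beta * a * q_low (q_low a low quantile of the sample), so both
# parameters are dimensionless and O(1).
.vsn_objective <- function(theta, x, ref, keep_n, q_low) {
  a <- exp(theta[1L])
  b <- theta[2L] * a * q_low
  z <- a * x + b
  r <- asinh(z) / log(2) - ref
  keep <- order(abs(r))[seq_len(keep_n)]
  rss <- sum(r[keep]^2)
  log_jac <- sum(log(a) - 0.5 * log1p(z[keep]^2))
  keep_n / 2 * log(rss + 1e-300) - log_jac
}

#' Variance-stabilizing normalization (affine + glog calibration)
#'
#' Calibrates each sample with an affine map (scale `a_s` > 0, offset `b_s`)
#' followed by a generalized-log transform,
#' `h_s(x) = asinh(a_s * x + b_s) / ln(2)`, so the output is log2-like at
#' high intensity and variance-stabilized at low intensity. Parameters are
#' fitted per sample by least trimmed squares (trim fraction `trim`) of the
#' calibrated values against the across-sample row-median reference profile,
#' with `passes` alternating reference/parameter updates. Scale factors are
#' initialized from median intensity ratios, which already removes pure
#' per-sample scaling exactly.
#'
#' By default only the scale factors are fitted and offsets stay 0:
#' MaxLFQ-style DIA intensity matrices are ratio-scale with no additive
#' background, where a free per-sample offset is weakly identified (only
#' the lowest-intensity rows inform it) and can only distort them. Set
#' `fit_offset = TRUE` for data with a real additive background.
#'
#' @param m A raw-scale [protein_matrix()] with at least 2 samples.
#' @param trim Fraction of largest squared residuals ignored in the fit.
#' @param passes Number of alternating reference/parameter passes.
#' @param fit_offset Also fit the per-sample additive offsets `b_s`.
#' @return A list with `matrix` (the normalized `protein_matrix`, scale
#'   `"normalized"`) and `model` (per-sample `scale` and `offset`, class
#'   `normalization_model`).
#' @export
vsn_normalize <- function(m, trim = 0.1, passes = 2L, fit_offset = FALSE) {
  stopifnot(inherits(m, "protein_matrix"))
  if (m$scale != "raw")
    stop("vsn_normalize expects a raw-scale matrix (got ", m$scale, ")")
  x <- m$intensity
  ns <- ncol(x)
  if (ns < 2) stop("vsn_normalize needs at least 2 samples")
  ref_raw <- apply(x, 1L, stats::median, na.rm = TRUE)
  med_ref <- stats::median(ref_raw, na.rm = TRUE)
  a <- vapply(seq_len(ns), function(s)
    med_ref / stats::median(x[, s], na.rm = TRUE), numeric(1))
  b <- numeric(ns)
  for (s in seq_len(ns)) {
    if (sum(!is.na(x[, s]) & !is.na(ref_raw)) < 3)
      stop("sample '", colnames(x)[s],
           "' shares fewer than 3 quantified proteins with the reference")
  }
  calibrated <- function() {
    h <- x
    for (s in seq_len(ns)) h[, s] <- .glog2(x[, s], a[s], b[s])
    h
  }
  q_low <- vapply(seq_len(ns), function(s)
    stats::quantile(x[, s], 0.1, na.rm = TRUE, names = FALSE), numeric(1))
  for (pass in seq_len(passes)) {
    h <- calibrated()
    ref <- apply(h, 1L, stats::median, na.rm = TRUE)
    for (s in seq_len(ns)) {
      ok <- !is.na(x[, s]) & !is.na(ref)
      keep_n <- max(3L, ceiling((1 - trim) * sum(ok)))
      if (fit_offset) {
        fit <- stats::optim(c(log(a[s]), b[s] / (a[s] * q_low[s])),
                            .vsn_objective,
                            x = x[ok, s], ref = ref[ok], keep_n = keep_n,
                            q_low = q_low[s],
                            method = "Nelder-Mead",
                            control = list(reltol = 1e-12, maxit = 2000L,
                                           parscale = c(0.1, 0.1)))
        a[s] <- exp(fit$par[1L])
        b[s] <- fit$par[2L] * a[s] * q_low[s]
      } else {
        fit <- stats::optimize(function(la)
          .vsn_objective(c(la, 0), x[ok, s], ref[ok], keep_n, q_low[s]),
          interval = log(a[s]) + c(-3, 3), tol = 1e-10)
        a[s] <- exp(fit$minimum)
      }
    }
  }
  names(a) <- names(b) <- colnames(x)
  model <- structure(list(scale = a, offset = b, trim = trim,
                          passes = passes),
                     class = "normalization_model")
  out <- protein_matrix(calibrated(), m$annotation, scale = "normalized")
  list(matrix = out, model = model)
}

# Cholesky of a covariance block with escalating ridge on failure; the
# ridge is applied only when the block is numerically singular so exact
# (e.g. perfectly correlated) cases stay exact. Attribute "ridged" records
# whether regularization was needed.
.safe_chol <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) {
    attr(ch, "ridged") <- FALSE
    return(ch)
  }
  eps <- 1e-8 * mean(diag(S))
  if (eps <= 0 || !is.finite(eps)) eps <- 1e-12
  while (is.null(ch)) {
    ch <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    eps <- eps * 10
    if (eps > 1e6 * mean(diag(S)) + 1e6) stop("covariance block not PD")
  }
  attr(ch, "ridged") <- TRUE
  ch
}

#' Maximum-likelihood (EM) imputation of missing intensities
#'
#' Fits a multivariate normal over the sample dimension (proteins are
#' observations, samples are variables) by expectation-maximization and
#' replaces each missing cell with its conditional mean given the observed
#' cells of the same protein row. Observed cells are never altered. Rows
#' that are entirely missing are dropped (with the count recorded in the
#' model). The observed-data log-likelihood is monitored and must be
#' non-decreasing; convergence is declared when its relative change falls
#' below `tol`.
#'
#' @param m A [protein_matrix()] on `log2` or `normalized` scale.
#' @param max_iter Maximum EM iterations (exceeded -> error carrying the
#'   log-likelihood trace).
#' @param tol Relative log-likelihood change at convergence.
#' @return A list with `matrix` (completed `protein_matrix`) and `model`
#'   (class `imputation_model`: `mu`, `sigma`, `converged`, `n_iterations`,
#'   `loglik`, `n_dropped`).
#' @export
mle_impute <- function(m, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(m, "protein_matrix"))
  if (m$scale == "raw")
    stop("mle_impute expects a log2 or normalized matrix")
  x <- m$intensity
  p <- ncol(x)
  all_na <- rowSums(!is.na(x)) == 0L
  n_dropped <- sum(all_na)
  if (n_dropped) {
    m <- subset_matrix(m, proteins = !all_na)
    x <- m$intensity
  }
  n <- nrow(x)
  if (n < 2) stop("too few rows to fit an imputation model")
  obs <- !is.na(x)
  if (all(obs)) {
    mu <- colMeans(x)
    sigma <- stats::cov(x) * (n - 1) / n
    model <- structure(list(mu = mu, sigma = sigma, converged = TRUE,
                            n_iterations = 0L, loglik = numeric(0),
                            n_dropped = n_dropped),
                       class = "imputation_model")
    return(list(matrix = m, model = model))
  }
  complete <- rowSums(obs) == p
  if (sum(complete) > p) {
    mu <- colMeans(x[complete, , drop = FALSE])
    sigma <- stats::cov(x[complete, , drop = FALSE]) *
      (sum(complete) - 1) / sum(complete)
  } else {
    mu <- colMeans(x, na.rm = TRUE)
    sigma <- stats::cov(x, use = "pairwise.complete.obs")
    sigma[is.na(sigma)] <- 0
    sigma <- sigma + diag(1e-6 * mean(diag(sigma)) + 1e-12, p)
  }
  pattern <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern)
  xc <- x
  ll_trace <- numeric(0)
  converged <- FALSE
  regularized <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    scatter_extra <- matrix(0, p, p)
    for (rows in groups) {
      o <- obs[rows[1L], ]
      mi <- which(!o); oi <- which(o)
      xo <- x[rows, oi, drop = FALSE]
      ch <- .safe_chol(sigma[oi, oi, drop = FALSE])
      if (attr(ch, "ridged")) regularized <- TRUE
      dev <- sweep(xo, 2L, mu[oi])
      z <- backsolve(ch, t(dev), transpose = TRUE)
      ll <- ll - 0.5 * (length(rows) * (length(oi) * log(2 * pi) +
                                          2 * sum(log(diag(ch)))) +
                          sum(z * z))
      if (length(mi)) {
        K <- backsolve(ch, backsolve(ch, sigma[oi, mi, drop = FALSE],
                                     transpose = TRUE)) # Soo^-1 Som
        cond <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
          dev %*% K
        xc[rows, mi] <- cond
        Cmm <- sigma[mi, mi, drop = FALSE] -
          t(sigma[oi, mi, drop = FALSE]) %*% K
        scatter_extra[mi, mi] <- scatter_extra[mi, mi] +
          length(rows) * Cmm
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1) {
      prev <- ll_trace[iter - 1L]
      # the monotonicity guarantee holds for the exact EM; a singular
      # covariance block forces a ridge, under which the computed
      # likelihood is for a perturbed model and may jitter
      if (!regularized && ll < prev - 1e-6 * (abs(prev) + 1))
        stop("EM log-likelihood decreased at iteration ", iter)
      if (abs(ll - prev) <= tol * (abs(prev) + 1)) {
        converged <- TRUE
        break
      }
    }
    mu <- colMeans(xc)
    devc <- sweep(xc, 2L, mu)
    sigma <- (crossprod(devc) + scatter_extra) / n
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "EM did not converge within %d iterations", max_iter))
    cond$loglik <- ll_trace
    stop(cond)
  }
  stopifnot(all(is.finite(xc)))
  out <- protein_matrix(xc, m$annotation, scale = m$scale)
  model <- structure(list(mu = mu, sigma = sigma, converged = TRUE,
                          n_iterations = length(ll_trace),
                          loglik = ll_trace, n_dropped = n_dropped),
                     class = "imputation_model")
  list(matrix = out, model = model)
}
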