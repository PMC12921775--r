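# Two-class PLS-DA via NIPALS (PLS1 on a +/-1 class indicator) and 95%
# confidence ellipses for score plots.

#' Fit a two-class PLS-DA model (NIPALS)
#'
#' Supervised ordination of samples against their class (diet) label:
#' PLS1 regression of the centered +/-1 class indicator on the protein
#' matrix, fitted component-by-component with NIPALS and X-deflation.
#' Proteins are autoscaled (mean-centered, unit variance) by default;
#' constant proteins are dropped before autoscaling. Each weight vector is
#' unit-norm with its largest-magnitude element made positive (a fixed sign
#' convention so score plots are reproducible); score vectors are mutually
#' orthogonal. Per-component explained X-variance is reported; it need not
#' be non-increasing for PLS.
#'
#' @param m A complete [protein_matrix()] (imputed; samples are columns),
#'   or a plain samples x variables numeric matrix.
#' @param d A `sample_design` supplying the class label (`diet`) per
#'   sample, or a vector of class labels (one per sample) when `m` is a
#'   plain matrix.
#' @param n_components Number of latent components (<= min(samples - 1,
#'   proteins)).
#' @param scaling `"autoscale"` (default) or `"mean_center"`.
#' @return A `plsda_model` with `weights`, `loadings`, `scores`,
#'   `x_variance_explained`, `scaling`, `classes`.
#' @export
plsda_fit <- function(m, d, n_components = 2L,
                      scaling = c("autoscale", "mean_center")) {
  scaling <- match.arg(scaling)
  if (inherits(m, "protein_matrix")) {
    if (anyNA(m$intensity))
      stop("plsda_fit expects a complete (imputed) matrix")
    X <- t(m$intensity)
  } else {
    X <- as.matrix(m)
    if (anyNA(X)) stop("plsda_fit expects a complete matrix")
  }
  classes <- if (inherits(d, "sample_design")) {
    d$diet[match(rownames(X), d$sample_id)]
  } else as.vector(d)
  if (anyNA(classes) || length(classes) != nrow(X))
    stop("every sample needs a class label")
  lev <- sort(unique(classes))
  if (length(lev) != 2)
    stop("plsda_fit needs exactly two classes (got ",
         length(lev), ")")
  y <- ifelse(classes == lev[2], 1, -1)
  y <- y - mean(y)
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  if (scaling == "autoscale" && !all(keep)) X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("no variable proteins to fit")
  Xs <- scale(X, center = TRUE,
              scale = if (scaling == "autoscale") TRUE else FALSE)
  Xs <- Xs[, , drop = FALSE]
  n <- nrow(Xs); p <- ncol(Xs)
  if (n_components > min(n - 1, p))
    stop("n_components exceeds min(samples - 1, proteins)")
  tss <- sum(Xs^2)
  W <- matrix(0, p, n_components, dimnames = list(colnames(Xs), NULL))
  P <- matrix(0, p, n_components, dimnames = list(colnames(Xs), NULL))
  Tm <- matrix(0, n, n_components, dimnames = list(rownames(Xs), NULL))
  varx <- numeric(n_components)
  E <- Xs
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(E, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("degenerate component ", k,
         ": no covariance between X and the class indicator")
    w <- w / nw
    i_max <- which.max(abs(w))
    if (w[i_max] < 0) w <- -w
    t_k <- drop(E %*% w)
    p_k <- drop(crossprod(E, t_k)) / sum(t_k^2)
    E <- E - tcrossprod(t_k, p_k)
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k
    varx[k] <- sum(t_k^2) * sum(p_k^2) / tss
  }
  structure(list(weights = W, loadings = P, scores = Tm,
                 x_variance_explained = varx, scaling = scaling,
                 classes = stats::setNames(classes, rownames(Xs)),
                 levels = lev),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d samples, %d components (%s)\n",
              nrow(x$scores), ncol(x$scores), x$scaling))
  cat("  X variance explained:",
      paste(sprintf("%.1f%%", 100 * x$x_variance_explained),
            collapse = ", "), "\n")
  invisible(x)
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Ellipse of the bivariate-normal confidence region at the given level:
#' centered on the sample mean, axes along the eigenvectors of the sample
#' covariance, semi-axis lengths `sqrt(eigenvalue * qchisq(level, 2))`.
#'
#' @param scores An n x 2 matrix of component coordinates for one class
#'   (n >= 3).
#' @param level Coverage probability in (0, 1).
#' @return A list with `center` (length 2), `semi_axes` (major, minor),
#'   `rotation` (radians, angle of the major axis), and `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  if (nrow(scores) < 3) stop("need at least 3 points")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1))
    stop("singular covariance: points are (nearly) collinear")
  r2 <- stats::qchisq(level, df = 2)
  v1 <- ev$vectors[, 1]
  list(center = ctr,
       semi_axes = sqrt(ev$values * r2),
       rotation = atan2(v1[2], v1[1]),
       level = level)
}
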