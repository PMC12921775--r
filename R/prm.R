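# Parallel reaction monitoring (PRM) validation: transition-area roll-up,
# protein-level two-group testing, and concordance with the DIA calls.

#' Sum PRM transition areas per peptide and log2-transform
#'
#' For each (peptide, sample), sums the chromatographic peak areas of all
#' measured transitions and takes log2. A zero total area is a
#' non-detection and becomes `NA`. Doubling every transition area adds
#' exactly 1 to every log2 sum.
#'
#' @param transitions Long-format data.frame with columns `protein_id`,
#'   `peptide_sequence`, `transition_id`, `sample_id`, `area` (>= 0);
#'   (peptide, transition, sample) combinations must be unique and each
#'   peptide must map to a single protein.
#' @return A list with `log2sum` (peptide x sample matrix) and `peptides`
#'   (data.frame mapping `peptide_sequence` to `protein_id`).
#' @export
summarize_prm <- function(transitions) {
  req <- c("protein_id", "peptide_sequence", "transition_id", "sample_id",
           "area")
  miss <- setdiff(req, names(transitions))
  if (length(miss))
    stop("transition table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(transitions$area < 0, na.rm = TRUE))
    stop("negative transition area")
  key <- interaction(transitions$peptide_sequence,
                     transitions$transition_id, transitions$sample_id,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (peptide, transition, sample) row")
  pmap <- unique(transitions[, c("peptide_sequence", "protein_id")])
  if (anyDuplicated(pmap$peptide_sequence))
    stop("a peptide maps to more than one protein")
  tot <- tapply(transitions$area,
                list(transitions$peptide_sequence, transitions$sample_id),
                sum)
  log2sum <- ifelse(is.na(tot) | tot == 0, NA_real_, log2(tot))
  list(log2sum = log2sum,
       peptides = pmap[order(pmap$peptide_sequence), , drop = FALSE])
}

#' Protein-level PRM comparison between two groups
#'
#' Rolls peptides up to proteins (unweighted mean of the peptides' log2
#' transition sums per sample, missing peptides excluded), then applies the
#' pooled two-sided [student_ttest()] between the two groups. `log2fc` is
#' `mean(group 2) - mean(group 1)` and `direction` its sign. A group shift
#' with zero within-group variance is reported as the limit `t = +/-Inf`,
#' `p = 0`.
#'
#' @param pepmatrix Result of [summarize_prm()].
#' @param d A `sample_design` (diet defines the groups), or `NULL` when
#'   `groups` lists sample ids.
#' @param groups Pair of diet labels or list of two sample-id vectors;
#'   defaults to the two diets in `d`.
#' @return A data.frame with `protein_id`, `log2fc`, `t`, `p`,
#'   `direction` (-1, 0, +1).
#' @export
prm_compare <- function(pepmatrix, d = NULL, groups = NULL) {
  log2sum <- pepmatrix$log2sum
  pmap <- pepmatrix$peptides
  if (nrow(pmap) == 0) stop("no peptides to compare")
  sids <- colnames(log2sum)
  if (is.null(groups)) {
    if (is.null(d)) stop("supply a design or explicit groups")
    diets <- sort(unique(d$diet))
    stopifnot(length(diets) == 2)
    groups <- list(d$sample_id[d$diet == diets[1]],
                   d$sample_id[d$diet == diets[2]])
  }
  g1 <- intersect(groups[[1]], sids)
  g2 <- intersect(groups[[2]], sids)
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 PRM samples")
  proteins <- unique(pmap$protein_id)
  res <- lapply(proteins, function(pr) {
    peps <- pmap$peptide_sequence[pmap$protein_id == pr]
    if (length(peps) == 0) stop("protein with zero peptides: ", pr)
    sub <- log2sum[peps, , drop = FALSE]
    prot <- colMeans(sub, na.rm = TRUE)
    x <- prot[g1]; y <- prot[g2]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(protein_id = pr, log2fc = NA_real_, t = NA_real_,
                        p = NA_real_, direction = NA_integer_))
    fc <- mean(y) - mean(x)
    # zero within-group variance with a real shift: the statistic diverges
    # and the p-value is below any threshold; report the limit
    tt <- tryCatch(student_ttest(x, y),
                   error = function(e) list(t = Inf * sign(fc), p = 0))
    data.frame(protein_id = pr, log2fc = fc, t = tt$t, p = tt$p,
               direction = as.integer(sign(fc)))
  })
  do.call(rbind, res)
}

#' Direction concordance between DIA calls and PRM results
#'
#' Joins on protein id and compares the sign of the DIA log2 fold change
#' with the PRM direction; the summary is the fraction of shared proteins
#' whose directions agree.
#'
#' @param dia_calls A `dap_call` (or `fit_result`) data.frame with
#'   `protein_id` and `log2fc`.
#' @param prm_results Output of [prm_compare()].
#' @return A list with `table` (per-protein `dia_direction`,
#'   `prm_direction`, `agree`) and `agreement` (fraction agreeing).
#' @export
concordance <- function(dia_calls, prm_results) {
  shared <- intersect(dia_calls$protein_id, prm_results$protein_id)
  if (length(shared) == 0)
    stop("no shared protein ids between DIA and PRM results")
  di <- dia_calls[match(shared, dia_calls$protein_id), ]
  pr <- prm_results[match(shared, prm_results$protein_id), ]
  tab <- data.frame(protein_id = shared,
                    dia_direction = as.integer(sign(di$log2fc)),
                    prm_direction = pr$direction,
                    row.names = NULL)
  tab$agree <- tab$dia_direction == tab$prm_direction
  list(table = tab, agreement = mean(tab$agree, na.rm = TRUE))
}
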