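# Protein-group matrix container and TSV readers/writers for the DIA-NN
# pg_matrix dialect plus sample-design and result tables.

#' Construct a protein-group intensity matrix
#'
#' The central container of the package: a proteins x samples matrix of
#' quantified intensities with optional annotation columns and an explicit
#' scale tag. Missing (non-quantified) cells are stored as `NA`. On the raw
#' scale all non-missing values must be strictly positive; zeros are
#' non-detections and must be converted to `NA` before construction (the
#' readers do this).
#'
#' @param intensity Numeric matrix, one row per protein group, one column per
#'   sample. Row names are the protein-group identifiers (non-empty, unique);
#'   column names are the sample identifiers (non-empty, unique).
#' @param annotation Optional data.frame of annotation columns (protein ids,
#'   names, genes, description) with one row per protein.
#' @param scale One of `"raw"`, `"log2"`, `"normalized"`. Scale transitions
#'   are one-way: raw -> log2/normalized.
#' @return An object of class `protein_matrix`: a list with elements
#'   `intensity`, `annotation` and `scale`.
#' @export
protein_matrix <- function(intensity, annotation = NULL,
                           scale = c("raw", "log2", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  ids <- rownames(intensity)
  if (nrow(intensity) > 0) {
    if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
      stop("every row must have a non-empty protein_id (rownames)")
    if (anyDuplicated(ids))
      stop("duplicate protein_id: ", ids[duplicated(ids)][1L])
  }
  sids <- colnames(intensity)
  if (is.null(sids) || any(!nzchar(sids)))
    stop("every column must have a non-empty sample_id (colnames)")
  if (anyDuplicated(sids))
    stop("duplicate sample_id: ", sids[duplicated(sids)][1L])
  if (scale == "raw" && any(intensity <= 0, na.rm = TRUE))
    stop("raw-scale intensities must be strictly positive or NA; ",
         "map zeros to NA before construction")
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (nrow(annotation) != nrow(intensity))
      stop("annotation rows must match intensity rows")
  }
  structure(list(intensity = intensity, annotation = annotation,
                 scale = scale),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples [%s scale]\n",
              nrow(x$intensity), ncol(x$intensity), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$intensity)),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$intensity)

#' Subset a protein matrix by rows (proteins) and/or columns (samples)
#'
#' @param m A `protein_matrix`.
#' @param proteins,samples Row / column index vectors (names, integers or
#'   logical), defaulting to everything.
#' @return A `protein_matrix` on the same scale.
#' @export
subset_matrix <- function(m, proteins = NULL, samples = NULL) {
  stopifnot(inherits(m, "protein_matrix"))
  ri <- if (is.null(proteins)) seq_len(nrow(m$intensity)) else proteins
  ci <- if (is.null(samples)) seq_len(ncol(m$intensity)) else samples
  ann <- m$annotation
  int <- m$intensity[ri, ci, drop = FALSE]
  if (!is.null(ann)) ann <- ann[ri, , drop = FALSE]
  protein_matrix(int, ann, m$scale)
}

# Canonical DIA-NN pg_matrix annotation headers, in file order.
.pg_annotation_names <- c("Protein.Group", "Protein.Ids", "Protein.Names",
                          "Genes", "First.Protein.Description")

#' Read a DIA-NN protein-group matrix (report.pg_matrix TSV)
#'
#' Parses the tab-separated protein-group quantification table written by
#' DIA-NN: 1-5 leading annotation columns (the first is the protein-group
#' identifier) followed by one numeric intensity column per sample.
#' Annotation columns are auto-detected by the canonical DIA-NN header names
#' and, failing that, by non-numeric content in the first five columns.
#' Empty cells and literal zeros become `NA` (non-detections, not
#' measurements).
#'
#' @param path Path to the TSV file.
#' @return A raw-scale [protein_matrix()].
#' @export
read_pg_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  hdr <- names(raw)
  if (length(hdr) < 2 || any(!nzchar(hdr)))
    stop("format error: missing or incomplete header in ", path)
  if (anyDuplicated(hdr))
    stop("format error: duplicate column names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  looks_numeric <- function(v) {
    v <- v[nzchar(v)]
    if (length(v) == 0) return(TRUE)
    !anyNA(suppressWarnings(as.numeric(v)))
  }
  n_ann <- 1L
  for (j in 2:min(5L, length(hdr) - 1L)) {
    if (hdr[j] %in% .pg_annotation_names ||
        (nrow(raw) > 0 && !looks_numeric(raw[[j]]))) n_ann <- j else break
  }
  ids <- raw[[1L]]
  if (any(!nzchar(ids)))
    stop("format error: empty protein_id in row ",
         which(!nzchar(ids))[1L])
  if (anyDuplicated(ids))
    stop("format error: duplicate protein_id: ", ids[duplicated(ids)][1L])
  sample_cols <- setdiff(seq_along(hdr), seq_len(n_ann))
  int <- matrix(NA_real_, nrow(raw), length(sample_cols),
                dimnames = list(ids, hdr[sample_cols]))
  for (k in seq_along(sample_cols)) {
    v <- raw[[sample_cols[k]]]
    blank <- !nzchar(v) | v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) & !blank
    if (any(bad))
      stop(sprintf(
        "format error: non-numeric intensity '%s' at row %d, column '%s'",
        v[which(bad)[1L]], which(bad)[1L], hdr[sample_cols[k]]))
    num[blank | num == 0] <- NA_real_
    int[, k] <- num
  }
  ann <- if (n_ann >= 1L) raw[, seq_len(n_ann), drop = FALSE] else NULL
  protein_matrix(int, ann, scale = "raw")
}

#' Write a protein matrix in the pg_matrix TSV dialect
#'
#' Annotation columns first, then one intensity column per sample; `NA`
#' serialized as an empty cell. Numeric values are written with 17
#' significant digits so a re-read reproduces them bitwise.
#'
#' @param m A [protein_matrix()].
#' @param path Output path.
#' @export
write_pg_matrix <- function(m, path) {
  stopifnot(inherits(m, "protein_matrix"))
  ann <- m$annotation
  if (is.null(ann)) {
    ann <- data.frame(Protein.Group = rownames(m$intensity),
                      check.names = FALSE)
  }
  num <- as.data.frame(m$intensity, check.names = FALSE)
  num[] <- lapply(num, function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  out <- cbind(ann, num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sample-design table
#'
#' Tab-separated table mapping sample columns of the intensity matrix to
#' experimental factors. Required columns: `sample_id`, `tissue`, `diet`,
#' `replicate`; optional `half` (1 or 2, membership in the within-diet
#' split). Unassigned halves are `NA`.
#'
#' @param path Path to the TSV file.
#' @return A validated `sample_design` data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  sample_design(d)
}

#' Construct and validate a sample design
#'
#' @param d A data.frame with columns `sample_id`, `tissue`, `diet`,
#'   `replicate` and optionally `half`.
#' @return The validated design with class `sample_design`.
#' @export
sample_design <- function(d) {
  req <- c("sample_id", "tissue", "diet", "replicate")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id in design: ",
         d$sample_id[duplicated(d$sample_id)][1L])
  d$replicate <- as.integer(d$replicate)
  if (!"half" %in% names(d)) d$half <- NA_integer_
  d$half <- as.integer(d$half)
  if (any(!is.na(d$half) & !d$half %in% c(1L, 2L)))
    stop("half must be 1, 2 or NA (unassigned)")
  key <- interaction(d$tissue, d$diet, d$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (tissue, diet, replicate) combination in design")
  for (tis in unique(d$tissue)) {
    cnt <- table(d$diet[d$tissue == tis])
    if (length(unique(cnt)) > 1)
      warning(sprintf(
        "tissue '%s': unequal replicate counts across diets (%s); ",
        tis, paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")),
        "effect-size planning will refuse this tissue")
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Check that a design matches a protein matrix
#'
#' @param d A `sample_design`.
#' @param m A `protein_matrix`.
#' @return Invisibly `TRUE`; errors listing unmatched samples otherwise.
#' @export
validate_design <- function(d, m) {
  stopifnot(inherits(d, "sample_design"), inherits(m, "protein_matrix"))
  unmatched <- setdiff(d$sample_id, colnames(m$intensity))
  if (length(unmatched))
    stop("design samples absent from matrix: ",
         paste(unmatched, collapse = ", "))
  invisible(TRUE)
}

#' Write a result table as TSV
#'
#' Deterministic column order (as supplied), tab-separated UTF-8, `NA`
#' serialized as an empty cell, numeric columns written with 17 significant
#' digits so [read_results()] reproduces them bitwise.
#'
#' @param table A data.frame of results.
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(table)
  out[] <- lapply(out, function(v) {
    if (is.numeric(v) && !is.integer(v))
      ifelse(is.na(v), "", sprintf("%.17g", v))
    else
      ifelse(is.na(v), "", as.character(v))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame; empty cells become `NA`.
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
}

#' Analysis configuration for differential-abundance calling
#'
#' Holds the thresholds of the dual p-value / fold-change rule and the
#' detection-filter settings. Defaults follow the feeding-trial analysis:
#' unadjusted p < 0.05 together with a raw-scale fold change >= 1.3
#' (increased) or <= 0.76 (decreased), and detection in at least 3 of 4
#' replicates per group.
#'
#' @param p_cut Significance threshold on the unadjusted p-value (exclusive).
#' @param fc_up Raw-scale fold-change lower bound for "increased" (inclusive).
#' @param fc_down Raw-scale fold-change upper bound for "decreased"
#'   (inclusive).
#' @param min_detect Minimum non-missing replicates per group.
#' @param group_size Replicates per group in each comparison.
#' @param detection_scope `"any_group"` keeps a protein if at least one group
#'   reaches `min_detect`; `"all_groups"` requires every group to.
#' @param seed Integer seed for the seeded half-split and any other
#'   randomized step.
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(p_cut = 0.05, fc_up = 1.3, fc_down = 0.76,
                            min_detect = 3L, group_size = 4L,
                            detection_scope = c("any_group", "all_groups"),
                            seed = 1L) {
  detection_scope <- match.arg(detection_scope)
  stopifnot(p_cut > 0, p_cut < 1, fc_up > 1, fc_down > 0, fc_down < 1,
            min_detect >= 1, min_detect <= group_size)
  structure(list(p_cut = p_cut, fc_up = fc_up, fc_down = fc_down,
                 min_detect = as.integer(min_detect),
                 group_size = as.integer(group_size),
                 detection_scope = detection_scope,
                 seed = as.integer(seed)),
            class = "analysis_config")
}
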