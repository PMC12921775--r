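# Small in-code fixtures shared across test files.

# A tiny raw-scale matrix with controllable missingness.
toy_matrix <- function(n_proteins = 20, n_samples = 4, seed = 1,
                       missing = 0) {
  set.seed(seed)
  x <- 2^matrix(rnorm(n_proteins * n_samples, 20, 2),
                n_proteins, n_samples)
  if (missing > 0)
    x[sample(length(x), round(missing * length(x)))] <- NA
  dimnames(x) <- list(sprintf("P%04d", seq_len(n_proteins)),
                      sprintf("S%02d", seq_len(n_samples)))
  protein_matrix(x, scale = "raw")
}

# A 2-diet, 2x4-replicate single-tissue design (16 samples).
toy_design <- function(n_per_diet = 8, tissue = "brain") {
  sample_design(data.frame(
    sample_id = paste0(rep(c("A", "B"), each = n_per_diet),
                       seq_len(n_per_diet)),
    tissue = tissue,
    diet = rep(c("A", "B"), each = n_per_diet),
    replicate = rep(seq_len(n_per_diet), 2),
    stringsAsFactors = FALSE))
}

# Ordinary pooled two-sample t computed from first principles, used as the
# brute-force oracle for the moderated fit with moderation disabled.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
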