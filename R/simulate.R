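# Ground-truth synthetic data: DIA-like protein matrices with planted
# diet effects and intensity-dependent (MNAR) missingness, PRM transition
# tables sharing the same truth, and feeding-trial growth records.

#' Simulation configuration
#'
#' Defines the generative model for a two-diet DIA experiment shaped like
#' the feeding trial: two diets x `n_per_group` biological replicates,
#' log-normal protein intensities, a planted fraction of diet-responsive
#' proteins, per-protein residual spread drawn from a scaled
#' inverse-chi-square (so the empirical-Bayes variance model is exercised),
#' per-sample log2 scale shifts (the normalization challenge), and a
#' logistic intensity-dependent detection model (missing not at random).
#'
#' @param seed Integer seed (mandatory; generation is bit-reproducible).
#' @param n_proteins Number of protein groups.
#' @param n_per_group Replicates per diet (split into two halves).
#' @param baseline_mean,baseline_sd Log2-intensity distribution of protein
#'   baselines.
#' @param protein_sd_shape,protein_sd_scale Per-protein residual SD model:
#'   variance `= protein_sd_scale^2 * shape / chisq(shape)`, i.e.
#'   `protein_sd_scale` is the typical residual SD (log2 units) and
#'   `protein_sd_shape` its spread (smaller = heavier tails).
#' @param pi_dap Fraction of proteins given a true diet effect.
#' @param effect_log2fc Magnitude of the planted log2 fold change (sign
#'   drawn with equal probability).
#' @param sample_scale_sd SD of the per-sample log2 shift.
#' @param mnar_threshold,mnar_slope Logistic detection model: a cell of
#'   log2 intensity `z` is detected with probability
#'   `plogis((z - mnar_threshold) / mnar_slope)`. Set
#'   `mnar_threshold = -Inf` for complete data.
#' @param tissues Character vector of tissue labels to simulate.
#' @param diets Two diet labels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_proteins = 4000L, n_per_group = 8L,
                       baseline_mean = 20, baseline_sd = 2,
                       protein_sd_shape = 4, protein_sd_scale = 0.25,
                       pi_dap = 0.1, effect_log2fc = 1.5,
                       sample_scale_sd = 0.5,
                       mnar_threshold = 14, mnar_slope = 1,
                       tissues = "brain", diets = c("A", "B")) {
  stopifnot(!missing(seed), pi_dap >= 0, pi_dap <= 1,
            baseline_sd >= 0, protein_sd_scale >= 0, sample_scale_sd >= 0,
            mnar_slope > 0, length(diets) == 2, n_per_group >= 2)
  structure(list(seed = as.integer(seed),
                 n_proteins = as.integer(n_proteins),
                 n_per_group = as.integer(n_per_group),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 protein_sd_shape = protein_sd_shape,
                 protein_sd_scale = protein_sd_scale,
                 pi_dap = pi_dap, effect_log2fc = effect_log2fc,
                 sample_scale_sd = sample_scale_sd,
                 mnar_threshold = mnar_threshold,
                 mnar_slope = mnar_slope,
                 tissues = tissues, diets = diets),
            class = "sim_config")
}

#' Generate a raw-scale DIA-like matrix with known truth
#'
#' Latent log2 intensity of protein i in sample s:
#' `baseline_i + effect_i * I(diet = B) + shift_s + eps`, with
#' `eps ~ N(0, sd_i)`. The raw intensity is `2^latent`. Each cell is then
#' independently censored (missing) with probability
#' `1 - plogis((latent - mnar_threshold) / mnar_slope)` -- detection
#' depends on the observed, post-shift intensity, as on the instrument.
#'
#' @param cfg A [sim_config()].
#' @param tissue Tissue label to generate (default first of
#'   `cfg$tissues`); the RNG substream is offset by the tissue's position
#'   so tissues differ but each is reproducible.
#' @return A list with `matrix` (raw-scale [protein_matrix()]), `design`
#'   (a `sample_design` with halves assigned by replicate), and `truth`
#'   (class `synthetic_truth`: per-protein `is_dap`, `true_log2fc`,
#'   `true_sd`, `baseline`; per-sample `shift`; `latent` log2 matrix;
#'   the config).
#' @export
generate_matrix <- function(cfg, tissue = cfg$tissues[[1L]]) {
  stopifnot(inherits(cfg, "sim_config"))
  t_idx <- match(tissue, cfg$tissues)
  if (is.na(t_idx)) t_idx <- 1L
  seed <- cfg$seed + 7919L * (t_idx - 1L)
  np <- cfg$n_proteins; ng <- cfg$n_per_group
  n_samples <- 2L * ng
  out <- .with_seed(seed, {
    baseline <- stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd)
    sd_i <- cfg$protein_sd_scale *
      sqrt(cfg$protein_sd_shape /
             stats::rchisq(np, df = cfg$protein_sd_shape))
    is_dap <- stats::runif(np) < cfg$pi_dap
    true_fc <- ifelse(is_dap,
                      cfg$effect_log2fc *
                        sign(stats::runif(np) - 0.5), 0)
    shift <- stats::rnorm(n_samples, 0, cfg$sample_scale_sd)
    diet_of <- rep(cfg$diets, each = ng)
    eps <- matrix(stats::rnorm(np * n_samples), np, n_samples) * sd_i
    latent <- baseline +
      outer(true_fc, as.numeric(diet_of == cfg$diets[2])) +
      matrix(shift, np, n_samples, byrow = TRUE) + eps
    detect_p <- stats::plogis((latent - cfg$mnar_threshold) /
                                cfg$mnar_slope)
    detected <- matrix(stats::runif(np * n_samples), np, n_samples) <
      detect_p
    list(baseline = baseline, sd_i = sd_i, is_dap = is_dap,
         true_fc = true_fc, shift = shift, diet_of = diet_of,
         latent = latent, detected = detected)
  })
  sample_id <- paste0(tissue, "_", out$diet_of, rep(seq_len(ng), 2))
  protein_id <- sprintf("P%05d", seq_len(np))
  intensity <- 2^out$latent
  intensity[!out$detected] <- NA_real_
  dimnames(intensity) <- list(protein_id, sample_id)
  dimnames(out$latent) <- dimnames(intensity)
  m <- protein_matrix(intensity, scale = "raw")
  design <- sample_design(data.frame(
    sample_id = sample_id, tissue = tissue, diet = out$diet_of,
    replicate = rep(seq_len(ng), 2),
    half = rep(ifelse(seq_len(ng) <= ng / 2, 1L, 2L), 2),
    stringsAsFactors = FALSE))
  truth <- structure(list(
    proteins = data.frame(protein_id = protein_id, is_dap = out$is_dap,
                          true_log2fc = out$true_fc, true_sd = out$sd_i,
                          baseline = out$baseline),
    samples = data.frame(sample_id = sample_id, diet = out$diet_of,
                         shift = out$shift),
    latent = out$latent,
    config = cfg, tissue = tissue),
    class = "synthetic_truth")
  list(matrix = m, design = design, truth = truth)
}

#' Generate a study: one matrix per configured tissue
#'
#' @param cfg A [sim_config()].
#' @return Named list (by tissue) of [generate_matrix()] results, plus a
#'   combined design in attribute `design`.
#' @export
generate_study <- function(cfg) {
  res <- lapply(cfg$tissues, function(t) generate_matrix(cfg, t))
  names(res) <- cfg$tissues
  design <- sample_design(do.call(rbind, lapply(res, `[[`, "design")))
  attr(res, "design") <- design
  res
}

#' Generate a PRM transition table sharing a matrix's ground truth
#'
#' For a subset of the simulated proteins, emits 2-4 peptides per protein
#' and 3-6 transitions per peptide. The peptide's latent log2 abundance in
#' a sample is the protein's baseline plus its planted diet effect plus
#' `N(0, noise_sd)`; fixed per-peptide response factors and per-transition
#' shares apportion the raw abundance `2^latent` into transition areas, so
#' summed transitions recover the peptide abundance up to lognormal noise
#' and group fold changes recover the planted effect.
#'
#' @param truth A `synthetic_truth` from [generate_matrix()].
#' @param protein_ids Proteins to target (default: all planted DAPs up to
#'   12, padded with null proteins to at least 8 targets).
#' @param noise_sd Log2-scale measurement noise SD.
#' @return A long data.frame: `protein_id`, `peptide_sequence`,
#'   `transition_id`, `sample_id`, `area`.
#' @export
generate_prm <- function(truth, protein_ids = NULL, noise_sd = 0.2) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  pr <- truth$proteins
  if (is.null(protein_ids)) {
    daps <- pr$protein_id[pr$is_dap]
    nulls <- pr$protein_id[!pr$is_dap]
    protein_ids <- c(utils::head(daps, 12L),
                     utils::head(nulls, max(0L, 8L - min(12L,
                                                         length(daps)))))
  }
  stopifnot(all(protein_ids %in% pr$protein_id))
  samples <- truth$samples
  rows <- .with_seed(cfg$seed + 104729L, {
    out <- list()
    aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
            "S","T","V","W","Y")
    for (pid in protein_ids) {
      i <- match(pid, pr$protein_id)
      n_pep <- sample(2:4, 1L)
      for (j in seq_len(n_pep)) {
        pep <- paste0(paste(sample(aa, 8L, replace = TRUE),
                            collapse = ""), "K")
        pep_factor <- 2^stats::rnorm(1L, 0, 1)  # response factor
        n_tr <- sample(3:6, 1L)
        share <- stats::rgamma(n_tr, shape = 2)
        share <- share / sum(share)
        for (s in seq_len(nrow(samples))) {
          latent <- pr$baseline[i] +
            pr$true_log2fc[i] *
            as.numeric(samples$diet[s] == cfg$diets[2]) +
            stats::rnorm(1L, 0, noise_sd)
          total <- pep_factor * 2^latent
          out[[length(out) + 1L]] <- data.frame(
            protein_id = pid,
            peptide_sequence = paste0(pid, "_", pep),
            transition_id = paste0("y", seq_len(n_tr) + 2L),
            sample_id = samples$sample_id[s],
            area = total * share,
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Generate feeding-trial growth records with known truth
#'
#' Per-fish records for two diets; `gain = final - initial` holds by
#' construction. Defaults emulate a 12-week trial of ~500 g fish roughly
#' doubling in weight.
#'
#' @param seed Integer seed.
#' @param days Trial duration (days).
#' @param diets Two diet labels.
#' @param n_fish Fish sampled per diet.
#' @param initial_mean,initial_sd Initial body weight model (g), per diet
#'   (recycled).
#' @param gain_mean,gain_sd Weight-gain model (g), per diet.
#' @param intake_mean,intake_sd Per-fish dry-matter feed intake model (g),
#'   per diet.
#' @return A data.frame of growth records (`diet`, `fish`,
#'   `initial_weight`, `final_weight`, `gain`, `days`, `feed_intake`,
#'   `daily_intake`).
#' @export
generate_growth <- function(seed, days = 84L, diets = c("A", "B"),
                            n_fish = 8L,
                            initial_mean = c(513.92, 513.49),
                            initial_sd = 1.3,
                            gain_mean = c(683.25, 683.72), gain_sd = 15,
                            intake_mean = c(864.35, 827.85),
                            intake_sd = 25) {
  initial_mean <- rep_len(initial_mean, 2L)
  gain_mean <- rep_len(gain_mean, 2L)
  intake_mean <- rep_len(intake_mean, 2L)
  .with_seed(seed, {
    recs <- lapply(1:2, function(k) {
      initial <- stats::rnorm(n_fish, initial_mean[k], initial_sd)
      gain <- stats::rnorm(n_fish, gain_mean[k], gain_sd)
      intake <- stats::rnorm(n_fish, intake_mean[k], intake_sd)
      data.frame(diet = diets[k], fish = seq_len(n_fish),
                 initial_weight = initial,
                 final_weight = initial + gain, gain = gain,
                 days = as.integer(days), feed_intake = intake,
                 daily_intake = intake / days,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}
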