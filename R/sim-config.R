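#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. Defaults mirror the study conditions the generators emulate: a
#' methylation cohort of 44 BRCA1/2 loss-of-function tumors and 36 negatives
#' profiled on ~10,000 retained CpG probes with a planted differential signal,
#' and a 37-gene capture panel sequenced to ~500x mean target depth.
#'
#' @param seed integer master seed; every generator output is a deterministic
#'   function of it (Mersenne-Twister, inversion normals).
#' @param n_pos,n_neg methylation cohort class sizes (positive = BRCA1/2
#'   deficient).
#' @param n_probes total CpG probes simulated.
#' @param n_informative probes carrying the planted group difference; must not
#'   exceed `n_probes`.
#' @param effect_delta group-mean beta difference planted at informative
#'   probes, in `[0, 1)`. `0` gives a null cohort.
#' @param beta_precision concentration of the beta noise distribution
#'   (variance = m(1-m)/(precision+1) around mean m).
#' @param block_size probes per correlated block; probes inside a block share
#'   a per-sample latent factor.
#' @param block_cor latent-scale correlation between probes of one block
#'   (pairwise beta-scale R-squared is approximately `block_cor^2`).
#' @param n_samples_cov FFPE tumor samples in the coverage cohort.
#' @param n_controls whole-blood control samples (CNV-free reference
#'   population) in the coverage cohort; at least 2.
#' @param panel_genes number of genes on the capture panel.
#' @param targets_per_gene coverage targets (exons) per gene.
#' @param mean_depth mean sequencing depth per target, reads.
#' @param depth_dispersion negative-binomial size parameter of depth noise
#'   (larger = closer to Poisson). The default 400 gives a per-target
#'   coefficient of variation of about 7% at 500x — the precision a
#'   clinically validated read-depth CNV assay operates at; lower it to
#'   emulate noisier FFPE libraries.
#' @param tumor_fraction default allelic fraction used when spiking CNV
#'   events, in `[0, 1]`.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_pos + cfg$n_neg
#' @export
sim_config <- function(seed = 1L,
                       n_pos = 44L,
                       n_neg = 36L,
                       n_probes = 10000L,
                       n_informative = 200L,
                       effect_delta = 0.15,
                       beta_precision = 50,
                       block_size = 10L,
                       block_cor = 0.95,
                       n_samples_cov = 24L,
                       n_controls = 8L,
                       panel_genes = 37L,
                       targets_per_gene = 10L,
                       mean_depth = 500,
                       depth_dispersion = 400,
                       tumor_fraction = 1.0) {
  cfg <- list(
    seed = seed,
    n_pos = assert_count(n_pos, "n_pos"),
    n_neg = assert_count(n_neg, "n_neg"),
    n_probes = assert_count(n_probes, "n_probes"),
    n_informative = assert_count(n_informative, "n_informative"),
    effect_delta = effect_delta,
    beta_precision = beta_precision,
    block_size = assert_count(block_size, "block_size"),
    block_cor = block_cor,
    n_samples_cov = assert_count(n_samples_cov, "n_samples_cov"),
    n_controls = assert_count(n_controls, "n_controls"),
    panel_genes = assert_count(panel_genes, "panel_genes"),
    targets_per_gene = assert_count(targets_per_gene, "targets_per_gene"),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    tumor_fraction = tumor_fraction
  )
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_brcadx("'seed' must be a single finite number")
  }
  if (!is.numeric(effect_delta) || length(effect_delta) != 1L ||
      effect_delta < 0 || effect_delta >= 1) {
    stop_brcadx("'effect_delta' must lie in [0, 1)")
  }
  if (cfg$n_informative > cfg$n_probes) {
    stop_brcadx("'n_informative' must not exceed 'n_probes'")
  }
  assert_fraction(tumor_fraction, "tumor_fraction")
  assert_fraction(block_cor, "block_cor")
  if (!is.numeric(beta_precision) || beta_precision <= 0) {
    stop_brcadx("'beta_precision' must be positive")
  }
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop_brcadx("'mean_depth' must be positive")
  }
  if (!is.numeric(depth_dispersion) || depth_dispersion <= 0) {
    stop_brcadx("'depth_dispersion' must be positive")
  }
  if (cfg$n_controls < 2L) {
    stop_brcadx("'n_controls' must be at least 2 (reference population)")
  }
  if (cfg$panel_genes < 2L) {
    stop_brcadx("'panel_genes' must be at least 2")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  methylation: %d pos + %d neg samples, %d probes (%d informative, delta=%.3g)\n",
    x$n_pos, x$n_neg, x$n_probes, x$n_informative, x$effect_delta
  ))
  cat(sprintf("  coverage: %d FFPE + %d whole-blood, %d genes x %d targets, depth %g\n",
    x$n_samples_cov, x$n_controls, x$panel_genes, x$targets_per_gene,
    x$mean_depth
  ))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

#' Capture-panel gene symbols
#'
#' The 37 hereditary-cancer genes modelled on the capture panel. BRCA1 and
#' BRCA2 are always the first two; when `n` differs from 37 the list is
#' truncated or padded with placeholder symbols.
#'
#' @param n number of genes requested.
#' @return character vector of length `n`.
#' @export
panel_gene_symbols <- function(n = 37L) {
  base <- c(
    "BRCA1", "BRCA2", "ATM", "BARD1", "BRIP1", "CDH1", "CDK4", "CDKN2A",
    "CHEK2", "EPCAM", "FH", "FLCN", "MEN1", "MLH1", "MRE11A", "MSH2",
    "MSH6", "MUTYH", "NBN", "PALB2", "PMS2", "PTEN", "RAD50", "RAD51C",
    "RAD51D", "RET", "SDHB", "SDHD", "SMAD4", "STK11", "TP53", "TSC1",
    "TSC2", "VHL", "WT1", "APC", "BMPR1A"
  )
  n <- assert_count(n, "n")
  if (n <= length(base)) {
    base[seq_len(n)]
  } else {
    c(base, sprintf("GENE%02d", seq_len(n - length(base))))
  }
}
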