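# Synthetic cohort generators. Every generator is a deterministic function of
# the seed it is given; independent cohorts derived from one master seed use
# the documented splitting rule in derive_seed().

# Draw a beta variate via the inverse-CDF of a Gaussian copula value, so that
# within-block latent correlation survives the transform while the marginal
# stays exactly Beta(mean * precision, (1 - mean) * precision).
.qbeta_from_z <- function(z, mean, precision) {
  mean <- pmin(pmax(mean, 1e-6), 1 - 1e-6)
  stats::qbeta(stats::pnorm(z), shape1 = mean * precision,
               shape2 = (1 - mean) * precision)
}

#' Simulate a labelled genome-wide methylation cohort
#'
#' Generates a probes-by-samples beta matrix with a planted differential
#' methylation signal and block-correlated probes, plus the ground truth
#' needed to verify feature selection and classification downstream.
#'
#' Non-informative probes draw from a beta distribution around a per-probe
#' baseline mean sampled from a bimodal prior (most CpGs are near-fully
#' methylated or unmethylated). Informative probes have their two group means
#' separated by `effect_delta`, with a random gain/loss direction per probe;
#' means are clamped to `[0.02, 0.98]` and clamping is recorded in the truth.
#' Probes within one block of `block_size` share a per-sample latent factor
#' (loading `block_cor` on the Gaussian-copula scale), so within-group
#' pairwise R-squared inside a block is approximately `block_cor^2`.
#' Informative probes occupy whole blocks, emulating co-methylated regions.
#'
#' @param config a [sim_config()].
#' @return object of class `meth_cohort`: list with `betas` (matrix, probes x
#'   samples, values in `[0,1]`), `labels` (named factor,
#'   positive/negative), `truth` (informative probe ids, per-probe planted
#'   direction, number of clamped means, block assignment), and `config`.
#' @examples
#' cohort <- simulate_methylation_cohort(sim_config(seed = 1, n_probes = 500,
#'   n_informative = 20))
#' dim(cohort$betas)
#' @export
simulate_methylation_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, {
    n_samples <- config$n_pos + config$n_neg
    n_probes <- config$n_probes
    bs <- min(config$block_size, n_probes)
    n_blocks <- ceiling(n_probes / bs)
    block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(n_probes)]

    probe_ids <- sprintf("cg%06d", seq_len(n_probes))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    labels <- factor(
      rep(c("positive", "negative"), c(config$n_pos, config$n_neg)),
      levels = c("negative", "positive")
    )
    names(labels) <- sample_ids

    # bimodal baseline means: hypo / hyper / intermediate CpG compartments
    comp <- sample.int(3L, n_probes, replace = TRUE,
                       prob = c(0.45, 0.45, 0.10))
    baseline <- numeric(n_probes)
    baseline[comp == 1L] <- stats::runif(sum(comp == 1L), 0.03, 0.25)
    baseline[comp == 2L] <- stats::runif(sum(comp == 2L), 0.75, 0.97)
    baseline[comp == 3L] <- stats::runif(sum(comp == 3L), 0.25, 0.75)

    # informative probes fill whole blocks so block-mates carry signal too
    n_inf_blocks <- ceiling(config$n_informative / bs)
    inf_blocks <- sort(sample.int(n_blocks, min(n_inf_blocks, n_blocks)))
    inf_idx <- which(block_of %in% inf_blocks)[seq_len(config$n_informative)]
    baseline[inf_idx] <- stats::runif(length(inf_idx), 0.25, 0.75)
    direction <- integer(n_probes)
    direction[inf_idx] <- sample(c(-1L, 1L), length(inf_idx), replace = TRUE)

    half <- config$effect_delta / 2
    mean_pos <- baseline + direction * half
    mean_neg <- baseline - direction * half
    clamp <- function(m) pmin(pmax(m, 0.02), 0.98)
    n_clamped <- sum(mean_pos != clamp(mean_pos) | mean_neg != clamp(mean_neg))
    mean_pos <- clamp(mean_pos)
    mean_neg <- clamp(mean_neg)

    # Gaussian copula: shared per-(block, sample) factor + probe-level noise
    u <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks, n_samples)
    eps <- matrix(stats::rnorm(n_probes * n_samples), n_probes, n_samples)
    rho <- config$block_cor
    z <- sqrt(rho) * u[block_of, , drop = FALSE] + sqrt(1 - rho) * eps

    means <- matrix(mean_neg, n_probes, n_samples)
    pos_cols <- which(labels == "positive")
    means[, pos_cols] <- mean_pos
    betas <- .qbeta_from_z(z, means, config$beta_precision)
    dim(betas) <- c(n_probes, n_samples)
    dimnames(betas) <- list(probe = probe_ids, sample = sample_ids)

    structure(list(
      betas = betas,
      labels = labels,
      truth = list(
        informative_probes = probe_ids[inf_idx],
        direction = stats::setNames(direction[inf_idx], probe_ids[inf_idx]),
        informative_blocks = inf_blocks,
        block_of = stats::setNames(block_of, probe_ids),
        n_clamped_means = n_clamped
      ),
      config = config
    ), class = "meth_cohort")
  })
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "<meth_cohort> %d probes x %d samples (%d positive / %d negative), %d informative probes\n",
    nrow(x$betas), ncol(x$betas), sum(x$labels == "positive"),
    sum(x$labels == "negative"), length(x$truth$informative_probes)
  ))
  invisible(x)
}

#' Simulate a panel read-depth cohort with optional spiked CNVs
#'
#' Per-target depths are drawn from a negative binomial around per-target
#' baseline efficiency times a per-sample library-size factor. Samples
#' carrying a spiked copy-number event have the affected targets' expected
#' depth scaled by `1 - f/2` (deletion) or `1 + f/2` (duplication), `f` being
#' the event's allelic (tumor) fraction under a diploid background. A
#' disjoint set of whole-blood control samples never carries events and
#' serves as the normalization reference population.
#'
#' @param config a [sim_config()]; `mean_depth` must be positive.
#' @param events optional data.frame of events to spike with columns
#'   `sample` (FFPE sample index or id), `gene`, `event` (`"deletion"` or
#'   `"duplication"`), optional `fraction` (defaults to
#'   `config$tumor_fraction`) and optional `exons` (integer vector or
#'   comma-separated string restricting the event to those exon indices).
#' @return object of class `cov_cohort`: list with `depths` (samples x
#'   targets integer matrix), `targets` (target metadata: id, gene, exon,
#'   0-based half-open interval), `samples` (sample metadata with `tissue`
#'   FFPE / whole_blood_control), `truth` (spiked events) and `config`.
#' @examples
#' cc <- simulate_coverage_cohort(sim_config(seed = 2, n_samples_cov = 6),
#'   events = data.frame(sample = 1, gene = "BRCA1", event = "deletion"))
#' dim(cc$depths)
#' @export
simulate_coverage_cohort <- function(config = sim_config(), events = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- panel_gene_symbols(config$panel_genes)
  tpg <- config$targets_per_gene
  n_targets <- length(genes) * tpg
  targets <- data.frame(
    target_id = sprintf("%s_t%02d", rep(genes, each = tpg),
                        rep(seq_len(tpg), length(genes))),
    gene = rep(genes, each = tpg),
    exon = rep(seq_len(tpg), length(genes)),
    start = rep((seq_len(tpg) - 1L) * 1000L, length(genes)) +
      rep(seq_along(genes) - 1L, each = tpg) * 100000L,
    stringsAsFactors = FALSE
  )
  targets$end <- targets$start + 120L  # 0-based half-open, 120 bp targets

  n_ffpe <- config$n_samples_cov
  n_wb <- config$n_controls
  sample_ids <- c(sprintf("FFPE_%02d", seq_len(n_ffpe)),
                  sprintf("WB_%02d", seq_len(n_wb)))
  tissue <- rep(c("FFPE", "whole_blood_control"), c(n_ffpe, n_wb))

  events <- .normalize_events(events, sample_ids[seq_len(n_ffpe)], genes,
                              config$tumor_fraction)

  with_rng(config$seed, {
    t_eff <- exp(stats::rnorm(n_targets, 0, 0.3))     # target efficiency
    s_lib <- exp(stats::rnorm(length(sample_ids), 0, 0.15))  # library size
    cn <- matrix(1, length(sample_ids), n_targets,
                 dimnames = list(sample_ids, targets$target_id))
    if (nrow(events)) {
      for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        idx <- which(targets$gene == ev$gene)
        if (!is.na(ev$exons) && nzchar(ev$exons)) {
          ex <- as.integer(strsplit(ev$exons, ",")[[1]])
          idx <- idx[targets$exon[idx] %in% ex]
        }
        fac <- if (ev$event == "deletion") 1 - ev$fraction / 2 else
          1 + ev$fraction / 2
        cn[ev$sample, idx] <- cn[ev$sample, idx] * fac
      }
    }
    mu <- config$mean_depth * outer(s_lib, t_eff) * cn
    depths <- matrix(
      stats::rnbinom(length(mu), size = config$depth_dispersion, mu = mu),
      nrow = nrow(mu), dimnames = dimnames(cn)
    )
    structure(list(
      depths = depths,
      targets = targets,
      samples = data.frame(sample_id = sample_ids, tissue = tissue,
                           stringsAsFactors = FALSE),
      truth = events,
      config = config
    ), class = "cov_cohort")
  })
}

.normalize_events <- function(events, ffpe_ids, genes, default_fraction) {
  empty <- data.frame(sample = character(), gene = character(),
                      event = character(), fraction = numeric(),
                      exons = character(), stringsAsFactors = FALSE)
  if (is.null(events) || !nrow(events)) return(empty)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (!all(c("sample", "gene", "event") %in% names(events))) {
    stop_brcadx("'events' needs columns sample, gene, event")
  }
  if (is.numeric(events$sample)) events$sample <- ffpe_ids[events$sample]
  if (!all(events$sample %in% ffpe_ids)) {
    stop_brcadx("spiked events must target FFPE samples")
  }
  if (!all(events$gene %in% genes)) {
    stop_brcadx("spiked events must target panel genes")
  }
  if (!all(events$event %in% c("deletion", "duplication"))) {
    stop_brcadx("event must be 'deletion' or 'duplication'")
  }
  if (is.null(events$fraction)) events$fraction <- default_fraction
  events$fraction[is.na(events$fraction)] <- default_fraction
  stopifnot(all(events$fraction >= 0 & events$fraction <= 1))
  if (is.null(events$exons)) events$exons <- NA_character_
  events$exons <- as.character(events$exons)
  events[, c("sample", "gene", "event", "fraction", "exons")]
}

#' @export
print.cov_cohort <- function(x, ...) {
  cat(sprintf(
    "<cov_cohort> %d samples (%d FFPE + %d whole-blood) x %d targets, %d spiked events\n",
    nrow(x$depths), sum(x$samples$tissue == "FFPE"),
    sum(x$samples$tissue == "whole_blood_control"), ncol(x$depths),
    nrow(x$truth)
  ))
  invisible(x)
}

#' Simulate a promoter methylation screening cohort
#'
#' Emulates promoter-region beta values for BRCA1/BRCA2 in sequence-negative
#' tumors: background samples are fully hypomethylated (region medians below
#' 0.15), while `n_hyper` spiked samples carry a monoallelic BRCA1 promoter
#' methylation gain with region medians in roughly `[0.45, 0.60]`.
#'
#' @param n_neg total cohort size (sequence/CNV-negative samples screened).
#' @param n_hyper number of spiked hypermethylated samples (`<= n_neg`).
#' @param seed RNG seed.
#' @param beta_precision concentration of the beta noise around probe means.
#' @return object of class `promoter_cohort`: list with `betas` (promoter
#'   probes x samples), `regions` (BED-like data.frame: gene, chrom, start,
#'   end), `probe_regions` (probe to gene map with positions), `truth`
#'   (spiked sample ids) and the arguments used.
#' @examples
#' pc <- simulate_promoter_cohort(n_neg = 38, n_hyper = 2, seed = 1)
#' table(pc$truth$hypermethylated_samples)
#' @export
simulate_promoter_cohort <- function(n_neg = 38L, n_hyper = 2L, seed = 1L,
                                     beta_precision = 80) {
  n_neg <- assert_count(n_neg, "n_neg")
  if (!is.numeric(n_hyper) || n_hyper < 0 || n_hyper != round(n_hyper)) {
    stop_brcadx("'n_hyper' must be a non-negative integer")
  }
  n_hyper <- as.integer(n_hyper)
  if (n_hyper > n_neg) stop_brcadx("'n_hyper' must not exceed 'n_neg'")

  regions <- data.frame(
    gene = c("BRCA1", "BRCA2"),
    chrom = c("17", "13"),
    start = c(43125100L, 32315000L),  # 0-based half-open, > 500 bp each
    end = c(43125800L, 32315600L),
    stringsAsFactors = FALSE
  )
  n_probe <- c(BRCA1 = 14L, BRCA2 = 12L)
  probe_regions <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    g <- regions$gene[i]
    k <- n_probe[[g]]
    pos <- as.integer(round(seq(regions$start[i] + 10, regions$end[i] - 10,
                                length.out = k)))
    data.frame(
      probe_id = sprintf("%s_p%02d", tolower(g), seq_len(k)),
      gene = g, chrom = regions$chrom[i], position = pos,
      stringsAsFactors = FALSE
    )
  }))

  with_rng(seed, {
    sample_ids <- sprintf("N%03d", seq_len(n_neg))
    hyper_ids <- if (n_hyper > 0L) sort(sample(sample_ids, n_hyper)) else
      character()
    base_mean <- stats::runif(nrow(probe_regions), 0.03, 0.10)
    means <- matrix(base_mean, nrow(probe_regions), n_neg,
                    dimnames = list(probe_regions$probe_id, sample_ids))
    brca1_rows <- probe_regions$gene == "BRCA1"
    for (s in hyper_ids) {
      # monoallelic gain: region mean drawn inside [0.48, 0.58] keeps the
      # realized median safely in the reported [0.45, 0.60] gain band
      means[brca1_rows, s] <- stats::runif(1, 0.48, 0.58)
    }
    betas <- matrix(
      stats::rbeta(length(means), shape1 = means * beta_precision,
                   shape2 = (1 - means) * beta_precision),
      nrow = nrow(means), dimnames = dimnames(means)
    )
    structure(list(
      betas = betas,
      regions = regions,
      probe_regions = probe_regions,
      truth = list(hypermethylated_samples = hyper_ids),
      n_neg = n_neg, n_hyper = n_hyper, seed = seed
    ), class = "promoter_cohort")
  })
}

#' @export
print.promoter_cohort <- function(x, ...) {
  cat(sprintf(
    "<promoter_cohort> %d promoter probes x %d samples, %d spiked hypermethylated\n",
    nrow(x$betas), ncol(x$betas), length(x$truth$hypermethylated_samples)
  ))
  invisible(x)
}
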