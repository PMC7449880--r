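# Read-depth CNV calling on the capture panel: two-step coverage
# normalization against a whole-blood reference population, four normalized
# concordance parameters per sample-gene, whole-gene calls at a minimum
# allelic fraction, and sub-gene (exon-run) deviation calls.

#' Normalize a panel coverage matrix against whole-blood controls
#'
#' Two-step scheme: each sample's depths are divided by that sample's median
#' target depth (library-size correction), then each target is divided by
#' the mean of the library-corrected values across the whole-blood reference
#' population. An unaffected diploid target has expectation 1. Targets whose
#' reference mean is zero are masked (`NA`) and reported.
#'
#' @param depths samples x targets depth matrix (non-negative), or a
#'   `cov_cohort` from [simulate_coverage_cohort()].
#' @param tissue character vector per sample (`"FFPE"` or
#'   `"whole_blood_control"`); taken from the cohort when `depths` is one.
#' @return the normalized matrix with attributes `tissue` and
#'   `masked_targets` (character vector of masked target names).
#' @examples
#' cc <- simulate_coverage_cohort(sim_config(seed = 1, n_samples_cov = 4))
#' nm <- normalize_coverage(cc)
#' round(mean(nm), 2)
#' @export
normalize_coverage <- function(depths, tissue = NULL) {
  if (inherits(depths, "cov_cohort")) {
    tissue <- depths$samples$tissue
    depths <- depths$depths
  }
  stopifnot(is.matrix(depths), !is.null(tissue),
            length(tissue) == nrow(depths))
  if (any(depths < 0)) stop_brcadx("depths must be non-negative")
  wb <- tissue == "whole_blood_control"
  if (sum(wb) < 2L) {
    stop_brcadx("at least 2 whole-blood controls are required as reference")
  }
  lib <- apply(depths, 1, stats::median)
  if (any(lib <= 0)) stop_brcadx("sample with zero median depth")
  norm1 <- depths / lib
  ref <- colMeans(norm1[wb, , drop = FALSE])
  masked <- !is.finite(ref) | ref <= 0
  ref[masked] <- NA_real_
  out <- sweep(norm1, 2, ref, "/")
  attr(out, "tissue") <- tissue
  attr(out, "masked_targets") <- colnames(depths)[masked]
  out
}

.gene_means <- function(norm, gene_of, gene) {
  idx <- which(gene_of == gene)
  if (!length(idx)) stop_brcadx("gene not on panel: ", gene)
  vals <- norm[, idx, drop = FALSE]
  if (all(!is.finite(vals))) {
    stop_brcadx("all targets masked for gene ", gene)
  }
  rowMeans(vals, na.rm = TRUE)
}

#' Four CNV concordance parameters for one sample and gene
#'
#' Computes, on the normalized matrix, the four parameters used for
#' whole-gene calling: `raw_value` (mean normalized value of the gene in the
#' sample), `intra_ratio` (gene mean over the mean of the per-gene means of
#' the remaining panel genes in the same sample), `ffpe_inter_ratio` (gene
#' mean over the mean of the same gene across the other FFPE samples) and
#' `wb_inter_ratio` (gene mean over the mean of the same gene across the
#' whole-blood controls). Inter-sample denominators exclude the index
#' sample and are centered with `center` (default `"median"`, robust to
#' other event carriers in the cohort; `"mean"` restores the plain
#' average). For an unaffected diploid sample each parameter is close to 1.
#'
#' @param norm normalized matrix from [normalize_coverage()].
#' @param targets target metadata data.frame with a `gene` column aligned to
#'   the matrix columns.
#' @param sample sample name (matrix row).
#' @param gene panel gene symbol.
#' @param center centering statistic of the inter-sample denominators.
#' @return object of class `cnv_params`: named list with the four parameters
#'   plus `sample` and `gene`.
#' @export
compute_cnv_parameters <- function(norm, targets, sample, gene,
                                   center = c("median", "mean")) {
  center_fn <- switch(match.arg(center), median = stats::median,
                      mean = mean)
  tissue <- attr(norm, "tissue")
  stopifnot(!is.null(tissue), nrow(targets) == ncol(norm))
  if (!sample %in% rownames(norm)) stop_brcadx("unknown sample: ", sample)
  gene_of <- targets$gene
  genes <- unique(gene_of)
  if (!gene %in% genes) stop_brcadx("gene not on panel: ", gene)

  gm <- vapply(genes, function(g) .gene_means(norm, gene_of, g),
               numeric(nrow(norm)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(
    rownames(norm), genes))
  i <- match(sample, rownames(norm))
  raw_value <- gm[i, gene]
  intra <- raw_value / mean(gm[i, setdiff(genes, gene)])
  ffpe_others <- which(tissue == "FFPE" & seq_along(tissue) != i)
  wb <- which(tissue == "whole_blood_control")
  if (!length(ffpe_others)) stop_brcadx("no other FFPE samples for ratio")
  ffpe_inter <- raw_value / center_fn(gm[ffpe_others, gene])
  wb_inter <- raw_value / center_fn(gm[wb, gene])
  structure(list(
    sample = sample, gene = gene,
    raw_value = raw_value, intra_ratio = intra,
    ffpe_inter_ratio = ffpe_inter, wb_inter_ratio = wb_inter
  ), class = "cnv_params")
}

#' @export
print.cnv_params <- function(x, ...) {
  cat(sprintf(
    "<cnv_params> %s / %s  raw=%.3f intra=%.3f ffpe_inter=%.3f wb_inter=%.3f\n",
    x$sample, x$gene, x$raw_value, x$intra_ratio, x$ffpe_inter_ratio,
    x$wb_inter_ratio
  ))
  invisible(x)
}

#' Robust per-gene raw-value baseline across the FFPE cohort
#'
#' Trimmed mean (20% each tail) of a gene's mean normalized value across the
#' FFPE samples; robust to the event carriers themselves. Used as the
#' comparison baseline for the `raw_value` concordance criterion.
#'
#' @inheritParams compute_cnv_parameters
#' @param trim trimming fraction passed to [mean()].
#' @return numeric baseline.
#' @export
gene_raw_baseline <- function(norm, targets, gene, trim = 0.2) {
  tissue <- attr(norm, "tissue")
  gm <- .gene_means(norm, targets$gene, gene)
  mean(gm[tissue == "FFPE"], trim = trim)
}

#' Whole-gene CNV call from the four concordance parameters
#'
#' A deletion is called when the parameters agree on a depth drop of at
#' least `min_fraction / 2` (ratio at or below `1 - min_fraction/2`;
#' `raw_value` at or below that multiple of the cohort baseline), a
#' duplication symmetrically at or above `1 + min_fraction/2`. Boundary
#' values are inclusive. `concordance = "all"` (default) requires all four
#' criteria; `"three_of_four"` any three. The estimated allelic fraction is
#' `2 * |1 - r|` with `r` the median of the three ratio parameters, assuming
#' a diploid background.
#'
#' @param params a `cnv_params` object.
#' @param min_fraction minimum allelic fraction of a callable event.
#' @param raw_baseline cohort baseline from [gene_raw_baseline()].
#' @param concordance `"all"` or `"three_of_four"`.
#' @return one-row data.frame of class `cnv_call`: sample, gene, event
#'   (`none`, `full_deletion` or `full_duplication`),
#'   `estimated_allelic_fraction`, the four parameters, and `concordant`.
#' @examples
#' p <- structure(list(sample = "s", gene = "BRCA1", raw_value = 0.85,
#'   intra_ratio = 0.85, ffpe_inter_ratio = 0.85, wb_inter_ratio = 0.85),
#'   class = "cnv_params")
#' call_whole_gene(p, raw_baseline = 1)
#' @export
call_whole_gene <- function(params, min_fraction = 0.30, raw_baseline = 1,
                            concordance = c("all", "three_of_four")) {
  stopifnot(inherits(params, "cnv_params"))
  concordance <- match.arg(concordance)
  assert_fraction(min_fraction, "min_fraction", open_left = TRUE)
  ratios <- c(params$intra_ratio, params$ffpe_inter_ratio,
              params$wb_inter_ratio)
  if (any(!is.finite(ratios)) || !is.finite(params$raw_value)) {
    stop_brcadx("non-finite CNV parameters")
  }
  lo <- 1 - min_fraction / 2
  hi <- 1 + min_fraction / 2
  need <- if (concordance == "all") 4L else 3L
  del_hits <- sum(c(ratios <= lo, params$raw_value <= lo * raw_baseline))
  dup_hits <- sum(c(ratios >= hi, params$raw_value >= hi * raw_baseline))
  r <- stats::median(ratios)
  est <- 2 * abs(1 - r)
  event <- "none"
  if (del_hits >= need && r < 1 && est >= min_fraction) {
    event <- "full_deletion"
  } else if (dup_hits >= need && r > 1 && est >= min_fraction) {
    event <- "full_duplication"
  }
  out <- data.frame(
    sample_id = params$sample, gene = params$gene, event = event,
    estimated_allelic_fraction = if (event == "none") NA_real_ else est,
    raw_value = params$raw_value, intra_ratio = params$intra_ratio,
    ffpe_inter_ratio = params$ffpe_inter_ratio,
    wb_inter_ratio = params$wb_inter_ratio,
    concordant = event != "none",
    stringsAsFactors = FALSE
  )
  class(out) <- c("cnv_call", class(out))
  out
}

#' Sub-gene (exon-run) CNV call for one gene in one sample
#'
#' Scans every contiguous run of exon targets covering at most half the
#' gene (the "remainder of the gene" it is compared against must be the
#' majority) and calls the run whose mean normalized value deviates most
#' from the mean of the remaining exons, provided the deviation reaches
#' `min_dev` (ratio at or below `1 - min_dev`, or at or above
#' `1 + min_dev`; boundaries inclusive). Ties on deviation prefer the
#' longer run, then the earlier start.
#'
#' @param values named numeric vector of one gene's normalized exon values
#'   for one sample, in panel exon order; needs at least 3 exons.
#' @param sample,gene identifiers recorded in the call.
#' @param min_dev minimum relative deviation (0.5 = 50%).
#' @return one-row `cnv_call` data.frame with event `exon_deletion` /
#'   `exon_duplication` and the exon interval, or event `none`.
#' @examples
#' v <- c(1, 1, 1.5, 1, 1); names(v) <- 1:5
#' call_subgene(v, "s", "BRCA1")
#' @export
call_subgene <- function(values, sample, gene, min_dev = 0.5) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop_brcadx("sub-gene calling needs >= 3 exon targets")
  exon_ids <- names(values) %||% as.character(seq_len(n))

  max_run <- max(1L, n %/% 2L)  # event run is the minority of the gene
  best <- NULL
  for (a in seq_len(n)) {
    for (b in a:min(n, a + max_run - 1L)) {
      run <- a:b
      ratio <- mean(values[run]) / mean(values[-run])
      if (!is.finite(ratio) || ratio <= 0) next
      dev <- abs(log2(ratio))
      hit <- ratio <= 1 - min_dev || ratio >= 1 + min_dev
      if (!hit) next
      if (is.null(best) || dev > best$dev + 1e-12 ||
          (abs(dev - best$dev) <= 1e-12 && length(run) > length(best$run))) {
        best <- list(run = run, ratio = ratio, dev = dev)
      }
    }
  }
  if (is.null(best)) {
    out <- data.frame(
      sample_id = sample, gene = gene, event = "none",
      exons = NA_character_, estimated_allelic_fraction = NA_real_,
      ratio = NA_real_, stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      sample_id = sample, gene = gene,
      event = if (best$ratio < 1) "exon_deletion" else "exon_duplication",
      exons = paste0(exon_ids[best$run[1]], "-",
                     exon_ids[best$run[length(best$run)]]),
      estimated_allelic_fraction = 2 * abs(1 - best$ratio),
      ratio = best$ratio,
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("cnv_call", class(out))
  out
}

#' Call CNVs across a coverage cohort
#'
#' Runs normalization, computes the four concordance parameters for every
#' FFPE sample and panel gene, makes whole-gene calls, and optionally scans
#' each sample-gene for sub-gene exon-run events. Only BRCA1/BRCA2 are
#' scanned by default, matching the clinical reporting scope; pass
#' `genes = NULL` to scan the whole panel.
#'
#' @param cohort a `cov_cohort`, or a list with `depths`, `targets`,
#'   `samples` in the same layout.
#' @param genes genes to call; `NULL` = all panel genes.
#' @param min_fraction minimum allelic fraction for whole-gene calls.
#' @param subgene logical; also scan for exon-run events.
#' @param concordance concordance rule, see [call_whole_gene()].
#' @return list with `calls` (data.frame of non-`none` calls), `params`
#'   (all whole-gene evaluations with their parameters) and
#'   `masked_targets`.
#' @export
call_cnvs <- function(cohort, genes = c("BRCA1", "BRCA2"),
                      min_fraction = 0.30, subgene = TRUE,
                      concordance = "all") {
  norm <- normalize_coverage(cohort$depths, cohort$samples$tissue)
  targets <- cohort$targets
  ffpe <- cohort$samples$sample_id[cohort$samples$tissue == "FFPE"]
  genes <- genes %||% unique(targets$gene)

  params_rows <- list()
  call_rows <- list()
  for (g in genes) {
    baseline <- gene_raw_baseline(norm, targets, g)
    gidx <- which(targets$gene == g)
    for (s in ffpe) {
      p <- compute_cnv_parameters(norm, targets, s, g)
      wc <- call_whole_gene(p, min_fraction = min_fraction,
                            raw_baseline = baseline,
                            concordance = concordance)
      params_rows[[length(params_rows) + 1L]] <- wc
      if (wc$event != "none") {
        call_rows[[length(call_rows) + 1L]] <- wc
      } else if (subgene && length(gidx) >= 3L) {
        vals <- stats::setNames(norm[s, gidx], targets$exon[gidx])
        sc <- call_subgene(vals, s, g)
        if (sc$event != "none") call_rows[[length(call_rows) + 1L]] <- sc
      }
    }
  }
  bind <- function(rows) {
    if (!length(rows)) return(NULL)
    cols <- Reduce(union, lapply(rows, names))
    rows <- lapply(rows, function(r) {
      r[setdiff(cols, names(r))] <- NA
      r[cols]
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  list(
    calls = bind(call_rows),
    params = bind(params_rows),
    masked_targets = attr(norm, "masked_targets")
  )
}
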