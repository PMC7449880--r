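# BRCA1/2 promoter hypermethylation calling from promoter-region beta
# values: cross-region medians, threshold-based status, cohort screening.

#' Median promoter methylation of one sample over one region
#'
#' Median of the sample's beta values across the region's member probes
#' (R's default midpoint convention for even counts). At least 3 region
#' probes must be present after QC.
#'
#' @param betas probes x samples beta matrix.
#' @param probe_ids member probe ids of the region.
#' @param sample sample (column) name.
#' @return the median beta, a fraction.
#' @examples
#' b <- matrix(c(0.05, 0.10, 0.08), 3, 1,
#'   dimnames = list(c("p1", "p2", "p3"), "s1"))
#' region_median_beta(b, c("p1", "p2", "p3"), "s1")
#' @export
region_median_beta <- function(betas, probe_ids, sample) {
  present <- intersect(probe_ids, rownames(betas))
  if (length(present) < 3L) {
    stop_brcadx("insufficient region coverage: ", length(present),
                " probe(s) present, need >= 3")
  }
  stats::median(betas[present, sample])
}

#' Promoter methylation status from a region median
#'
#' Below `baseline_thresh` the promoter is called hypomethylated (the fully
#' unmethylated state of an intact promoter); at or above `hyper_thresh` it
#' is called hypermethylated (consistent with a monoallelic gain, observed
#' medians up to ~0.6); the gap between the two thresholds is an explicit
#' indeterminate zone flagged for review rather than forced into either
#' call.
#'
#' @param median_beta region median beta.
#' @param baseline_thresh hypomethylated upper bound (exclusive).
#' @param hyper_thresh hypermethylated lower bound (inclusive).
#' @return `"hypomethylated"`, `"indeterminate"` or `"hypermethylated"`.
#' @examples
#' call_hypermethylation(0.58)
#' call_hypermethylation(0.20)
#' @export
call_hypermethylation <- function(median_beta, baseline_thresh = 0.15,
                                  hyper_thresh = 0.30) {
  if (baseline_thresh >= hyper_thresh) {
    stop_brcadx("baseline_thresh must be below hyper_thresh")
  }
  assert_fraction(median_beta, "median_beta")
  if (median_beta < baseline_thresh) "hypomethylated"
  else if (median_beta >= hyper_thresh) "hypermethylated"
  else "indeterminate"
}

#' Screen a cohort for BRCA1/2 promoter hypermethylation
#'
#' Computes one promoter call per sample per gene and a status summary. If a
#' variant table is supplied, samples carrying a reportable Tier 1/2 variant
#' that nevertheless screen hypermethylated are reported with a warning
#' (pathogenic-variant carriers are expected to show no additional promoter
#' methylation) — a consistency check, not an error.
#'
#' @param betas probes x samples beta matrix restricted to (or containing)
#'   promoter probes.
#' @param probe_regions data.frame mapping `probe_id` to `gene`; a
#'   `promoter_cohort` from [simulate_promoter_cohort()] may be passed as
#'   `betas`, in which case its probe map is used.
#' @param samples samples to screen; defaults to all matrix columns.
#' @param baseline_thresh,hyper_thresh thresholds, see
#'   [call_hypermethylation()].
#' @param variants optional cohort variant table for the consistency check.
#' @return list of class `promoter_screen`: `calls` (data.frame sample_id,
#'   gene, median_beta, status), `summary` (status counts per gene) and
#'   `conflicts` (sample/gene rows violating the consistency check).
#' @examples
#' pc <- simulate_promoter_cohort(n_neg = 10, n_hyper = 1, seed = 3)
#' screen_promoters(pc)$summary
#' @export
screen_promoters <- function(betas, probe_regions = NULL, samples = NULL,
                             baseline_thresh = 0.15, hyper_thresh = 0.30,
                             variants = NULL) {
  if (inherits(betas, "promoter_cohort")) {
    probe_regions <- probe_regions %||% betas$probe_regions
    betas <- betas$betas
  }
  if (is.null(probe_regions)) {
    stop_brcadx("probe_regions mapping is required")
  }
  samples <- samples %||% colnames(betas)
  genes <- unique(probe_regions$gene)

  rows <- list()
  for (g in genes) {
    pids <- probe_regions$probe_id[probe_regions$gene == g]
    for (s in samples) {
      m <- region_median_beta(betas, pids, s)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = g, median_beta = m,
        status = call_hypermethylation(m, baseline_thresh, hyper_thresh),
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- table(gene = calls$gene, status = factor(
    calls$status,
    levels = c("hypomethylated", "indeterminate", "hypermethylated")
  ))

  conflicts <- calls[0, ]
  if (!is.null(variants) && nrow(variants)) {
    tier12 <- unique(variants$sample_id[variants$tier %in% c(1L, 2L)])
    conflicts <- calls[calls$status == "hypermethylated" &
                       calls$sample_id %in% tier12, , drop = FALSE]
    if (nrow(conflicts)) {
      warning(sprintf(
        "%d sample(s) with a reportable Tier 1/2 variant screen promoter-hypermethylated: %s",
        length(unique(conflicts$sample_id)),
        paste(unique(conflicts$sample_id), collapse = ", ")
      ), call. = FALSE)
    }
  }
  structure(list(calls = calls, summary = summary, conflicts = conflicts),
            class = "promoter_screen")
}

#' @export
print.promoter_screen <- function(x, ...) {
  cat("Promoter methylation screen\n")
  print(x$summary)
  n_hyper <- sum(x$calls$status == "hypermethylated")
  cat(sprintf("hypermethylated calls: %d\n", n_hyper))
  invisible(x)
}
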