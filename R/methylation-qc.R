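# Methylation array quality control: beta computation from signal
# intensities, probe-level exclusion rules, genome-wide bimodality check and
# PCA-based sample outlier / batch inspection.

#' Beta value from methylated / unmethylated intensities
#'
#' `M / (M + U + offset)`. With `offset = 0` this is the literal
#' methylated-over-total ratio; the default offset of 100 is the common
#' array-practice stabilizer for low-intensity probes. Vectorized.
#'
#' @param methylated,unmethylated non-negative signal intensities.
#' @param offset non-negative intensity offset added to the denominator.
#' @return beta values in `[0, 1]` (`[0, 1)` when `offset > 0`). With
#'   `offset = 0` a probe with both intensities zero is defined as 0.
#' @examples
#' compute_beta(300, 700, offset = 100)
#' @export
compute_beta <- function(methylated, unmethylated, offset = 100) {
  if (any(methylated < 0) || any(unmethylated < 0) || offset < 0) {
    stop_brcadx("intensities and offset must be non-negative")
  }
  denom <- methylated + unmethylated + offset
  beta <- ifelse(denom == 0, 0, methylated / denom)
  if (offset == 0 && any(denom == 0)) {
    warning("probe(s) with zero total intensity: beta defined as 0",
            call. = FALSE)
  }
  beta
}

#' Probe-level quality filtering of a beta matrix
#'
#' Removes a probe when any of the exclusion rules fires: detection p-value
#' above `p_thresh` (strictly) in any sample, location on chromosome X or Y,
#' a SNP at the CpG or single-base-extension site, or known cross-reactivity.
#' Filtering is a pure selection: retained values are unchanged, and the
#' operation is idempotent.
#'
#' @param betas probes x samples matrix with probe rownames.
#' @param annotation data.frame with columns `probe_id`, `chromosome`,
#'   `snp_at_cpg_or_extension`, `cross_reactive`; every matrix probe must be
#'   annotated.
#' @param detection_p optional matrix of per-entry detection p-values,
#'   aligned with `betas`.
#' @param p_thresh detection p-value threshold; a probe at exactly the
#'   threshold is retained.
#' @param p_scope `"any"` (default) removes a probe failing detection in any
#'   sample; `"all"` only when it fails in every sample.
#' @return the filtered matrix, with attribute `qc_removed`: a list with
#'   per-rule counts (a probe can violate several rules) and the
#'   deduplicated total.
#' @examples
#' b <- matrix(0.5, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' ann <- data.frame(probe_id = c("p1", "p2"), chromosome = c("1", "X"),
#'   snp_at_cpg_or_extension = FALSE, cross_reactive = FALSE)
#' attr(qc_filter_probes(b, ann), "qc_removed")$per_rule
#' @export
qc_filter_probes <- function(betas, annotation, detection_p = NULL,
                             p_thresh = 0.1, p_scope = c("any", "all")) {
  p_scope <- match.arg(p_scope)
  stopifnot(is.matrix(betas))
  probes <- rownames(betas)
  if (is.null(probes)) stop_brcadx("beta matrix needs probe rownames")
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) {
    stop_brcadx("unannotated probes: ",
                paste(utils::head(probes[is.na(idx)], 10), collapse = ", "))
  }
  ann <- annotation[idx, , drop = FALSE]

  fail_p <- rep(FALSE, length(probes))
  if (!is.null(detection_p)) {
    stopifnot(all(dim(detection_p) == dim(betas)))
    above <- detection_p > p_thresh  # strict: p == threshold is retained
    fail_p <- if (p_scope == "any") apply(above, 1, any) else
      apply(above, 1, all)
  }
  fail_sex <- ann$chromosome %in% c("X", "Y")
  fail_snp <- as.logical(ann$snp_at_cpg_or_extension) %in% TRUE
  fail_xr <- as.logical(ann$cross_reactive) %in% TRUE

  drop <- fail_p | fail_sex | fail_snp | fail_xr
  out <- betas[!drop, , drop = FALSE]
  attr(out, "qc_removed") <- list(
    per_rule = c(detection_p = sum(fail_p), sex_chromosome = sum(fail_sex),
                 snp = sum(fail_snp), cross_reactive = sum(fail_xr)),
    total = sum(drop),
    removed_probes = probes[drop]
  )
  out
}

#' Genome-wide methylation bimodality check
#'
#' A well-measured methylome concentrates beta values near 0 and 1. The
#' check computes the fraction of a sample's betas falling in the open
#' mid-band `(lower, upper)` and passes when that fraction is below
#' `max_mid` — a simple mass statistic standing in for a formal dip test.
#'
#' @param betas numeric vector of one sample's beta values; at least 1000
#'   probes required for a stable density.
#' @param lower,upper mid-band limits.
#' @param max_mid pass threshold on the mid-band fraction.
#' @return list with `pass` (logical) and `statistic` (mid-band fraction).
#' @export
bimodality_check <- function(betas, lower = 0.3, upper = 0.7,
                             max_mid = 0.5) {
  betas <- betas[is.finite(betas)]
  if (length(betas) < 1000L) {
    stop_brcadx("bimodality check needs >= 1000 probes")
  }
  stat <- mean(betas > lower & betas < upper)
  list(pass = stat < max_mid, statistic = stat)
}

#' PCA-based sample outlier and batch inspection
#'
#' Projects samples onto the top principal components of the probe-centered
#' beta matrix and flags samples whose robust z-score (median/MAD per
#' component) exceeds `z_thresh` on any retained component. When batch
#' labels are supplied, the centroid separation between batches is reported
#' in pooled-SD units per component.
#'
#' @param betas probes x samples matrix.
#' @param k_components number of components to inspect.
#' @param z_thresh robust z-score threshold for flagging.
#' @param batch optional batch labels per sample.
#' @return list with `flagged` (sample names), `scores` (samples x
#'   components), `robust_z` (same shape) and `batch_separation` (named
#'   numeric per component, or NULL).
#' @export
pca_outlier_check <- function(betas, k_components = 2, z_thresh = 3,
                              batch = NULL) {
  stopifnot(is.matrix(betas))
  n <- ncol(betas)
  if (n < 3L) stop_brcadx("PCA check needs >= 3 samples")
  k <- min(k_components, n - 1L)
  centered <- betas - rowMeans(betas)
  sv <- svd(centered, nu = 0, nv = k)
  scores <- sv$v * rep(sv$d[seq_len(k)], each = n)
  dimnames(scores) <- list(colnames(betas), sprintf("PC%d", seq_len(k)))

  rz <- apply(scores, 2, function(s) {
    md <- stats::mad(s)
    if (md <= 0) md <- stats::sd(s)
    if (!is.finite(md) || md <= 0) return(rep(0, length(s)))
    (s - stats::median(s)) / md
  })
  rz <- matrix(rz, nrow = n, dimnames = dimnames(scores))
  flagged <- rownames(scores)[apply(abs(rz) > z_thresh, 1, any)]

  batch_sep <- NULL
  if (!is.null(batch)) {
    stopifnot(length(batch) == n)
    levs <- unique(batch)
    if (length(levs) == 2L) {
      a <- scores[batch == levs[1], , drop = FALSE]
      b <- scores[batch == levs[2], , drop = FALSE]
      pooled <- sqrt((apply(a, 2, stats::var) + apply(b, 2, stats::var)) / 2)
      batch_sep <- abs(colMeans(a) - colMeans(b)) / pmax(pooled, 1e-12)
    }
  }
  list(flagged = flagged, scores = scores, robust_z = rz,
       batch_separation = batch_sep)
}
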