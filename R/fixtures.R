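# Packaged transcriptions of the published reportable-variant table and the
# cross-validation metric table, plus their validating loaders.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "brcadx")
  if (!nzchar(path)) stop_brcadx("packaged fixture not found: ", file)
  path
}

.read_fixture_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Load the packaged reportable-variant and CNV table
#'
#' Reads the hand-transcribed table of reportable BRCA1/2 sequence variants
#' and copy-number variants in the 172-sample ovarian carcinoma cohort.
#' The transcription's extracted layout loses column boundaries, so a
#' `source` column records the provenance of each row: `"table"` (direct
#' transcription), `"reconciled"` (tier assignment forced by the
#' results-text sample counts), `"results_text"` (row present only in the
#' results prose — the fourth BRCA1 full-gene deletion), and
#' `"table_unreconciled"` (printed rows that cannot be reconciled with the
#' stated counts; excluded unless `include_unreconciled = TRUE`).
#'
#' @param include_unreconciled logical; include the flagged unreconciled
#'   variant rows in the returned variant table.
#' @param path optional directory holding alternative fixture files (used
#'   for validation testing); defaults to the packaged files.
#' @return list with `variants` (one row per reported sequence variant:
#'   sample_id, gene, hgvs_c, hgvs_p, tier, allele_fraction, confirmed,
#'   meth_tested, low_tumor, source), `cnvs` (one row per CNV: sample_id,
#'   gene, event, exons, truncating, confirmed), `unreconciled_variants`,
#'   and `cohort_size` (172, the number of sequenced tumors).
#' @examples
#' tab1 <- load_table1_fixture()
#' nrow(tab1$variants)
#' @export
load_table1_fixture <- function(include_unreconciled = FALSE, path = NULL) {
  vpath <- if (is.null(path)) .extdata("table1_variants.tsv") else
    file.path(path, "table1_variants.tsv")
  cpath <- if (is.null(path)) .extdata("table1_cnvs.tsv") else
    file.path(path, "table1_cnvs.tsv")
  variants <- .read_fixture_tsv(vpath)
  cnvs <- .read_fixture_tsv(cpath)

  vcols <- c("sample_id", "gene", "hgvs_c", "tier", "allele_fraction",
             "confirmed", "source")
  if (!all(vcols %in% names(variants))) {
    stop_brcadx("malformed variant fixture: missing columns ",
                paste(setdiff(vcols, names(variants)), collapse = ", "))
  }
  bad_tier <- which(!variants$tier %in% c(1L, 2L, 3L))
  if (length(bad_tier)) {
    stop_brcadx("malformed variant fixture row ", bad_tier[1], " (sample ",
                variants$sample_id[bad_tier[1]], "): tier must be 1, 2 or 3")
  }
  bad_af <- which(!is.finite(variants$allele_fraction) |
                  variants$allele_fraction <= 0 |
                  variants$allele_fraction > 1)
  if (length(bad_af)) {
    stop_brcadx("malformed variant fixture row ", bad_af[1], " (sample ",
                variants$sample_id[bad_af[1]],
                "): allele_fraction must lie in (0, 1]")
  }

  ccols <- c("sample_id", "gene", "event", "exons", "truncating", "confirmed")
  if (!all(ccols %in% names(cnvs))) {
    stop_brcadx("malformed CNV fixture: missing columns ",
                paste(setdiff(ccols, names(cnvs)), collapse = ", "))
  }
  ok_events <- c("full_deletion", "full_duplication", "exon_duplication",
                 "exon_deletion")
  bad_ev <- which(!cnvs$event %in% ok_events)
  if (length(bad_ev)) {
    stop_brcadx("malformed CNV fixture row ", bad_ev[1], " (sample ",
                cnvs$sample_id[bad_ev[1]], "): unknown event '",
                cnvs$event[bad_ev[1]], "'")
  }
  exon_level <- cnvs$event %in% c("exon_duplication", "exon_deletion")
  bad_ex <- which(exon_level & is.na(cnvs$exons))
  if (length(bad_ex)) {
    stop_brcadx("malformed CNV fixture row ", bad_ex[1],
                ": exon-level event without exon interval")
  }
  bad_full <- which(!exon_level & !is.na(cnvs$exons))
  if (length(bad_full)) {
    stop_brcadx("malformed CNV fixture row ", bad_full[1],
                ": full-gene event must not carry an exon interval")
  }

  unrec <- variants[variants$source == "table_unreconciled", , drop = FALSE]
  if (!include_unreconciled) {
    variants <- variants[variants$source != "table_unreconciled", ,
                         drop = FALSE]
  }
  rownames(variants) <- NULL
  rownames(unrec) <- NULL
  list(
    variants = variants,
    cnvs = cnvs,
    unreconciled_variants = unrec,
    cohort_size = 172L
  )
}

#' Load the packaged fivefold cross-validation metric table
#'
#' Reads the transcribed per-fold accuracy panel (overall accuracy,
#' sensitivity, specificity, PPV, NPV, AUC over five folds plus the printed
#' average column) into a [cv_report] object. The printed averages are kept
#' alongside the recomputed fold means so rounding can be checked.
#'
#' @param path optional alternative fixture file.
#' @return a `cv_report` whose `folds` data.frame holds the five fold rows,
#'   with attribute `printed_average` holding the table's average column.
#' @examples
#' rep <- load_table2_fixture()
#' rep$average["accuracy"]
#' @export
load_table2_fixture <- function(path = NULL) {
  p <- if (is.null(path)) .extdata("table2_metrics.tsv") else path
  tab <- .read_fixture_tsv(p)
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "auc")
  if (!identical(sort(tab$metric), sort(metrics)) ||
      !all(c(sprintf("fold%d", 1:5), "average") %in% names(tab))) {
    stop_brcadx("malformed metric fixture: expected 6 metric rows and ",
                "fold1..fold5 + average columns")
  }
  rownames(tab) <- tab$metric
  folds <- data.frame(fold = 1:5)
  for (m in metrics) {
    folds[[m]] <- as.numeric(tab[m, sprintf("fold%d", 1:5)])
  }
  if (any(!is.finite(as.matrix(folds[metrics]))) ||
      any(as.matrix(folds[metrics]) < 0 | as.matrix(folds[metrics]) > 1)) {
    stop_brcadx("malformed metric fixture: metrics must lie in [0, 1]")
  }
  rep <- new_cv_report(folds)
  attr(rep, "printed_average") <- stats::setNames(
    as.numeric(tab[metrics, "average"]), metrics
  )
  rep
}
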