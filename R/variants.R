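# Variant reporting: allele-fraction filtering, PARP-inhibitor eligibility
# rules, and cohort summary counts over tiered somatic variant calls and CNV
# records.

.brca_genes <- c("BRCA1", "BRCA2")

# Loss-of-function CNV: full-gene deletion, intragenic deletion, or a
# curated truncating intragenic duplication. Whole-gene duplications are not
# assessed clinically and never count.
.is_lof_cnv <- function(cnvs) {
  if (is.null(cnvs) || !nrow(cnvs)) return(logical(0))
  trunc <- if ("truncating" %in% names(cnvs)) {
    !is.na(cnvs$truncating) & cnvs$truncating
  } else rep(FALSE, nrow(cnvs))
  cnvs$event %in% c("full_deletion", "exon_deletion") |
    (cnvs$event == "exon_duplication" & trunc)
}

#' Filter variant records by allele fraction
#'
#' Retains records whose alternate allele fraction strictly exceeds the
#' reporting threshold, mirroring the clinical pipeline's `AF > 10%` filter.
#'
#' @param records data.frame of variant records with an `allele_fraction`
#'   column (fractions in `(0, 1]`).
#' @param threshold reporting threshold, a fraction in `(0, 1)`; a record at
#'   exactly the threshold is removed.
#' @return the retained rows of `records`.
#' @examples
#' v <- data.frame(sample_id = "s1", allele_fraction = c(0.103, 0.10))
#' filter_by_allele_fraction(v)
#' @export
filter_by_allele_fraction <- function(records, threshold = 0.10) {
  assert_fraction(threshold, "threshold", open_left = TRUE,
                  open_right = TRUE)
  if (is.null(records) || !nrow(records)) return(records)
  records[records$allele_fraction > threshold, , drop = FALSE]
}

#' PARP-inhibitor eligibility for one sample
#'
#' Applies the reporting rules for therapy eligibility: a Tier 1 or Tier 2
#' BRCA1/2 sequence variant, a loss-of-function BRCA1/2 CNV (full-gene
#' deletion or truncating intragenic duplication), or a positive promoter
#' hypermethylation call each confer eligibility, in that basis priority.
#' Whole-gene duplications never confer eligibility. When every qualifying
#' variant sits at an allele fraction at or below `af_note_threshold` an
#' advisory note is attached (tumor-content caveat); with `af_gate = TRUE`
#' such variants are excluded from conferring eligibility instead.
#'
#' @param variants data.frame of the sample's sequence variants (columns
#'   `sample_id`, `gene`, `tier`, `allele_fraction`); may be empty or NULL.
#' @param cnvs data.frame of the sample's CNV records (columns `sample_id`,
#'   `gene`, `event`, optional `truncating`); may be empty or NULL.
#' @param promoter_positive logical; is the sample's BRCA1/2 promoter
#'   hypermethylation call positive?
#' @param af_note_threshold allele fraction below or at which the advisory
#'   note is attached.
#' @param af_gate logical; make the allele-fraction remark a hard gate.
#' @param sample_id sample identifier; inferred from the records when NULL.
#' @return one-row data.frame (class `eligibility_call`): `sample_id`,
#'   `eligible`, `basis` (`tier1_2_variant`, `lof_cnv`,
#'   `promoter_methylation` or `none`) and `notes`.
#' @examples
#' classify_parpi_eligibility(
#'   variants = data.frame(sample_id = "s", gene = "BRCA1", tier = 2,
#'                         allele_fraction = 0.45),
#'   cnvs = data.frame(sample_id = "s", gene = "BRCA2",
#'                     event = "full_duplication")
#' )
#' @export
classify_parpi_eligibility <- function(variants = NULL, cnvs = NULL,
                                       promoter_positive = FALSE,
                                       af_note_threshold = 0.40,
                                       af_gate = FALSE,
                                       sample_id = NULL) {
  ids <- unique(c(
    if (!is.null(variants) && nrow(variants)) variants$sample_id,
    if (!is.null(cnvs) && nrow(cnvs)) cnvs$sample_id
  ))
  if (length(ids) > 1L) {
    stop_brcadx("records from multiple samples passed: ",
                paste(ids, collapse = ", "))
  }
  sample_id <- sample_id %||% if (length(ids)) ids else NA_character_

  notes <- character()
  qual <- if (!is.null(variants) && nrow(variants)) {
    variants[variants$gene %in% .brca_genes & variants$tier %in% c(1L, 2L), ,
             drop = FALSE]
  } else NULL
  has_variant_basis <- !is.null(qual) && nrow(qual) > 0L
  if (has_variant_basis && all(qual$allele_fraction <= af_note_threshold)) {
    notes <- c(notes, sprintf(
      "all qualifying variants at allele fraction <= %.0f%%; consider tumor content",
      100 * af_note_threshold
    ))
    if (af_gate) has_variant_basis <- FALSE
  }

  lof <- !is.null(cnvs) && nrow(cnvs) &&
    any(.is_lof_cnv(cnvs) & cnvs$gene %in% .brca_genes)

  basis <- if (has_variant_basis) "tier1_2_variant"
    else if (lof) "lof_cnv"
    else if (isTRUE(promoter_positive)) "promoter_methylation"
    else "none"

  out <- data.frame(
    sample_id = sample_id,
    eligible = basis != "none",
    basis = basis,
    notes = paste(notes, collapse = "; "),
    stringsAsFactors = FALSE
  )
  class(out) <- c("eligibility_call", class(out))
  out
}

#' PARP-inhibitor eligibility for a whole cohort
#'
#' Applies [classify_parpi_eligibility()] to every sample appearing in the
#' variant table, the CNV table, or the promoter call table.
#'
#' @param variants,cnvs cohort-level record tables (see
#'   [classify_parpi_eligibility()]).
#' @param promoter_calls optional data.frame with `sample_id` and `status`
#'   (`"hypermethylated"` counts as positive) or a logical vector named by
#'   sample id.
#' @inheritParams classify_parpi_eligibility
#' @return data.frame of eligibility calls, one row per sample.
#' @export
classify_cohort_eligibility <- function(variants = NULL, cnvs = NULL,
                                        promoter_calls = NULL,
                                        af_note_threshold = 0.40,
                                        af_gate = FALSE) {
  promoter_pos <- character()
  if (!is.null(promoter_calls)) {
    if (is.data.frame(promoter_calls)) {
      promoter_pos <- unique(promoter_calls$sample_id[
        promoter_calls$status == "hypermethylated"])
    } else {
      promoter_pos <- names(promoter_calls)[as.logical(promoter_calls)]
    }
  }
  ids <- unique(c(
    if (!is.null(variants)) variants$sample_id,
    if (!is.null(cnvs)) cnvs$sample_id,
    promoter_pos
  ))
  calls <- lapply(ids, function(s) {
    classify_parpi_eligibility(
      variants = if (!is.null(variants))
        variants[variants$sample_id == s, , drop = FALSE],
      cnvs = if (!is.null(cnvs))
        cnvs[cnvs$sample_id == s, , drop = FALSE],
      promoter_positive = s %in% promoter_pos,
      af_note_threshold = af_note_threshold,
      af_gate = af_gate,
      sample_id = s
    )
  })
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), eligible = logical(),
                      basis = character(), notes = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Cohort summary counts over reported variants and CNVs
#'
#' Per-sample counts of diagnostic findings: samples with at least one
#' Tier 1/2 variant, Tier 1 carriers split by gene, samples whose only
#' entries are VUS (Tier 3, no CNV), loss-of-function CNV carriers, and CNV
#' carriers per gene. Counting is per sample: a sample with two Tier 1
#' variants counts once.
#'
#' @param variants cohort variant table (columns `sample_id`, `gene`,
#'   `tier`, `allele_fraction`).
#' @param cnvs cohort CNV table (columns `sample_id`, `gene`, `event`,
#'   optional `truncating`).
#' @param af_threshold optional allele-fraction reporting threshold applied
#'   (strictly) before counting; `NULL` counts the records as given.
#' @return object of class `cohort_summary` (a named list of counts).
#' @examples
#' tab1 <- load_table1_fixture()
#' summarize_cohort(tab1$variants, tab1$cnvs)
#' @export
summarize_cohort <- function(variants = NULL, cnvs = NULL,
                             af_threshold = NULL) {
  if (!is.null(af_threshold)) {
    variants <- filter_by_allele_fraction(variants, af_threshold)
  }
  v <- if (!is.null(variants) && nrow(variants)) variants else
    data.frame(sample_id = character(), gene = character(), tier = integer())
  c0 <- if (!is.null(cnvs) && nrow(cnvs)) cnvs else
    data.frame(sample_id = character(), gene = character(),
               event = character())

  tier12 <- unique(v$sample_id[v$tier %in% c(1L, 2L)])
  tier1 <- unique(v$sample_id[v$tier == 1L])
  tier1_gene <- vapply(.brca_genes, function(g) {
    length(unique(v$sample_id[v$tier == 1L & v$gene == g]))
  }, integer(1))
  cnv_samples <- unique(c0$sample_id)
  vus_only <- setdiff(unique(v$sample_id[v$tier == 3L]),
                      c(tier12, cnv_samples))
  lof <- unique(c0$sample_id[.is_lof_cnv(c0)])
  cnv_gene <- vapply(.brca_genes, function(g) {
    length(unique(c0$sample_id[c0$gene == g]))
  }, integer(1))

  structure(list(
    n_tier12_samples = length(tier12),
    n_tier1_samples = length(tier1),
    n_tier1_by_gene = tier1_gene,
    n_tier2_only_samples = length(setdiff(tier12, tier1)),
    n_vus_only_samples = length(vus_only),
    n_lof_cnv_samples = length(lof),
    n_cnv_samples_by_gene = cnv_gene,
    n_any_cnv_samples = length(cnv_samples),
    tier12_samples = sort(tier12),
    lof_cnv_samples = sort(lof),
    vus_only_samples = sort(vus_only)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  samples with >=1 Tier 1/2 variant : %d\n",
              x$n_tier12_samples))
  cat(sprintf("  samples with >=1 Tier 1 variant   : %d (BRCA1 %d / BRCA2 %d)\n",
              x$n_tier1_samples, x$n_tier1_by_gene[["BRCA1"]],
              x$n_tier1_by_gene[["BRCA2"]]))
  cat(sprintf("  Tier 2-only samples               : %d\n",
              x$n_tier2_only_samples))
  cat(sprintf("  VUS-only samples                  : %d\n",
              x$n_vus_only_samples))
  cat(sprintf("  loss-of-function CNV samples      : %d\n",
              x$n_lof_cnv_samples))
  cat(sprintf("  any CNV per gene                  : BRCA1 %d / BRCA2 %d\n",
              x$n_cnv_samples_by_gene[["BRCA1"]],
              x$n_cnv_samples_by_gene[["BRCA2"]]))
  invisible(x)
}
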