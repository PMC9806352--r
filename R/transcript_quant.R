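#' Compute transcripts per million (TPM)
#'
#' \deqn{TPM_i = 10^6 \frac{c_i / \ell_i}{\sum_j c_j / \ell_j}}
#' with \eqn{c} the expected read count and \eqn{\ell} the effective length.
#' TPM is invariant to uniform scaling of the counts and sums to
#' \eqn{10^6} by construction.
#'
#' @param records transcript table from [read_transcript_quant()] (columns
#'   \code{expected_count}, \code{effective_length}).
#' @return \code{records} with the \code{tpm} column (re)computed.
#' @export
compute_tpm <- function(records) {
  if (all(records$expected_count == 0)) {
    stop_venomcomp("degenerate input: all expected counts are zero",
                   "venomcomp_degenerate_error")
  }
  rate <- records$expected_count / records$effective_length
  records$tpm <- 1e6 * rate / sum(rate)
  records
}

#' Check that a TPM column is properly normalised
#'
#' @param records transcript table with \code{tpm} set.
#' @param tolerance relative tolerance on the \eqn{10^6} total.
#' @return list with \code{pass}, \code{total}, \code{relative_error} and
#'   \code{negative} (ids of records with negative TPM).
#' @export
validate_tpm <- function(records, tolerance = 1e-6) {
  if (anyNA(records$tpm)) {
    stop_venomcomp("tpm column is unset; run compute_tpm first",
                   "venomcomp_validation_error")
  }
  total <- sum(records$tpm)
  rel <- abs(total - 1e6) / 1e6
  list(pass = rel <= tolerance && all(records$tpm >= 0),
       total = total, relative_error = rel,
       negative = records$transcript_id[records$tpm < 0])
}

#' Family-level transcript abundance
#'
#' Aggregates TPM over toxin-annotated transcripts into family percentages:
#' \code{100 * sum(tpm of family members) / sum(tpm of all toxin
#' transcripts)}. Restricting the denominator to toxin transcripts mirrors
#' the proteome statistic's denominator (all toxin hits), so the two
#' compositions are directly comparable.
#'
#' @param records transcript table with \code{tpm} set.
#' @param annotations annotation data frame ([read_annotation_map()]) keyed
#'   by transcript id, or a named character vector \code{id -> family} (in
#'   which case every named transcript counts as a toxin).
#' @return A family-level [composition_table()].
#' @export
family_transcript_abundance <- function(records, annotations) {
  if (anyNA(records$tpm)) {
    stop_venomcomp("tpm column is unset; run compute_tpm first",
                   "venomcomp_validation_error")
  }
  if (is.data.frame(annotations)) {
    ann <- annotations[annotations$is_toxin, , drop = FALSE]
    fam <- setNames(ann$family, ann$accession)
  } else {
    fam <- annotations
  }
  keep <- records$transcript_id %in% names(fam)
  if (!any(keep) || sum(records$tpm[keep]) <= 0) {
    stop_venomcomp("no toxin-annotated transcripts with positive TPM",
                   "venomcomp_degenerate_error")
  }
  sub <- records[keep, , drop = FALSE]
  groups <- fam[sub$transcript_id]
  agg <- rowsum(sub$tpm, groups, reorder = FALSE)
  percent <- 100 * agg[, 1] / sum(agg[, 1])
  percent <- sort(setNames(percent, rownames(agg)), decreasing = TRUE)
  composition_table(percent, level = "family")
}
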