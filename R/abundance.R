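#' Within-band relative spectral AUC
#'
#' Fraction of each protein's spectral AUC relative to the total AUC of all
#' toxin hits in one gel band — the per-band normalisation at the heart of
#' the quantification.
#'
#' @param hits filtered toxin \code{spectral_hits} all sharing one
#'   \code{band_id}, none flagged as contaminant.
#' @return named numeric vector of fractions summing to 1.
#' @export
band_relative_auc <- function(hits) {
  if (length(unique(hits$band_id)) != 1) {
    stop_venomcomp("hits must all belong to a single band",
                   "venomcomp_validation_error")
  }
  if (any(hits$is_contaminant)) {
    stop_venomcomp("contaminant hits must be filtered out before quantification",
                   "venomcomp_validation_error")
  }
  total <- sum(hits$auc)
  if (total <= 0) {
    stop_venomcomp(sprintf("band %s has zero total toxin AUC", hits$band_id[1]),
                   "venomcomp_empty_band_error")
  }
  # duplicate accessions were merged on load, but tolerate unmerged input
  frac <- rowsum(hits$auc, hits$accession, reorder = FALSE)[, 1] / total
  frac
}

#' Band-proportion-weighted relative abundance
#'
#' The central statistic: for each protein X,
#' \deqn{\%X = 100 \sum_{n=1}^{N} \frac{AUC_{X,B_n}}{\sum_{toxins} AUC_{B_n}}
#'   \times p(B_n)}
#' where \eqn{p(B_n)} is band \eqn{B_n}'s densitometric proportion of the
#' lane. A protein identified in several bands accumulates over all of them.
#' Non-toxin and contaminant hits must already be excluded: they belong in
#' neither the numerator nor the per-band denominator.
#'
#' Bands with positive densitometric proportion but no toxin hit (or zero
#' total AUC) cannot contribute. Under the default
#' \code{zero_band_policy = "renormalise"} the proportions are re-scaled over
#' the toxin-bearing bands so the output still sums to 100; with
#' \code{"error"} such a band aborts the run (audit mode).
#'
#' @param hits filtered toxin \code{spectral_hits} across bands.
#' @param proportions a \code{band_proportions} table (from
#'   [integrate_bands()] or [proportions_from_areas()]) or a named numeric
#'   vector of proportions. Every band present in \code{hits} must appear.
#' @param zero_band_policy \code{"renormalise"} (default) or \code{"error"}.
#' @return A protein-level [composition_table()] whose percentages sum to
#'   100; \code{attr(x, "provenance")} holds per-protein contributing band
#'   and hit counts.
#' @export
relative_abundance <- function(hits, proportions,
                               zero_band_policy = c("renormalise", "error")) {
  zero_band_policy <- match.arg(zero_band_policy)
  if (inherits(proportions, "band_proportions") || is.data.frame(proportions)) {
    prop <- setNames(proportions$proportion, proportions$band_id)
  } else {
    prop <- proportions
  }
  if (any(hits$is_contaminant)) {
    stop_venomcomp("contaminant hits must be filtered out before quantification",
                   "venomcomp_validation_error")
  }
  missing_bands <- setdiff(unique(hits$band_id), names(prop))
  if (length(missing_bands) > 0) {
    stop_venomcomp(
      sprintf("band(s) in hits without densitometric proportion: %s",
              paste(missing_bands, collapse = ", ")),
      "venomcomp_validation_error"
    )
  }

  band_auc <- rowsum(hits$auc, hits$band_id)
  live <- rownames(band_auc)[band_auc[, 1] > 0]
  dead <- setdiff(names(prop)[prop > 0], live)
  if (length(dead) > 0) {
    if (zero_band_policy == "error") {
      stop_venomcomp(
        sprintf("band(s) with positive proportion but no toxin signal: %s",
                paste(dead, collapse = ", ")),
        "venomcomp_policy_error"
      )
    }
    prop <- prop[names(prop) %in% live]
    prop <- prop / sum(prop)
  }

  accs <- unique(hits$accession)
  percent <- setNames(numeric(length(accs)), accs)
  n_bands <- setNames(integer(length(accs)), accs)
  n_hits <- setNames(integer(length(accs)), accs)
  for (b in live) {
    in_band <- hits[hits$band_id == b, , drop = FALSE]
    frac <- band_relative_auc(in_band)
    percent[names(frac)] <- percent[names(frac)] + frac * prop[b]
    n_bands[names(frac)] <- n_bands[names(frac)] + 1L
    tab <- table(in_band$accession)
    n_hits[names(tab)] <- n_hits[names(tab)] + as.integer(tab)
  }
  provenance <- data.frame(label = accs, n_bands = as.integer(n_bands),
                           n_hits = as.integer(n_hits),
                           stringsAsFactors = FALSE)
  composition_table(100 * percent, level = "protein", provenance = provenance)
}

annotation_lookup <- function(annotations) {
  if (is.data.frame(annotations)) {
    setNames(annotations$family, annotations$accession)
  } else {
    annotations
  }
}

#' Aggregate a protein-level composition to toxin families
#'
#' Family percentages are the exact sums of their members' percentages, so
#' the table total is preserved.
#'
#' @param table a protein-level [composition_table()].
#' @param annotations annotation data frame from [read_annotation_map()] or
#'   a named character vector \code{accession -> family}.
#' @return A family-level \code{composition_table}, sorted by descending
#'   percentage.
#' @export
aggregate_families <- function(table, annotations) {
  fam <- annotation_lookup(annotations)
  unknown <- setdiff(table$label, names(fam))
  if (length(unknown) > 0) {
    stop_venomcomp(
      sprintf("unannotated accession(s): %s", paste(unknown, collapse = ", ")),
      "venomcomp_validation_error"
    )
  }
  groups <- fam[table$label]
  agg <- rowsum(table$percent, groups, reorder = FALSE)
  percent <- setNames(agg[, 1], rownames(agg))
  percent <- percent[order(-percent)]
  composition_table(percent, level = "family")
}

#' Proteome-to-transcriptome translation index
#'
#' For each toxin family, the ratio of its venom proteome percentage to its
#' venom-gland transcriptome percentage. Values above 1 indicate a family
#' that is over-translated relative to its transcription. Families absent
#' from one table get 0 on that side; the index is undefined
#' (\code{defined = FALSE}, index \code{NA}) exactly when the transcriptome
#' percentage is 0.
#'
#' @param proteome,transcriptome family-level [composition_table()]s.
#' @return A \code{translation_index} data frame with columns \code{family},
#'   \code{proteome_percent}, \code{transcriptome_percent}, \code{index},
#'   \code{defined}.
#' @export
translation_index <- function(proteome, transcriptome) {
  if (!identical(attr(proteome, "level"), "family") ||
      !identical(attr(transcriptome, "level"), "family")) {
    stop_venomcomp("both tables must be at family level",
                   "venomcomp_validation_error")
  }
  fams <- union(proteome$label, transcriptome$label)
  p <- setNames(rep(0, length(fams)), fams)
  t <- setNames(rep(0, length(fams)), fams)
  p[proteome$label] <- proteome$percent
  t[transcriptome$label] <- transcriptome$percent
  defined <- t > 0
  idx <- ifelse(defined, p / t, NA_real_)
  df <- data.frame(family = fams, proteome_percent = as.numeric(p),
                   transcriptome_percent = as.numeric(t),
                   index = as.numeric(idx), defined = defined,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df[order(-df$proteome_percent), , drop = FALSE],
            class = c("translation_index", "data.frame"))
}

#' Estimate translation-efficiency folds from a translation-index table
#'
#' Because proteome and transcriptome compositions are each closed to 100\%,
#' raw translation indices determine the underlying per-family translation
#' efficiencies only up to one global scale factor (multiplying every
#' efficiency by a constant leaves both compositions unchanged). This
#' estimator resolves the scale by centring the defined indices on their
#' median (or geometric mean), under the usual assumption that most families
#' are translated at baseline efficiency; a family's centred index then
#' estimates its efficiency fold relative to that baseline.
#'
#' @param index a [translation_index()] table.
#' @param center \code{"median"} (robust default) or \code{"geomean"}.
#' @return \code{index} with an added \code{fold_estimate} column (NA where
#'   the index is undefined).
#' @export
estimate_translation_fold <- function(index, center = c("median", "geomean")) {
  center <- match.arg(center)
  idx <- index$index[index$defined]
  if (length(idx) == 0) {
    stop_venomcomp("no defined translation indices to centre",
                   "venomcomp_degenerate_error")
  }
  scale <- if (center == "median") stats::median(idx) else exp(mean(log(idx)))
  index$fold_estimate <- index$index / scale
  index
}
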