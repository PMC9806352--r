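#' Identification quality-filter settings
#'
#' Defaults follow the standard stringent gel-band search regime: protein
#' score (\eqn{-10 \log_{10} p}) of at least 50, at least one unique
#' peptide, peptide-spectrum FDR of 0.1\% (enforced upstream by the search
#' engine; the value is carried for reporting), and exclusion of common
#' contaminants (cRAP-style entries) and decoys by accession prefix.
#'
#' @param min_score minimum protein score, inclusive.
#' @param min_unique_peptides minimum unique-peptide count, inclusive.
#' @param max_fdr search-level FDR setting (proportion), recorded in run
#'   summaries; filtering itself operates on score/peptides/contaminants.
#' @param contaminant_prefixes accession prefixes (or exact accessions)
#'   marking contaminant and decoy entries.
#' @return A \code{filter_config} list.
#' @export
filter_config <- function(min_score = 50, min_unique_peptides = 1,
                          max_fdr = 0.001,
                          contaminant_prefixes = c("CRAP_", "DECOY_")) {
  if (min_score < 0 || min_unique_peptides < 0 || max_fdr < 0 || max_fdr > 1) {
    stop_venomcomp("invalid filter thresholds", "venomcomp_validation_error")
  }
  structure(list(min_score = min_score,
                 min_unique_peptides = min_unique_peptides,
                 max_fdr = max_fdr,
                 contaminant_prefixes = as.character(contaminant_prefixes)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(paste0("Quality filters: score >= %g, unique peptides >= %g, ",
                     "FDR <= %g%%\n"),
              x$min_score, x$min_unique_peptides, 100 * x$max_fdr))
  cat(sprintf("Contaminant/decoy prefixes: %s\n",
              paste(x$contaminant_prefixes, collapse = ", ")))
  invisible(x)
}

#' Flag contaminant hits by accession
#'
#' Sets \code{is_contaminant} to \code{TRUE} where the accession equals an
#' entry of \code{contaminants} or starts with one of them (cRAP naming
#' conventions vary, so both exact accessions and prefixes are supported).
#' All other fields are unchanged.
#'
#' @param hits a \code{spectral_hits} table.
#' @param contaminants character vector of exact accessions and/or prefixes.
#' @return \code{hits} with \code{is_contaminant} updated.
#' @export
flag_contaminants <- function(hits, contaminants) {
  if (length(contaminants) == 0) return(hits)
  flagged <- rep(FALSE, nrow(hits))
  for (p in contaminants) {
    flagged <- flagged | hits$accession == p | startsWith(hits$accession, p)
  }
  hits$is_contaminant <- hits$is_contaminant | flagged
  hits
}

#' Apply identification quality filters
#'
#' Retains exactly the hits with \code{score >= min_score},
#' \code{unique_peptides >= min_unique_peptides} (both inclusive) and
#' \code{is_contaminant == FALSE}. Counts of hits removed by each criterion
#' are attached as \code{attr(x, "removed")} (a hit failing several criteria
#' is counted once per criterion).
#'
#' @param hits a \code{spectral_hits} table (run [flag_contaminants()] first
#'   if contaminants are identified by accession).
#' @param config a [filter_config()].
#' @return the retained \code{spectral_hits}; an empty result is legal.
#' @export
apply_quality_filters <- function(hits, config = filter_config()) {
  fail_score <- hits$score < config$min_score
  fail_unique <- hits$unique_peptides < config$min_unique_peptides
  fail_contam <- hits$is_contaminant
  keep <- !(fail_score | fail_unique | fail_contam)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(score = sum(fail_score),
                            unique_peptides = sum(fail_unique),
                            contaminant = sum(fail_contam))
  attr(out, "n_merged") <- attr(hits, "n_merged")
  class(out) <- class(hits)
  out
}

#' Target-decoy FDR estimate at a score threshold
#'
#' Standard target-decoy estimate: the number of decoy hits at or above the
#' threshold divided by the number of target hits at or above it. Intended
#' for synthetic datasets carrying planted decoys; real search exports
#' normally arrive with FDR already controlled by the engine.
#'
#' @param hits a \code{spectral_hits} table containing target and decoy
#'   accessions.
#' @param decoy_prefix accession prefix marking decoys.
#' @param score_threshold score cutoff (inclusive).
#' @return list with \code{fdr} (NA when no targets pass), \code{defined},
#'   \code{n_decoys}, \code{n_targets}.
#' @export
estimate_decoy_fdr <- function(hits, decoy_prefix = "DECOY_",
                               score_threshold = 50) {
  is_decoy <- startsWith(hits$accession, decoy_prefix)
  pass <- hits$score >= score_threshold
  n_decoys <- sum(is_decoy & pass)
  n_targets <- sum(!is_decoy & pass)
  if (n_targets == 0) {
    return(list(fdr = if (n_decoys == 0) 0 else NA_real_,
                defined = n_decoys == 0,
                n_decoys = n_decoys, n_targets = n_targets))
  }
  list(fdr = n_decoys / n_targets, defined = TRUE,
       n_decoys = n_decoys, n_targets = n_targets)
}
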