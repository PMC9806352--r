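#' End-to-end composition quantification (in memory)
#'
#' Convenience wrapper chaining the pipeline stages on in-memory objects:
#' contaminant flagging, quality filtering, restriction to toxin-annotated
#' accessions, band-weighted relative abundance, and family aggregation.
#'
#' @param hits a \code{spectral_hits} table (raw; flagging and filtering are
#'   applied here).
#' @param proportions band proportions (see [relative_abundance()]).
#' @param annotations annotation data frame from [read_annotation_map()].
#' @param config a [filter_config()].
#' @param zero_band_policy see [relative_abundance()].
#' @return list with \code{protein} and \code{family}
#'   [composition_table()]s, plus filtering bookkeeping (\code{n_input},
#'   \code{n_retained}, \code{removed}, \code{n_non_toxin}).
#' @export
quantify_composition <- function(hits, proportions, annotations,
                                 config = filter_config(),
                                 zero_band_policy = c("renormalise", "error")) {
  zero_band_policy <- match.arg(zero_band_policy)
  flagged <- flag_contaminants(hits, config$contaminant_prefixes)
  kept <- apply_quality_filters(flagged, config)
  removed <- attr(kept, "removed")

  unknown <- setdiff(kept$accession, annotations$accession)
  if (length(unknown) > 0) {
    stop_venomcomp(
      sprintf("unannotated accession(s) after filtering: %s",
              paste(unknown, collapse = ", ")),
      "venomcomp_validation_error"
    )
  }
  toxin_acc <- annotations$accession[annotations$is_toxin]
  n_non_toxin <- sum(!kept$accession %in% toxin_acc)
  toxin_hits <- kept[kept$accession %in% toxin_acc, , drop = FALSE]
  class(toxin_hits) <- class(kept)

  protein <- relative_abundance(toxin_hits, proportions,
                                zero_band_policy = zero_band_policy)
  family <- aggregate_families(protein, annotations)
  list(protein = protein, family = family,
       n_input = nrow(hits), n_retained = nrow(kept),
       removed = as.list(removed), n_non_toxin = n_non_toxin)
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop_venomcomp(sprintf("missing %s file: %s", what,
                           if (is.null(path)) "(not given)" else path),
                   "venomcomp_input_error")
  }
  path
}

#' Run the quantification pipeline on files
#'
#' Reads a spectral-hit export plus either a precomputed band-area table or
#' a lane profile with band definitions (baseline-corrected and integrated
#' here), quantifies the venom composition, and writes
#' \code{protein_composition.csv}, \code{family_composition.csv} and a
#' machine-readable \code{summary.json} (thresholds used, discarded-hit
#' counts, bands analysed, policy applied, config hash) into
#' \code{out_dir}. Outputs are byte-deterministic for identical inputs and
#' configuration. Errors signal conditions of class
#' \code{venomcomp_input_error} (missing/invalid inputs) or
#' \code{venomcomp_policy_error} (zero-toxin band in audit mode).
#'
#' @param hits_file CSV of spectral hits.
#' @param annotations_file TSV annotation map.
#' @param out_dir output directory (created if needed).
#' @param band_areas_file TSV of precomputed band areas; mutually exclusive
#'   with \code{profile_file}/\code{bands_file}.
#' @param profile_file,bands_file lane profile and band definition TSVs.
#' @param config a [filter_config()].
#' @param zero_band_policy see [relative_abundance()].
#' @return the [quantify_composition()] result, invisibly.
#' @export
run_quantify <- function(hits_file, annotations_file, out_dir,
                         band_areas_file = NULL, profile_file = NULL,
                         bands_file = NULL, config = filter_config(),
                         zero_band_policy = c("renormalise", "error")) {
  zero_band_policy <- match.arg(zero_band_policy)
  hits <- read_spectral_hits(require_file(hits_file, "spectral hits"))
  annotations <- read_annotation_map(require_file(annotations_file, "annotations"))
  if (!is.null(band_areas_file) && (!is.null(profile_file) || !is.null(bands_file))) {
    stop_venomcomp("give either band_areas_file or profile_file+bands_file, not both",
                   "venomcomp_input_error")
  }
  if (!is.null(band_areas_file)) {
    proportions <- proportions_from_areas(
      read_band_areas(require_file(band_areas_file, "band areas")))
  } else {
    profile <- read_lane_profile(require_file(profile_file, "lane profile"))
    bands <- read_band_definitions(require_file(bands_file, "band definitions"))
    proportions <- integrate_bands(subtract_baseline(profile, bands), bands)
  }

  res <- quantify_composition(hits, proportions, annotations,
                              config = config,
                              zero_band_policy = zero_band_policy)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_cfg <- list(filters = unclass(config), zero_band_policy = zero_band_policy)
  write_composition(res$protein, file.path(out_dir, "protein_composition.csv"),
                    config = run_cfg)
  write_composition(res$family, file.path(out_dir, "family_composition.csv"),
                    config = run_cfg)
  jsonlite::write_json(list(
    tool = "venomcomp",
    version = as.character(utils::packageVersion("venomcomp")),
    config_hash = config_hash(run_cfg),
    thresholds = list(min_score = config$min_score,
                      min_unique_peptides = config$min_unique_peptides,
                      max_fdr = config$max_fdr,
                      contaminant_prefixes = config$contaminant_prefixes),
    zero_band_policy = zero_band_policy,
    n_input_hits = res$n_input,
    n_retained_hits = res$n_retained,
    removed = res$removed,
    n_non_toxin_excluded = res$n_non_toxin,
    bands_analysed = if (is.data.frame(proportions)) proportions$band_id else names(proportions),
    n_proteins = nrow(res$protein),
    n_families = nrow(res$family)
  ), file.path(out_dir, "summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Compare a venom proteome against the venom-gland transcriptome
#'
#' Reads a proteome composition CSV (from [run_quantify()] or
#' [write_composition()]), a transcript quantification TSV and the
#' annotation map; computes family-level transcriptome percentages over
#' toxin transcripts and the per-family translation index; writes a CSV with
#' columns \code{family, proteome_percent, transcriptome_percent, index,
#' defined}. Disjoint family sets produce a warning, not an error.
#'
#' @param proteome_file composition CSV at family level.
#' @param quant_file RSEM-style TSV; TPM recomputed when absent.
#' @param annotations_file TSV annotation map (transcript ids).
#' @param out_file destination CSV (optional).
#' @return the [translation_index()] table, invisibly when writing.
#' @export
run_compare <- function(proteome_file, quant_file, annotations_file,
                        out_file = NULL) {
  proteome <- read_composition(require_file(proteome_file, "proteome composition"))
  quant <- read_transcript_quant(require_file(quant_file, "transcript quantification"))
  annotations <- read_annotation_map(require_file(annotations_file, "annotations"))
  if (anyNA(quant$tpm)) quant <- compute_tpm(quant)
  transcriptome <- family_transcript_abundance(quant, annotations)
  if (length(intersect(proteome$label, transcriptome$label)) == 0) {
    warning("proteome and transcriptome share no family labels")
  }
  idx <- translation_index(proteome, transcriptome)
  if (!is.null(out_file)) {
    con <- file(out_file, "wb")
    on.exit(close(con))
    writeLines(c(output_header(),
                 "family,proteome_percent,transcriptome_percent,index,defined",
                 sprintf("%s,%s,%s,%s,%s", idx$family,
                         num_chr(idx$proteome_percent),
                         num_chr(idx$transcriptome_percent),
                         ifelse(idx$defined, num_chr(idx$index), "NA"),
                         idx$defined)), con, sep = "\n")
    return(invisible(idx))
  }
  idx
}

#' Run assay unit calculations from a measurement CSV
#'
#' The input CSV has one row per well with columns \code{role} (one of
#' \code{sample}, \code{control}, \code{blank}, \code{positive},
#' \code{standard}), \code{label}, \code{absorbance}, and, depending on the
#' assay, \code{venom_mass_mg}, \code{time_min}, \code{amount_nmol},
#' \code{time_s}, \code{censored}, \code{censoring_limit}.
#'
#' Per assay type:
#' \describe{
#'   \item{hyaluronidase}{control row + sample rows; TRU activity per sample
#'     ([turbidity_reduction_units()]).}
#'   \item{phospholipase}{standard rows fit the curve; sample activities via
#'     [specific_activity_from_curve()].}
#'   \item{haemolysis}{blank + positive rows required; percentages via
#'     [relative_haemolysis()].}
#'   \item{coagulation}{control row + venom rows with \code{time_s};
#'     [clotting_delay()] per row.}
#' }
#' Sample rows also get a \code{fold_vs_reference} column (ratio of each
#' sample's activity to the first sample row's), the fold-difference report
#' between labelled venoms.
#'
#' @param assay_file measurement CSV.
#' @param type assay type.
#' @param out_file optional destination CSV (with version header).
#' @return data frame of per-sample results.
#' @export
run_assay <- function(assay_file,
                      type = c("hyaluronidase", "phospholipase",
                               "haemolysis", "coagulation"),
                      out_file = NULL) {
  type <- match.arg(type)
  df <- utils::read.csv(require_file(assay_file, "assay"), header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("role", "label") %in% names(df))) {
    stop_venomcomp("assay file needs 'role' and 'label' columns",
                   "venomcomp_format_error")
  }
  samples <- df[df$role == "sample", , drop = FALSE]

  if (type == "hyaluronidase") {
    ctrl <- df[df$role == "control", , drop = FALSE]
    if (nrow(ctrl) != 1) {
      stop_venomcomp("hyaluronidase assay needs exactly one control row",
                     "venomcomp_input_error")
    }
    act <- vapply(seq_len(nrow(samples)), function(i) {
      turbidity_reduction_units(ctrl$absorbance, samples$absorbance[i],
                                samples$venom_mass_mg[i],
                                samples$time_min[i])$activity
    }, numeric(1))
    out <- data.frame(label = samples$label, activity = act,
                      unit = "TRU.mg-1.min-1", stringsAsFactors = FALSE)
  } else if (type == "phospholipase") {
    std <- df[df$role == "standard", , drop = FALSE]
    if (nrow(std) < 2) {
      stop_venomcomp("phospholipase assay needs >= 2 standard rows",
                     "venomcomp_input_error")
    }
    curve <- fit_standard_curve(std$amount_nmol, std$absorbance)
    act <- vapply(seq_len(nrow(samples)), function(i) {
      specific_activity_from_curve(curve, samples$absorbance[i],
                                   samples$venom_mass_mg[i],
                                   samples$time_min[i])$activity
    }, numeric(1))
    out <- data.frame(label = samples$label, activity = act,
                      unit = "nmol.mg-1.min-1", stringsAsFactors = FALSE)
  } else if (type == "haemolysis") {
    blank <- df[df$role == "blank", , drop = FALSE]
    pos <- df[df$role == "positive", , drop = FALSE]
    if (nrow(pos) != 1) {
      stop_venomcomp("haemolysis assay needs exactly one positive-control row",
                     "venomcomp_input_error")
    }
    a_blank <- if (nrow(blank) == 1) blank$absorbance else 0
    act <- vapply(samples$absorbance, relative_haemolysis, numeric(1),
                  a_blank = a_blank, a_positive = pos$absorbance)
    out <- data.frame(label = samples$label, activity = act,
                      unit = "percent_of_positive_control",
                      stringsAsFactors = FALSE)
  } else {
    ctrl <- df[df$role == "control", , drop = FALSE]
    if (nrow(ctrl) != 1) {
      stop_venomcomp("coagulation assay needs exactly one control row",
                     "venomcomp_input_error")
    }
    if (is.null(samples$censored)) samples$censored <- FALSE
    res <- lapply(seq_len(nrow(samples)), function(i) {
      clotting_delay(ctrl$time_s, samples$time_s[i],
                     censored = isTRUE(as.logical(samples$censored[i])))
    })
    out <- data.frame(label = samples$label,
                      time_s = samples$time_s,
                      delay_s = vapply(res, `[[`, 0, "delay_s"),
                      fold = vapply(res, `[[`, 0, "fold"),
                      fold_is_lower_bound = vapply(res, `[[`, TRUE,
                                                   "fold_is_lower_bound"),
                      stringsAsFactors = FALSE)
    out$activity <- out$fold
  }

  out$fold_vs_reference <- if (nrow(out) > 0) out$activity / out$activity[1] else numeric(0)
  if (!is.null(out_file)) {
    con <- file(out_file, "wb")
    num <- vapply(out, is.numeric, TRUE)
    o <- out
    for (col in names(o)[num]) o[[col]] <- num_chr(o[[col]])
    writeLines(c(output_header(list(type = type)),
                 paste(names(o), collapse = ","),
                 do.call(paste, c(unname(o), sep = ","))), con, sep = "\n")
    close(con)
  }
  out
}
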