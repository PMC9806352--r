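#' Construct and validate a table of spectral hits
#'
#' A spectral hit is one protein identification in one gel band, carrying the
#' search engine's protein confidence score (\eqn{-10 \log_{10} p}), the
#' number of unique peptides supporting the identification, and the spectral
#' intensity area under the curve (AUC) used as the label-free abundance
#' proxy.
#'
#' @param df data frame with columns \code{band_id}, \code{accession},
#'   \code{score}, \code{unique_peptides}, \code{auc}; optional
#'   \code{description} and logical \code{is_contaminant}.
#' @param merge_duplicates merge repeated \code{(band_id, accession)} rows by
#'   summing their AUC (search exports commonly split rows by protein-group
#'   member). Non-AUC fields are taken from the first occurrence.
#' @return A \code{spectral_hits} data frame with one row per
#'   \code{(band_id, accession)} pair. The number of rows merged away is
#'   stored in \code{attr(x, "n_merged")}.
#' @export
spectral_hits <- function(df, merge_duplicates = TRUE) {
  required <- c("band_id", "accession", "score", "unique_peptides", "auc")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  df$band_id <- as.character(df$band_id)
  df$accession <- as.character(df$accession)
  for (col in c("score", "unique_peptides", "auc")) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop_venomcomp(
        sprintf("column '%s' not numeric at row(s) %s", col,
                paste(which(is.na(v)), collapse = ", ")),
        "venomcomp_format_error"
      )
    }
    df[[col]] <- v
  }
  bad <- which(df$auc < 0 | df$score < 0)
  if (length(bad) > 0) {
    stop_venomcomp(
      sprintf("negative score/auc at row(s) %s", paste(bad, collapse = ", ")),
      "venomcomp_validation_error"
    )
  }
  if (any(df$unique_peptides < 0) || any(df$unique_peptides != round(df$unique_peptides))) {
    stop_venomcomp("unique_peptides must be non-negative integers",
                   "venomcomp_validation_error")
  }
  if (is.null(df$description)) df$description <- ""
  if (is.null(df$is_contaminant)) df$is_contaminant <- FALSE
  df$is_contaminant <- as.logical(df$is_contaminant)

  n_merged <- 0L
  key <- paste(df$band_id, df$accession, sep = "\r")
  if (merge_duplicates && anyDuplicated(key)) {
    n_merged <- sum(duplicated(key))
    auc_sum <- rowsum(df$auc, key, reorder = FALSE)
    first <- df[!duplicated(key), , drop = FALSE]
    first$auc <- as.vector(auc_sum[match(paste(first$band_id, first$accession, sep = "\r"),
                                         rownames(auc_sum)), 1])
    df <- first
  }
  rownames(df) <- NULL
  structure(df, n_merged = n_merged,
            class = c("spectral_hits", "data.frame"))
}

#' Read a per-band protein identification export
#'
#' Reads a CSV export from a database-search engine: one row per protein
#' identification per gel band, with a mandatory header. Duplicate
#' \code{(band_id, accession)} rows are merged by summing their AUC.
#'
#' @param file path or connection to a CSV file with columns
#'   \code{band_id, accession, score, unique_peptides, auc} (plus optional
#'   \code{description}; unknown extra columns are kept and ignored by all
#'   computations).
#' @return A \code{spectral_hits} data frame; see [spectral_hits()].
#' @export
read_spectral_hits <- function(file) {
  df <- utils::read.csv(file, header = TRUE, stringsAsFactors = FALSE,
                        comment.char = "#")
  spectral_hits(df)
}

#' Read a toxin-family annotation map
#'
#' @param file TSV with columns \code{accession}, \code{family},
#'   \code{is_toxin} (logical or 0/1). One record per accession; exact
#'   duplicate rows are deduplicated, conflicting family assignments are an
#'   error.
#' @return data frame with columns \code{accession}, \code{family},
#'   \code{is_toxin}.
#' @export
read_annotation_map <- function(file) {
  df <- utils::read.csv(file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
  required <- c("accession", "family", "is_toxin")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  df$accession <- as.character(df$accession)
  df$family <- as.character(df$family)
  df$is_toxin <- as.logical(df$is_toxin)
  df <- unique(df[required])
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    stop_venomcomp(
      sprintf("conflicting annotations for accession(s): %s",
              paste(unique(dup), collapse = ", ")),
      "venomcomp_validation_error"
    )
  }
  bad <- df$is_toxin & (is.na(df$family) | !nzchar(df$family))
  if (any(bad)) {
    stop_venomcomp(
      sprintf("toxin accession(s) without family label: %s",
              paste(df$accession[bad], collapse = ", ")),
      "venomcomp_validation_error"
    )
  }
  rownames(df) <- NULL
  df
}

#' Read an RSEM-style transcript quantification table
#'
#' @param file TSV in the RSEM \code{.results} column convention:
#'   \code{transcript_id, length, effective_length, expected_count} and
#'   optionally \code{TPM}. When \code{TPM} is absent the column is returned
#'   as \code{NA} for [compute_tpm()] to fill.
#' @return data frame with columns \code{transcript_id}, \code{length},
#'   \code{effective_length}, \code{expected_count}, \code{tpm}.
#' @export
read_transcript_quant <- function(file) {
  df <- utils::read.csv(file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
  required <- c("transcript_id", "length", "effective_length", "expected_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  out <- data.frame(
    transcript_id = as.character(df$transcript_id),
    length = as.numeric(df$length),
    effective_length = as.numeric(df$effective_length),
    expected_count = as.numeric(df$expected_count),
    tpm = if ("TPM" %in% names(df)) as.numeric(df$TPM) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(out$length <= 0) || any(out$effective_length <= 0)) {
    stop_venomcomp("length and effective_length must be > 0",
                   "venomcomp_validation_error")
  }
  if (any(out$effective_length > out$length)) {
    stop_venomcomp("effective_length exceeds length for some transcripts",
                   "venomcomp_validation_error")
  }
  if (any(out$expected_count < 0)) {
    stop_venomcomp("expected_count must be >= 0", "venomcomp_validation_error")
  }
  out
}

#' Construct a lane densitometry profile
#'
#' @param position strictly increasing migration coordinates (arbitrary
#'   units).
#' @param intensity non-negative densitometric values, one per position.
#' @return A \code{lane_profile} data frame.
#' @export
lane_profile <- function(position, intensity) {
  position <- as.numeric(position)
  intensity <- as.numeric(intensity)
  if (length(position) != length(intensity)) {
    stop_venomcomp("position and intensity must have equal length",
                   "venomcomp_validation_error")
  }
  if (length(position) < 2 || any(diff(position) <= 0)) {
    stop_venomcomp("positions must be strictly increasing (>= 2 points)",
                   "venomcomp_validation_error")
  }
  if (any(intensity < 0)) {
    stop_venomcomp("intensities must be >= 0", "venomcomp_validation_error")
  }
  structure(data.frame(position = position, intensity = intensity),
            class = c("lane_profile", "data.frame"))
}

#' Read a lane densitometry profile
#'
#' @param file 2-column TSV with header \code{position, intensity}.
#' @return A \code{lane_profile} data frame.
#' @export
read_lane_profile <- function(file) {
  df <- utils::read.csv(file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c("position", "intensity"), names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  lane_profile(df$position, df$intensity)
}

#' Construct gel-band definitions
#'
#' Bands are half-open migration intervals \code{[start, end)}; adjacent
#' bands therefore partition cleanly. Intervals within one lane must be
#' pairwise disjoint.
#'
#' @param band_id character band labels.
#' @param start,end numeric interval endpoints with \code{start < end}.
#' @return A \code{band_definitions} data frame.
#' @export
band_definitions <- function(band_id, start, end) {
  band_id <- as.character(band_id)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyDuplicated(band_id)) {
    stop_venomcomp("duplicate band_id", "venomcomp_validation_error")
  }
  if (any(start >= end)) {
    stop_venomcomp("band start must be < end", "venomcomp_validation_error")
  }
  o <- order(start)
  if (any(end[o][-length(o)] > start[o][-1])) {
    stop_venomcomp("band intervals overlap", "venomcomp_validation_error")
  }
  structure(data.frame(band_id = band_id, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("band_definitions", "data.frame"))
}

#' Read band definitions from a TSV file
#'
#' @param file TSV with columns \code{band_id, start, end}.
#' @return A \code{band_definitions} data frame; see [band_definitions()].
#' @export
read_band_definitions <- function(file) {
  df <- utils::read.csv(file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c("band_id", "start", "end"), names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  band_definitions(df$band_id, df$start, df$end)
}

#' Read a precomputed band-area table
#'
#' Entry point for lanes quantified in external gel software.
#'
#' @param file TSV with columns \code{band_id, area}.
#' @return named numeric vector of areas.
#' @export
read_band_areas <- function(file) {
  df <- utils::read.csv(file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c("band_id", "area"), names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  setNames(as.numeric(df$area), as.character(df$band_id))
}

#' Construct a composition table
#'
#' The pipeline's headline output: relative-abundance percentages per toxin
#' (level \code{"protein"}) or per toxin family (level \code{"family"}).
#' Percentages are kept at full precision internally; rounding happens only
#' on display and in the rounded column of the CSV output.
#'
#' @param percent named numeric vector of percentages (names are accessions
#'   or family labels), all \code{>= 0}.
#' @param level \code{"protein"} or \code{"family"}.
#' @param provenance optional data frame of per-label bookkeeping (e.g.
#'   contributing band and hit counts).
#' @return A \code{composition_table} data frame with columns \code{label},
#'   \code{percent}.
#' @export
composition_table <- function(percent, level = c("protein", "family"),
                              provenance = NULL) {
  level <- match.arg(level)
  if (is.data.frame(percent)) {
    percent <- setNames(percent$percent, percent$label)
  }
  if (any(percent < 0)) {
    stop_venomcomp("percentages must be >= 0", "venomcomp_validation_error")
  }
  df <- data.frame(label = names(percent), percent = as.numeric(percent),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, level = level, provenance = provenance,
            class = c("composition_table", "data.frame"))
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Venom composition (%s level): %d entries, total %.4f%%\n",
              attr(x, "level"), nrow(x), sum(x$percent)))
  df <- data.frame(label = x$label, percent = round(x$percent, 2))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.composition_table <- function(object, ...) {
  o <- object[order(-object$percent), , drop = FALSE]
  cat(sprintf("Composition at %s level\n", attr(object, "level")))
  cat(sprintf("  entries: %d, total: %.6f%%\n", nrow(o), sum(o$percent)))
  if (nrow(o) > 0) {
    cat(sprintf("  dominant: %s (%.2f%%)\n", o$label[1], o$percent[1]))
  }
  invisible(object)
}

#' Doughnut-style chart of a composition table
#'
#' @param x a \code{composition_table}.
#' @param inner.radius radius of the blank centre, as a fraction of the pie
#'   radius (0 gives an ordinary pie chart).
#' @param ... passed on to \code{\link[graphics]{pie}}.
#' @export
plot.composition_table <- function(x, inner.radius = 0.5, ...) {
  o <- x[order(-x$percent), , drop = FALSE]
  labs <- sprintf("%s (%.2f%%)", o$label, o$percent)
  graphics::pie(o$percent, labels = labs, ...)
  if (inner.radius > 0) {
    graphics::symbols(0, 0, circles = inner.radius * 0.8, inches = FALSE,
                      add = TRUE, bg = "white", fg = "white")
  }
  invisible(x)
}

#' Write a composition table to CSV
#'
#' Columns: \code{family} (the label), \code{percent} rounded to 2 decimals
#' for reporting, and \code{percent_full} at full precision so that
#' \code{read_composition(write_composition(x))} reproduces \code{x}
#' exactly. A comment header records the tool version (and, when supplied, a
#' configuration hash).
#'
#' @param table a \code{composition_table}.
#' @param file destination path.
#' @param config optional run configuration to fingerprint in the header.
#' @return \code{file}, invisibly.
#' @export
write_composition <- function(table, file, config = NULL) {
  lines <- c(
    output_header(config),
    sprintf("# level: %s", attr(table, "level") %||% "family"),
    "family,percent,percent_full"
  )
  if (nrow(table) > 0) {
    lines <- c(lines, sprintf("%s,%.2f,%s", table$label,
                              round(table$percent, 2), num_chr(table$percent)))
  }
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a composition table written by [write_composition()]
#'
#' @param file path to the CSV.
#' @return A \code{composition_table} at full precision.
#' @export
read_composition <- function(file) {
  first <- readLines(file, n = 5L)
  lvl <- sub("^# level: ", "", grep("^# level: ", first, value = TRUE))
  if (length(lvl) != 1 || !lvl %in% c("protein", "family")) lvl <- "family"
  df <- utils::read.csv(file, header = TRUE, stringsAsFactors = FALSE,
                        comment.char = "#")
  missing <- setdiff(c("family", "percent_full"), names(df))
  if (length(missing) > 0) {
    stop_venomcomp(
      sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      "venomcomp_format_error"
    )
  }
  if (nrow(df) == 0) {
    return(composition_table(setNames(numeric(0), character(0)), level = lvl))
  }
  composition_table(setNames(as.numeric(df$percent_full),
                             as.character(df$family)), level = lvl)
}
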