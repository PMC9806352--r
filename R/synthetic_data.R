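default_families <- function() {
  # family labels and venom-proteome-like default composition (percent scale)
  fams <- c("CAP", "PLA1", "TRY", "HYL", "DPP", "LAAO", "SP",
            "AP", "CP", "PLA2i", "PLA2", "CHI", "CHY", "PER")
  pct <- c(26.09, 21.86, 18.95, 15.20, 6.87, 6.79, 1.91,
           0.93, 0.58, 0.45, 0.17, 0.11, 0.08, 0.02)
  setNames(pct / sum(pct), fams)
}

#' Ground truth for a synthetic proteotranscriptomic dataset
#'
#' Describes the planted state a synthetic dataset is generated from: the
#' true family composition of the venom (a simplex \eqn{\pi}), how many
#' proteins and transcripts realise each family, the proteins' molecular
#' weights (which determine gel migration), per-family translation
#' efficiencies \eqn{\tau} (proteome share relative to transcriptome share),
#' the multiplicative log-normal noise on spectral intensities, and the
#' numbers of planted contaminants and decoys.
#'
#' @param families character vector of family labels; defaults to a
#'   14-family wasp-venom-like panel.
#' @param composition numeric vector of true family mass shares (normalised
#'   to sum to 1); defaults to a hornet-venom-like composition for the
#'   default panel, equal shares otherwise.
#' @param proteins_per_family proteins realising each family.
#' @param molecular_weights optional kDa per protein (length
#'   \code{families * proteins_per_family}); drawn log-uniformly in 10-100
#'   kDa when \code{NULL}.
#' @param translation_efficiency per-family fold multiplier \eqn{\tau}
#'   (recycled); transcriptome shares are proportional to
#'   \eqn{\pi_f / \tau_f}.
#' @param noise_sd_log SD of the log-normal multiplicative noise applied to
#'   spectral AUCs and per-transcript abundances.
#' @param n_contaminants,n_decoys planted cRAP-style contaminants
#'   (\code{CRAP_} prefix) and decoys (\code{DECOY_} prefix).
#' @param transcripts_per_family transcripts realising each family.
#' @param seed integer seed; the single source of randomness for
#'   [simulate_venom_dataset()].
#' @return A \code{synthetic_truth} list.
#' @export
synthetic_truth <- function(families = NULL, composition = NULL,
                            proteins_per_family = 2,
                            molecular_weights = NULL,
                            translation_efficiency = 1,
                            noise_sd_log = 0.2,
                            n_contaminants = 3, n_decoys = 5,
                            transcripts_per_family = 3, seed = 1) {
  if (is.null(families)) {
    def <- default_families()
    families <- names(def)
    if (is.null(composition)) composition <- unname(def)
  }
  families <- as.character(families)
  if (is.null(composition)) composition <- rep(1 / length(families), length(families))
  if (length(composition) != length(families) || any(composition < 0)) {
    stop_venomcomp("composition must be non-negative, one entry per family",
                   "venomcomp_validation_error")
  }
  composition <- composition / sum(composition)
  tau <- rep_len(translation_efficiency, length(families))
  if (any(tau < 0)) {
    stop_venomcomp("translation efficiencies must be >= 0",
                   "venomcomp_validation_error")
  }
  if (noise_sd_log < 0) {
    stop_venomcomp("noise_sd_log must be >= 0", "venomcomp_validation_error")
  }
  n_prot <- length(families) * proteins_per_family
  if (!is.null(molecular_weights) && length(molecular_weights) != n_prot) {
    stop_venomcomp("molecular_weights must have one entry per protein",
                   "venomcomp_validation_error")
  }
  structure(list(
    families = families,
    composition = setNames(composition, families),
    proteins_per_family = as.integer(proteins_per_family),
    molecular_weights = molecular_weights,
    translation_efficiency = setNames(tau, families),
    noise_sd_log = noise_sd_log,
    n_contaminants = as.integer(n_contaminants),
    n_decoys = as.integer(n_decoys),
    transcripts_per_family = as.integer(transcripts_per_family),
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d families x %d proteins, seed %d\n",
              length(x$families), x$proteins_per_family, x$seed))
  cat(sprintf("  noise_sd_log = %g; contaminants = %d; decoys = %d\n",
              x$noise_sd_log, x$n_contaminants, x$n_decoys))
  top <- sort(x$composition, decreasing = TRUE)[seq_len(min(3, length(x$composition)))]
  cat(sprintf("  dominant families: %s\n",
              paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic proteotranscriptomic dataset
#'
#' Builds every input the pipeline consumes from the planted ground truth,
#' using one deterministic pseudo-random stream seeded by
#' \code{truth$seed} (draw order: proteins, lane, hits, contaminants,
#' decoys, transcripts):
#' \itemize{
#'   \item each protein's lane signal is a Gaussian peak centred at a
#'     migration position linear in \eqn{\log_{10}} molecular weight
#'     (descending, the standard SDS-PAGE calibration), height proportional
#'     to its true mass share; bands are intervals around peak clusters;
#'   \item per-band spectral AUC of protein p = (true share of p within the
#'     band) x band area x log-normal noise; identification scores are drawn
#'     so true hits pass the default quality filters while decoys mostly
#'     fail; contaminants carry the \code{CRAP_} prefix, decoys
#'     \code{DECOY_} (neither contributes to the densitometry signal:
#'     planted contamination is trace-level, not band-forming);
#'   \item transcript abundance of family f is proportional to
#'     \eqn{\pi_f / \tau_f} with per-transcript log-normal dispersion,
#'     renormalised to \eqn{10^6} TPM.
#' }
#'
#' @param truth a [synthetic_truth()].
#' @return A \code{synthetic_dataset} list with elements \code{hits},
#'   \code{lane}, \code{bands}, \code{band_areas}, \code{quant},
#'   \code{annotations}, \code{truth} (with drawn molecular weights and
#'   per-protein mass shares filled in) and \code{planted} (bookkeeping:
#'   per-protein truth and the exact number of hits passing the default
#'   filters).
#' @export
simulate_venom_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, {
    fams <- truth$families
    k <- truth$proteins_per_family
    np <- length(fams) * k

    # proteins: within-family splits, mass shares, molecular weights
    split_raw <- rgamma(np, shape = 2, rate = 1)
    family_of <- rep(fams, each = k)
    split <- unlist(lapply(fams, function(f) {
      w <- split_raw[family_of == f]
      w / sum(w)
    }))
    mass_share <- truth$composition[family_of] * split
    accession <- sprintf("%s_p%02d", family_of, rep(seq_len(k), length(fams)))
    mw <- truth$molecular_weights
    if (is.null(mw)) mw <- 10^runif(np, 1, 2)

    # migration: linear in log10(MW), descending (high MW runs less far)
    pos <- 20 + 60 * (2 - log10(mw))
    sigma <- 0.4
    margin <- 3 * sigma

    # bands around peak clusters: single-linkage with a gap wide enough
    # that the +/- margin extensions of adjacent clusters stay disjoint
    o <- order(pos)
    gap <- 2.5 * margin
    cl <- integer(np)
    cl[o] <- cumsum(c(1, diff(pos[o]) > gap))
    n_bands <- max(cl)
    band_id_of <- sprintf("B%02d", cl)
    starts <- vapply(seq_len(n_bands), function(i) min(pos[cl == i]) - margin, 0)
    ends <- vapply(seq_len(n_bands), function(i) max(pos[cl == i]) + margin, 0)
    bands <- band_definitions(sprintf("B%02d", seq_len(n_bands)), starts, ends)

    # lane profile: sum of Gaussian peaks, height ~ mass share
    grid <- seq(min(starts) - 4, max(ends) + 4, by = 0.1)
    intensity <- rep(0, length(grid))
    for (i in seq_len(np)) {
      intensity <- intensity + 1000 * mass_share[i] * dnorm(grid, pos[i], sigma)
    }
    lane <- lane_profile(grid, intensity)

    # analytic band areas (same arbitrary scale as the lane signal)
    band_mass <- rowsum(as.numeric(mass_share), band_id_of)
    band_areas <- setNames(1000 * band_mass[, 1], rownames(band_mass))
    band_areas <- band_areas[bands$band_id]

    # spectral hits: AUC = within-band share x band area x lognormal noise,
    # which reduces to mass share x lognormal noise after normalisation
    eps <- exp(rnorm(np, 0, truth$noise_sd_log))
    auc <- 1e6 * mass_share * eps
    score <- pmax(55, rnorm(np, 85, 12))
    uniq <- rpois(np, 4) + 1
    hits <- data.frame(
      band_id = band_id_of, accession = accession, score = score,
      unique_peptides = uniq, auc = auc,
      description = sprintf("synthetic %s toxin", family_of),
      stringsAsFactors = FALSE
    )

    if (truth$n_contaminants > 0) {
      nc <- truth$n_contaminants
      hits <- rbind(hits, data.frame(
        band_id = sample(bands$band_id, nc, replace = TRUE),
        accession = sprintf("CRAP_C%02d", seq_len(nc)),
        score = pmax(55, rnorm(nc, 75, 10)),
        unique_peptides = rpois(nc, 3) + 1,
        auc = 0.03 * max(auc) * exp(rnorm(nc, 0, 0.5)),
        description = "synthetic contaminant",
        stringsAsFactors = FALSE
      ))
    }
    if (truth$n_decoys > 0) {
      nd <- truth$n_decoys
      hits <- rbind(hits, data.frame(
        band_id = sample(bands$band_id, nd, replace = TRUE),
        accession = sprintf("DECOY_D%02d", seq_len(nd)),
        score = pmax(0, rnorm(nd, 25, 10)),
        unique_peptides = stats::rbinom(nd, 1, 0.5),
        auc = 0.01 * max(auc) * exp(rnorm(nd, 0, 0.5)),
        description = "synthetic decoy",
        stringsAsFactors = FALSE
      ))
    }
    hits <- spectral_hits(hits)

    # transcripts: family share ~ pi_f / tau_f, per-transcript dispersion
    kt <- truth$transcripts_per_family
    weight <- truth$composition / ifelse(truth$translation_efficiency > 0,
                                         truth$translation_efficiency, Inf)
    tr_family <- rep(fams, each = kt)
    tr_id <- sprintf("TR_%s_t%02d", tr_family, rep(seq_len(kt), length(fams)))
    disp <- exp(rnorm(length(tr_id), 0, truth$noise_sd_log))
    rate <- (weight[tr_family] / kt) * disp
    len <- round(runif(length(tr_id), 500, 3000))
    efflen <- len - 150
    quant <- data.frame(
      transcript_id = tr_id, length = len, effective_length = efflen,
      expected_count = rate * efflen * 2e5,
      tpm = NA_real_, stringsAsFactors = FALSE
    )
    quant <- compute_tpm(quant)

    annotations <- data.frame(
      accession = c(accession,
                    if (truth$n_contaminants > 0) sprintf("CRAP_C%02d", seq_len(truth$n_contaminants)),
                    tr_id),
      family = c(family_of,
                 rep("contaminant", truth$n_contaminants),
                 tr_family),
      is_toxin = c(rep(TRUE, np), rep(FALSE, truth$n_contaminants),
                   rep(TRUE, length(tr_id))),
      stringsAsFactors = FALSE
    )

    cfg <- filter_config()
    flagged <- flag_contaminants(hits, cfg$contaminant_prefixes)
    n_pass <- sum(flagged$score >= cfg$min_score &
                    flagged$unique_peptides >= cfg$min_unique_peptides &
                    !flagged$is_contaminant)

    truth$molecular_weights <- mw
    structure(list(
      hits = hits, lane = lane, bands = bands, band_areas = band_areas,
      quant = quant, annotations = annotations, truth = truth,
      planted = list(
        proteins = data.frame(accession = accession, family = family_of,
                              mass_share = as.numeric(mass_share),
                              mw_kda = mw, band_id = band_id_of,
                              stringsAsFactors = FALSE),
        n_pass_default = n_pass,
        n_hits_total = nrow(hits)
      )
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic venom dataset (seed %d): %d hits in %d bands, %d transcripts\n",
              x$truth$seed, nrow(x$hits), nrow(x$bands), nrow(x$quant)))
  invisible(x)
}

write_tsv_raw <- function(df, file, num_cols) {
  for (col in num_cols) df[[col]] <- num_chr(df[[col]])
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(unname(df), sep = "\t"))), con, sep = "\n")
  invisible(file)
}

#' Write a synthetic dataset to disk
#'
#' Emits every file in the pipeline's native dialects —
#' \code{hits.csv}, \code{lane_profile.tsv}, \code{bands.tsv},
#' \code{band_areas.tsv}, \code{quant.tsv}, \code{annotations.tsv} — plus a
#' \code{truth.json} recording the generator parameters (including the
#' seed). Numeric fields are written at full precision, so reading the files
#' back reproduces the in-memory dataset, and repeated writes of the same
#' dataset are byte-identical.
#'
#' @param ds a [simulate_venom_dataset()] result.
#' @param dir output directory; must not exist unless \code{force = TRUE}.
#' @param force overwrite an existing directory.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(ds, dir, force = FALSE) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (dir.exists(dir) && !force) {
    stop_venomcomp(sprintf("directory exists (use force = TRUE): %s", dir),
                   "venomcomp_exists_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  h <- ds$hits
  con <- file(file.path(dir, "hits.csv"), "wb")
  writeLines(c("band_id,accession,score,unique_peptides,auc,description",
               sprintf("%s,%s,%s,%d,%s,%s", h$band_id, h$accession,
                       num_chr(h$score), h$unique_peptides, num_chr(h$auc),
                       h$description)), con, sep = "\n")
  close(con)

  write_tsv_raw(data.frame(position = ds$lane$position,
                           intensity = ds$lane$intensity),
                file.path(dir, "lane_profile.tsv"),
                c("position", "intensity"))
  write_tsv_raw(as.data.frame(ds$bands), file.path(dir, "bands.tsv"),
                c("start", "end"))
  write_tsv_raw(data.frame(band_id = names(ds$band_areas),
                           area = as.numeric(ds$band_areas)),
                file.path(dir, "band_areas.tsv"), "area")
  q <- ds$quant
  write_tsv_raw(data.frame(transcript_id = q$transcript_id, length = q$length,
                           effective_length = q$effective_length,
                           expected_count = q$expected_count, TPM = q$tpm),
                file.path(dir, "quant.tsv"),
                c("length", "effective_length", "expected_count", "TPM"))
  a <- ds$annotations
  con <- file(file.path(dir, "annotations.tsv"), "wb")
  writeLines(c("accession\tfamily\tis_toxin",
               sprintf("%s\t%s\t%s", a$accession, a$family, a$is_toxin)),
             con, sep = "\n")
  close(con)

  tr <- ds$truth
  jsonlite::write_json(
    list(seed = tr$seed, families = tr$families,
         composition = as.numeric(tr$composition),
         proteins_per_family = tr$proteins_per_family,
         molecular_weights_kda = as.numeric(tr$molecular_weights),
         translation_efficiency = as.numeric(tr$translation_efficiency),
         noise_sd_log = tr$noise_sd_log,
         n_contaminants = tr$n_contaminants, n_decoys = tr$n_decoys,
         transcripts_per_family = tr$transcripts_per_family,
         n_pass_default = ds$planted$n_pass_default),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
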