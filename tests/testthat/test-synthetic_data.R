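recover_family_composition <- function(ds) {
  res <- quantify_composition(ds$hits,
                              proportions_from_areas(ds$band_areas),
                              ds$annotations)
  rec <- setNames(res$family$percent, res$family$label)
  out <- setNames(rep(0, length(ds$truth$families)), ds$truth$families)
  out[names(rec)] <- rec
  out
}

test_that("simulation is deterministic for a fixed seed", {
  tr <- synthetic_truth(seed = 0)
  expect_identical(simulate_venom_dataset(tr), simulate_venom_dataset(tr))
  # a different seed gives different data
  tr2 <- synthetic_truth(seed = 99)
  expect_false(identical(simulate_venom_dataset(tr2)$hits$auc,
                         simulate_venom_dataset(tr)$hits$auc))
})

test_that("noise-free pipelines recover the planted composition exactly", {
  tr <- synthetic_truth(noise_sd_log = 0, seed = 4)
  ds <- simulate_venom_dataset(tr)
  rec <- recover_family_composition(ds)
  expect_lt(max(abs(rec - 100 * tr$composition)), 1e-9)
})

test_that("planted pass/fail counts are reproduced exactly by the default filters", {
  tr <- synthetic_truth(seed = 8)
  ds <- simulate_venom_dataset(tr)
  cfg <- filter_config()
  kept <- apply_quality_filters(
    flag_contaminants(ds$hits, cfg$contaminant_prefixes), cfg)
  expect_identical(nrow(kept), ds$planted$n_pass_default)
  # decoys are built to fail, true hits to pass
  expect_false(any(startsWith(kept$accession, "DECOY_")))
  expect_false(any(startsWith(kept$accession, "CRAP_")))
  expect_equal(sort(kept$accession), sort(ds$planted$proteins$accession))
})

test_that("recovery error grows with spectral noise in expectation", {
  mae_at <- function(noise) {
    mean(vapply(1:8, function(s) {
      tr <- synthetic_truth(noise_sd_log = noise, seed = s)
      ds <- simulate_venom_dataset(tr)
      mean(abs(recover_family_composition(ds) - 100 * tr$composition))
    }, numeric(1)))
  }
  expect_lt(mae_at(0.05), mae_at(0.6))
})

test_that("planted translation efficiencies shape the transcriptome as pi/tau", {
  tau <- c(10, rep(1, 13))
  tr <- synthetic_truth(translation_efficiency = tau, noise_sd_log = 0, seed = 2)
  ds <- simulate_venom_dataset(tr)
  tx <- family_transcript_abundance(ds$quant, ds$annotations)
  prot <- composition_table(setNames(100 * tr$composition, tr$families),
                            level = "family")
  ti <- translation_index(prot, tx)
  idx <- setNames(ti$index, ti$family)
  z <- sum(tr$composition / tr$translation_efficiency)
  # index = tau_f * sum_g(pi_g / tau_g); ratios between families recover tau
  expect_equal(unname(idx[tr$families]), tau * z, tolerance = 1e-9)
  ref_fam <- tr$families[tau == 1][1]
  expect_equal(unname(idx["CAP"] / idx[ref_fam]), 10, tolerance = 1e-9)
  # median-centred estimator resolves the closure scale exactly here
  est <- estimate_translation_fold(ti)
  expect_equal(est$fold_estimate[est$family == "CAP"], 10, tolerance = 1e-9)
})

test_that("datasets round-trip through the on-disk dialects", {
  tr <- synthetic_truth(seed = 5)
  ds <- simulate_venom_dataset(tr)
  dir <- file.path(tempfile("dataset"))
  write_dataset(ds, dir)

  expect_error(write_dataset(ds, dir), class = "venomcomp_exists_error")
  expect_silent(write_dataset(ds, dir, force = TRUE))

  hits <- read_spectral_hits(file.path(dir, "hits.csv"))
  expect_equal(hits$auc, ds$hits$auc, tolerance = 0)
  expect_equal(hits$accession, ds$hits$accession)

  lane <- read_lane_profile(file.path(dir, "lane_profile.tsv"))
  expect_equal(lane$intensity, ds$lane$intensity, tolerance = 0)

  bands <- read_band_definitions(file.path(dir, "bands.tsv"))
  expect_equal(bands$start, ds$bands$start, tolerance = 0)

  areas <- read_band_areas(file.path(dir, "band_areas.tsv"))
  expect_equal(areas, ds$band_areas, tolerance = 0)

  quant <- read_transcript_quant(file.path(dir, "quant.tsv"))
  expect_equal(quant$tpm, ds$quant$tpm, tolerance = 0)

  ann <- read_annotation_map(file.path(dir, "annotations.tsv"))
  expect_equal(ann, ds$annotations)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 5)
})

test_that("lane-profile densitometry approximates the analytic band areas", {
  tr <- synthetic_truth(noise_sd_log = 0, seed = 6)
  ds <- simulate_venom_dataset(tr)
  integrated <- integrate_bands(ds$lane, ds$bands)
  analytic <- proportions_from_areas(ds$band_areas)
  expect_equal(setNames(integrated$proportion, integrated$band_id),
               setNames(analytic$proportion, analytic$band_id),
               tolerance = 0.02)
})

test_that("invalid truths are rejected", {
  expect_error(synthetic_truth(composition = c(-1, 2)),
               class = "venomcomp_validation_error")
  expect_error(synthetic_truth(noise_sd_log = -0.1),
               class = "venomcomp_validation_error")
  expect_error(synthetic_truth(families = c("A", "B"),
                               composition = c(0.5, 0.3, 0.2)),
               class = "venomcomp_validation_error")
})
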