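test_that("within-band AUC fractions normalise to 1", {
  expect_equal(band_relative_auc(make_hits("B1", c("X", "Y"), c(3, 1))),
               c(X = 0.75, Y = 0.25))
  expect_equal(band_relative_auc(make_hits("B1", "X", 7)), c(X = 1))
  expect_equal(band_relative_auc(make_hits("B1", c("X", "Y", "Z"), c(2, 2, 4))),
               c(X = 0.25, Y = 0.25, Z = 0.5))
  expect_error(band_relative_auc(make_hits("B1", c("X", "Y"), c(0, 0))),
               class = "venomcomp_empty_band_error")
  expect_error(band_relative_auc(make_hits(c("B1", "B2"), c("X", "Y"), c(1, 1))),
               class = "venomcomp_validation_error")
})

test_that("band-weighted relative abundance reproduces hand-evaluated cases", {
  one <- relative_abundance(make_hits("B1", "X", 42),
                            proportions_from_areas(c(B1 = 5)))
  expect_equal(setNames(one$percent, one$label), c(X = 100))

  # B1 (prop 0.6): X=2, Y=2; B2 (prop 0.4): X=5
  hits <- make_hits(c("B1", "B1", "B2"), c("X", "Y", "X"), c(2, 2, 5))
  prop <- proportions_from_areas(c(B1 = 0.6, B2 = 0.4))
  comp <- relative_abundance(hits, prop)
  expect_equal(setNames(comp$percent, comp$label), c(X = 70, Y = 30))
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)

  prov <- attr(comp, "provenance")
  expect_equal(prov$n_bands[prov$label == "X"], 2L)
})

test_that("relative abundance matches the brute-force double-loop oracle", {
  set.seed(11)
  for (i in 1:200) {
    nb <- sample(1:4, 1)
    np <- sample(1:6, 1)
    auc <- matrix(0, np, nb,
                  dimnames = list(paste0("P", 1:np), paste0("B", 1:nb)))
    # each band gets at least one positive hit; proteins appear sparsely
    for (b in 1:nb) {
      members <- unique(c(sample(np, 1), which(runif(np) < 0.5)))
      auc[members, b] <- runif(length(members), 0.1, 10)
    }
    prop_raw <- runif(nb, 0.1, 1)
    prop <- setNames(prop_raw / sum(prop_raw), colnames(auc))

    expected <- oracle_relative_abundance(auc, prop)
    comp <- relative_abundance(hits_from_auc_matrix(auc), prop)
    got <- setNames(comp$percent, comp$label)[names(expected)]
    got[is.na(got)] <- 0
    expect_lt(max(abs(got - expected)), 1e-10)
  }
})

test_that("zero-toxin bands follow the chosen policy", {
  hits <- make_hits("B1", "X", 3)
  prop <- proportions_from_areas(c(B1 = 0.5, B2 = 0.5))
  expect_error(relative_abundance(hits, prop, zero_band_policy = "error"),
               "B2", class = "venomcomp_policy_error")
  comp <- relative_abundance(hits, prop, zero_band_policy = "renormalise")
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
})

test_that("composition is invariant to within-band AUC scaling and monotone in AUC", {
  hits <- make_hits(c("B1", "B1", "B2", "B2"), c("X", "Y", "X", "Z"),
                    c(2, 3, 1, 4))
  prop <- proportions_from_areas(c(B1 = 0.7, B2 = 0.3))
  base <- relative_abundance(hits, prop)

  scaled <- hits
  scaled$auc[scaled$band_id == "B1"] <- 11 * scaled$auc[scaled$band_id == "B1"]
  comp2 <- relative_abundance(scaled, prop)
  expect_equal(setNames(comp2$percent, comp2$label),
               setNames(base$percent, base$label), tolerance = 1e-12)

  bumped <- hits
  bumped$auc[bumped$accession == "X" & bumped$band_id == "B1"] <- 5
  comp3 <- relative_abundance(bumped, prop)
  b3 <- setNames(comp3$percent, comp3$label)
  b0 <- setNames(base$percent, base$label)
  expect_gt(b3["X"], b0["X"])
  expect_lt(b3["Y"], b0["Y"])
  expect_equal(b3["Z"], b0["Z"], tolerance = 1e-12)
})

test_that("family aggregation preserves totals and rejects unannotated proteins", {
  comp <- composition_table(c(PLA1 = 21.86, PLA2 = 0.17, CAP = 77.97),
                            level = "protein")
  ann <- c(PLA1 = "Phospholipases", PLA2 = "Phospholipases", CAP = "CAP")
  fam <- aggregate_families(comp, ann)
  expect_equal(fam$percent[fam$label == "Phospholipases"], 22.03)
  expect_equal(sum(fam$percent), sum(comp$percent), tolerance = 1e-12)

  ident <- aggregate_families(comp, c(PLA1 = "PLA1", PLA2 = "PLA2", CAP = "CAP"))
  expect_setequal(ident$label, comp$label)
  expect_equal(setNames(ident$percent, ident$label)[comp$label],
               setNames(comp$percent, comp$label))

  three <- composition_table(c(A = 10, B = 20, C = 70), level = "protein")
  one_fam <- aggregate_families(three, c(A = "F", B = "F", C = "F"))
  expect_equal(one_fam$percent, 100)

  expect_error(aggregate_families(comp, c(PLA1 = "Phospholipases")),
               "PLA2", class = "venomcomp_validation_error")
})

test_that("translation indices divide proteome by transcriptome percentages", {
  prot <- composition_table(c(CAP = 26.09, HYL = 15.20), level = "family")
  tx <- composition_table(c(CAP = 2.88, HYL = 7.63, AK = 74.29),
                          level = "family")
  ti <- translation_index(prot, tx)
  expect_equal(ti$index[ti$family == "CAP"], 26.09 / 2.88)
  expect_gt(ti$index[ti$family == "CAP"], 9)

  # equal percentages -> index 1; absent from transcriptome -> undefined
  eq <- translation_index(composition_table(c(F1 = 100), level = "family"),
                          composition_table(c(F1 = 100), level = "family"))
  expect_equal(eq$index, 1)

  only_p <- translation_index(
    composition_table(c(F1 = 60, F2 = 40), level = "family"),
    composition_table(c(F1 = 100), level = "family"))
  expect_false(only_p$defined[only_p$family == "F2"])
  expect_true(is.na(only_p$index[only_p$family == "F2"]))
  expect_equal(only_p$transcriptome_percent[only_p$family == "F2"], 0)
})
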