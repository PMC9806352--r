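make_quant <- function(id, count, efflen) {
  data.frame(transcript_id = id, length = efflen + 150,
             effective_length = efflen, expected_count = count,
             tpm = NA_real_, stringsAsFactors = FALSE)
}

test_that("TPM follows the length-normalised formula and sums to 1e6", {
  eq <- compute_tpm(make_quant(c("T1", "T2"), c(10, 10), c(100, 100)))
  expect_equal(eq$tpm, c(5e5, 5e5))

  uneq <- compute_tpm(make_quant(c("T1", "T2"), c(10, 10), c(100, 200)))
  expect_equal(uneq$tpm, c(2e6 / 3, 1e6 / 3))
  expect_equal(round(uneq$tpm, 2), c(666666.67, 333333.33))

  single <- compute_tpm(make_quant("T1", 5, 300))
  expect_equal(single$tpm, 1e6)

  expect_error(compute_tpm(make_quant(c("T1", "T2"), c(0, 0), c(100, 100))),
               class = "venomcomp_degenerate_error")
})

test_that("TPM is invariant to uniform count scaling", {
  set.seed(3)
  q <- make_quant(paste0("T", 1:8), runif(8, 1, 100), runif(8, 200, 2000))
  base <- compute_tpm(q)
  q2 <- q
  q2$expected_count <- 1000 * q2$expected_count
  expect_equal(compute_tpm(q2)$tpm, base$tpm, tolerance = 1e-12)
})

test_that("validate_tpm flags badly scaled tables at the stated tolerance", {
  q <- compute_tpm(make_quant(c("T1", "T2"), c(4, 6), c(500, 500)))
  expect_true(validate_tpm(q)$pass)

  half <- q
  half$tpm <- 0.5 * half$tpm
  rep_half <- validate_tpm(half)
  expect_false(rep_half$pass)
  expect_equal(rep_half$total, 5e5)

  near <- q
  near$tpm <- q$tpm * 1.005
  expect_true(validate_tpm(near, tolerance = 0.01)$pass)
  expect_false(validate_tpm(near, tolerance = 1e-6)$pass)
})

test_that("family transcript abundance normalises over toxin transcripts only", {
  q <- compute_tpm(make_quant(paste0("T", 1:4), c(3, 3, 2, 10),
                              rep(1000, 4)))
  ann <- data.frame(accession = paste0("T", 1:4),
                    family = c("F1", "F1", "F2", "housekeeping"),
                    is_toxin = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  fam <- family_transcript_abundance(q, ann)
  expect_equal(setNames(fam$percent, fam$label)[c("F1", "F2")],
               c(F1 = 75, F2 = 25))
  expect_equal(sum(fam$percent), 100, tolerance = 1e-9)

  solo <- family_transcript_abundance(q, c(T1 = "F1"))
  expect_equal(solo$percent, 100)

  none <- ann
  none$is_toxin <- FALSE
  expect_error(family_transcript_abundance(q, none),
               class = "venomcomp_degenerate_error")
})

test_that("percent-scaled TPM totals reproduce themselves as percentages", {
  # AK 30.38, PLA1 25.67, rest 43.95 (already on a percent scale)
  q <- make_quant(c("TA", "TP", "TR"), c(30.38, 25.67, 43.95), rep(1000, 3))
  q <- compute_tpm(q)
  fam <- family_transcript_abundance(q, c(TA = "AK", TP = "PLA1", TR = "rest"))
  expect_equal(setNames(fam$percent, fam$label)[c("AK", "PLA1", "rest")],
               c(AK = 30.38, PLA1 = 25.67, rest = 43.95), tolerance = 1e-9)
})

test_that("family abundance is permutation-invariant", {
  set.seed(5)
  q <- compute_tpm(make_quant(paste0("T", 1:9), runif(9, 1, 50),
                              runif(9, 300, 3000)))
  ann <- setNames(rep(c("F1", "F2", "F3"), 3), paste0("T", 1:9))
  base <- family_transcript_abundance(q, ann)
  perm <- family_transcript_abundance(q[sample(9), ], ann)
  expect_equal(setNames(perm$percent, perm$label)[base$label],
               setNames(base$percent, base$label), tolerance = 1e-12)
})
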