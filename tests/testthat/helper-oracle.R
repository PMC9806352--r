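# Independent brute-force evaluation of the band-weighted relative-abundance
# statistic: a literal double loop over proteins and bands, kept deliberately
# naive and separate from the implementation it checks.
oracle_relative_abundance <- function(auc, prop) {
  # auc: proteins x bands matrix; prop: named proportions per band
  live <- colnames(auc)[colSums(auc) > 0]
  prop <- prop[live] / sum(prop[live])
  out <- setNames(numeric(nrow(auc)), rownames(auc))
  for (p in rownames(auc)) {
    for (b in live) {
      total_in_band <- 0
      for (q in rownames(auc)) total_in_band <- total_in_band + auc[q, b]
      out[p] <- out[p] + auc[p, b] / total_in_band * prop[b]
    }
  }
  100 * out
}

make_hits <- function(band_id, accession, auc, score = 80, unique_peptides = 2) {
  spectral_hits(data.frame(
    band_id = band_id, accession = accession, auc = auc,
    score = score, unique_peptides = unique_peptides,
    stringsAsFactors = FALSE
  ))
}

hits_from_auc_matrix <- function(auc) {
  idx <- which(auc > 0, arr.ind = TRUE)
  make_hits(band_id = colnames(auc)[idx[, 2]],
            accession = rownames(auc)[idx[, 1]],
            auc = auc[idx])
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
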