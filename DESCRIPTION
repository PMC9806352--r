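Package: venomcomp
Title: Gel-Band Label-Free Quantification of Venom Proteome Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for proteotranscriptomic profiling of animal venoms from
    SDS-PAGE gel-band mass spectrometry. Implements band-resolved label-free
    quantification in which each protein's spectral-intensity area under the
    curve (AUC) is normalised within its gel band and weighted by the band's
    densitometric proportion of the lane, yielding relative-abundance
    percentages per toxin and per toxin family. Includes identification
    quality filtering (protein score, unique peptides, contaminant
    exclusion), lane densitometry (baseline subtraction, trapezoidal band
    integration), TPM-based transcript abundance aggregation and
    proteome-to-transcriptome translation indices, enzyme and pharmacology
    assay unit calculations (turbidity reduction units, standard-curve
    specific activity, relative haemolysis, clotting delay), and a
    seed-deterministic synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
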