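Package: ptmladder
Title: Peptide Mass Fingerprint Interpretation for Phosphorylation and
    Polyglycylation Ladders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico tryptic digestion and monoisotopic mass prediction,
    MALDI reflector peak-list interpretation for phosphorylation (+79.96633 Da)
    and polyglycylation (57.02146 Da ladder series), scanning for the
    polyglycylation signature motif, pairwise global alignment identity and
    similarity statistics with alignment-column conservation classes, and
    salt-bridge-based dimerization compatibility scoring for 14-3-3 family
    proteins. Includes a deterministic synthetic-data generator for peak lists
    and motif-bearing sequences so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
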