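Package: goconverge
Title: Gene Ontology Overrepresentation Tests of Genomic Functional Convergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether a convergently evolved syndrome (the motivating
    case is plant carnivory) leaves a detectable signal of functional
    overrepresentation in annotated genomes. A literature-derived reference
    set of syndrome-associated Gene Ontology functions is scored against
    per-taxon gene-to-GO annotation tables to give genes-per-thousand
    representation profiles; profiles from sequence-similarity ("mapped")
    annotation are calibrated against curated annotation using per-function
    adjustment factors from a dual-annotated taxon; study-group taxa are then
    tested for overrepresentation with upper-tailed Welch t-tests (group
    level) and Z-tests against control-derived reference distributions
    (taxon level), with Storey q-value false discovery rate control. A
    synthetic annotated-genome generator with known baseline rates,
    enrichment effects and annotation-method bias makes every stage testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
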