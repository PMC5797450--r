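# Fixtures built in code: random annotation tables, a miniature reference
# set, and a small hand-written GBFF record set.

tiny_refset <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("label\tabbreviation\tcodes",
               "lipase activity\tLipase\tGO:0016298",
               "lipid transport\tLipTrans\tGO:0006869",
               "heat shock protein activity\tHeatShock\tGO:0042026; GO:0006986; GO:0034620"),
             path)
  load_reference_set(path)
}

random_codes_pool <- sprintf("GO:%07d", c(16298, 6869, 42026, 6986, 34620,
                                          5884, 4568, 9916, 1:30))

random_annotation_table <- function(n_genes, taxon_id = "tx",
                                    method = "curated",
                                    pool = random_codes_pool,
                                    p_empty = 0.25) {
  codes <- lapply(seq_len(n_genes), function(i) {
    if (stats::runif(1) < p_empty) return(character(0))
    sample(pool, sample.int(3, 1))
  })
  annotation_table(taxon_id, method, sprintf("%s_g%05d", taxon_id, seq_len(n_genes)),
                   codes)
}

# independent double-loop oracle for count_functions()
brute_force_counts <- function(table, ref) {
  abbrs <- ref$entries$abbreviation
  counts <- structure(integer(length(abbrs)), names = abbrs)
  for (j in seq_along(abbrs)) {
    entry_codes <- ref$codes[[abbrs[j]]]
    for (g in seq_along(table$gene_id)) {
      if (any(table$codes[[g]] %in% entry_codes)) {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}

# three-gene GBFF stream: two genes with GO codes (one repeated across two
# qualifiers), one gene without any
gbff_fixture_lines <- function() {
  c("LOCUS       SYNCTG01             9000 bp    DNA     linear   PLN 01-JAN-2020",
    "DEFINITION  synthetic test contig 1.",
    "FEATURES             Location/Qualifiers",
    "     source          1..9000",
    '                     /organism="Testus plantus"',
    "     gene            1..1200",
    '                     /locus_tag="TP_0001"',
    "     CDS             1..1200",
    '                     /locus_tag="TP_0001"',
    '                     /db_xref="GO:0004568"',
    '                     /GO_function="chitinase activity [GO:0004568]"',
    "     gene            2000..3500",
    '                     /locus_tag="TP_0002"',
    "     CDS             2000..3500",
    '                     /locus_tag="TP_0002"',
    '                     /db_xref="GO:0016298"',
    '                     /db_xref="GO:0006869"',
    "     gene            4000..5000",
    '                     /locus_tag="TP_0003"',
    "     CDS             4000..5000",
    '                     /locus_tag="TP_0003"',
    '                     /product="hypothetical protein"',
    "ORIGIN",
    "//")
}

make_profile <- function(taxon_id, class_label, per_mille,
                         method = "curated", adjusted = FALSE) {
  counts <- structure(list(taxon_id = taxon_id, method = method,
                           counts = per_mille, n_assigned = 1000L),
                      class = "function_counts")
  p <- to_profile(counts, class_label)
  p$adjusted <- adjusted
  p
}
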