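# A small worked example corpus, fixed by hand, exercising every branch
# of the pipeline: all four record classes, a subset-A and a subset-C
# compound, a unit conversion, a cited (identical) value re-reported in a
# second paper, a >3 orders-of-magnitude potency range, and one
# contaminating row per high-confidence curation rule.

#' Worked twenty-row example corpus
#'
#' Returns a fixed miniature corpus used throughout the documentation and
#' tests. Clean content (14 rows): compound C001 with a single 5 nM Ki on
#' T01 (subset A); C002 with replicate determinations on T02 in one paper
#' plus a second target; C003 with the same 50 nM value re-reported in
#' two papers (once as 0.05 uM); C004 with 2 nM and 9000 nM in two papers
#' (a 3.65 order-of-magnitude spread); C005 active against six targets in
#' a single paper (subset C). Six further rows each violate exactly one
#' high-confidence rule: an approximate relation, a low confidence score,
#' a non-"D" relationship, a non-human organism, a non-protein target,
#' and a patent document.
#'
#' @return A list with `measurements`, `publications` and a `manifest`
#'   of the expected pipeline outcomes (see [generate_corpus()] for the
#'   manifest layout; this one adds `set1_audit`).
#' @export
fixture_small <- function() {
  measurements <- tibble(
    compound_id = c(
      "C001", "C002", "C002", "C002", "C003", "C003", "C004", "C004",
      rep("C005", 6),
      "C006", "C007", "C008", "C009", "C010", "C011"
    ),
    assay_id = c(
      "A01", "A02", "A03", "A05", "A04", "A06", "A07", "A08",
      paste0("A", 9:14),
      paste0("A", 15:20)
    ),
    target_id = c(
      "T01", "T02", "T02", "T11", "T03", "T03", "T04", "T04",
      paste0("T", sprintf("%02d", 5:10)),
      rep("T01", 6)
    ),
    target_organism = c(
      rep("Homo sapiens", 17), "Rattus norvegicus", "Homo sapiens",
      "Homo sapiens"
    ),
    target_type = c(
      rep("SINGLE PROTEIN", 18), "CELL-LINE", "SINGLE PROTEIN"
    ),
    confidence_score = c(rep(9L, 15), 5L, rep(9L, 4)),
    relationship_type = c(rep("D", 16), "N", rep("D", 3)),
    activity_type = c(
      "Ki", "Ki", "IC50", "Ki", "Ki", "Ki", "IC50", "IC50",
      rep("Ki", 6), rep("Ki", 6)
    ),
    relation = c(rep("=", 14), ">", rep("=", 5)),
    value = c(
      5, 10, 0.08, 20, 50, 0.05, 2, 9000,
      100, 200, 300, 400, 500, 600,
      rep(10, 6)
    ),
    units = c(
      "nM", "nM", "uM", "nM", "nM", "uM", "nM", "nM",
      rep("nM", 6), rep("nM", 6)
    ),
    doc_id = c(
      "D1", "D1", "D1", "D2", "D1", "D2", "D2", "D3",
      rep("D2", 6),
      rep("D1", 5), "DP1"
    )
  )
  publications <- tibble(
    doc_id = c("D1", "D2", "D3", "DP1"),
    journal = c(
      "Bioorg. Med. Chem. Lett.", "J. Med. Chem.", "J. Med. Chem.",
      "Patent Office"
    ),
    year = c(2010L, 2012L, 2014L, 2011L),
    doc_type = c("PUBLICATION", "PUBLICATION", "PUBLICATION", "PATENT")
  )
  manifest <- list(
    compounds = tibble(
      compound_id = c("C001", "C002", "C003", "C004", "C005"),
      degree = c(1L, 2L, 1L, 1L, 6L),
      n_publications = c(1L, 2L, 2L, 2L, 1L),
      subset = c("A", "NONE", "NONE", "NONE", "C")
    ),
    records = tibble(
      compound_id = c(
        "C001", "C002", "C002", "C003", "C004", rep("C005", 6)
      ),
      target_id = c(
        "T01", "T02", "T11", "T03", "T04",
        paste0("T", sprintf("%02d", 5:10))
      ),
      n_publications = c(1L, 1L, 1L, 2L, 2L, rep(1L, 6)),
      n_measurements = c(1L, 2L, 1L, 2L, 2L, rep(1L, 6)),
      n_distinct_values = c(1L, 2L, 1L, 1L, 2L, rep(1L, 6)),
      record_class = c(
        "SINGLE_PUB_SINGLE_VALUE", "SINGLE_PUB_MULTI_VALUE",
        "SINGLE_PUB_SINGLE_VALUE", "MULTI_PUB_SAME_VALUE",
        "MULTI_PUB_VARYING_VALUES", rep("SINGLE_PUB_SINGLE_VALUE", 6)
      ),
      log_range = c(
        0, log10(80 / 10), 0, 0, log10(9000 / 2), rep(0, 6)
      )
    ),
    rows = tibble(
      contaminated = c(rep(FALSE, 14), rep(TRUE, 6)),
      rule = c(rep(NA_character_, 14),
        "approximate_relation", "low_confidence", "non_d_relationship",
        "non_human_organism", "non_protein_target", "non_publication_doc")
    ),
    set1_audit = c(
      require_doc_type = 1L,
      require_target_organism = 1L,
      require_target_type = 1L,
      exclude_approximate = 1L,
      unconvertible_units = 0L,
      allowed_activity_types = 0L,
      require_relationship_type = 1L,
      require_confidence_score = 1L
    ),
    n_set1_kept = 14L,
    n_set2_kept = 16L
  )
  list(
    measurements = measurements, publications = publications,
    manifest = manifest
  )
}
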