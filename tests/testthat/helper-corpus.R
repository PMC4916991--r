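# shared synthetic corpora, generated once per test run

small_corpus <- generate_corpus(generator_config(seed = 42L,
  n_compounds = 400L))

small_set1 <- curate(small_corpus$measurements, small_corpus$publications,
  curation_policy("set1"))
small_records <- build_records(small_set1$kept)
small_profiles <- compound_profiles(small_records)

# independent row-by-row predicate oracle for the set-1 rules, written
# without reference to curate()'s rule machinery
oracle_set1_keep <- function(m, pubs) {
  doc_type <- pubs$doc_type[match(m$doc_id, pubs$doc_id)]
  doc_type == "PUBLICATION" &
    m$target_organism == "Homo sapiens" &
    m$target_type == "SINGLE PROTEIN" &
    m$relation == "=" &
    m$units %in% c("nM", "uM", "M") &
    m$activity_type %in% c("Ki", "IC50") &
    m$relationship_type == "D" &
    m$confidence_score == 9L
}
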