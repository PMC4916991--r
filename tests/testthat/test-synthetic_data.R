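test_that("identical configurations give byte-identical corpora", {
  c1 <- generate_corpus(generator_config(seed = 7L, n_compounds = 200L))
  c2 <- generate_corpus(generator_config(seed = 7L, n_compounds = 200L))
  td <- tempfile()
  dir.create(td)
  write_table(c1$measurements, file.path(td, "a.csv"))
  write_table(c2$measurements, file.path(td, "b.csv"))
  expect_identical(readLines(file.path(td, "a.csv")),
    readLines(file.path(td, "b.csv")))
  write_table(c1$publications, file.path(td, "pa.csv"))
  write_table(c2$publications, file.path(td, "pb.csv"))
  expect_identical(readLines(file.path(td, "pa.csv")),
    readLines(file.path(td, "pb.csv")))
  expect_identical(c1$manifest, c2$manifest)

  c3 <- generate_corpus(generator_config(seed = 8L, n_compounds = 200L))
  expect_false(identical(c1$measurements, c3$measurements))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_corpus(generator_config(seed = 5L,
    n_compounds = 50L)))
  expect_identical(runif(1), before)
})

test_that("a contamination-free corpus passes curation in full", {
  cfg <- generator_config(seed = 2L, n_compounds = 100L,
    contamination = setNames(rep(0, 6), names(generator_config()$contamination)))
  corp <- generate_corpus(cfg)
  cur <- curate(corp$measurements, corp$publications,
    curation_policy("set1"))
  expect_equal(nrow(cur$kept), nrow(corp$measurements))
  expect_true(all(cur$audit == 0L))
  expect_false(any(corp$manifest$rows$contaminated))
})

test_that("contaminated rows each violate exactly their flagged rule", {
  m <- small_corpus$measurements
  pubs <- small_corpus$publications
  flags <- small_corpus$manifest$rows
  cur <- curate(m, pubs, curation_policy("set1"))
  # clean rows all kept, contaminated rows all rejected
  expect_equal(nrow(cur$kept), sum(!flags$contaminated))
  expect_equal(nrow(cur$kept), small_corpus$manifest$n_set1_kept)
  # audit counts equal the injected contamination counts
  k <- small_corpus$manifest$contamination_counts
  expect_equal(cur$audit[["exclude_approximate"]],
    k[["approximate_relation"]])
  expect_equal(cur$audit[["require_confidence_score"]],
    k[["low_confidence"]])
  expect_equal(cur$audit[["require_relationship_type"]],
    k[["non_d_relationship"]])
  expect_equal(cur$audit[["require_target_organism"]],
    k[["non_human_organism"]])
  expect_equal(cur$audit[["require_target_type"]],
    k[["non_protein_target"]])
  expect_equal(cur$audit[["require_doc_type"]],
    k[["non_publication_doc"]])
  # relaxed policy keeps exactly the relationship/confidence violators too
  cur2 <- curate(m, pubs, curation_policy("set2"))
  expect_equal(nrow(cur2$kept), small_corpus$manifest$n_set2_kept)
})

test_that("the pipeline recovers the manifest exactly", {
  corp <- generate_corpus(generator_config(seed = 31L,
    n_compounds = 1000L))
  cur <- curate(corp$measurements, corp$publications,
    curation_policy("set1"))
  recs <- build_records(cur$kept)
  expect_identical(
    as.data.frame(recs[names(corp$manifest$records)]),
    as.data.frame(corp$manifest$records)
  )
  prof <- compound_profiles(recs)
  expect_identical(as.data.frame(prof),
    as.data.frame(corp$manifest$compounds))
})

test_that("binned sampling stays within exact binomial bounds", {
  corp <- generate_corpus(generator_config(seed = 1L,
    n_compounds = 1000L))
  prof <- corp$manifest$compounds
  probs <- chembl21_degree_distribution()
  counts <- table(factor(
    cut(prof$degree,
      breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 10.5, 20.5, Inf),
      labels = names(probs)),
    levels = names(probs)
  ))
  n <- nrow(prof)
  for (b in names(probs)) {
    sd <- sqrt(n * probs[[b]] * (1 - probs[[b]]))
    expect_lt(abs(counts[[b]] - n * probs[[b]]), 3 * sd + 1)
  }
})

test_that("infeasible and malformed configurations are rejected early", {
  expect_error(generator_config(n_compounds = 100L, n_targets = 50L),
    "infeasible")
  bad <- chembl21_degree_distribution()
  bad[1] <- bad[1] + 0.1
  expect_error(generator_config(degree_distribution = bad), "sum to 1")
  expect_error(
    generator_config(contamination = c(nope = 0.1)),
    "contamination"
  )
})

test_that("the worked fixture covers every branch by construction", {
  fx <- fixture_small()
  expect_equal(nrow(fx$measurements), 20L)
  expect_setequal(
    unique(fx$manifest$records$record_class),
    c("SINGLE_PUB_SINGLE_VALUE", "SINGLE_PUB_MULTI_VALUE",
      "MULTI_PUB_SAME_VALUE", "MULTI_PUB_VARYING_VALUES")
  )
  subsets <- table(fx$manifest$compounds$subset)
  expect_equal(subsets[["A"]], 1L)
  expect_equal(subsets[["C"]], 1L)
  expect_equal(sum(fx$manifest$rows$contaminated), 6L)
  expect_equal(anyDuplicated(fx$manifest$rows$rule[
    fx$manifest$rows$contaminated]), 0L)
  # one record spans more than three orders of magnitude
  expect_gt(max(fx$manifest$records$log_range), 3)
})
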