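test_that("unit normalization to nM is exact", {
  expect_equal(normalize_to_nM(1, "uM"), 1000)
  expect_equal(normalize_to_nM(1, "nM"), 1)
  expect_equal(normalize_to_nM(2e-9, "M"), 2)
  expect_equal(normalize_to_nM(c(5, 0.05), c("nM", "uM")), c(5, 50))
  expect_error(normalize_to_nM(1, "mg/mL"), "unknown potency unit")
})

test_that("log_range spans orders of magnitude", {
  expect_equal(log_range(c(1, 1000)), 3)
  expect_equal(log_range(7), 0)
  # oracle: closed form log10(9000/20)
  expect_equal(log_range(c(20, 500, 9000)), log10(9000 / 20))
  expect_error(log_range(numeric(0)), "at least one")
  expect_error(log_range(c(1, -1)), "positive")
})

test_that("log_range is invariant under uniform unit rescaling", {
  set.seed(9)
  for (i in 1:20) {
    v <- 10^runif(5, -1, 5)
    f <- sample(c(1e-3, 1, 1e3, 1e9), 1)
    expect_equal(log_range(v * f), log_range(v))
  }
})

test_that("record aggregation pools assays and publications per pair", {
  toy <- tibble::tibble(
    compound_id = c("C1", "C1"), assay_id = c("A1", "A2"),
    target_id = c("T1", "T1"),
    target_organism = "Homo sapiens", target_type = "SINGLE PROTEIN",
    confidence_score = 9L, relationship_type = "D", activity_type = "Ki",
    relation = "=", value = c(10, 100), units = "nM",
    doc_id = c("D1", "D2")
  )
  rec <- build_records(toy)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_publications, 2L)
  expect_equal(rec$n_measurements, 2L)
  expect_equal(rec$n_distinct_values, 2L)
  expect_equal(rec$record_class, "MULTI_PUB_VARYING_VALUES")
  expect_equal(rec$log_range, 1)
  expect_equal(rec$doc_ids[[1]], c("D1", "D2"))

  single <- build_records(toy[1, ])
  expect_equal(single$record_class, "SINGLE_PUB_SINGLE_VALUE")
  expect_equal(single$log_range, 0)

  two_targets <- toy
  two_targets$target_id <- c("T1", "T2")
  expect_equal(nrow(build_records(two_targets)), 2L)

  expect_error(build_records(transform(toy, relation = ">")),
    "curated input")
})

test_that("decision tree covers the four classes and partitions records", {
  expect_equal(classify_record(1L, 1L, 1L), "SINGLE_PUB_SINGLE_VALUE")
  expect_equal(classify_record(1L, 2L, 2L), "SINGLE_PUB_MULTI_VALUE")
  # replicates within one paper stay multi-value even when identical
  expect_equal(classify_record(1L, 2L, 1L), "SINGLE_PUB_MULTI_VALUE")
  expect_equal(classify_record(2L, 2L, 1L), "MULTI_PUB_SAME_VALUE")
  expect_equal(classify_record(2L, 2L, 2L), "MULTI_PUB_VARYING_VALUES")

  cls <- table(small_records$record_class)
  expect_equal(sum(cls), nrow(small_records))
  expect_true(all(unique(small_records$record_class) %in%
    c("SINGLE_PUB_SINGLE_VALUE", "SINGLE_PUB_MULTI_VALUE",
      "MULTI_PUB_SAME_VALUE", "MULTI_PUB_VARYING_VALUES")))
})

test_that("measurements are conserved through aggregation", {
  expect_equal(sum(small_records$n_measurements), nrow(small_set1$kept))
  expect_equal(
    nrow(small_records),
    nrow(unique(small_set1$kept[c("compound_id", "target_id")]))
  )
})

test_that("cited values re-reported in other units collapse to one", {
  fx <- fixture_small()
  cur <- curate(fx$measurements, fx$publications, curation_policy("set1"))
  rec <- build_records(cur$kept)
  c3 <- rec[rec$compound_id == "C003", ]
  expect_equal(c3$n_distinct_values, 1L) # 50 nM == 0.05 uM
  expect_equal(c3$record_class, "MULTI_PUB_SAME_VALUE")
  expect_equal(c3$log_range, 0)
})

test_that("potency-range histogram respects the publication threshold", {
  rec <- build_records(tibble::tibble(
    compound_id = "C1", assay_id = paste0("A", 1:12),
    target_id = "T1", target_organism = "Homo sapiens",
    target_type = "SINGLE PROTEIN", confidence_score = 9L,
    relationship_type = "D", activity_type = "Ki", relation = "=",
    value = c(1, rep(100, 10), 5000), units = "nM",
    doc_id = paste0("D", 1:12)
  ))
  h <- range_histogram(rec, min_publications = 10L)
  expect_equal(h$pct[h$bin == ">3"], 100)
  expect_equal(sum(h$n), 1L)
  expect_warning(h0 <- range_histogram(rec, min_publications = 20L),
    "threshold")
  expect_equal(nrow(h0), 0L)

  # oracle recount on the synthetic corpus at a low threshold
  h2 <- range_histogram(small_records, min_publications = 1L)
  sel <- small_records[small_records$n_publications > 1L, ]
  brute <- c(
    sum(sel$log_range <= 1),
    sum(sel$log_range > 1 & sel$log_range <= 2),
    sum(sel$log_range > 2 & sel$log_range <= 3),
    sum(sel$log_range > 3)
  )
  expect_equal(h2$n, brute)
  expect_equal(sum(h2$pct), 100)
})
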