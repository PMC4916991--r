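test_that("publication categories follow assay and target counts", {
  expect_equal(classify_publication(1L, 1L), "SINGLE_ASSAY")
  expect_equal(classify_publication(4L, 1L), "MULTI_ASSAY_SINGLE_TARGET")
  expect_equal(classify_publication(2L, 2L), "MULTI_ASSAY_MULTI_TARGET")
  expect_error(classify_publication(1L, 2L), "single")
})

test_that("profiles count distinct assays, targets and compounds", {
  fx <- fixture_small()
  cur <- curate(fx$measurements, fx$publications, curation_policy("set1"))
  prof <- profile_publications(cur$kept, fx$publications)
  expect_equal(prof$doc_id, c("D1", "D2", "D3"))
  d1 <- prof[prof$doc_id == "D1", ]
  expect_equal(c(d1$n_assays, d1$n_targets, d1$n_compounds), c(4L, 3L, 3L))
  expect_equal(d1$category, "MULTI_ASSAY_MULTI_TARGET")
  d3 <- prof[prof$doc_id == "D3", ]
  expect_equal(c(d3$n_assays, d3$n_targets, d3$n_compounds), c(1L, 1L, 1L))
  expect_equal(d3$category, "SINGLE_ASSAY")
  expect_equal(d1$journal, "Bioorg. Med. Chem. Lett.")
  expect_equal(d1$year, 2010L)

  bad <- cur$kept
  bad$doc_id[1] <- "nope"
  expect_error(profile_publications(bad, fx$publications), "nope")
})

test_that("category partition holds on a synthetic corpus", {
  prof <- profile_publications(small_set1$kept, small_corpus$publications)
  expect_equal(sum(table(prof$category)), nrow(prof))
  # every kept document profiled, none invented
  expect_setequal(prof$doc_id, unique(small_set1$kept$doc_id))
  expect_true(all(prof$n_targets <= prof$n_assays))
})

test_that("distribution summary matches hand computation", {
  prof <- tibble::tibble(
    doc_id = c("D1", "D2", "D3"), journal = "J", year = 2010L,
    n_assays = c(1L, 1L, 2L), n_targets = 1L, n_compounds = c(3L, 7L, 2L),
    category = "x"
  )
  s <- distribution_summary(prof, "n_assays")
  expect_equal(s$mean_1dp, 1.3)
  expect_equal(s$median, 1)
  expect_equal(s$histogram$pct[s$histogram$bin == "1"], 200 / 3)
  expect_equal(s$histogram$pct[s$histogram$bin == "2"], 100 / 3)
  expect_equal(sum(s$histogram$pct), 100)

  one <- distribution_summary(prof[1, ], "n_compounds")
  expect_equal(one$mean, one$median)
  expect_error(distribution_summary(prof[0, ], "n_assays"), "empty")

  # oracle recount on the synthetic corpus
  prof2 <- profile_publications(small_set1$kept,
    small_corpus$publications)
  s2 <- distribution_summary(prof2, "n_compounds")
  expect_equal(s2$mean, mean(prof2$n_compounds))
  expect_equal(sum(s2$histogram$n), nrow(prof2))
})

test_that("journal ranking sorts by count with alphabetical ties", {
  prof <- tibble::tibble(
    doc_id = paste0("D", 1:6),
    journal = c("B", "B", "A", "A", "C", "B"),
    year = 2010L, n_assays = 1L, n_targets = 1L, n_compounds = 1L,
    category = "SINGLE_ASSAY"
  )
  r <- journal_ranking(prof, min_publications = 0L)
  expect_equal(r$journal, c("B", "A", "C"))
  expect_equal(r$n_publications, c(3L, 2L, 1L))
  expect_equal(nrow(journal_ranking(prof, min_publications = 100L)), 0L)
})

test_that("year histogram counts per calendar year ascending", {
  prof <- tibble::tibble(
    doc_id = paste0("D", 1:3), journal = "J",
    year = c(2012L, 2010L, 2010L),
    n_assays = 1L, n_targets = 1L, n_compounds = 1L, category = "x"
  )
  h <- year_histogram(prof)
  expect_equal(h$year, c(2010L, 2012L))
  expect_equal(h$n_publications, c(2L, 1L))
  expect_equal(nrow(year_histogram(prof[0, ])), 0L)
})
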