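test_that("subset assignment uses one and more-than-five cut-offs", {
  expect_equal(assign_subset(1L, 1L), "A")
  expect_equal(assign_subset(1L, 6L), "B")
  expect_equal(assign_subset(6L, 1L), "C")
  expect_equal(assign_subset(6L, 6L), "D") # ">5" means six or more
  expect_equal(assign_subset(3L, 2L), "NONE")
  expect_equal(assign_subset(5L, 5L), "NONE") # five is not "more than five"
  expect_equal(assign_subset(1L, 5L), "NONE")
})

test_that("compound profiles conserve degrees and pool publications", {
  fx <- fixture_small()
  cur <- curate(fx$measurements, fx$publications, curation_policy("set1"))
  prof <- compound_profiles(build_records(cur$kept))
  expect_identical(as.data.frame(prof),
    as.data.frame(fx$manifest$compounds))
  expect_equal(sum(prof$degree), 11L) # one per record

  # toy: 4 compounds, 7 records in total
  toy <- tibble::tibble(
    compound_id = c("C1", "C1", "C1", "C2", "C2", "C3", "C4"),
    target_id = paste0("T", c(1, 2, 3, 1, 2, 1, 1)),
    n_publications = 1L, n_measurements = 1L, n_distinct_values = 1L,
    record_class = "SINGLE_PUB_SINGLE_VALUE", log_range = 0,
    doc_ids = as.list(c("D1", "D1", "D1", "D2", "D3", "D4", "D5")),
    values_nM = as.list(rep(1, 7))
  )
  p <- compound_profiles(toy)
  expect_equal(sum(p$degree), 7L)
  expect_equal(p$degree, c(3L, 2L, 1L, 1L))
  expect_equal(p$n_publications, c(1L, 2L, 1L, 1L))
  expect_equal(p$subset, c("NONE", "NONE", "A", "A"))
})

test_that("degree conservation holds on the synthetic corpus", {
  expect_equal(sum(small_profiles$degree), nrow(small_records))
  expect_equal(sum(table(small_profiles$subset)), nrow(small_profiles))
})

test_that("binned distributions count every compound once", {
  prof <- tibble::tibble(
    compound_id = paste0("C", 1:4),
    degree = c(1L, 1L, 2L, 7L),
    n_publications = c(1L, 1L, 1L, 25L),
    subset = "NONE"
  )
  dd <- degree_distribution(prof)
  expect_equal(dd$n[dd$bin == "1"], 2L)
  expect_equal(dd$n[dd$bin == "2"], 1L)
  expect_equal(dd$n[dd$bin == "6-10"], 1L)
  expect_equal(sum(dd$n), 4L)
  pf <- publication_frequency_distribution(prof)
  expect_equal(pf$n[pf$bin == "1"], 3L)
  expect_equal(pf$n[pf$bin == ">20"], 1L)
  expect_error(degree_distribution(prof[0, ]), "empty")

  all_one <- prof
  all_one$degree <- 1L
  d1 <- degree_distribution(all_one)
  expect_equal(d1$pct[d1$bin == "1"], 100)
})

test_that("percentage labels print one decimal, two below 0.1", {
  expect_equal(format_percent(c(69.71, 0.9, 0.02, 0.0577)),
    c("69.7", "0.9", "0.02", "0.06"))
})

test_that("matrix cells and marginals agree with the distributions", {
  prof <- tibble::tibble(
    compound_id = paste0("C", 1:3),
    degree = c(1L, 6L, 6L),
    n_publications = c(1L, 1L, 6L),
    subset = c("A", "C", "D")
  )
  m <- degree_publication_matrix(prof)
  expect_equal(m["1", "1"], 1L)
  expect_equal(m["6-10", "1"], 1L)
  expect_equal(m["6-10", "6-10"], 1L)
  expect_equal(sum(m), 3L)

  big <- degree_publication_matrix(small_profiles)
  expect_equal(sum(big), nrow(small_profiles))
  expect_identical(unname(rowSums(big)),
    as.double(degree_distribution(small_profiles)$n))
  expect_identical(unname(colSums(big)),
    as.double(publication_frequency_distribution(small_profiles)$n))
})

test_that("mean and median degree are plain arithmetic", {
  prof <- tibble::tibble(
    compound_id = paste0("C", 1:4), degree = c(1L, 1L, 1L, 3L),
    n_publications = 1L, subset = "NONE"
  )
  s <- mean_median_degree(prof)
  expect_equal(s$mean_1dp, 1.5)
  expect_equal(s$median, 1)
  prof$degree <- 2L
  s2 <- mean_median_degree(prof)
  expect_equal(s2$mean, 2)
  expect_equal(s2$median, 2)
  expect_error(mean_median_degree(prof[0, ]), "empty")
})
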