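# Promiscuity: per-compound degree (number of distinct targets with
# qualifying activity), per-compound publication frequency, their binned
# distributions, the degree-by-publication matrix, and the four compound
# subsets:
#   A: one target, one publication        B: one target, >5 publications
#   C: >5 targets, one publication        D: >5 targets, >5 publications
# ">5" means six or more throughout (the bins "5" and "6-10" are
# reported separately, which fixes the boundary).

#' Assign a compound to subset A, B, C, D or NONE
#'
#' Vectorized over degree and publication count.
#'
#' @param degree Integer vector of promiscuity degrees (>= 1).
#' @param n_publications Integer vector of per-compound publication
#'   counts (>= 1).
#' @return Character vector over `"A"`, `"B"`, `"C"`, `"D"`, `"NONE"`.
#' @export
assign_subset <- function(degree, n_publications) {
  stopifnot(all(degree >= 1L), all(n_publications >= 1L))
  case_when(
    degree == 1L & n_publications == 1L ~ "A",
    degree == 1L & n_publications > 5L ~ "B",
    degree > 5L & n_publications == 1L ~ "C",
    degree > 5L & n_publications > 5L ~ "D",
    TRUE ~ "NONE"
  )
}

#' Per-compound promiscuity profiles
#'
#' The degree is the number of activity records of the compound (one per
#' distinct target); the publication count is the number of distinct
#' documents contributing any qualifying measurement of the compound,
#' i.e. the union of `doc_ids` over its records. The sum of the degrees
#' over all compounds equals the number of records exactly.
#'
#' @param records Tibble from [build_records()].
#' @return A tibble sorted by `compound_id` with `degree`,
#'   `n_publications` and `subset`.
#' @export
compound_profiles <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(
      compound_id = character(), degree = integer(),
      n_publications = integer(), subset = character()
    ))
  }
  records %>%
    group_by(.data$compound_id) %>%
    summarise(
      degree = n(),
      n_publications = n_distinct(unlist(.data$doc_ids)),
      .groups = "drop"
    ) %>%
    mutate(subset = assign_subset(.data$degree, .data$n_publications)) %>%
    arrange(.data$compound_id)
}

.binned_distribution <- function(x, what) {
  if (length(x) == 0L) {
    stop("cannot bin an empty ", what, " vector", call. = FALSE)
  }
  tab <- table(bin_factor(x))
  pct <- 100 * as.integer(tab) / length(x)
  tibble(
    bin = names(tab),
    n = as.integer(tab),
    pct = pct,
    pct_label = format_percent(pct)
  )
}

#' Binned promiscuity-degree distribution
#'
#' Counts and percentages of compounds per degree bin (1, 2, 3, 4, 5,
#' 6-10, 11-20, >20). `pct_label` prints one decimal, or two below 0.1
#' percent.
#'
#' @param profiles Tibble from [compound_profiles()].
#' @return A tibble with columns `bin`, `n`, `pct`, `pct_label`.
#' @export
degree_distribution <- function(profiles) {
  .binned_distribution(profiles$degree, "degree")
}

#' Binned per-compound publication-frequency distribution
#'
#' Same bins and formatting as [degree_distribution()], over the number
#' of publications reporting each compound.
#'
#' @inheritParams degree_distribution
#' @return A tibble with columns `bin`, `n`, `pct`, `pct_label`.
#' @export
publication_frequency_distribution <- function(profiles) {
  .binned_distribution(profiles$n_publications, "publication count")
}

#' Degree-by-publication-count matrix
#'
#' Cross-tabulates compounds over the shared 8-bin scheme: rows are
#' degree bins (increasing promiscuity top to bottom), columns are
#' publication-count bins. Row sums reproduce [degree_distribution()]
#' and column sums reproduce [publication_frequency_distribution()]
#' exactly.
#'
#' @param profiles Tibble from [compound_profiles()].
#' @return An 8x8 integer matrix with bin labels as dimnames; convert to
#'   a writable table with [matrix_to_table()].
#' @export
degree_publication_matrix <- function(profiles) {
  if (nrow(profiles) == 0L) {
    stop("cannot tabulate an empty profile set", call. = FALSE)
  }
  m <- table(
    degree = bin_factor(profiles$degree),
    publications = bin_factor(profiles$n_publications)
  )
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  m
}

#' Mean and median promiscuity degree
#'
#' The mean degree equals the number of activity records divided by the
#' number of compounds; it is also reported rounded to one decimal, the
#' precision the summary tables print.
#'
#' @param profiles Tibble from [compound_profiles()].
#' @return A list with `mean`, `mean_1dp` and `median`.
#' @export
mean_median_degree <- function(profiles) {
  if (nrow(profiles) == 0L) {
    stop("cannot summarise an empty profile set", call. = FALSE)
  }
  list(
    mean = mean(profiles$degree),
    mean_1dp = round(mean(profiles$degree), 1),
    median = median(profiles$degree)
  )
}
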