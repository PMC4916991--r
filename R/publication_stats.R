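# Publication-level statistics: per-document assay/target/compound
# counts, the three-way categorization (single assay; multiple assays for
# one target; multiple assays for multiple targets), histogram summaries,
# journal ranking and publication-year histogram.

#' Categorize a publication by its assay and target counts
#'
#' @param n_assays,n_targets Integer vectors; each assay has exactly one
#'   target, so `n_targets <= n_assays` is required.
#' @return Character vector over `SINGLE_ASSAY`,
#'   `MULTI_ASSAY_SINGLE_TARGET`, `MULTI_ASSAY_MULTI_TARGET`.
#' @export
classify_publication <- function(n_assays, n_targets) {
  if (any(n_targets > n_assays)) {
    stop(
      "n_targets exceeds n_assays; assays are expected to have a single",
      " target each",
      call. = FALSE
    )
  }
  stopifnot(all(n_assays >= 1L), all(n_targets >= 1L))
  case_when(
    n_assays == 1L ~ "SINGLE_ASSAY",
    n_targets == 1L ~ "MULTI_ASSAY_SINGLE_TARGET",
    TRUE ~ "MULTI_ASSAY_MULTI_TARGET"
  )
}

#' Profile the publications behind a curated measurement set
#'
#' One profile per document that contributed at least one kept
#' measurement: distinct assay, target and compound counts within the
#' document, plus its category. Assays are expected to be
#' document-exclusive (ChEMBL semantics: an assay is reported in exactly
#' one document); a violation in foreign data triggers a warning.
#'
#' @param kept Curated measurement tibble.
#' @param publications Publication tibble; every `doc_id` in `kept` must
#'   resolve.
#' @return A tibble sorted by `doc_id` with journal, year, the three
#'   counts and `category`.
#' @export
profile_publications <- function(kept, publications) {
  missing_docs <- setdiff(kept$doc_id, publications$doc_id)
  if (length(missing_docs)) {
    stop(
      "unresolvable doc_id(s): ",
      paste(utils::head(missing_docs, 10L), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(kept) == 0L) {
    return(tibble(
      doc_id = character(), journal = character(), year = integer(),
      n_assays = integer(), n_targets = integer(), n_compounds = integer(),
      category = character()
    ))
  }
  shared <- kept %>%
    distinct(.data$assay_id, .data$doc_id) %>%
    count(.data$assay_id) %>%
    filter(.data$n > 1L)
  if (nrow(shared)) {
    warning(
      nrow(shared), " assay(s) appear in more than one document;",
      " per-document assay counts may not be comparable",
      call. = FALSE
    )
  }
  kept %>%
    group_by(.data$doc_id) %>%
    summarise(
      n_assays = n_distinct(.data$assay_id),
      n_targets = n_distinct(.data$target_id),
      n_compounds = n_distinct(.data$compound_id),
      .groups = "drop"
    ) %>%
    left_join(
      publications %>% select("doc_id", "journal", "year"),
      by = "doc_id"
    ) %>%
    mutate(category = classify_publication(.data$n_assays,
      .data$n_targets)) %>%
    select(
      "doc_id", "journal", "year", "n_assays", "n_targets",
      "n_compounds", "category"
    ) %>%
    arrange(.data$doc_id)
}

#' Histogram summary of a per-publication count
#'
#' Bins one of the profile count fields over 1, 2, 3, 4, 5 and >5, and
#' reports the arithmetic mean (full precision and rounded to one
#' decimal, the precision the summary tables print) and the median.
#'
#' @param profiles Tibble from [profile_publications()].
#' @param field `"n_assays"`, `"n_targets"` or `"n_compounds"`.
#' @return A list with `histogram` (tibble: `bin`, `n`, `pct`), `mean`,
#'   `mean_1dp` and `median`.
#' @export
distribution_summary <- function(profiles,
                                 field = c("n_assays", "n_targets",
                                   "n_compounds")) {
  field <- match.arg(field)
  if (nrow(profiles) == 0L) {
    stop("cannot summarise an empty profile set", call. = FALSE)
  }
  x <- profiles[[field]]
  bins <- cut(x,
    breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, Inf),
    labels = c("1", "2", "3", "4", "5", ">5")
  )
  tab <- table(bins)
  list(
    histogram = tibble(
      bin = names(tab),
      n = as.integer(tab),
      pct = 100 * as.integer(tab) / length(x)
    ),
    mean = mean(x),
    mean_1dp = round(mean(x), 1),
    median = median(x)
  )
}

#' Rank journals by number of qualifying source publications
#'
#' @param profiles Tibble from [profile_publications()].
#' @param min_publications Only journals with strictly more than this
#'   many qualifying publications are listed (default 100, the threshold
#'   used for the headline journal table; use 0 to list all).
#' @return A tibble (`journal`, `n_publications`) sorted by descending
#'   count, ties broken alphabetically.
#' @export
journal_ranking <- function(profiles, min_publications = 100L) {
  out <- profiles %>%
    count(.data$journal, name = "n_publications") %>%
    filter(.data$n_publications > min_publications)
  out[order(-out$n_publications, out$journal, method = "radix"), ]
}

#' Publications per calendar year
#'
#' @param profiles Tibble from [profile_publications()].
#' @return A tibble (`year`, `n_publications`) in ascending year order.
#' @export
year_histogram <- function(profiles) {
  profiles %>%
    count(.data$year, name = "n_publications") %>%
    arrange(.data$year)
}
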