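# Orchestration: run the whole pipeline under one policy and assemble a
# summary report (the Table-1-style count panel plus the class, category
# and subset breakdowns), with arithmetic self-checks.

.record_classes <- c(
  "SINGLE_PUB_SINGLE_VALUE", "SINGLE_PUB_MULTI_VALUE",
  "MULTI_PUB_SAME_VALUE", "MULTI_PUB_VARYING_VALUES"
)
.pub_categories <- c(
  "SINGLE_ASSAY", "MULTI_ASSAY_SINGLE_TARGET", "MULTI_ASSAY_MULTI_TARGET"
)
.subset_labels <- c("A", "B", "C", "D", "NONE")

.count_levels <- function(x, levels) {
  out <- setNames(integer(length(levels)), levels)
  tab <- table(factor(x, levels = levels))
  out[names(tab)] <- as.integer(tab)
  out
}

#' Run the full analysis pipeline under one curation policy
#'
#' Curates, builds activity records, profiles publications and compounds,
#' and assembles a report: headline counts (compounds, assays, targets,
#' activity records, potency measurements, publications), the
#' publication-category and record-class breakdowns, the promiscuity
#' distributions and the degree-by-publication matrix. When `out_dir` is
#' given every stage output is also persisted as CSV; per-stage row
#' counts and the curation audit are logged to stderr.
#'
#' @param measurements,publications Input tibbles (see
#'   [read_measurements()], [read_publications()]).
#' @param policy A [curation_policy()].
#' @param min_publications Publication threshold of the potency-range
#'   histogram (records in strictly more publications enter; default 10).
#' @param journal_min_publications Threshold of [journal_ranking()].
#' @param out_dir Optional output directory (created if needed).
#' @return An object of class `promlit_report`: a list with `summary`
#'   (named counts and statistics), `audit`, and the stage outputs
#'   (`records`, `publication_profiles`, `compound_profiles`,
#'   `degree_distribution`, `publication_frequency`, `matrix`,
#'   `range_histogram`, `journal_ranking`, `year_histogram`).
#' @export
run_all <- function(measurements, publications,
                    policy = curation_policy("set1"),
                    min_publications = 10L,
                    journal_min_publications = 100L,
                    out_dir = NULL) {
  stopifnot(min_publications >= 1L)
  cur <- curate(measurements, publications, policy)
  kept <- cur$kept
  message("curate: kept ", nrow(kept), " of ", nrow(measurements),
    " rows (audit: ",
    paste(names(cur$audit), cur$audit, sep = "=", collapse = ", "), ")")
  empty <- nrow(kept) == 0L
  if (empty) {
    warning("curation kept no measurements; reporting zeros",
      call. = FALSE)
  }
  records <- build_records(kept)
  message("records: ", nrow(records), " unique compound-target pairs")
  pub_profiles <- profile_publications(kept, publications)
  cmp_profiles <- compound_profiles(records)

  summary <- list(
    policy = policy$set,
    n_compounds = nrow(cmp_profiles),
    n_assays = n_distinct(kept$assay_id),
    n_targets = n_distinct(kept$target_id),
    n_records = nrow(records),
    n_measurements = nrow(kept),
    n_publications = nrow(pub_profiles),
    category_counts = .count_levels(pub_profiles$category,
      .pub_categories),
    class_counts = .count_levels(records$record_class, .record_classes),
    subset_counts = .count_levels(cmp_profiles$subset, .subset_labels),
    degree_total = sum(cmp_profiles$degree),
    measurement_total = sum(records$n_measurements),
    mean_degree = if (empty) NA_real_ else mean(cmp_profiles$degree),
    median_degree = if (empty) NA_real_ else median(cmp_profiles$degree)
  )
  out <- structure(
    list(
      summary = summary,
      audit = cur$audit,
      records = records,
      publication_profiles = pub_profiles,
      compound_profiles = cmp_profiles,
      degree_distribution =
        if (empty) NULL else degree_distribution(cmp_profiles),
      publication_frequency =
        if (empty) NULL else
          publication_frequency_distribution(cmp_profiles),
      matrix = if (empty) NULL else
        degree_publication_matrix(cmp_profiles),
      range_histogram = if (empty) NULL else
        suppressWarnings(range_histogram(records, min_publications)),
      journal_ranking = if (empty) NULL else
        journal_ranking(pub_profiles, journal_min_publications),
      year_histogram = if (empty) NULL else year_histogram(pub_profiles)
    ),
    class = "promlit_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(records, file.path(out_dir, "records.csv"))
    write_table(pub_profiles,
      file.path(out_dir, "publication_profiles.csv"))
    write_table(cmp_profiles,
      file.path(out_dir, "compound_profiles.csv"))
    if (!empty) {
      write_table(out$matrix, file.path(out_dir, "matrix.csv"))
    }
    scalars <- summary[c(
      "n_compounds", "n_assays", "n_targets", "n_records",
      "n_measurements", "n_publications", "degree_total",
      "measurement_total", "mean_degree", "median_degree"
    )]
    readr::write_csv(
      tibble(
        quantity = c(names(scalars),
          names(summary$category_counts), names(summary$class_counts),
          names(summary$subset_counts)),
        value = c(unlist(scalars), summary$category_counts,
          summary$class_counts, summary$subset_counts)
      ),
      file.path(out_dir, "summary.csv")
    )
    message("report written to ", out_dir)
  }
  out
}

#' @export
print.promlit_report <- function(x, ...) {
  s <- x$summary
  cat("<promlit_report policy='", s$policy, "'>\n", sep = "")
  cat(sprintf(
    "  compounds %d | assays %d | targets %d | records %d | measurements %d | publications %d\n",
    s$n_compounds, s$n_assays, s$n_targets, s$n_records,
    s$n_measurements, s$n_publications
  ))
  cat("  mean degree ", round(s$mean_degree, 1), ", median ",
    s$median_degree, "\n", sep = "")
  invisible(x)
}

#' Arithmetic consistency checks of a pipeline report
#'
#' Verifies the identities any correct report must satisfy: the four
#' record classes partition the records, the three publication categories
#' partition the publications, the five subsets partition the compounds,
#' the summed promiscuity degrees equal the record count, the summed
#' per-record measurement counts equal the measurement count, and the
#' matrix marginals reproduce the two binned distributions exactly.
#' Failures are reported, not raised.
#'
#' @param report A `promlit_report`, or any list with a compatible
#'   `summary` element (hand-typed counts can be checked this way).
#' @return A tibble with columns `check` and `pass`; checks whose inputs
#'   are absent from the report are skipped.
#' @export
consistency_check <- function(report) {
  s <- report$summary
  checks <- list()
  if (!is.null(s$class_counts) && !is.null(s$n_records)) {
    checks$class_partition <- sum(s$class_counts) == s$n_records
  }
  if (!is.null(s$category_counts) && !is.null(s$n_publications)) {
    checks$category_partition <-
      sum(s$category_counts) == s$n_publications
  }
  if (!is.null(s$subset_counts) && !is.null(s$n_compounds)) {
    checks$subset_partition <- sum(s$subset_counts) == s$n_compounds
  }
  if (!is.null(s$degree_total) && !is.null(s$n_records)) {
    checks$degree_conservation <- s$degree_total == s$n_records
  }
  if (!is.null(s$measurement_total) && !is.null(s$n_measurements)) {
    checks$measurement_conservation <-
      s$measurement_total == s$n_measurements
  }
  if (!is.null(report$matrix) && !is.null(report$degree_distribution) &&
      !is.null(report$publication_frequency)) {
    checks$matrix_row_marginals <- identical(
      unname(rowSums(report$matrix)),
      as.double(report$degree_distribution$n)
    )
    checks$matrix_column_marginals <- identical(
      unname(colSums(report$matrix)),
      as.double(report$publication_frequency$n)
    )
  }
  tibble(
    check = names(checks),
    pass = unlist(checks, use.names = FALSE)
  )
}
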