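# Activity records: one row per unique compound-target combination,
# pooling all assays, publications and potency values that report it,
# classified by a four-leaf decision tree:
#
#   single publication  -> one value            SINGLE_PUB_SINGLE_VALUE
#                       -> two or more values   SINGLE_PUB_MULTI_VALUE
#   multiple pubs       -> all values identical MULTI_PUB_SAME_VALUE
#                          (a value cited from an earlier paper)
#                       -> varying values       MULTI_PUB_VARYING_VALUES

# two potencies count as "the same value" when equal after normalization
# to nM and rounding to 3 significant figures; re-reported (cited) values
# with trivial formatting/unit differences then still match
.value_key <- function(values_nM) signif(values_nM, 3)

#' Convert a potency value to nM
#'
#' @param value Positive numeric vector.
#' @param units Character vector over `"nM"`, `"uM"`, `"M"`, recycled
#'   against `value`.
#' @return Numeric vector in nM.
#' @export
normalize_to_nM <- function(value, units) {
  factors <- c(nM = 1, uM = 1e3, M = 1e9)
  unknown <- setdiff(unique(units), names(factors))
  if (length(unknown)) {
    stop("unknown potency unit(s): ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }
  unname(value * factors[units])
}

#' Logarithmic potency range of a set of values
#'
#' `log10(max) - log10(min)`, i.e. the number of orders of magnitude the
#' values span; 0 for a single value.
#'
#' @param values_nM Positive numeric vector (at least one value).
#' @return Non-negative scalar.
#' @export
log_range <- function(values_nM) {
  if (length(values_nM) == 0L) {
    stop("log_range() needs at least one value", call. = FALSE)
  }
  if (any(values_nM <= 0)) {
    stop("potency values must be positive", call. = FALSE)
  }
  log10(max(values_nM)) - log10(min(values_nM))
}

#' Classify an activity record
#'
#' Vectorized over the three count fields; the four classes partition all
#' records. The single-publication split is by the number of reported
#' values (measurements): replicate determinations within one paper land
#' in `SINGLE_PUB_MULTI_VALUE` even if they happen to coincide
#' numerically.
#'
#' @param n_publications,n_measurements,n_distinct_values Integer vectors.
#' @return Character vector of class labels.
#' @export
classify_record <- function(n_publications, n_measurements,
                            n_distinct_values) {
  case_when(
    n_publications == 1L & n_measurements == 1L ~ "SINGLE_PUB_SINGLE_VALUE",
    n_publications == 1L ~ "SINGLE_PUB_MULTI_VALUE",
    n_distinct_values == 1L ~ "MULTI_PUB_SAME_VALUE",
    TRUE ~ "MULTI_PUB_VARYING_VALUES"
  )
}

#' Aggregate curated measurements into activity records
#'
#' Exactly one record per distinct (compound, target) pair, pooling the
#' publications and nM-normalized potency values over all assays. The
#' potency range (`log_range`) is computed over the distinct values
#' (3-significant-figure resolution), so it is 0 exactly when
#' `n_distinct_values` is 1.
#'
#' @param kept Curated measurement tibble (all relations must be "=").
#' @return A tibble keyed and sorted by (`compound_id`, `target_id`) with
#'   counts, class label, `log_range`, and list columns `doc_ids` and
#'   `values_nM`.
#' @export
build_records <- function(kept) {
  if (nrow(kept) && any(kept$relation != "=")) {
    stop(
      "build_records() expects curated input; found non-'=' relations",
      call. = FALSE
    )
  }
  if (nrow(kept) == 0L) {
    return(tibble(
      compound_id = character(), target_id = character(),
      n_publications = integer(), n_measurements = integer(),
      n_distinct_values = integer(), record_class = character(),
      log_range = double(), doc_ids = list(), values_nM = list()
    ))
  }
  kept %>%
    mutate(value_nM = normalize_to_nM(.data$value, .data$units)) %>%
    group_by(.data$compound_id, .data$target_id) %>%
    summarise(
      n_publications = n_distinct(.data$doc_id),
      n_measurements = n(),
      n_distinct_values = n_distinct(.value_key(.data$value_nM)),
      log_range = log_range(unique(.value_key(.data$value_nM))),
      doc_ids = list(sort(unique(.data$doc_id), method = "radix")),
      values_nM = list(sort(.data$value_nM)),
      .groups = "drop"
    ) %>%
    mutate(record_class = classify_record(
      .data$n_publications, .data$n_measurements, .data$n_distinct_values
    )) %>%
    select(
      "compound_id", "target_id", "n_publications", "n_measurements",
      "n_distinct_values", "record_class", "log_range", "doc_ids",
      "values_nM"
    ) %>%
    arrange(.data$compound_id, .data$target_id)
}

#' Potency-range histogram of extensively published records
#'
#' Restricts to records reported in more than `min_publications`
#' publications and bins their logarithmic potency ranges into at most
#' one, one to two, two to three, and more than three orders of
#' magnitude.
#'
#' @param records Tibble from [build_records()].
#' @param min_publications Records with `n_publications` strictly greater
#'   than this enter the histogram (default 10).
#' @return A tibble with columns `bin`, `n`, `pct`; zero rows (with a
#'   warning) when no record qualifies.
#' @export
range_histogram <- function(records, min_publications = 10L) {
  stopifnot(min_publications >= 1L)
  sel <- records[records$n_publications > min_publications, ]
  if (nrow(sel) == 0L) {
    warning("no activity record above the publication threshold",
      call. = FALSE)
    return(tibble(bin = character(), n = integer(), pct = double()))
  }
  bins <- cut(sel$log_range,
    breaks = c(-Inf, 1, 2, 3, Inf),
    labels = c("<=1", "(1,2]", "(2,3]", ">3")
  )
  tab <- table(bins)
  tibble(
    bin = names(tab),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / nrow(sel)
  )
}
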