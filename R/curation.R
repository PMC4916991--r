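# Curation: selection of qualifying potency measurements.
#
# Two shipped policies mirror the two confidence levels of the analysis:
# "set1" is the high-confidence selection (direct interactions,
# relationship type "D", assay confidence score 9, Ki/IC50 only, single
# human protein targets, original publications, exact relations); "set2"
# relaxes the assay relationship and confidence requirements but keeps
# everything else. Approximate measurements are always excluded.

#' Construct a curation policy
#'
#' @param set `"set1"` (high confidence: relationship type "D" and
#'   confidence score 9 required) or `"set2"` (no relationship/confidence
#'   requirement). Individual fields can be overridden.
#' @param require_relationship_type Single character, or `NULL` to skip
#'   the rule.
#' @param require_confidence_score Integer 0-9, or `NULL` to skip.
#' @param allowed_activity_types Character vector of admitted potency
#'   types. Defaults to `c("Ki", "IC50")` for both sets; pass a wider set
#'   for a more permissive definition of "defined potency values".
#' @param require_target_organism,require_target_type,require_doc_type
#'   Required values of the respective columns.
#' @param allowed_units Units convertible to nM; rows with other units are
#'   rejected (they could not enter potency-range computations).
#' @return An object of class `curation_policy`.
#' @export
curation_policy <- function(set = c("set1", "set2"),
                            require_relationship_type = NULL,
                            require_confidence_score = NULL,
                            allowed_activity_types = c("Ki", "IC50"),
                            require_target_organism = "Homo sapiens",
                            require_target_type = "SINGLE PROTEIN",
                            require_doc_type = "PUBLICATION",
                            allowed_units = c("nM", "uM", "M")) {
  set <- match.arg(set)
  if (set == "set1") {
    require_relationship_type <- require_relationship_type %||% "D"
    require_confidence_score <- require_confidence_score %||% 9L
  }
  structure(
    list(
      set = set,
      require_relationship_type = require_relationship_type,
      require_confidence_score = require_confidence_score,
      allowed_activity_types = allowed_activity_types,
      require_target_organism = require_target_organism,
      require_target_type = require_target_type,
      require_doc_type = require_doc_type,
      exclude_approximate = TRUE,
      allowed_units = allowed_units
    ),
    class = "curation_policy"
  )
}

#' @export
print.curation_policy <- function(x, ...) {
  cat("<curation_policy '", x$set, "'>\n", sep = "")
  cat("  doc type:        ", x$require_doc_type, "\n")
  cat("  organism:        ", x$require_target_organism, "\n")
  cat("  target type:     ", x$require_target_type, "\n")
  cat("  relation:        '=' only (approximate excluded)\n")
  cat("  units:           ", paste(x$allowed_units, collapse = ", "), "\n")
  cat("  activity types:  ",
    paste(x$allowed_activity_types, collapse = ", "), "\n")
  cat("  relationship:    ",
    x$require_relationship_type %||% "(not required)", "\n")
  cat("  confidence:      ",
    x$require_confidence_score %||% "(not required)", "\n")
  invisible(x)
}

# rule order fixes audit attribution only (coarse-to-fine); membership in
# the kept set is order-independent because rules are conjunctive
.curation_rules <- function(m, doc_type, policy) {
  rules <- list(
    require_doc_type = doc_type == policy$require_doc_type,
    require_target_organism =
      m$target_organism == policy$require_target_organism,
    require_target_type = m$target_type == policy$require_target_type,
    exclude_approximate = m$relation == "=",
    unconvertible_units = m$units %in% policy$allowed_units,
    allowed_activity_types =
      m$activity_type %in% policy$allowed_activity_types
  )
  if (!is.null(policy$require_relationship_type)) {
    rules$require_relationship_type <-
      m$relationship_type == policy$require_relationship_type
  }
  if (!is.null(policy$require_confidence_score)) {
    rules$require_confidence_score <-
      m$confidence_score == policy$require_confidence_score
  }
  rules
}

#' Apply a curation policy to raw measurements
#'
#' Keeps the rows passing every policy predicate and attributes each
#' rejected row to the first rule (in declared order) that disqualifies
#' it. Conservation always holds: `nrow(kept) + sum(audit)` equals the
#' number of input rows.
#'
#' @param measurements Tibble as returned by [read_measurements()] or
#'   [generate_corpus()].
#' @param publications Tibble as returned by [read_publications()]; every
#'   `doc_id` in `measurements` must be present.
#' @param policy A [curation_policy()].
#' @return A list with `kept` (tibble of passing measurements, input
#'   order preserved) and `audit` (named integer vector of per-rule
#'   rejection counts).
#' @export
curate <- function(measurements, publications, policy) {
  stopifnot(inherits(policy, "curation_policy"))
  missing_docs <- setdiff(measurements$doc_id, publications$doc_id)
  if (length(missing_docs)) {
    stop(
      "measurement doc_id(s) absent from publication table: ",
      paste(utils::head(missing_docs, 10L), collapse = ", "),
      call. = FALSE
    )
  }
  doc_type <- publications$doc_type[
    match(measurements$doc_id, publications$doc_id)
  ]
  rules <- .curation_rules(measurements, doc_type, policy)
  alive <- rep(TRUE, nrow(measurements))
  audit <- setNames(integer(length(rules)), names(rules))
  for (nm in names(rules)) {
    failed <- alive & !rules[[nm]]
    audit[[nm]] <- sum(failed)
    alive <- alive & rules[[nm]]
  }
  list(kept = measurements[alive, ], audit = audit)
}

#' Check that a high-confidence selection nests inside a relaxed one
#'
#' The set-1 predicates imply the set-2 predicates, so on identical raw
#' input every set-1 row must also be a set-2 row.
#'
#' @param set1_kept,set2_kept `kept` tibbles from two [curate()] calls on
#'   the same raw input.
#' @return `TRUE` if every `set1_kept` row occurs in `set2_kept`.
#' @export
assert_subset <- function(set1_kept, set2_kept) {
  nrow(anti_join(set1_kept, set2_kept,
    by = names(set1_kept))) == 0L
}
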