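# Flat-table I/O: measurement and publication inputs, result tables.
#
# All files are UTF-8 delimited text with a header row. The delimiter is
# taken from the file extension (".tsv" -> tab, otherwise comma) unless
# given explicitly. Writers emit a stable column order and a deterministic
# row order (sorted by the schema's declared key) so that outputs are
# bit-stable; numeric fields round-trip exactly.

.schemas <- list(
  measurement = list(
    columns = c(
      "compound_id", "assay_id", "target_id", "target_organism",
      "target_type", "confidence_score", "relationship_type",
      "activity_type", "relation", "value", "units", "doc_id"
    ),
    types = c(
      compound_id = "c", assay_id = "c", target_id = "c",
      target_organism = "c", target_type = "c", confidence_score = "i",
      relationship_type = "c", activity_type = "c", relation = "c",
      value = "d", units = "c", doc_id = "c"
    ),
    key = c("compound_id", "target_id", "doc_id", "assay_id", "value")
  ),
  publication = list(
    columns = c("doc_id", "journal", "year", "doc_type"),
    types = c(doc_id = "c", journal = "c", year = "i", doc_type = "c"),
    key = "doc_id"
  ),
  record = list(
    columns = c(
      "compound_id", "target_id", "n_publications", "n_measurements",
      "n_distinct_values", "record_class", "log_range", "doc_ids",
      "values_nM"
    ),
    types = c(
      compound_id = "c", target_id = "c", n_publications = "i",
      n_measurements = "i", n_distinct_values = "i", record_class = "c",
      log_range = "d", doc_ids = "list_c", values_nM = "list_d"
    ),
    key = c("compound_id", "target_id")
  ),
  publication_profile = list(
    columns = c(
      "doc_id", "journal", "year", "n_assays", "n_targets",
      "n_compounds", "category"
    ),
    types = c(
      doc_id = "c", journal = "c", year = "i", n_assays = "i",
      n_targets = "i", n_compounds = "i", category = "c"
    ),
    key = "doc_id"
  ),
  compound_profile = list(
    columns = c("compound_id", "degree", "n_publications", "subset"),
    types = c(
      compound_id = "c", degree = "i", n_publications = "i", subset = "c"
    ),
    key = "compound_id"
  ),
  matrix = list(
    # bin labels as in promiscuity_bins(), inlined for load order
    columns = c("degree_bin", "1", "2", "3", "4", "5", "6-10", "11-20",
      ">20"),
    types = c(degree_bin = "c", setNames(rep("i", 8),
      c("1", "2", "3", "4", "5", "6-10", "11-20", ">20"))),
    key = character(0) # fixed bin order, already deterministic
  )
)

#' Table schemas used by the pipeline
#'
#' Returns the declared column order, column types and sort key of one of
#' the six table layouts the package reads and writes.
#'
#' @param table One of `"measurement"`, `"publication"`, `"record"`,
#'   `"publication_profile"`, `"compound_profile"`, `"matrix"`.
#' @return A list with elements `columns`, `types` and `key`.
#' @export
promlit_schema <- function(table) {
  table <- match.arg(table, names(.schemas))
  .schemas[[table]]
}

.delim_for <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

.read_raw <- function(path, delim) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  readr::read_delim(
    path,
    delim = .delim_for(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
}

.check_columns <- function(raw, schema, what) {
  missing <- setdiff(schema$columns, names(raw))
  if (length(missing)) {
    stop(
      "missing mandatory column(s) in ", what, " table: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

# parse a character column to numeric/integer, failing with file line
# numbers (header is line 1, so data row i is line i + 1)
.parse_numeric <- function(x, col, integer = FALSE) {
  val <- suppressWarnings(as.numeric(x))
  bad <- is.na(val) | (x == "")
  if (any(bad)) {
    stop(
      "unparsable numeric value in column '", col, "' at file line(s) ",
      paste(which(bad) + 1L, collapse = ", "),
      call. = FALSE
    )
  }
  if (integer) as.integer(round(val)) else val
}

.check_nonempty <- function(raw, cols, what) {
  for (col in cols) {
    bad <- which(raw[[col]] == "")
    if (length(bad)) {
      stop(
        "empty '", col, "' in ", what, " table at file line(s) ",
        paste(bad + 1L, collapse = ", "),
        call. = FALSE
      )
    }
  }
}

#' Read a measurement table
#'
#' One row per potency determination: compound, assay, target (with
#' organism and type), assay confidence score and relationship type,
#' activity type (e.g. Ki or IC50), relation, value, units and source
#' document. The reader never filters: approximate relations (">", "<",
#' "~", ">=", "<=") are kept verbatim, because disqualifying them is the
#' job of [curate()], not of file parsing. An empty relation defaults to
#' "=".
#'
#' @param path Path to a CSV/TSV file with a header row containing at
#'   least the columns of `promlit_schema("measurement")` (order does not
#'   matter; extra columns are ignored).
#' @param delim Field delimiter; default is inferred from the extension.
#' @return A tibble with one row per data row of the file.
#' @export
read_measurements <- function(path, delim = NULL) {
  sc <- promlit_schema("measurement")
  raw <- .read_raw(path, delim)
  .check_columns(raw, sc, "measurement")
  raw <- raw[sc$columns]
  if (nrow(raw) == 0L) {
    return(tibble(
      compound_id = character(), assay_id = character(),
      target_id = character(), target_organism = character(),
      target_type = character(), confidence_score = integer(),
      relationship_type = character(), activity_type = character(),
      relation = character(), value = double(), units = character(),
      doc_id = character()
    ))
  }
  raw$relation <- trimws(raw$relation)
  raw$relation[raw$relation == ""] <- "="
  .check_nonempty(raw, setdiff(sc$columns, c("relation", "value",
    "confidence_score")), "measurement")
  value <- .parse_numeric(raw$value, "value")
  if (any(value <= 0)) {
    stop(
      "non-positive potency value at file line(s) ",
      paste(which(value <= 0) + 1L, collapse = ", "),
      call. = FALSE
    )
  }
  confidence <- .parse_numeric(raw$confidence_score, "confidence_score",
    integer = TRUE)
  tibble(
    compound_id = raw$compound_id,
    assay_id = raw$assay_id,
    target_id = raw$target_id,
    target_organism = raw$target_organism,
    target_type = raw$target_type,
    confidence_score = confidence,
    relationship_type = raw$relationship_type,
    activity_type = raw$activity_type,
    relation = raw$relation,
    value = value,
    units = raw$units,
    doc_id = raw$doc_id
  )
}

#' Read a publication table
#'
#' One row per source document: identifier, journal, year and document
#' type (`"PUBLICATION"` for original research articles; anything else,
#' e.g. patents, is excluded later by curation).
#'
#' @inheritParams read_measurements
#' @return A tibble with columns `doc_id`, `journal`, `year`, `doc_type`.
#' @export
read_publications <- function(path, delim = NULL) {
  sc <- promlit_schema("publication")
  raw <- .read_raw(path, delim)
  .check_columns(raw, sc, "publication")
  raw <- raw[sc$columns]
  if (nrow(raw) == 0L) {
    return(tibble(
      doc_id = character(), journal = character(), year = integer(),
      doc_type = character()
    ))
  }
  dup <- unique(raw$doc_id[duplicated(raw$doc_id)])
  if (length(dup)) {
    stop(
      "duplicate doc_id in publication table: ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  .check_nonempty(raw, c("doc_id", "journal", "doc_type"), "publication")
  year <- .parse_numeric(raw$year, "year", integer = TRUE)
  if (any(year < 1900 | year > 2100)) {
    stop(
      "implausible publication year at file line(s) ",
      paste(which(year < 1900 | year > 2100) + 1L, collapse = ", "),
      call. = FALSE
    )
  }
  tibble(
    doc_id = raw$doc_id, journal = raw$journal, year = year,
    doc_type = raw$doc_type
  )
}

.infer_schema <- function(cols) {
  for (nm in names(.schemas)) {
    if (setequal(cols, .schemas[[nm]]$columns)) return(nm)
  }
  stop(
    "columns do not match any declared table schema: ",
    paste(cols, collapse = ", "),
    call. = FALSE
  )
}

#' Write a result table to a delimited file
#'
#' Emits UTF-8 with a header row, the schema's declared column order and a
#' deterministic row order (sorted by the schema key, radix/C-locale).
#' List columns of the record table (`doc_ids`, `values_nM`) are joined
#' with ";" in sorted order; numbers use a shortest round-trip
#' representation so `read_table()` recovers them exactly.
#'
#' @param x A tibble conforming to one declared schema, or the matrix
#'   returned by [degree_publication_matrix()].
#' @param path Output path.
#' @param table Schema name; inferred from the columns when `NULL`.
#' @param delim Field delimiter; default inferred from the extension.
#' @return Invisibly, the number of data rows written.
#' @export
write_table <- function(x, path, table = NULL, delim = NULL) {
  if (is.matrix(x)) {
    x <- matrix_to_table(x)
    table <- "matrix"
  }
  table <- table %||% .infer_schema(names(x))
  sc <- promlit_schema(table)
  .check_columns(x, sc, table)
  x <- x[sc$columns]
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      type <- sc$types[[col]]
      x[[col]] <- vapply(x[[col]], function(v) {
        if (type == "list_d") {
          paste(fmt_num(sort(v)), collapse = ";")
        } else {
          paste(sort(as.character(v), method = "radix"), collapse = ";")
        }
      }, character(1))
    }
  }
  if (length(sc$key) && nrow(x) > 1L) {
    x <- x[radix_order(x, sc$key), ]
  }
  readr::write_delim(x, path, delim = .delim_for(path, delim),
    progress = FALSE)
  invisible(nrow(x))
}

#' Read back a result table written by [write_table()]
#'
#' @param path Path to the file.
#' @param table Schema name (see [promlit_schema()]); required because
#'   several result tables share column names.
#' @param delim Field delimiter; default inferred from the extension.
#' @return A tibble typed per the schema, with record list columns
#'   (`doc_ids`, `values_nM`) restored.
#' @export
read_table <- function(path, table, delim = NULL) {
  sc <- promlit_schema(table)
  raw <- .read_raw(path, delim)
  .check_columns(raw, sc, table)
  raw <- raw[sc$columns]
  out <- raw
  for (col in names(out)) {
    type <- sc$types[[col]]
    if (nrow(out) == 0L) {
      out[[col]] <- switch(type,
        c = character(), i = integer(), d = double(), list())
      next
    }
    out[[col]] <- switch(type,
      c = out[[col]],
      i = .parse_numeric(out[[col]], col, integer = TRUE),
      d = .parse_numeric(out[[col]], col),
      list_c = strsplit(out[[col]], ";", fixed = TRUE),
      list_d = lapply(strsplit(out[[col]], ";", fixed = TRUE), as.numeric)
    )
  }
  out
}

#' @rdname degree_publication_matrix
#' @param m A degree-by-publication count matrix.
#' @export
matrix_to_table <- function(m) {
  stopifnot(is.matrix(m))
  out <- as_tibble(m, rownames = "degree_bin")
  for (col in setdiff(names(out), "degree_bin")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
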