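# Synthetic corpus generator.
#
# Emits ChEMBL-shaped measurement and publication tables with a known
# ground-truth manifest, emulating the statistical structure of curated
# medicinal-chemistry bioactivity data: heavily right-skewed
# publications-per-compound counts (~94% singletons), a promiscuity-degree
# distribution with ~70% single-target compounds, documents that read
# like chemical-series papers (many compounds against a small assay
# panel), replicated potency values with log-scale scatter, value
# duplication by citation, and contaminating rows that high-confidence
# curation must remove.
#
# Degree and publication count are sampled independently per compound
# (the data show no correlation between the two), from binned categorical
# distributions whose defaults are the observed distributions of the
# curated high-confidence set. Documents carry a planned target-panel
# size ("budget"); compounds land in documents whose panel fits their
# degree and preferentially reuse targets already on the panel, which is
# what keeps targets and assays per publication low (~2-3) while
# compounds per publication is high (~17).

.chembl21_set1_compounds <- 168208L

#' Observed set-1 promiscuity-degree distribution (ChEMBL 21)
#'
#' Proportions of compounds per degree bin in the curated high-confidence
#' set (117253, 30457, 12092, 5214, 1514, 1368, 280 and 30 compounds out
#' of 168208). Used as the generator default.
#'
#' @return Named numeric vector over [promiscuity_bins()] labels, summing
#'   to 1.
#' @export
chembl21_degree_distribution <- function() {
  setNames(
    c(117253, 30457, 12092, 5214, 1514, 1368, 280, 30) /
      .chembl21_set1_compounds,
    promiscuity_bins()$labels
  )
}

#' Observed set-1 publications-per-compound distribution (ChEMBL 21)
#'
#' Proportions of compounds per publication-count bin in the curated
#' high-confidence set (158995, 7054, 991, 398, 200, 327, 146 and 97
#' compounds out of 168208). Used as the generator default.
#'
#' @return Named numeric vector over [promiscuity_bins()] labels, summing
#'   to 1.
#' @export
chembl21_publication_distribution <- function() {
  setNames(
    c(158995, 7054, 991, 398, 200, 327, 146, 97) /
      .chembl21_set1_compounds,
    promiscuity_bins()$labels
  )
}

.default_panel_distribution <- function() {
  setNames(
    c(0.55, 0.20, 0.09, 0.06, 0.04, 0.044, 0.011, 0.005),
    promiscuity_bins()$labels
  )
}

.contamination_rules <- c(
  "approximate_relation", "low_confidence", "non_d_relationship",
  "non_human_organism", "non_protein_target", "non_publication_doc"
)

#' Configuration of the synthetic corpus generator
#'
#' All randomness is driven by `seed`: an identical configuration gives
#' byte-identical tables.
#'
#' @param seed Integer RNG seed.
#' @param n_compounds Number of clean compounds to generate.
#' @param n_targets Size of the target pool; defaults to roughly one
#'   target per 107 compounds (the observed ratio), floored at 120 so the
#'   most promiscuous degree band always fits.
#' @param degree_distribution,publication_count_distribution Named
#'   probabilities over the [promiscuity_bins()] labels; within banded
#'   bins values are drawn uniformly, with ">20" capped at 80 targets
#'   (the most promiscuous observed compounds reach 71).
#' @param targets_per_publication_distribution Named probabilities (same
#'   bins) for the planned target-panel size of a document. The default
#'   (mean ~2.7) makes about half of all documents single-target
#'   series papers and reproduces the observed 2-3 assays and targets
#'   per publication.
#' @param compounds_per_publication_mean Average number of compounds per
#'   document (default 16.7, the observed mean); sets the document pool
#'   size.
#' @param target_reuse_probability Probability that a compound takes a
#'   target already on its documents' panels rather than adding a fresh
#'   one when the panel has room (default 0.9).
#' @param retest_doc_affinity Probability that an additional publication
#'   of a record is drawn from documents already covering the target
#'   (default 0.8); retests and citations cluster on well-studied
#'   targets, which keeps document panels small.
#' @param replicate_probability Probability that a document runs more
#'   than one assay for a given target on its panel, so that every
#'   compound measured there gets replicate determinations (default
#'   0.107, the observed fraction of single-publication records with
#'   multiple values).
#' @param replicate_extra_mean Poisson mean for assay runs beyond the
#'   second when a target is replicated (default 0.3).
#' @param referenced_value_probability Probability that a
#'   multi-publication record repeats one identical (cited) value in
#'   every publication (default 0.39, the observed same-value fraction
#'   among multi-publication records).
#' @param log10_potency_mean,log10_potency_sd_between_records Location
#'   and spread of per-record true potencies on the log10 nM scale
#'   (defaults 2.0, i.e. 100 nM, and 1.0).
#' @param log10_potency_sd_within_record Log10 standard deviation of
#'   measurement scatter around a record's true potency (default 0.5,
#'   which reproduces multi-order-of-magnitude ranges in heavily
#'   re-measured records).
#' @param unit_probabilities Named probabilities over nM/uM/M used to
#'   express each measurement.
#' @param activity_type_probabilities Named probabilities over potency
#'   types (default Ki/IC50 in equal parts).
#' @param max_targets_per_publication Feasibility cap: a compound's
#'   publication count is raised to `ceiling(degree / cap)` when its
#'   targets cannot fit its documents.
#' @param contamination Named fractions (relative to the clean row count)
#'   of extra rows violating exactly one high-confidence curation rule
#'   each: `approximate_relation`, `low_confidence`,
#'   `non_d_relationship`, `non_human_organism`, `non_protein_target`,
#'   `non_publication_doc`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_compounds = 1000L,
                             n_targets = NULL,
                             degree_distribution =
                               chembl21_degree_distribution(),
                             publication_count_distribution =
                               chembl21_publication_distribution(),
                             targets_per_publication_distribution =
                               .default_panel_distribution(),
                             compounds_per_publication_mean = 16.7,
                             target_reuse_probability = 0.9,
                             retest_doc_affinity = 0.8,
                             replicate_probability = 0.107,
                             replicate_extra_mean = 0.3,
                             referenced_value_probability = 0.39,
                             log10_potency_mean = 2.0,
                             log10_potency_sd_between_records = 1.0,
                             log10_potency_sd_within_record = 0.5,
                             unit_probabilities =
                               c(nM = 0.70, uM = 0.25, M = 0.05),
                             activity_type_probabilities =
                               c(Ki = 0.5, IC50 = 0.5),
                             max_targets_per_publication = 80L,
                             contamination = setNames(
                               rep(0.01, 6), .contamination_rules)) {
  bins <- promiscuity_bins()
  check_dist <- function(d, what) {
    if (!identical(sort(names(d)), sort(bins$labels))) {
      stop(what, " must be named over the bins ",
        paste(bins$labels, collapse = ", "), call. = FALSE)
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
    d[bins$labels]
  }
  degree_distribution <- check_dist(degree_distribution,
    "degree_distribution")
  publication_count_distribution <- check_dist(
    publication_count_distribution, "publication_count_distribution")
  targets_per_publication_distribution <- check_dist(
    targets_per_publication_distribution,
    "targets_per_publication_distribution")
  n_targets <- n_targets %||%
    max(120L, as.integer(ceiling(n_compounds / 107)))
  max_degree <- max(bins$upper[degree_distribution > 0])
  if (max_degree > n_targets) {
    stop(
      "infeasible configuration: highest degree band (", max_degree,
      ") exceeds the target pool (", n_targets, ")",
      call. = FALSE
    )
  }
  stopifnot(
    n_compounds >= 1L,
    compounds_per_publication_mean > 0,
    target_reuse_probability >= 0, target_reuse_probability <= 1,
    retest_doc_affinity >= 0, retest_doc_affinity <= 1,
    replicate_probability >= 0, replicate_probability <= 1,
    referenced_value_probability >= 0, referenced_value_probability <= 1,
    replicate_extra_mean >= 0,
    log10_potency_sd_between_records >= 0,
    log10_potency_sd_within_record >= 0,
    max_targets_per_publication >= 1L
  )
  if (!identical(sort(names(contamination)),
      sort(.contamination_rules)) ||
      any(contamination < 0) || any(contamination > 1)) {
    stop(
      "contamination must be fractions in [0,1] named over: ",
      paste(.contamination_rules, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed),
      n_compounds = as.integer(n_compounds),
      n_targets = as.integer(n_targets),
      degree_distribution = degree_distribution,
      publication_count_distribution = publication_count_distribution,
      targets_per_publication_distribution =
        targets_per_publication_distribution,
      compounds_per_publication_mean = compounds_per_publication_mean,
      target_reuse_probability = target_reuse_probability,
      retest_doc_affinity = retest_doc_affinity,
      replicate_probability = replicate_probability,
      replicate_extra_mean = replicate_extra_mean,
      referenced_value_probability = referenced_value_probability,
      log10_potency_mean = log10_potency_mean,
      log10_potency_sd_between_records = log10_potency_sd_between_records,
      log10_potency_sd_within_record = log10_potency_sd_within_record,
      unit_probabilities = unit_probabilities,
      activity_type_probabilities = activity_type_probabilities,
      max_targets_per_publication = as.integer(max_targets_per_publication),
      contamination = contamination[.contamination_rules]
    ),
    class = "generator_config"
  )
}

# draw integer values from the binned categorical: pick a bin, then
# uniform within the band
.sample_binned <- function(n, probs) {
  bins <- promiscuity_bins()
  b <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  width <- bins$upper[b] - bins$lower[b] + 1L
  bins$lower[b] + pmin(width - 1L, as.integer(floor(runif(n) * width)))
}

.journal_pool <- function() {
  list(
    names = c(
      "Bioorg. Med. Chem. Lett.", "J. Med. Chem.", "Bioorg. Med. Chem.",
      "Eur. J. Med. Chem.", "ACS Med. Chem. Lett.", "J. Nat. Prod.",
      "MedChemComm", "Med. Chem. Res.", "Other Med. Chem. J."
    ),
    weights = c(4456, 3417, 1424, 689, 419, 200, 186, 111, 311)
  )
}

#' Generate a synthetic bioactivity corpus with a ground-truth manifest
#'
#' See [generator_config()] for the generative model. The user's RNG
#' state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A list with:
#'   * `measurements`: measurement tibble (clean rows realise each
#'     compound's sampled degree and publication count; contaminated rows
#'     each violate exactly one high-confidence rule);
#'   * `publications`: publication tibble covering every referenced
#'     document;
#'   * `manifest`: ground truth - `compounds` (true degree, publication
#'     count, subset), `records` (true counts, class and log-range per
#'     compound-target pair), `rows` (per measurement-row contamination
#'     flag and violated rule, aligned with `measurements`),
#'     `contamination_counts`, `n_set1_kept` and `n_set2_kept`;
#'   * `config`: the configuration used.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n_compounds
  d <- .sample_binned(n, config$degree_distribution)
  p <- .sample_binned(n, config$publication_count_distribution)
  p <- pmax(p, as.integer(ceiling(d / config$max_targets_per_publication)))

  n_docs <- max(
    max(p),
    as.integer(round(sum(p) / config$compounds_per_publication_mean)),
    1L
  )
  budget <- .sample_binned(n_docs,
    config$targets_per_publication_distribution)
  cid <- sprintf("C%06d", seq_len(n))
  tid <- sprintf("T%05d", seq_len(config$n_targets))
  did <- sprintf("D%06d", seq_len(n_docs))
  unit_factor <- c(nM = 1, uM = 1e3, M = 1e9)
  unit_names <- names(config$unit_probabilities)
  type_names <- names(config$activity_type_probabilities)

  doc_targets <- vector("list", n_docs) # realized panel per document
  doc_mult <- vector("list", n_docs)    # assay runs per panel target
  docs_with_target <- vector("list", config$n_targets)
  acc <- vector("list", n)
  rec_acc <- vector("list", n)

  # put a target on a document's panel (once), sampling how many assay
  # runs the document performs for it
  add_to_panel <- function(doc, t) {
    if (!(t %in% doc_targets[[doc]])) {
      doc_targets[[doc]] <<- c(doc_targets[[doc]], t)
      runs <- if (runif(1) < config$replicate_probability) {
        2L + rpois(1, config$replicate_extra_mean)
      } else 1L
      doc_mult[[doc]] <<- c(doc_mult[[doc]], runs)
      docs_with_target[[t]] <<- c(docs_with_target[[t]], doc)
    }
  }

  for (i in seq_len(n)) {
    di <- d[i]
    pi_ <- p[i]
    # primary document: a series paper whose planned panel fits the
    # compound's degree (fall back to the largest panels when the degree
    # outgrows every document)
    eligible <- which(budget >= di)
    if (!length(eligible)) {
      eligible <- order(budget, decreasing = TRUE)[
        seq_len(min(n_docs, 10L))]
    }
    Dp <- eligible[sample.int(length(eligible), 1L)]
    # one target per record, reusing the primary panel where possible;
    # fresh targets only while the panel has room (the panel grows past
    # its budget only when the degree leaves no other choice)
    chosen <- integer(di)
    for (r in seq_len(di)) {
      used <- chosen[seq_len(r - 1L)]
      avail <- setdiff(doc_targets[[Dp]], used)
      roomy <- length(doc_targets[[Dp]]) < budget[Dp]
      take_reuse <- length(avail) > 0L &&
        (!roomy || runif(1) < config$target_reuse_probability)
      if (take_reuse) {
        t <- avail[sample.int(length(avail), 1L)]
      } else {
        repeat {
          t <- sample.int(config$n_targets, 1L)
          if (!(t %in% used)) break
        }
      }
      chosen[r] <- t
      add_to_panel(Dp, t)
    }
    # additional publications re-report one record each, preferring
    # documents that already cover the target (retests and citations
    # cluster on popular targets)
    ri <- seq_len(di)
    dd <- rep(Dp, di)
    D_used <- Dp
    if (pi_ > 1L) {
      for (e in seq_len(pi_ - 1L)) {
        r <- sample.int(di, 1L)
        t <- chosen[r]
        cands <- setdiff(docs_with_target[[t]], D_used)
        if (length(cands) &&
            runif(1) < config$retest_doc_affinity) {
          doc <- cands[sample.int(length(cands), 1L)]
        } else {
          others <- setdiff(seq_len(n_docs), D_used)
          doc <- others[sample.int(length(others), 1L)]
          add_to_panel(doc, t)
        }
        D_used <- c(D_used, doc)
        ri <- c(ri, r)
        dd <- c(dd, doc)
      }
    }

    m_doc <- integer(0); m_rec <- integer(0)
    m_occ <- integer(0); m_val <- double(0)
    rec_np <- integer(di); rec_nm <- integer(di)
    rec_ndv <- integer(di); rec_lr <- double(di)
    for (r in seq_len(di)) {
      docs_r <- unique(dd[ri == r])
      # one measurement per assay run of this target in each document
      reps <- vapply(docs_r, function(doc) {
        doc_mult[[doc]][match(chosen[r], doc_targets[[doc]])]
      }, integer(1))
      mdoc <- rep(docs_r, reps)
      mm <- length(mdoc)
      mu <- config$log10_potency_mean +
        rnorm(1, 0, config$log10_potency_sd_between_records)
      if (length(docs_r) >= 2L &&
          runif(1) < config$referenced_value_probability) {
        v <- rep(signif(
          10^(mu + rnorm(1, 0, config$log10_potency_sd_within_record)),
          3), mm)
      } else {
        v <- signif(
          10^(mu + rnorm(mm, 0, config$log10_potency_sd_within_record)),
          3)
      }
      uv <- unique(v)
      rec_np[r] <- length(docs_r)
      rec_nm[r] <- mm
      rec_ndv[r] <- length(uv)
      rec_lr[r] <- log10(max(uv)) - log10(min(uv))
      m_doc <- c(m_doc, mdoc)
      m_rec <- c(m_rec, rep(r, mm))
      m_occ <- c(m_occ, unlist(lapply(reps, seq_len)))
      m_val <- c(m_val, v)
    }
    mm_tot <- length(m_val)
    units <- sample(unit_names, mm_tot, replace = TRUE,
      prob = config$unit_probabilities)
    atype <- sample(type_names, mm_tot, replace = TRUE,
      prob = config$activity_type_probabilities)
    m_tid <- tid[chosen[m_rec]]
    acc[[i]] <- list(
      compound_id = rep(cid[i], mm_tot),
      assay_id = paste0("A", formatC(m_doc, width = 6, flag = "0"), "_",
        m_tid, ifelse(m_occ > 1L, paste0("_r", m_occ), "")),
      target_id = m_tid,
      value = m_val / unit_factor[units],
      units = units,
      activity_type = atype,
      doc_id = did[m_doc]
    )
    rec_acc[[i]] <- list(
      compound_id = rep(cid[i], di),
      target_id = tid[chosen],
      n_publications = rec_np,
      n_measurements = rec_nm,
      n_distinct_values = rec_ndv,
      log_range = rec_lr
    )
  }

  pull <- function(lst, field) {
    unlist(lapply(lst, `[[`, field), use.names = FALSE)
  }
  clean <- tibble(
    compound_id = pull(acc, "compound_id"),
    assay_id = pull(acc, "assay_id"),
    target_id = pull(acc, "target_id"),
    target_organism = "Homo sapiens",
    target_type = "SINGLE PROTEIN",
    confidence_score = 9L,
    relationship_type = "D",
    activity_type = pull(acc, "activity_type"),
    relation = "=",
    value = pull(acc, "value"),
    units = pull(acc, "units"),
    doc_id = pull(acc, "doc_id")
  )
  n_clean <- nrow(clean)

  used <- sort(unique(match(clean$doc_id, did)))
  jp <- .journal_pool()
  year_main <- sample(2006:2014, length(used), replace = TRUE)
  year_tail <- sample(1995:2005, length(used), replace = TRUE)
  publications <- tibble(
    doc_id = did[used],
    journal = sample(jp$names, length(used), replace = TRUE,
      prob = jp$weights),
    year = as.integer(ifelse(runif(length(used)) < 0.85, year_main,
      year_tail)),
    doc_type = "PUBLICATION"
  )

  # contaminating rows: clone a clean row, corrupt exactly one field
  contam <- list()
  contam_rule <- character(0)
  k_per_rule <- setNames(integer(length(.contamination_rules)),
    .contamination_rules)
  extra_pubs <- NULL
  ax <- 0L
  for (rule in .contamination_rules) {
    k <- min(n_clean, as.integer(round(config$contamination[[rule]] *
      n_clean)))
    k_per_rule[[rule]] <- k
    if (k == 0L) next
    idx <- sample.int(n_clean, k)
    rows <- clean[idx, ]
    rows$assay_id <- sprintf("AX%06d", ax + seq_len(k))
    ax <- ax + k
    if (rule == "approximate_relation") {
      rows$relation <- sample(c(">", "<", "~"), k, replace = TRUE)
    } else if (rule == "low_confidence") {
      rows$confidence_score <- sample(0:8, k, replace = TRUE)
    } else if (rule == "non_d_relationship") {
      rows$relationship_type <- sample(c("H", "N", "U"), k,
        replace = TRUE)
    } else if (rule == "non_human_organism") {
      rows$target_organism <- sample(
        c("Rattus norvegicus", "Mus musculus"), k, replace = TRUE)
    } else if (rule == "non_protein_target") {
      rows$target_type <- sample(
        c("PROTEIN COMPLEX", "CELL-LINE", "ORGANISM"), k, replace = TRUE)
    } else if (rule == "non_publication_doc") {
      new_docs <- sprintf("DX%05d", seq_len(k))
      rows$doc_id <- new_docs
      extra_pubs <- tibble(
        doc_id = new_docs,
        journal = "Patent Office",
        year = sample(2006:2014, k, replace = TRUE),
        doc_type = sample(c("PATENT", "DATASET"), k, replace = TRUE)
      )
    }
    contam[[rule]] <- rows
    contam_rule <- c(contam_rule, rep(rule, k))
  }
  measurements <- bind_rows(c(list(clean), unname(contam)))
  rule_col <- c(rep(NA_character_, n_clean), contam_rule)
  if (!is.null(extra_pubs)) {
    publications <- bind_rows(publications, extra_pubs)
  }

  ord <- radix_order(measurements, promlit_schema("measurement")$key)
  measurements <- measurements[ord, ]
  rule_col <- rule_col[ord]

  records <- tibble(
    compound_id = pull(rec_acc, "compound_id"),
    target_id = pull(rec_acc, "target_id"),
    n_publications = pull(rec_acc, "n_publications"),
    n_measurements = pull(rec_acc, "n_measurements"),
    n_distinct_values = pull(rec_acc, "n_distinct_values"),
    log_range = pull(rec_acc, "log_range")
  )
  records$record_class <- classify_record(
    records$n_publications, records$n_measurements,
    records$n_distinct_values
  )
  records <- records[radix_order(records, c("compound_id", "target_id")), ]

  manifest <- list(
    compounds = tibble(
      compound_id = cid,
      degree = d,
      n_publications = p,
      subset = assign_subset(d, p)
    ),
    records = records[, c(
      "compound_id", "target_id", "n_publications", "n_measurements",
      "n_distinct_values", "record_class", "log_range"
    )],
    rows = tibble(
      contaminated = !is.na(rule_col),
      rule = rule_col
    ),
    contamination_counts = k_per_rule,
    n_set1_kept = n_clean,
    n_set2_kept = n_clean + k_per_rule[["low_confidence"]] +
      k_per_rule[["non_d_relationship"]]
  )

  list(
    measurements = measurements,
    publications = publications[order(publications$doc_id,
      method = "radix"), ],
    manifest = manifest,
    config = config
  )
}
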