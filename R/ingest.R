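#' Merge evidence arms into one unique target list
#'
#' Combines the three sourcing arms — the unstructured literature corpus,
#' structured genomic database memberships, and the genomics raw-data
#' survivors (differential expression and variant analysis) — into one row
#' per distinct gene symbol with full provenance. Symbols are normalized by
#' uppercasing and an optional alias table; rows with a missing symbol or an
#' unknown asset class are skipped and counted.
#'
#' @param documents Evidence-document tibble (see [read_documents()]); may be
#'   `NULL` or empty.
#' @param db_table Tibble with columns `target`, `database` listing
#'   structured-database memberships, or `NULL`.
#' @param deg_targets Character vector of DE-survivor gene symbols, or `NULL`.
#' @param variant_targets Character vector of genes carrying surviving
#'   variants, or `NULL`.
#' @param alias Optional alias tibble with columns `alias`, `symbol`; matched
#'   case-insensitively and applied before aggregation.
#' @param relevance_min Optional cut-off applied to a per-document
#'   `relevance` column when present; by default all rows are accepted.
#' @return A tibble of class `target_evidence`: one row per target with
#'   per-asset-class document counts (`n_publication`, ...), `n_docs`,
#'   provenance flags (`in_literature`, `in_structured_db`, `in_expression`,
#'   `in_mutation`), and a `db_names` list-column. The number of skipped
#'   document rows is attached as attribute `n_skipped`.
#' @export
#' @examples
#' docs <- tibble::tibble(
#'   doc_id = c("d1", "d2"), target = c("il13", "IL13"),
#'   asset_class = "publication", date = as.Date("2022-01-01"),
#'   impact_factor = 5, citations = 1L, position = "title",
#'   phase = NA_real_, status = NA_character_
#' )
#' ingest_evidence(docs)$n_publication
ingest_evidence <- function(documents = NULL, db_table = NULL,
                            deg_targets = NULL, variant_targets = NULL,
                            alias = NULL, relevance_min = NULL) {
  norm <- function(x) normalize_symbols(x, alias)
  n_skipped <- 0L

  if (is.null(documents) || !nrow(documents)) {
    documents <- tibble::tibble(target = character(), asset_class = character())
  } else {
    if (!is.null(relevance_min) && "relevance" %in% names(documents)) {
      documents <- dplyr::filter(documents, .data$relevance >= relevance_min)
    }
    bad <- is.na(documents$target) | !nzchar(documents$target) |
      is.na(documents$asset_class) | !documents$asset_class %in% asset_classes()
    n_skipped <- sum(bad)
    if (n_skipped > 0) {
      message(sprintf("ingest: skipped %d unparseable document row(s)", n_skipped))
      documents <- documents[!bad, ]
    }
    documents$target <- norm(documents$target)
  }

  doc_counts <- documents |>
    dplyr::count(.data$target, .data$asset_class) |>
    tidyr::pivot_wider(names_from = "asset_class", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  for (cls in asset_classes()) {
    col <- paste0("n_", cls)
    if (!col %in% names(doc_counts)) doc_counts[[col]] <- 0L
  }

  db_sets <- if (!is.null(db_table) && nrow(db_table)) {
    dplyr::summarise(
      dplyr::mutate(db_table, target = norm(.data$target)),
      db_names = list(sort(unique(.data$database))), .by = "target")
  } else {
    tibble::tibble(target = character(), db_names = list())
  }
  deg_targets <- unique(norm(deg_targets %||% character()))
  variant_targets <- unique(norm(variant_targets %||% character()))

  universe <- sort(unique(c(doc_counts$target, db_sets$target,
                            deg_targets, variant_targets)))
  out <- tibble::tibble(target = universe) |>
    dplyr::left_join(doc_counts, by = "target") |>
    dplyr::left_join(db_sets, by = "target") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                \(x) tidyr::replace_na(x, 0L)))
  out$db_names <- lapply(out$db_names, function(x) if (is.null(x)) character() else x)
  count_cols <- paste0("n_", asset_classes())
  out$n_docs <- as.integer(rowSums(as.matrix(out[, count_cols])))
  out$in_literature <- out$n_docs > 0L
  out$in_structured_db <- lengths(out$db_names) > 0L
  out$in_expression <- out$target %in% deg_targets
  out$in_mutation <- out$target %in% variant_targets
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("target_evidence", class(out))
  out
}

normalize_symbols <- function(x, alias = NULL) {
  x <- toupper(trimws(as.character(x)))
  if (!is.null(alias) && nrow(alias)) {
    map <- stats::setNames(toupper(alias$symbol), toupper(alias$alias))
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
  }
  x
}

#' Tabulate target counts by source
#'
#' Reproduces long-list source accounting: per-source target counts, the
#' three arm totals (literature, structured genomic databases, genomics raw
#' data), the grand total (sum over sources, with multiplicity — one target
#' found by several sources is counted once per source), and, when the
#' actual per-source symbol sets are supplied, the number of distinct
#' symbols across all sources.
#'
#' @param counts Tibble with columns `source`, `arm` (one of `"literature"`,
#'   `"structured"`, `"genomics_raw"`) and `n_targets`.
#' @param source_sets Optional named list of character vectors, the actual
#'   symbols per source, used to compute `unique_total`.
#' @return A list with `per_source` (the input tibble), `arm_totals` (tibble
#'   of `arm`, `total`), `grand_total`, and `unique_total` (`NA` when
#'   `source_sets` is not given).
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   source = c("publications", "clinvar", "expression"),
#'   arm = c("literature", "structured", "genomics_raw"),
#'   n_targets = c(10L, 4L, 6L)
#' )
#' account_sources(counts)$grand_total
account_sources <- function(counts, source_sets = NULL) {
  stopifnot(all(c("source", "arm", "n_targets") %in% names(counts)))
  bad_arm <- setdiff(unique(counts$arm),
                     c("literature", "structured", "genomics_raw"))
  if (length(bad_arm)) {
    stop("unknown source arm(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  }
  arm_totals <- counts |>
    dplyr::summarise(total = sum(.data$n_targets), .by = "arm")
  unique_total <- if (!is.null(source_sets)) {
    length(unique(toupper(unlist(source_sets, use.names = FALSE))))
  } else {
    NA_integer_
  }
  list(
    per_source = tibble::as_tibble(counts),
    arm_totals = arm_totals,
    grand_total = sum(counts$n_targets),
    unique_total = unique_total
  )
}

#' Partition two symbol sets
#'
#' Counts how many symbols are unique to each of two evidence sources and
#' how many are shared, e.g. variant-analysis targets against mutation
#' records in public structured databases.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @return A tibble with one row: `only_a`, `only_b`, `both`, `union`.
#' @export
#' @examples
#' overlap_partition(c("IL13", "TNF"), c("TNF", "VEGFA"))
overlap_partition <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  both <- length(intersect(a, b))
  tibble::tibble(
    only_a = length(a) - both,
    only_b = length(b) - both,
    both = both,
    union = length(union(a, b))
  )
}

#' Summarize clinical-trial sponsors
#'
#' Counts trials and distinct targets and drugs per sponsor, most active
#' sponsor first.
#'
#' @param trials Tibble with columns `trial_id`, `sponsor`, `target`, `drug`.
#' @return A tibble with `sponsor`, `n_trials`, `n_targets`, `n_drugs`.
#' @export
sponsor_summary <- function(trials) {
  trials |>
    dplyr::summarise(
      n_trials = dplyr::n_distinct(.data$trial_id),
      n_targets = dplyr::n_distinct(.data$target),
      n_drugs = dplyr::n_distinct(.data$drug),
      .by = "sponsor") |>
    dplyr::arrange(dplyr::desc(.data$n_trials), .data$sponsor)
}
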