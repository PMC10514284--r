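#' Configure literature asset-class scoring
#'
#' Per-document scores are sums of bounded components, one per scoring
#' parameter of the document's asset class: publications use recency, impact
#' factor and mention position; clinical trials use trial status, phase and
#' position; patents, grants, congresses, news and theses use recency and
#' position. Each component lies in `[0, 1]`, so a document scores at most
#' the number of components of its class.
#'
#' Component definitions: recency is an exponential decay
#' `2^(-age_years / recency_half_life_years)`; the impact-factor component is
#' `min(IF, if_cap) / if_cap`; position, phase and status components are
#' table lookups. An optional citation component `log1p(c)/log1p(cap)` can be
#' switched on for publications.
#'
#' @param recency_half_life_years Half-life of the recency decay, years.
#' @param if_cap Impact factor at (and above) which the impact component
#'   saturates at 1.
#' @param position_weights,phase_weights,status_weights Named weights in
#'   `[0, 1]` for the categorical components.
#' @param min_total_docs Relevance threshold: targets whose total document
#'   count across all classes is below this are dropped by
#'   [relevance_filter()].
#' @param include_citations Add the citation component to publication scores.
#' @param citations_cap Citation count at which that component saturates.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(recency_half_life_years = 5,
                           if_cap = 30,
                           position_weights = c(
                             title = 1, abstract = 0.8, indication = 0.7,
                             intervention = 0.7, full_text = 0.4, raw_text = 0.2
                           ),
                           phase_weights = c(`1` = 0.4, `2` = 0.6, `3` = 0.8, `4` = 1),
                           status_weights = c(
                             completed = 1, active = 1, recruiting = 0.8,
                             terminated = 0.2, withdrawn = 0.2
                           ),
                           min_total_docs = 20L,
                           include_citations = FALSE,
                           citations_cap = 1000) {
  cfg <- list(
    recency_half_life_years = recency_half_life_years, if_cap = if_cap,
    position_weights = position_weights, phase_weights = phase_weights,
    status_weights = status_weights, min_total_docs = min_total_docs,
    include_citations = include_citations, citations_cap = citations_cap
  )
  if (recency_half_life_years <= 0) stop("recency_half_life_years must be positive")
  if (if_cap <= 0) stop("if_cap must be positive")
  for (w in c("position_weights", "phase_weights", "status_weights")) {
    v <- cfg[[w]]
    if (any(v < 0 | v > 1) || is.null(names(v))) {
      stop(w, " must be named weights in [0, 1]", call. = FALSE)
    }
  }
  if (min_total_docs < 0) stop("min_total_docs must be >= 0")
  structure(cfg, class = "scoring_config")
}

#' Score evidence documents
#'
#' Computes the per-document parameter components and their sum for every
#' document, vectorized over the corpus. Unknown position, phase or status
#' values raise an error naming the offending document.
#'
#' @param documents Evidence-document tibble.
#' @param config A [scoring_config()].
#' @param today Reference date for recency (for simulated cohorts, the
#'   spec's `reference_date`).
#' @return The input with added columns `recency_component`, `if_component`,
#'   `position_component`, `phase_component`, `status_component`,
#'   `citation_component` and `doc_score`.
#' @export
score_documents <- function(documents, config = scoring_config(),
                            today = Sys.Date()) {
  if (!nrow(documents)) {
    return(dplyr::mutate(documents, doc_score = numeric(0)))
  }
  if (any(is.na(documents$date))) {
    bad <- documents$doc_id[is.na(documents$date)][1]
    stop(sprintf("document %s has no parseable date", bad), call. = FALSE)
  }
  lookup <- function(values, weights, what) {
    idx <- match(as.character(values), names(weights))
    missing_val <- !is.na(values) & is.na(idx)
    if (any(missing_val)) {
      bad <- documents$doc_id[missing_val][1]
      stop(sprintf("document %s has unknown %s '%s'", bad, what,
                   as.character(values)[missing_val][1]), call. = FALSE)
    }
    unname(weights[idx])
  }

  age_years <- pmax(as.numeric(today - documents$date), 0) / 365.25
  recency <- 2^(-age_years / config$recency_half_life_years)
  if_comp <- pmin(tidyr::replace_na(documents$impact_factor, 0),
                  config$if_cap) / config$if_cap
  pos_comp <- lookup(documents$position, config$position_weights, "position")
  pos_comp[is.na(pos_comp)] <- 0
  phase_comp <- lookup(documents$phase, config$phase_weights, "phase")
  status_comp <- lookup(documents$status, config$status_weights, "status")
  cit_comp <- if (config$include_citations) {
    log1p(pmin(tidyr::replace_na(documents$citations, 0L), config$citations_cap)) /
      log1p(config$citations_cap)
  } else {
    rep(0, nrow(documents))
  }

  cls <- documents$asset_class
  is_pub <- cls == "publication"
  is_ct <- cls == "clinical_trial"
  if (any(is_ct & (is.na(phase_comp) | is.na(status_comp)))) {
    bad <- documents$doc_id[is_ct & (is.na(phase_comp) | is.na(status_comp))][1]
    stop(sprintf("clinical trial document %s lacks phase or status", bad),
         call. = FALSE)
  }
  score <- ifelse(
    is_pub, recency + if_comp + pos_comp + cit_comp,
    ifelse(is_ct, status_comp + phase_comp + pos_comp,
           recency + pos_comp))

  dplyr::mutate(documents,
    recency_component = recency,
    if_component = ifelse(is_pub, if_comp, NA_real_),
    position_component = pos_comp,
    phase_component = ifelse(is_ct, phase_comp, NA_real_),
    status_component = ifelse(is_ct, status_comp, NA_real_),
    citation_component = ifelse(is_pub & config$include_citations, cit_comp, NA_real_),
    doc_score = score)
}

#' Raw and scaled asset-class scores across a cohort
#'
#' `class_scores()` sums document scores per target and asset class (zero
#' documents give a raw score of 0); `scale_scores()` min-max rescales raw
#' scores within each asset class across the cohort so the minimum maps to 0
#' and the maximum to 1. When all raw scores of a class are equal (including
#' a single-target cohort) every scaled score of that class is 0.
#'
#' @param documents Evidence-document tibble.
#' @param config A [scoring_config()].
#' @param today Reference date for recency.
#' @param targets Target universe; defaults to the targets present in
#'   `documents`. Targets with no documents get raw 0 in every class.
#' @return A tibble with columns `target`, `asset_class`, `raw` (and after
#'   `scale_scores()`, `scaled`).
#' @export
class_scores <- function(documents, config = scoring_config(),
                         today = Sys.Date(),
                         targets = NULL) {
  targets <- sort(unique(targets %||% documents$target))
  scored <- score_documents(documents, config, today)
  out <- scored |>
    dplyr::summarise(raw = sum(.data$doc_score),
                     .by = c("target", "asset_class"))
  full <- tidyr::expand_grid(target = targets, asset_class = asset_classes())
  full |>
    dplyr::left_join(out, by = c("target", "asset_class")) |>
    dplyr::mutate(raw = tidyr::replace_na(.data$raw, 0))
}

#' @rdname class_scores
#' @param scores Output of `class_scores()`.
#' @export
scale_scores <- function(scores) {
  if (!nrow(scores)) stop("cannot scale an empty score table", call. = FALSE)
  scores |>
    dplyr::mutate(
      scaled = {
        rng <- range(.data$raw)
        if (rng[2] > rng[1]) (.data$raw - rng[1]) / (rng[2] - rng[1])
        else rep(0, length(.data$raw))
      },
      .by = "asset_class")
}

#' Relevance filter cascade
#'
#' Drops targets whose total document count across all asset classes is
#' below the threshold, then drops targets that cleared the threshold from a
#' single asset class only unless their annotated pathways overlap the
#' disease pathway set (the pathway rescue). An exclusion log records which
#' rule removed each dropped target.
#'
#' @param documents Evidence-document tibble.
#' @param pathway_map Named list mapping target symbol to its pathway ids
#'   (may be empty).
#' @param disease_pathways Character vector of disease-relevant pathway ids.
#' @param min_total_docs Relevance threshold (documents, all classes
#'   counted equally).
#' @param targets Optional target universe; defaults to targets present in
#'   `documents`. Targets with no documents are excluded by the count rule.
#' @return A tibble with `target`, `n_docs`, `n_classes`,
#'   `pathway_overlap`, `kept` and `rule` (`NA` for survivors,
#'   otherwise `"count<threshold"` or `"single-class no pathway overlap"`).
#' @export
relevance_filter <- function(documents, pathway_map = list(),
                             disease_pathways = character(),
                             min_total_docs = 20L,
                             targets = NULL) {
  targets <- sort(unique(targets %||% documents$target))
  counts <- documents |>
    dplyr::summarise(
      n_docs = dplyr::n(),
      n_classes = dplyr::n_distinct(.data$asset_class),
      .by = "target")
  out <- tibble::tibble(target = targets) |>
    dplyr::left_join(counts, by = "target") |>
    dplyr::mutate(
      n_docs = as.integer(tidyr::replace_na(.data$n_docs, 0L)),
      n_classes = as.integer(tidyr::replace_na(.data$n_classes, 0L)),
      pathway_overlap = vapply(
        .data$target,
        function(t) length(intersect(pathway_map[[t]] %||% character(),
                                     disease_pathways)),
        integer(1)))
  out |>
    dplyr::mutate(
      kept = .data$n_docs >= min_total_docs &
        (.data$n_classes >= 2L | .data$pathway_overlap > 0L),
      rule = dplyr::case_when(
        kept ~ NA_character_,
        n_docs < min_total_docs ~ sprintf("count<%d", min_total_docs),
        TRUE ~ "single-class no pathway overlap"))
}
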