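#' Classify target druggability
#'
#' A target is *highly druggable* when it has clinical precedence (at least
#' one drug against it that reached phase 1 or beyond, in any indication)
#' together with an available 3D structure or cell-surface localization;
#' *potentially druggable* when it has the structure or localization but no
#' clinical precedence; otherwise not druggable. The modality of a highly
#' druggable target is the union of modalities over its clinical-stage drugs
#' (`both` when small molecules and antibodies are present); a potentially
#' druggable target's modality follows its features (structure implies small
#' molecule, surface localization implies antibody).
#'
#' @param annotations Tibble with `target`, `has_structure`,
#'   `surface_localized` (one row per target).
#' @param drugs Drug table with `target`, `modality`, `max_phase`.
#' @return A tibble with `target`, `druggability`
#'   (`highly`/`potentially`/`none`) and `modality`
#'   (`small_molecule`/`antibody`/`both`/`none`).
#' @export
classify_druggability <- function(annotations, drugs) {
  clin <- drugs |>
    dplyr::filter(.data$max_phase >= 1) |>
    dplyr::summarise(
      has_sm = any(.data$modality == "small_molecule"),
      has_ab = any(.data$modality == "antibody"),
      .by = "target")
  annotations |>
    dplyr::select("target", "has_structure", "surface_localized") |>
    dplyr::left_join(clin, by = "target") |>
    dplyr::mutate(
      has_sm = tidyr::replace_na(.data$has_sm, FALSE),
      has_ab = tidyr::replace_na(.data$has_ab, FALSE),
      precedence = .data$has_sm | .data$has_ab,
      feature = .data$has_structure | .data$surface_localized,
      druggability = dplyr::case_when(
        precedence & feature ~ "highly",
        !precedence & feature ~ "potentially",
        TRUE ~ "none"),
      modality = dplyr::case_when(
        druggability == "highly" & has_sm & has_ab ~ "both",
        druggability == "highly" & has_sm ~ "small_molecule",
        druggability == "highly" & has_ab ~ "antibody",
        druggability == "potentially" & has_structure & surface_localized ~ "both",
        druggability == "potentially" & has_structure ~ "small_molecule",
        druggability == "potentially" & surface_localized ~ "antibody",
        TRUE ~ "none")) |>
    dplyr::select("target", "druggability", "modality")
}

#' Classify target safety
#'
#' Three unsafe categories, evaluated in order with first-match semantics:
#' a drug withdrawn from the market for reasons attributed to the target; a
#' drug withdrawn or failed in the clinic for target-attributed reasons with
#' no other drug ongoing or successful at a higher phase; and essential
#' genes. Withdrawals whose reason is not attributed to the target do not
#' flag it.
#'
#' @param annotations Tibble with `target` and `essential_gene`.
#' @param drugs Drug table with `target`, `max_phase`, `status`,
#'   `withdrawal` (`none`/`market`/`clinical`) and
#'   `reason_target_attributed`.
#' @param rescue_statuses Trial statuses that count as ongoing/successful
#'   for the clinical-withdrawal rescue.
#' @return A tibble with `target` and `safety` (`safe`,
#'   `unsafe_market_withdrawal`, `unsafe_clinical_withdrawal`,
#'   `unsafe_essential`).
#' @export
classify_safety <- function(annotations, drugs,
                            rescue_statuses = c("completed", "active",
                                                "recruiting")) {
  per_target <- drugs |>
    dplyr::summarise(
      market_wd = any(.data$withdrawal == "market" &
                        .data$reason_target_attributed),
      clin_wd_phase = suppressWarnings(max(
        .data$max_phase[.data$withdrawal == "clinical" &
                          .data$reason_target_attributed], -Inf)),
      best_ongoing = suppressWarnings(max(
        .data$max_phase[.data$withdrawal == "none" &
                          .data$status %in% rescue_statuses], -Inf)),
      .by = "target")
  annotations |>
    dplyr::select("target", "essential_gene") |>
    dplyr::left_join(per_target, by = "target") |>
    dplyr::mutate(
      market_wd = tidyr::replace_na(.data$market_wd, FALSE),
      clin_wd_phase = tidyr::replace_na(.data$clin_wd_phase, -Inf),
      best_ongoing = tidyr::replace_na(.data$best_ongoing, -Inf),
      safety = dplyr::case_when(
        market_wd ~ "unsafe_market_withdrawal",
        is.finite(clin_wd_phase) & best_ongoing <= clin_wd_phase ~
          "unsafe_clinical_withdrawal",
        essential_gene ~ "unsafe_essential",
        TRUE ~ "safe")) |>
    dplyr::select("target", "safety")
}

#' Classify biomarker potential
#'
#' Aggregates tagged biomarker evidence rows into the set of categories per
#' target (diagnostic, prognostic, predictive, therapeutic); a target may
#' belong to several categories.
#'
#' @param biomarker_evidence Tibble with `target`, `category`.
#' @param targets Target universe to report over.
#' @return A tibble with `target`, list-column `biomarker_categories` and
#'   logical `is_biomarker`.
#' @export
classify_biomarker <- function(biomarker_evidence, targets) {
  valid <- c("diagnostic", "prognostic", "predictive", "therapeutic")
  bad <- setdiff(unique(biomarker_evidence$category), valid)
  if (length(bad)) {
    stop("unknown biomarker category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sets <- biomarker_evidence |>
    dplyr::summarise(biomarker_categories = list(sort(unique(.data$category))),
                     .by = "target")
  out <- tibble::tibble(target = sort(unique(targets))) |>
    dplyr::left_join(sets, by = "target")
  out$biomarker_categories <- lapply(out$biomarker_categories,
                                     function(x) if (is.null(x)) character() else x)
  out$is_biomarker <- lengths(out$biomarker_categories) > 0
  out
}

#' Classify target novelty
#'
#' A target is novel when all three criteria hold: discussion in a
#' high-impact journal (impact factor above `if_min`) within the last
#' `pub_window_years`, a news mention within the last `news_window_years`,
#' and no clinical exploration beyond phase `max_phase` for any drug against
#' it. Novel targets are further placed in a three-way taxonomy: targets that
#' entered the cohort only through the genomics arm (no literature
#' provenance) are *unknown knowns*; literature-backed novels with a known
#' mechanism are *known knowns*, without one *known unknowns*.
#'
#' @param annotations Tibble with `target`, `last_highif_pub_date`,
#'   `last_news_date`, `mechanism_known`.
#' @param drugs Drug table with `target`, `max_phase`.
#' @param evidence Optional [ingest_evidence()] result supplying the
#'   `in_literature` provenance flag; targets absent from it count as
#'   genomics-only.
#' @param today Reference date for the recency windows.
#' @param if_min,pub_window_years,news_window_years,max_phase Rule
#'   parameters. `if_min` is the impact-factor bound already applied when
#'   `last_highif_pub_date` was extracted; it is recorded but not re-checked
#'   here.
#' @return A tibble with `target`, logical `novel` and `novelty_taxonomy`
#'   (`known_knowns`, `known_unknowns`, `unknown_knowns`, or `"n/a"`).
#' @export
classify_novelty <- function(annotations, drugs, evidence = NULL,
                             today = Sys.Date(), if_min = 8,
                             pub_window_years = 10, news_window_years = 5,
                             max_phase = 1) {
  top_phase <- drugs |>
    dplyr::summarise(top_phase = max(.data$max_phase, -Inf), .by = "target")
  lit_flag <- if (!is.null(evidence)) {
    dplyr::select(evidence, "target", "in_literature")
  } else {
    tibble::tibble(target = character(), in_literature = logical())
  }
  within_years <- function(d, yrs) {
    !is.na(d) & d >= today - round(yrs * 365.25) & d <= today
  }
  annotations |>
    dplyr::select("target", "last_highif_pub_date", "last_news_date",
                  "mechanism_known") |>
    dplyr::left_join(top_phase, by = "target") |>
    dplyr::left_join(lit_flag, by = "target") |>
    dplyr::mutate(
      top_phase = tidyr::replace_na(.data$top_phase, 0),
      in_literature = tidyr::replace_na(.data$in_literature, FALSE),
      novel = within_years(.data$last_highif_pub_date, pub_window_years) &
        within_years(.data$last_news_date, news_window_years) &
        .data$top_phase <= max_phase,
      novelty_taxonomy = dplyr::case_when(
        !novel ~ "n/a",
        !in_literature ~ "unknown_knowns",
        mechanism_known ~ "known_knowns",
        TRUE ~ "known_unknowns")) |>
    dplyr::select("target", "novel", "novelty_taxonomy")
}

#' Classify disease-tissue expression
#'
#' For a lung-centric indication: a target is *exclusive* when it is
#' detected in lung and nowhere else, *high_shared* when lung expression is
#' high and at least one other tissue is detected, otherwise *other*.
#' Targets with no lung row are treated as not detected in lung (logged).
#'
#' @param tissue Long tibble with `target`, `tissue`, `level`
#'   (`not_detected`, `low`, `medium`, `high`).
#' @param disease_tissue Tissue of interest.
#' @return A tibble with `target` and `lung_expression`
#'   (`exclusive`/`high_shared`/`other`).
#' @export
classify_tissue <- function(tissue, disease_tissue = "lung") {
  levels_ok <- c("not_detected", "low", "medium", "high")
  bad <- setdiff(unique(tissue$level), levels_ok)
  if (length(bad)) {
    stop("unknown expression level: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  per <- tissue |>
    dplyr::summarise(
      lung_level = {
        lv <- .data$level[.data$tissue == disease_tissue]
        if (length(lv)) lv[1] else NA_character_
      },
      other_detected = any(.data$tissue != disease_tissue &
                             .data$level != "not_detected"),
      .by = "target")
  n_missing <- sum(is.na(per$lung_level))
  if (n_missing > 0) {
    message(sprintf("%d target(s) without a %s expression entry treated as not detected",
                    n_missing, disease_tissue))
    per$lung_level[is.na(per$lung_level)] <- "not_detected"
  }
  per |>
    dplyr::mutate(
      lung_expression = dplyr::case_when(
        lung_level != "not_detected" & !other_detected ~ "exclusive",
        lung_level == "high" & other_detected ~ "high_shared",
        TRUE ~ "other")) |>
    dplyr::select("target", "lung_expression")
}

#' Count overlap between target pathways and disease pathways
#'
#' @param pathway_map Named list: target symbol to pathway ids.
#' @param disease_pathways Character vector of disease pathway ids.
#' @param targets Target universe to report over; defaults to the names of
#'   `pathway_map`.
#' @return A tibble with `target` and `pathway_overlap_count`.
#' @export
pathway_overlap <- function(pathway_map, disease_pathways,
                            targets = names(pathway_map)) {
  tibble::tibble(
    target = sort(unique(targets)),
    pathway_overlap_count = vapply(
      sort(unique(targets)),
      function(t) length(intersect(pathway_map[[t]] %||% character(),
                                   disease_pathways)),
      integer(1), USE.NAMES = FALSE))
}

#' Invert a gene-set collection into a per-target pathway list
#'
#' Turns a named list of gene sets (as from [read_gmt()]) into the named
#' per-target pathway map consumed by [relevance_filter()] and
#' [pathway_overlap()].
#'
#' @param pathways Named list: pathway id to member gene symbols.
#' @return Named list: target symbol to pathway ids.
#' @export
pathways_by_target <- function(pathways) {
  if (!length(pathways)) return(list())
  long <- tibble::tibble(
    pathway = rep(names(pathways), lengths(pathways)),
    target = unlist(pathways, use.names = FALSE))
  split(long$pathway, long$target)
}

#' Hypergeometric pathway over-representation
#'
#' For each gene set, tests whether the target set overlaps it more than
#' expected under uniform sampling from the universe: an upper-tail
#' hypergeometric p-value with Benjamini-Hochberg adjustment across sets,
#' sorted by adjusted then raw p-value.
#'
#' @param targets Character vector of gene symbols (the query set).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all eligible symbols; must contain
#'   every query target.
#' @return A tibble with `pathway`, `k` (overlap), `set_size` (in-universe),
#'   `n_targets`, `universe_size`, `p_value`, `p_adj`.
#' @export
enrich_pathways <- function(targets, gene_sets, universe) {
  targets <- unique(targets)
  universe <- unique(universe)
  if (!length(targets)) {
    return(tibble::tibble(pathway = character(), k = integer(),
                          set_size = integer(), n_targets = integer(),
                          universe_size = integer(), p_value = numeric(),
                          p_adj = numeric()))
  }
  if (!all(targets %in% universe)) {
    stop("target set must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(targets)
  res <- purrr::imap(gene_sets, function(genes, nm) {
    set_in <- intersect(unique(genes), universe)
    K <- length(set_in)
    k <- length(intersect(set_in, targets))
    tibble::tibble(
      pathway = nm, k = k, set_size = K, n_targets = n, universe_size = N,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_adj, .data$p_value, .data$pathway)
}

#' Build one evaluation profile per target
#'
#' Runs every rule-based classifier — druggability, safety, biomarker,
#' novelty, tissue expression and disease-pathway overlap — over a target
#' universe and binds the results into one profile table.
#'
#' @param annotations,drugs,biomarker_evidence,tissue As the individual
#'   classifiers expect.
#' @param pathways Named list of gene sets (pathway to members).
#' @param disease_pathways Character vector of disease pathway ids.
#' @param evidence Optional [ingest_evidence()] result (novelty taxonomy
#'   provenance).
#' @param today Reference date for the novelty windows.
#' @param targets Target universe; defaults to the annotation table's
#'   targets.
#' @return A `target_profiles` tibble with one row per target and the
#'   columns of all classifier outputs.
#' @export
evaluate_targets <- function(annotations, drugs, biomarker_evidence, tissue,
                             pathways, disease_pathways, evidence = NULL,
                             today = Sys.Date(), targets = NULL) {
  targets <- sort(unique(targets %||% annotations$target))
  ann <- dplyr::filter(annotations, .data$target %in% targets)
  pmap <- pathways_by_target(pathways)
  profiles <- tibble::tibble(target = targets) |>
    dplyr::left_join(classify_druggability(ann, drugs), by = "target") |>
    dplyr::left_join(classify_safety(ann, drugs), by = "target") |>
    dplyr::left_join(classify_biomarker(biomarker_evidence, targets),
                     by = "target") |>
    dplyr::left_join(classify_novelty(ann, drugs, evidence, today),
                     by = "target") |>
    dplyr::left_join(classify_tissue(
      dplyr::filter(tissue, .data$target %in% targets)), by = "target") |>
    dplyr::left_join(pathway_overlap(pmap, disease_pathways, targets),
                     by = "target")
  # targets with no tissue rows at all: nothing detected anywhere
  profiles$lung_expression <- tidyr::replace_na(profiles$lung_expression, "other")
  profiles$biomarker_categories <- lapply(
    profiles$biomarker_categories, function(x) if (is.null(x)) character() else x)
  profiles$is_biomarker <- tidyr::replace_na(profiles$is_biomarker, FALSE)
  class(profiles) <- c("target_profiles", class(profiles))
  profiles
}
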