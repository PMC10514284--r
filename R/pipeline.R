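#' Run the full target prioritization pipeline
#'
#' Executes the complete triage on a cohort (simulated via
#' [simulate_cohort()] or loaded via [read_cohort()]): DE significance
#' selection; variant hard/downstream filtering with loss-of-function
#' calling and per-gene impact tallies; evidence ingestion across the three
#' sourcing arms; the relevance cascade (document-count threshold with
#' single-class pathway rescue); per-asset-class literature scoring with
#' cohort-wide min-max scaling over the survivors; rule-based target
#' evaluation; and the weighted 40/60 combination with deterministic
#' ranking.
#'
#' @param cohort A `target_cohort` (list with `documents`, `deg_table`,
#'   `variants`, `pathways`, `disease_pathways`, `db_table`, `drugs`,
#'   `annotations`, `tissue`, `biomarker_evidence`).
#' @param scoring A [scoring_config()].
#' @param weights A [weight_config()].
#' @param today Reference date for recency and novelty windows; defaults to
#'   the cohort spec's reference date when present, else the current date.
#' @param padj_max,abs_lfc_min DE significance thresholds.
#' @param overlap_cap Pathway-overlap saturation for the disease score.
#' @return A list of class `target_ranking` with elements `scores` (ranked
#'   tibble: per-class scaled scores, per-parameter scores, components,
#'   total, rank), `relevance` (the cascade log), `evidence`, `profiles`,
#'   `deg_survivors`, `variant_survivors`, `variant_impact`, `weights`,
#'   `scoring`, `today`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_targets = 40, n_planted_top = 4, seed = 3))
#' ranking <- prioritize_targets(cohort)
#' head(tidy(ranking), 4)
prioritize_targets <- function(cohort,
                               scoring = scoring_config(),
                               weights = weight_config(),
                               today = NULL,
                               padj_max = 0.05, abs_lfc_min = 1,
                               overlap_cap = 5) {
  validate_weight_config(weights)
  today <- today %||% cohort$spec$reference_date %||% Sys.Date()

  deg_surv <- select_significant(cohort$deg_table, padj_max, abs_lfc_min)
  variants <- filter_variants(cohort$variants)
  var_surv <- dplyr::filter(variants, .data$pass)
  var_impact <- classify_impact(var_surv)

  evidence <- ingest_evidence(
    documents = cohort$documents,
    db_table = cohort$db_table,
    deg_targets = deg_surv$gene_symbol,
    variant_targets = var_surv$gene)

  pmap <- pathways_by_target(cohort$pathways)
  relevance <- relevance_filter(
    cohort$documents, pmap, cohort$disease_pathways,
    min_total_docs = scoring$min_total_docs,
    targets = evidence$target)
  survivors <- relevance$target[relevance$kept]

  scaled <- cohort$documents |>
    dplyr::filter(.data$target %in% survivors) |>
    class_scores(scoring, today, targets = survivors) |>
    scale_scores()

  profiles <- evaluate_targets(
    cohort$annotations, cohort$drugs, cohort$biomarker_evidence,
    cohort$tissue, cohort$pathways, cohort$disease_pathways,
    evidence = evidence, today = today, targets = survivors)

  params <- disease_parameter_scores(
    profiles, deg_targets = deg_surv$gene_symbol,
    variant_impact = var_impact, overlap_cap = overlap_cap)

  scores <- combine_scores(scaled, params, weights) |> rank_targets()

  wide_scaled <- scaled |>
    dplyr::select("target", "asset_class", "scaled") |>
    tidyr::pivot_wider(names_from = "asset_class", values_from = "scaled",
                       names_prefix = "scaled_")
  scores <- scores |>
    dplyr::left_join(wide_scaled, by = "target") |>
    dplyr::left_join(params, by = "target") |>
    dplyr::relocate("rank", "total", "literature_component",
                    "disease_component", .after = "target")

  structure(list(
    scores = scores, relevance = relevance, evidence = evidence,
    profiles = profiles, deg_survivors = deg_surv,
    variant_survivors = var_surv, variant_impact = var_impact,
    weights = weights, scoring = scoring, today = today
  ), class = "target_ranking")
}

#' @export
print.target_ranking <- function(x, n = 5, ...) {
  cat("<target_ranking>\n")
  cat(sprintf("  %d ranked targets (of %d considered; %d excluded by the relevance cascade)\n",
              nrow(x$scores), nrow(x$relevance), sum(!x$relevance$kept)))
  cat(sprintf("  DE survivors: %d; variant survivors: %d (in %d genes)\n",
              nrow(x$deg_survivors), nrow(x$variant_survivors),
              nrow(x$variant_impact)))
  cat("  top targets:\n")
  top <- utils::head(x$scores, n)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("   %2d. %s  total %.1f (lit %.1f + disease %.1f)\n",
                top$rank[i], top$target[i], top$total[i],
                top$literature_component[i], top$disease_component[i]))
  }
  invisible(x)
}

#' Tidy a target ranking
#'
#' @param x A `target_ranking`.
#' @param ... Unused.
#' @return The ranked score tibble, one row per surviving target.
#' @export
tidy.target_ranking <- function(x, ...) {
  x$scores
}

#' One-row summary of a target ranking
#'
#' @param x A `target_ranking`.
#' @param ... Unused.
#' @return A tibble with cohort-level counts and score summaries.
#' @export
glance.target_ranking <- function(x, ...) {
  tibble::tibble(
    n_considered = nrow(x$relevance),
    n_ranked = nrow(x$scores),
    n_excluded_count = sum(!x$relevance$kept &
                             startsWith(x$relevance$rule, "count<"), na.rm = TRUE),
    n_excluded_single_class = sum(!x$relevance$kept &
                                    x$relevance$rule == "single-class no pathway overlap",
                                  na.rm = TRUE),
    n_deg_survivors = nrow(x$deg_survivors),
    n_variant_survivors = nrow(x$variant_survivors),
    top_target = if (nrow(x$scores)) x$scores$target[1] else NA_character_,
    max_total = if (nrow(x$scores)) max(x$scores$total) else NA_real_,
    median_total = if (nrow(x$scores)) stats::median(x$scores$total) else NA_real_
  )
}

#' Plot the top of a target ranking
#'
#' Horizontal bars of the composite score for the top `n` targets, split
#' into the literature (40%) and disease-relevance (60%) components.
#'
#' @param object A `target_ranking`.
#' @param n Number of top targets to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.target_ranking <- function(object, n = 20, ...) {
  top <- utils::head(object$scores, n)
  long <- top |>
    dplyr::select("target", "rank", "literature_component",
                  "disease_component") |>
    tidyr::pivot_longer(cols = c("literature_component", "disease_component"),
                        names_to = "component", values_to = "points") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
      literature_component = "literature (40%)",
      disease_component = "disease relevance (60%)"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$points,
    y = stats::reorder(.data$target, -.data$rank),
    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "priority score (points of 100)", y = NULL,
                  fill = NULL,
                  title = sprintf("Top %d prioritized targets", nrow(top))) +
    ggplot2::theme_minimal()
}

#' Plot pathway enrichment results
#'
#' Lollipop chart of `-log10` adjusted p-values for the most enriched gene
#' sets.
#'
#' @param enrichment [enrich_pathways()] output.
#' @param n Number of top pathways to show.
#' @param alpha Significance line to draw.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, n = 15, alpha = 0.05) {
  top <- utils::head(enrichment, n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = -log10(.data$p_adj),
    y = stats::reorder(.data$pathway, -.data$p_adj))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$pathway, -.data$p_adj)), color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$k), color = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10]~adjusted~italic(p)), y = NULL,
                  size = "overlap") +
    ggplot2::theme_minimal()
}
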