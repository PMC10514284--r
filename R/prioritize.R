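#' Prioritization weight configuration
#'
#' The composite priority score allocates 40 points across six literature
#' asset classes — publications 12, congress 3, clinical trials 9, patents
#' 4, grants 6, news 6 — and 60 points across seven disease-relevance
#' parameters — druggability 12, pathways 9, biomarker 3, safety 3,
#' expression/mutation 12, tissue expression 9, novelty 12. Theses are
#' ingested but carry no weight. Sums are validated before any scoring:
#' literature must total 40, disease 60, together 100.
#'
#' @param literature Named percentages per weighted asset class.
#' @param disease Named percentages per disease parameter.
#' @param policy How [reweight()] treats user overrides: `"strict"` demands
#'   the sums still hold, `"normalize"` rescales each arm proportionally
#'   back to its total.
#' @return A list of class `weight_config`.
#' @export
#' @examples
#' w <- weight_config()
#' sum(w$literature); sum(w$disease)
weight_config <- function(literature = c(
                            publication = 12, congress = 3, clinical_trial = 9,
                            patent = 4, grant = 6, news = 6
                          ),
                          disease = c(
                            druggability = 12, pathways = 9, biomarker = 3,
                            safety = 3, expression_mutation = 12,
                            tissue_expression = 9, novelty = 12
                          ),
                          policy = c("strict", "normalize")) {
  policy <- match.arg(policy)
  w <- structure(list(literature = literature, disease = disease,
                      policy = policy), class = "weight_config")
  validate_weight_config(w)
  w
}

validate_weight_config <- function(w) {
  check_names <- function(x, expected, what) {
    if (!setequal(names(x), expected)) {
      stop(sprintf("%s weights must cover exactly: %s", what,
                   paste(expected, collapse = ", ")), call. = FALSE)
    }
  }
  check_names(w$literature, weighted_classes(), "literature")
  check_names(w$disease,
              c("druggability", "pathways", "biomarker", "safety",
                "expression_mutation", "tissue_expression", "novelty"),
              "disease")
  if (any(w$literature < 0) || any(w$disease < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  tol <- 1e-8
  if (abs(sum(w$literature) - 40) > tol) {
    stop(sprintf("literature weights must sum to 40 (got %g)",
                 sum(w$literature)), call. = FALSE)
  }
  if (abs(sum(w$disease) - 60) > tol) {
    stop(sprintf("disease weights must sum to 60 (got %g)", sum(w$disease)),
         call. = FALSE)
  }
  invisible(w)
}

#' Override prioritization weights
#'
#' Applies user-supplied weight overrides for a multi-view ranking of the
#' same targets. Under the `"strict"` policy the overridden arm must still
#' sum to its total (40 literature / 60 disease) or an error is raised;
#' under `"normalize"` each arm is rescaled proportionally back to its
#' total after the override.
#'
#' @param weights A [weight_config()].
#' @param literature,disease Named numeric vectors overriding a subset of
#'   weights.
#' @param policy Optional policy override.
#' @return A validated `weight_config`.
#' @export
#' @examples
#' w <- reweight(weight_config(policy = "normalize"),
#'               disease = c(druggability = 24))
#' sum(w$disease)
reweight <- function(weights, literature = NULL, disease = NULL,
                     policy = NULL) {
  policy <- policy %||% weights$policy
  apply_override <- function(base, override, total, what) {
    if (is.null(override)) return(base)
    if (any(override < 0)) stop("weights must be non-negative", call. = FALSE)
    unknown <- setdiff(names(override), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown %s weight(s): %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    base[names(override)] <- override
    if (policy == "normalize") {
      s <- sum(base)
      if (s == 0) stop(sprintf("%s weights cannot all be zero", what),
                       call. = FALSE)
      base <- base * total / s
    }
    base
  }
  out <- structure(list(
    literature = apply_override(weights$literature, literature, 40, "literature"),
    disease = apply_override(weights$disease, disease, 60, "disease"),
    policy = policy
  ), class = "weight_config")
  validate_weight_config(out)
  out
}

#' Disease-relevance parameter scores
#'
#' Converts each target's evaluation profile plus its genomics evidence into
#' seven scores in `[0, 1]`, one per weighted disease parameter:
#' druggability (highly 1, potentially 0.5, none 0); pathways
#' (`min(overlap / overlap_cap, 1)`); biomarker (any category 1); safety
#' (safe 1, any unsafe 0 — unsafe targets are down-weighted, not removed);
#' expression/mutation (mean of a DE-survivor indicator and a variant
#' severity score with HIGH 1, MODERATE 0.6, LOW 0.3); tissue expression
#' (exclusive 1, high-shared 0.7, other 0.2); novelty (novel 1).
#'
#' @param profiles [evaluate_targets()] output.
#' @param deg_targets Gene symbols surviving DE significance selection.
#' @param variant_impact [classify_impact()] output for surviving variants.
#' @param overlap_cap Pathway-overlap count at which that score saturates.
#' @return A tibble with `target` and one column per disease parameter.
#' @export
disease_parameter_scores <- function(profiles, deg_targets = character(),
                                     variant_impact = NULL,
                                     overlap_cap = 5) {
  sev <- if (!is.null(variant_impact) && nrow(variant_impact)) {
    dplyr::transmute(variant_impact, target = .data$gene,
                     severity = unname(c(HIGH = 1, MODERATE = 0.6, LOW = 0.3)[
                       .data$headline_impact]))
  } else {
    tibble::tibble(target = character(), severity = numeric())
  }
  profiles |>
    dplyr::left_join(sev, by = "target") |>
    dplyr::transmute(
      target = .data$target,
      druggability = unname(
        c(highly = 1, potentially = 0.5, none = 0)[.data$druggability]),
      pathways = pmin(.data$pathway_overlap_count / overlap_cap, 1),
      biomarker = as.numeric(.data$is_biomarker),
      safety = as.numeric(.data$safety == "safe"),
      expression_mutation = (as.numeric(.data$target %in% deg_targets) +
                               tidyr::replace_na(.data$severity, 0)) / 2,
      tissue_expression = unname(
        c(exclusive = 1, high_shared = 0.7, other = 0.2)[.data$lung_expression]),
      novelty = as.numeric(.data$novel))
}

#' Combine literature and disease scores into priority scores
#'
#' The literature component is the weight-sum of the scaled asset-class
#' scores (at most 40); the disease component is the weight-sum of the
#' parameter scores (at most 60); the total is their sum on a 0-100 scale.
#' Weight sums are validated before any scoring.
#'
#' @param scaled_scores Long tibble from [scale_scores()] (`target`,
#'   `asset_class`, `scaled`).
#' @param parameter_scores [disease_parameter_scores()] output.
#' @param weights A [weight_config()].
#' @return A tibble with `target`, `literature_component`,
#'   `disease_component`, `total`.
#' @export
combine_scores <- function(scaled_scores, parameter_scores,
                           weights = weight_config()) {
  validate_weight_config(weights)
  lit <- scaled_scores |>
    dplyr::filter(.data$asset_class %in% weighted_classes()) |>
    dplyr::mutate(w = weights$literature[.data$asset_class]) |>
    dplyr::summarise(
      literature_component = sum(.data$w * .data$scaled), .by = "target")
  dis_w <- weights$disease
  m <- as.matrix(parameter_scores[, names(dis_w)])
  dis <- tibble::tibble(
    target = parameter_scores$target,
    disease_component = as.numeric(m %*% dis_w))
  dplyr::inner_join(lit, dis, by = "target") |>
    dplyr::mutate(total = .data$literature_component + .data$disease_component)
}

#' Rank targets by priority score
#'
#' Sorts descending by total score, breaking ties alphabetically by symbol,
#' and assigns ranks 1..N.
#'
#' @param scores [combine_scores()] output.
#' @return The input sorted, with a `rank` column.
#' @export
rank_targets <- function(scores) {
  scores |>
    dplyr::arrange(dplyr::desc(.data$total), .data$target) |>
    dplyr::mutate(rank = dplyr::row_number())
}
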