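#' Specify a synthetic evidence cohort
#'
#' A `cohort_spec` fixes every condition of a simulated target-discovery
#' cohort: how many gene symbols exist, how many of them are "planted top"
#' targets with saturated evidence, the mean document rate per asset class,
#' the fractions of background targets carrying each evaluation attribute,
#' the differential-expression effect and noise, and the fraction of
#' simulated variants drawn on the passing side of the hard-filter
#' thresholds. The same spec and seed always regenerate byte-identical
#' cohorts, so planted ground truth can be asserted exactly downstream.
#'
#' @param n_targets Number of gene symbols in the cohort universe.
#' @param n_planted_top Number of targets given saturated evidence in every
#'   asset class plus uniformly favorable evaluation attributes. Must not
#'   exceed `n_targets`.
#' @param seed Integer RNG seed; identical seed and spec give identical
#'   output, including written files.
#' @param asset_class_rates Named numeric vector, mean documents per target
#'   for each asset class (negative-binomial means; over-dispersed counts
#'   are typical of literature corpora).
#' @param frac_druggable,frac_unsafe,frac_novel,frac_biomarker Proportions
#'   in `[0, 1]` of background targets planted with the corresponding
#'   evaluation attribute.
#' @param de_effect_log2fc Log2 fold change planted for differentially
#'   expressed genes.
#' @param de_noise_sd Replicate-level standard deviation on the log2
#'   expression scale (positive).
#' @param variant_pass_fraction Proportion of simulated background variants
#'   drawn with all quality metrics strictly inside the hard-filter bounds.
#' @param n_de_up,n_de_down Number of genes planted up- and down-regulated
#'   (planted-top targets are always among the up genes). Defaults scale
#'   with the cohort: about 6% of genes up and 2% down.
#' @param n_variants Number of background variant records to simulate.
#' @param planted_docs_min Guaranteed minimum document count per asset class
#'   for each planted-top target (placed above the default relevance
#'   threshold of 20).
#' @param reference_date "Today" for the cohort: document dates fall in the
#'   15 years ending here, and recency-based scoring should use the same
#'   date. A fixed date keeps simulated cohorts reproducible across runs.
#'
#' @return A validated list of class `cohort_spec`.
#' @seealso [simulate_cohort()], [simulate_variant_fixture()]
#' @export
#' @examples
#' spec <- cohort_spec(n_targets = 50, n_planted_top = 5, seed = 1)
#' spec$n_planted_top
cohort_spec <- function(n_targets = 500,
                        n_planted_top = 10,
                        seed = 1L,
                        asset_class_rates = c(
                          publication = 3, clinical_trial = 0.5, patent = 1,
                          grant = 0.8, congress = 1, news = 0.8, thesis = 0.3
                        ),
                        frac_druggable = 0.3,
                        frac_unsafe = 0.05,
                        frac_novel = 0.05,
                        frac_biomarker = 0.1,
                        de_effect_log2fc = 2,
                        de_noise_sd = 0.25,
                        variant_pass_fraction = 0.6,
                        n_de_up = NULL,
                        n_de_down = NULL,
                        n_variants = 200,
                        planted_docs_min = 25,
                        reference_date = as.Date("2023-01-01")) {
  # default DE planting: ~6% of genes up, ~2% down (never fewer up genes
  # than planted tops, which are always up-regulated)
  n_de_up <- n_de_up %||% max(n_planted_top, ceiling(0.06 * n_targets))
  n_de_down <- n_de_down %||% ceiling(0.02 * n_targets)
  spec <- list(
    n_targets = n_targets, n_planted_top = n_planted_top, seed = seed,
    asset_class_rates = asset_class_rates,
    frac_druggable = frac_druggable, frac_unsafe = frac_unsafe,
    frac_novel = frac_novel, frac_biomarker = frac_biomarker,
    de_effect_log2fc = de_effect_log2fc, de_noise_sd = de_noise_sd,
    variant_pass_fraction = variant_pass_fraction,
    n_de_up = n_de_up, n_de_down = n_de_down, n_variants = n_variants,
    planted_docs_min = planted_docs_min,
    reference_date = as.Date(reference_date)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort spec: field '%s' %s", field, msg), call. = FALSE)
  }
  check_count <- function(field, min = 0) {
    x <- spec[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
      stop_field(field, sprintf("must be a single integer >= %d", min))
    }
  }
  check_prop <- function(field) {
    x <- spec[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop_field(field, "must be a proportion in [0, 1]")
    }
  }
  check_count("n_targets", min = 1)
  check_count("n_planted_top")
  check_count("seed")
  check_count("n_de_up"); check_count("n_de_down")
  check_count("n_variants"); check_count("planted_docs_min")
  if (spec$n_planted_top > spec$n_targets) {
    stop_field("n_planted_top", "must not exceed n_targets")
  }
  rates <- spec$asset_class_rates
  if (!is.numeric(rates) || is.null(names(rates)) ||
      !all(names(rates) %in% asset_classes()) || any(rates < 0) || any(is.na(rates))) {
    stop_field("asset_class_rates",
               "must be a named non-negative vector over known asset classes")
  }
  for (f in c("frac_druggable", "frac_unsafe", "frac_novel", "frac_biomarker",
              "variant_pass_fraction")) {
    check_prop(f)
  }
  if (!is.numeric(spec$de_effect_log2fc) || length(spec$de_effect_log2fc) != 1 ||
      is.na(spec$de_effect_log2fc)) {
    stop_field("de_effect_log2fc", "must be a single finite number")
  }
  if (!is.numeric(spec$de_noise_sd) || length(spec$de_noise_sd) != 1 ||
      is.na(spec$de_noise_sd) || spec$de_noise_sd <= 0) {
    stop_field("de_noise_sd", "must be a single positive number")
  }
  if (spec$n_de_up + spec$n_de_down > spec$n_targets) {
    stop_field("n_de_up", "n_de_up + n_de_down must not exceed n_targets")
  }
  if (spec$n_planted_top > spec$n_de_up && spec$n_de_up > 0) {
    # planted tops are always up-regulated; the up set must hold them
    stop_field("n_de_up", "must be >= n_planted_top (or 0 to disable DE planting)")
  }
  if (inherits(spec$reference_date, "Date") && is.na(spec$reference_date)) {
    stop_field("reference_date", "must be a valid date")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  targets: %d (%d planted top), seed %d\n",
              x$n_targets, x$n_planted_top, x$seed))
  cat(sprintf("  doc rates: %s\n",
              paste(sprintf("%s=%.2g", names(x$asset_class_rates),
                            x$asset_class_rates), collapse = ", ")))
  cat(sprintf("  DE: %d up / %d down, effect %.2g log2FC, noise sd %.2g\n",
              x$n_de_up, x$n_de_down, x$de_effect_log2fc, x$de_noise_sd))
  cat(sprintf("  variants: %d, pass fraction %.2f\n",
              x$n_variants, x$variant_pass_fraction))
  invisible(x)
}
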