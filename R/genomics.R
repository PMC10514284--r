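#' Assign up/down regulation to a differential-expression table
#'
#' Sets `abs_log2fc = |log2fc|` and `regulation` to `"up"` for positive and
#' `"down"` for negative log2 fold change. A log2 fold change of exactly 0
#' is neither up nor down: such rows get `regulation = NA` and their count
#' is attached as attribute `n_unregulated` (with a message).
#'
#' @param deg DE tibble with at least `gene_symbol` and `log2fc`.
#' @return The input with `abs_log2fc` and `regulation` columns set.
#' @export
#' @examples
#' assign_regulation(tibble::tibble(gene_symbol = "IL13", log2fc = 2))
assign_regulation <- function(deg) {
  stopifnot(all(is.finite(deg$log2fc)))
  out <- dplyr::mutate(deg,
    abs_log2fc = abs(.data$log2fc),
    regulation = dplyr::case_when(
      log2fc > 0 ~ "up",
      log2fc < 0 ~ "down",
      TRUE ~ NA_character_))
  n_zero <- sum(out$log2fc == 0)
  if (n_zero > 0) {
    message(sprintf("%d gene(s) with log2FC exactly 0 left unregulated", n_zero))
  }
  attr(out, "n_unregulated") <- n_zero
  out
}

#' Select significant differentially expressed genes
#'
#' Keeps rows with `p_adj <= padj_max` and `|log2fc| >= abs_lfc_min`. Rows
#' with log2 fold change exactly 0 never survive (they carry no regulation
#' direction).
#'
#' @param deg DE tibble (regulation columns are filled in if absent).
#' @param padj_max Adjusted p-value ceiling.
#' @param abs_lfc_min Minimum absolute log2 fold change.
#' @return The surviving rows, with `regulation` set.
#' @seealso [count_regulation()]
#' @export
select_significant <- function(deg, padj_max = 0.05, abs_lfc_min = 1) {
  stopifnot(padj_max >= 0, abs_lfc_min >= 0)
  if (!"regulation" %in% names(deg) || !"abs_log2fc" %in% names(deg)) {
    deg <- assign_regulation(deg)
  }
  dplyr::filter(deg,
                .data$p_adj <= padj_max,
                .data$abs_log2fc >= abs_lfc_min,
                !is.na(.data$regulation))
}

#' @rdname select_significant
#' @export
count_regulation <- function(deg) {
  tibble::tibble(
    n_up = sum(deg$regulation == "up", na.rm = TRUE),
    n_down = sum(deg$regulation == "down", na.rm = TRUE),
    n_total = nrow(deg)
  )
}

# severity helpers -------------------------------------------------------------

impact_severity <- function(impact) {
  # HIGH is most severe; unknown/missing sorts least severe
  match(impact, impact_levels(), nomatch = length(impact_levels()) + 1L)
}

#' Hard-filter variants on quality metrics
#'
#' Applies the GATK-style site filters, each strict exactly as conventionally
#' printed: `QD > 2`, `FS < 60`, `MQ > 40`, `MQRankSum > -12.5`,
#' `ReadPosRankSum > -8`, `SOR < 4`. A value equal to its threshold fails.
#' Metrics absent from a record (common for the rank-sum annotations on
#' homozygous sites) pass by default; set `missing_fails = TRUE` to fail
#' them instead.
#'
#' @param variants Variant tibble (see [read_vcf_variants()]).
#' @param missing_fails Treat an absent metric as failing its filter.
#' @return The input with logical `hard_pass` and list-column
#'   `hard_failed` naming the metrics that failed per variant.
#' @export
hard_filter <- function(variants, missing_fails = FALSE) {
  th <- hard_filter_thresholds()
  na_ok <- !missing_fails
  check <- function(x, t, greater) {
    ok <- if (greater) x > t else x < t
    ifelse(is.na(x), na_ok, ok)
  }
  verdicts <- cbind(
    QD = check(variants$QD, th$QD, TRUE),
    FS = check(variants$FS, th$FS, FALSE),
    MQ = check(variants$MQ, th$MQ, TRUE),
    MQRankSum = check(variants$MQRankSum, th$MQRankSum, TRUE),
    ReadPosRankSum = check(variants$ReadPosRankSum, th$ReadPosRankSum, TRUE),
    SOR = check(variants$SOR, th$SOR, FALSE)
  )
  variants$hard_pass <- rowSums(!verdicts) == 0L
  variants$hard_failed <- apply(verdicts, 1,
                                function(v) colnames(verdicts)[!v],
                                simplify = FALSE)
  variants
}

#' Downstream annotation filter
#'
#' On hard-filter survivors, keeps variants that are protein coding, rare
#' (`AF < af_max` and `ExAC_AF < exac_max`), not synonymous, and whose
#' impact is HIGH, MODERATE or LOW (not only MODIFIER). Absent allele
#' frequencies are treated as rare (an unobserved variant) by default.
#'
#' @param variants Variant tibble.
#' @param af_max,exac_max Population allele-frequency ceilings.
#' @param missing_af_rare Treat a missing AF/ExAC_AF as below the ceiling.
#' @return The input with logical `downstream_pass` and list-column
#'   `downstream_failed` naming the rules that failed
#'   (`"biotype"`, `"AF"`, `"ExAC_AF"`, `"consequence"`, `"impact"`).
#' @export
downstream_filter <- function(variants, af_max = 0.01, exac_max = 0.01,
                              missing_af_rare = TRUE) {
  rare <- function(x, cap) ifelse(is.na(x), missing_af_rare, x < cap)
  cons <- tidyr::replace_na(variants$consequence, "")
  verdicts <- cbind(
    biotype = variants$biotype %in% "protein_coding",
    AF = rare(variants$AF, af_max),
    ExAC_AF = rare(variants$ExAC_AF, exac_max),
    consequence = !grepl("(^|&)synonymous_variant($|&)", cons),
    impact = variants$impact %in% c("HIGH", "MODERATE", "LOW")
  )
  variants$downstream_pass <- rowSums(!verdicts) == 0L
  variants$downstream_failed <- apply(verdicts, 1,
                                      function(v) colnames(verdicts)[!v],
                                      simplify = FALSE)
  variants
}

#' Call loss-of-function variants
#'
#' A variant is loss-of-function when it is a missense variant whose SIFT
#' annotation begins with "deleterious" and whose PolyPhen-2 annotation is
#' damaging. Numeric suffixes such as `deleterious(0.01)` are accepted. Both
#' probably and possibly damaging PolyPhen calls count by default; restrict
#' via `damaging`.
#'
#' @param variants Variant tibble.
#' @param damaging PolyPhen categories accepted as damaging.
#' @return The input with a logical `is_lof` column.
#' @export
call_lof <- function(variants,
                     damaging = c("probably_damaging", "possibly_damaging")) {
  strip <- function(x) sub("\\(.*\\)$", "", x)
  sift <- strip(variants$SIFT)
  pp <- strip(variants$PolyPhen)
  variants$is_lof <-
    grepl("(^|&)missense_variant($|&)",
          tidyr::replace_na(variants$consequence, "")) &
    !is.na(sift) & startsWith(sift, "deleterious") &
    !is.na(pp) & pp %in% damaging
  variants
}

#' Run the full variant filter cascade
#'
#' Chains [hard_filter()], [downstream_filter()] (evaluated only on
#' hard-filter survivors) and [call_lof()]. The final survivor flag is
#' `pass = hard_pass & downstream_pass`.
#'
#' @inheritParams hard_filter
#' @inheritParams downstream_filter
#' @inheritParams call_lof
#' @return The variant tibble with all verdict columns plus `pass`.
#' @export
filter_variants <- function(variants, missing_fails = FALSE,
                            af_max = 0.01, exac_max = 0.01,
                            missing_af_rare = TRUE,
                            damaging = c("probably_damaging", "possibly_damaging")) {
  v <- hard_filter(variants, missing_fails = missing_fails)
  v <- downstream_filter(v, af_max = af_max, exac_max = exac_max,
                         missing_af_rare = missing_af_rare)
  v$downstream_pass <- v$hard_pass & v$downstream_pass
  v <- call_lof(v, damaging = damaging)
  v$pass <- v$hard_pass & v$downstream_pass
  v$is_lof <- v$is_lof & v$pass
  v
}

#' Per-gene variant impact tallies
#'
#' Groups surviving variants by gene and counts HIGH / MODERATE / LOW
#' variants plus loss-of-function calls; a gene's headline impact is the
#' most severe impact among its variants.
#'
#' @param variants Filtered variant tibble (survivors only, e.g.
#'   `dplyr::filter(filter_variants(v), pass)`).
#' @return A tibble with `gene`, `n_high`, `n_moderate`, `n_low`, `n_lof`,
#'   `n_variants` and `headline_impact`.
#' @export
classify_impact <- function(variants) {
  if (!nrow(variants)) {
    return(tibble::tibble(
      gene = character(), n_high = integer(), n_moderate = integer(),
      n_low = integer(), n_lof = integer(), n_variants = integer(),
      headline_impact = character()))
  }
  if (!"is_lof" %in% names(variants)) variants$is_lof <- FALSE
  variants |>
    dplyr::summarise(
      n_high = sum(.data$impact == "HIGH"),
      n_moderate = sum(.data$impact == "MODERATE"),
      n_low = sum(.data$impact == "LOW"),
      n_lof = sum(.data$is_lof),
      n_variants = dplyr::n(),
      headline_impact = impact_levels()[min(impact_severity(.data$impact))],
      .by = "gene") |>
    dplyr::arrange(.data$gene)
}
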