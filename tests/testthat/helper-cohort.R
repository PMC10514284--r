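# Shared fixtures, built in code once per test run.

small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_targets = 60, n_planted_top = 5, seed = seed, ...)
}

# One cohort reused by read-only tests.
shared_cohort <- simulate_cohort(small_spec())

ref_today <- shared_cohort$spec$reference_date

# Build a single evidence document with sensible defaults.
make_doc <- function(doc_id = "d1", target = "IL13",
                     asset_class = "publication",
                     date = as.Date("2022-06-01"),
                     impact_factor = NA_real_, citations = NA_integer_,
                     position = "title", phase = NA_real_,
                     status = NA_character_) {
  tibble::tibble(doc_id = doc_id, target = target, asset_class = asset_class,
                 date = date, impact_factor = impact_factor,
                 citations = citations, position = position, phase = phase,
                 status = status)
}

# Build a variant row with all metrics strictly inside the hard-filter
# bounds and a clean protein-coding missense annotation.
make_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                         QD = 10, FS = 10, MQ = 50, MQRankSum = 0,
                         ReadPosRankSum = 0, SOR = 1,
                         gene = "IL13", biotype = "protein_coding",
                         consequence = "missense_variant",
                         impact = "MODERATE", AF = 0.001, ExAC_AF = 0.001,
                         SIFT = "tolerated(0.5)", PolyPhen = "benign(0.1)") {
  tibble::tibble(chrom = chrom, pos = pos, rsid = NA_character_, ref = ref,
                 alt = alt, variant_class = "SNP", QD = QD, FS = FS, MQ = MQ,
                 MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
                 SOR = SOR, gene = gene, biotype = biotype,
                 consequence = consequence, impact = impact, AF = AF,
                 ExAC_AF = ExAC_AF, SIFT = SIFT, PolyPhen = PolyPhen)
}

# Independent brute-force oracle for the six hard-filter predicates,
# written directly from the printed thresholds (strict inequalities,
# missing metric passes).
oracle_hard_pass <- function(v) {
  ok <- function(x) is.na(x)
  (ok(v$QD) | v$QD > 2) & (ok(v$FS) | v$FS < 60) & (ok(v$MQ) | v$MQ > 40) &
    (ok(v$MQRankSum) | v$MQRankSum > -12.5) &
    (ok(v$ReadPosRankSum) | v$ReadPosRankSum > -8) &
    (ok(v$SOR) | v$SOR < 4)
}

# Independent oracle for the downstream annotation filter.
oracle_downstream_pass <- function(v) {
  rare <- function(x) is.na(x) | x < 0.01
  v$biotype == "protein_coding" & rare(v$AF) & rare(v$ExAC_AF) &
    !grepl("synonymous_variant", v$consequence, fixed = TRUE) &
    v$impact %in% c("HIGH", "MODERATE", "LOW")
}

# Independent oracle for the loss-of-function rule.
oracle_lof <- function(v) {
  strip <- function(x) sub("\\(.*", "", x)
  out <- grepl("missense_variant", v$consequence, fixed = TRUE) &
    grepl("^deleterious", strip(v$SIFT)) &
    grepl("damaging", strip(v$PolyPhen))
  out & !is.na(out)
}
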