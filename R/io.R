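#' Write a simulated cohort to disk
#'
#' Serializes every component of a [simulate_cohort()] result into the plain
#' text formats the pipeline reads back: a JSON-lines document corpus, a DE
#' CSV, a VCFv4.2 variant file with a VEP-style `CSQ` annotation field, a GMT
#' pathway collection, TSV annotation/drug/trial/tissue/database tables and a
#' ground-truth JSON.
#'
#' @param cohort A `target_cohort` from [simulate_cohort()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "target_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_documents_jsonl(cohort$documents, p("documents.jsonl"))
  readr::write_csv(cohort$deg_table, p("deg_table.csv"))
  write_variants_vcf(cohort$variants, p("variants.vcf"))
  write_gmt(cohort$pathways, p("pathways.gmt"))
  writeLines(cohort$disease_pathways, p("disease_pathways.txt"))
  readr::write_tsv(cohort$db_table, p("db_sources.tsv"))
  readr::write_tsv(cohort$drugs, p("drugs.tsv"))
  readr::write_tsv(cohort$trials, p("trials.tsv"))
  readr::write_tsv(cohort$annotations, p("annotations.tsv"))
  readr::write_tsv(cohort$tissue, p("tissue.tsv"))
  readr::write_tsv(cohort$biomarker_evidence, p("biomarker_evidence.tsv"))

  gt <- cohort$ground_truth
  gt$planted_classes <- dplyr::mutate(
    gt$planted_classes,
    biomarker = vapply(.data$biomarker, paste, character(1), collapse = ","))
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = FALSE,
                       dataframe = "columns", Date = "ISO8601", na = "null",
                       pretty = TRUE)

  files <- c("documents.jsonl", "deg_table.csv", "variants.vcf", "pathways.gmt",
             "disease_pathways.txt", "db_sources.tsv", "drugs.tsv", "trials.tsv",
             "annotations.tsv", "tissue.tsv", "biomarker_evidence.tsv",
             "ground_truth.json")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Read and write the document corpus
#'
#' One evidence document per JSON line, with asset-class specific fields
#' (`impact_factor`/`citations` for publications, `phase`/`status` for
#' clinical trials) null where not applicable.
#'
#' @param documents Tibble of evidence documents.
#' @param path File path.
#' @return `read_documents()` returns a tibble with typed columns.
#' @export
write_documents_jsonl <- function(documents, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  docs <- dplyr::mutate(documents, date = as.character(.data$date))
  jsonlite::stream_out(docs, con, verbose = FALSE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_documents_jsonl
#' @export
read_documents <- function(path) {
  docs <- tibble::as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  template <- list(doc_id = NA_character_, target = NA_character_,
                   asset_class = NA_character_, date = NA_character_,
                   impact_factor = NA_real_, citations = NA_integer_,
                   position = NA_character_, phase = NA_real_,
                   status = NA_character_)
  for (col in names(template)) {
    if (!col %in% names(docs)) docs[[col]] <- template[[col]]
  }
  docs$date <- as.Date(docs$date)
  docs$citations <- as.integer(docs$citations)
  docs$phase <- as.numeric(docs$phase)
  docs$impact_factor <- as.numeric(docs$impact_factor)
  docs[, names(template)]
}

# ---- VCF --------------------------------------------------------------------

csq_fields <- function() {
  c("Gene", "BIOTYPE", "Consequence", "IMPACT", "AF", "ExAC_AF", "SIFT", "PolyPhen")
}

#' Write variants as VCFv4.2
#'
#' Quality metrics are emitted as the INFO keys `QD`, `FS`, `MQ`,
#' `MQRankSum`, `ReadPosRankSum` and `SOR` (missing values omitted, as
#' variant callers do on e.g. homozygous sites), and the functional
#' annotation as a VEP-style pipe-delimited `CSQ` field whose subfield order
#' is declared in the header.
#'
#' @param variants Variant tibble as produced by [simulate_cohort()].
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                formatC(x, format = "g", digits = 6))
  metric_keys <- names(hard_filter_thresholds())
  info_metrics <- apply(
    do.call(cbind, lapply(metric_keys, function(k) {
      v <- fmt_num(variants[[k]])
      ifelse(is.na(v), NA_character_, paste0(k, "=", v))
    })),
    1, function(row) paste(row[!is.na(row)], collapse = ";"))

  csq_val <- function(x) ifelse(is.na(x), "", as.character(x))
  csq <- paste(
    csq_val(variants$gene), csq_val(variants$biotype),
    csq_val(variants$consequence), csq_val(variants$impact),
    fmt_csq_num(variants$AF), fmt_csq_num(variants$ExAC_AF),
    csq_val(variants$SIFT), csq_val(variants$PolyPhen), sep = "|")
  info <- paste0(ifelse(nchar(info_metrics) > 0, paste0(info_metrics, ";"), ""),
                 "CSQ=", csq)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=targetrank",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant confidence normalized by unfiltered depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Rank sum of ref vs alt mapping qualities\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Rank sum of ref vs alt read positions\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric strand odds ratio\">",
    sprintf("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations. Format: %s\">",
            paste(csq_fields(), collapse = "|")),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- paste(variants$chrom, variants$pos,
                ifelse(is.na(variants$rsid), ".", variants$rsid),
                variants$ref, variants$alt, ".", ".", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

fmt_csq_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "g", digits = 6))
}

#' Read an annotated VCF into a variant tibble
#'
#' Parses a VCFv4.2 file (via `vcfR`), pulls the GATK-style quality metrics
#' from INFO and expands the VEP-style `CSQ` annotation whose subfield order
#' is taken from the file header. Multi-allelic records are split into one
#' row per alternate allele. When a variant carries several annotation
#' blocks, the block with the most severe impact is kept; a variant is
#' "modifier only" exactly when all of its blocks are MODIFIER.
#'
#' @param path Path to a VCF file.
#' @return A variant tibble with columns `chrom`, `pos`, `rsid`, `ref`,
#'   `alt`, `variant_class`, the six quality metrics, and the annotation
#'   columns `gene`, `biotype`, `consequence`, `impact`, `AF`, `ExAC_AF`,
#'   `SIFT`, `PolyPhen`.
#' @export
read_vcf_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                                         stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))
  info <- fix$info
  if (is.null(info)) info <- vcf@fix[, "INFO"]

  # CSQ subfield order comes from the header declaration
  meta <- vcf@meta
  csq_line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  fields <- csq_fields()
  if (length(csq_line)) {
    m <- regmatches(csq_line[1],
                    regexpr("Format: [A-Za-z0-9_|]+", csq_line[1]))
    if (length(m)) fields <- strsplit(sub("^Format: ", "", m), "\\|")[[1]]
  }

  get_info_num <- function(key) {
    val <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.numeric(val)
  }
  out <- tibble::tibble(
    chrom = fix$chrom,
    pos = as.integer(fix$pos),
    rsid = ifelse(fix$id == "." | is.na(fix$id), NA_character_, fix$id),
    ref = fix$ref,
    alt = fix$alt,
    QD = get_info_num("QD"), FS = get_info_num("FS"), MQ = get_info_num("MQ"),
    MQRankSum = get_info_num("MQRankSum"),
    ReadPosRankSum = get_info_num("ReadPosRankSum"),
    SOR = get_info_num("SOR"),
    csq = stringr::str_match(info, "(?:^|;)CSQ=([^;]+)")[, 2]
  )
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  out$variant_class <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1,
                              "SNP", "INDEL")

  ann <- purrr::map(out$csq, parse_csq, fields = fields)
  out <- dplyr::bind_cols(dplyr::select(out, -"csq"), dplyr::bind_rows(ann))
  out$AF <- as.numeric(out$AF)
  out$ExAC_AF <- as.numeric(out$ExAC_AF)
  cols <- c("chrom", "pos", "rsid", "ref", "alt", "variant_class",
            "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR",
            "gene", "biotype", "consequence", "impact", "AF", "ExAC_AF",
            "SIFT", "PolyPhen")
  out[, cols]
}

# Pick the most severe annotation block of one CSQ string.
parse_csq <- function(csq, fields) {
  empty <- stats::setNames(as.list(rep(NA_character_, 8)),
                           c("gene", "biotype", "consequence", "impact",
                             "AF", "ExAC_AF", "SIFT", "PolyPhen"))
  if (is.na(csq) || !nzchar(csq)) return(tibble::as_tibble(empty))
  blocks <- strsplit(csq, ",", fixed = TRUE)[[1]]
  parts <- lapply(blocks, function(b) {
    v <- strsplit(b, "|", fixed = TRUE)[[1]]
    length(v) <- length(fields)
    stats::setNames(as.list(v), fields)
  })
  sev <- vapply(parts, function(p) {
    match(p$IMPACT %||% NA_character_, impact_levels(), nomatch = length(impact_levels()) + 1L)
  }, integer(1))
  best <- parts[[which.min(sev)]]
  blank_na <- function(x) {
    x <- x %||% NA_character_
    if (is.na(x) || !nzchar(x)) NA_character_ else x
  }
  tibble::tibble(
    gene = blank_na(best$Gene), biotype = blank_na(best$BIOTYPE),
    consequence = blank_na(best$Consequence), impact = blank_na(best$IMPACT),
    AF = blank_na(best$AF), ExAC_AF = blank_na(best$ExAC_AF),
    SIFT = blank_na(best$SIFT), PolyPhen = blank_na(best$PolyPhen)
  )
}

# ---- GMT --------------------------------------------------------------------

#' Read and write GMT gene-set collections
#'
#' @param pathways Named list of character vectors (gene symbols per set).
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Read a cohort directory back into memory
#'
#' Inverse of [write_cohort()]: loads every evidence file from `dir` into the
#' tibbles the pipeline functions consume.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list of class `target_cohort` (without `spec`/`ground_truth`
#'   unless `ground_truth.json` is present).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(
    documents = read_documents(p("documents.jsonl")),
    deg_table = readr::read_csv(p("deg_table.csv"), show_col_types = FALSE),
    variants = read_vcf_variants(p("variants.vcf")),
    pathways = read_gmt(p("pathways.gmt")),
    disease_pathways = readLines(p("disease_pathways.txt")),
    db_table = readr::read_tsv(p("db_sources.tsv"), show_col_types = FALSE),
    drugs = readr::read_tsv(p("drugs.tsv"), show_col_types = FALSE),
    trials = readr::read_tsv(p("trials.tsv"), show_col_types = FALSE),
    annotations = readr::read_tsv(p("annotations.tsv"), show_col_types = FALSE),
    tissue = readr::read_tsv(p("tissue.tsv"), show_col_types = FALSE),
    biomarker_evidence = readr::read_tsv(p("biomarker_evidence.tsv"),
                                         show_col_types = FALSE)
  )
  gt_path <- p("ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$planted_classes <- tibble::as_tibble(gt$planted_classes)
    out$ground_truth <- gt
  }
  out$targets <- sort(unique(out$annotations$target))
  structure(out, class = "target_cohort")
}
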