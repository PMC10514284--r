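#' Simulate a target-discovery evidence cohort with planted ground truth
#'
#' Generates every input the prioritization pipeline consumes — a literature
#' document corpus across seven asset classes, a differential-expression
#' table, an annotated variant set, pathway gene sets, structured-database
#' memberships, drug/trial tables and target annotations — together with the
#' ground truth that was planted into them. Planted-top targets receive
#' saturated evidence: document counts above the relevance threshold in every
#' asset class with recent, high-impact, title-position documents, membership
#' in disease pathways, up-regulation in the DE table, passing high-impact
#' and loss-of-function variants, and favorable druggability / safety /
#' biomarker / novelty attributes. Background targets receive sparse,
#' over-dispersed evidence with attributes drawn at the spec's planted
#' fractions, each realized so the rule-based classifiers recover the planted
#' label by construction.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given, all cohort files are written
#'   there (see [write_cohort()]) and the path is stored on the result.
#' @return A list of class `target_cohort` holding tibbles `documents`,
#'   `deg_table`, `variants`, `db_table`, `drugs`, `trials`, `annotations`,
#'   `tissue`, `biomarker_evidence`, the named list `pathways`, the character
#'   vector `disease_pathways`, and `ground_truth` (planted targets, DE
#'   genes, expected-pass variant keys, loss-of-function keys and the
#'   planted per-target class table).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_targets = 40, n_planted_top = 4, seed = 7))
#' cohort$ground_truth$planted_top_targets
simulate_cohort <- function(spec, dir = NULL) {
  validate_cohort_spec(spec)
  cohort <- with_preserved_seed(spec$seed, build_cohort(spec))
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    cohort$dir <- dir
  }
  cohort
}

# Run code under a seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

build_cohort <- function(spec) {
  targets <- sprintf("TRG%04d", seq_len(spec$n_targets))
  planted <- if (spec$n_planted_top > 0) {
    sort(sample(targets, spec$n_planted_top))
  } else {
    character()
  }

  classes <- plant_target_classes(spec, targets, planted)
  documents <- simulate_documents(spec, targets, planted, classes)
  # novelty taxonomy depends on how a target entered the cohort: novels with
  # no literature documents at all are genomics-arm discoveries
  no_lit <- setdiff(classes$novel_background, unique(documents$target))
  classes$labels$taxonomy[classes$labels$target %in% no_lit] <- "unknown_knowns"
  pathway_bits <- simulate_pathways(spec, targets, planted, classes)
  de <- simulate_deg_table(spec, targets, planted)
  var_bits <- simulate_variants(spec, targets, planted)
  db_table <- simulate_db_table(targets, planted)
  trials <- simulate_trials(classes$drugs)

  ground_truth <- list(
    planted_top_targets = planted,
    planted_up = de$planted_up,
    planted_down = de$planted_down,
    variants_expected_pass = var_bits$expected_pass_keys,
    planted_lof = var_bits$planted_lof_keys,
    planted_classes = classes$labels
  )

  structure(list(
    spec = spec,
    targets = targets,
    documents = documents,
    deg_table = de$table,
    variants = var_bits$variants,
    pathways = pathway_bits$pathways,
    disease_pathways = pathway_bits$disease_pathways,
    db_table = db_table,
    drugs = classes$drugs,
    trials = trials,
    annotations = classes$annotations,
    tissue = classes$tissue,
    biomarker_evidence = classes$biomarker_evidence,
    ground_truth = ground_truth
  ), class = "target_cohort")
}

#' @export
print.target_cohort <- function(x, ...) {
  cat("<target_cohort>\n")
  cat(sprintf("  %d targets (%d planted top), %d documents, %d DE rows, %d variants\n",
              length(x$targets), length(x$ground_truth$planted_top_targets),
              nrow(x$documents), nrow(x$deg_table), nrow(x$variants)))
  cat(sprintf("  %d pathways (%d disease), seed %d\n",
              length(x$pathways), length(x$disease_pathways), x$spec$seed))
  invisible(x)
}

# ---- evaluation attributes --------------------------------------------------

# Decide each target's planted evaluation class first, then emit attribute
# tables that realize those classes under the classifier rules by
# construction (no rule logic is re-run here).
plant_target_classes <- function(spec, targets, planted) {
  n <- length(targets)
  is_planted <- targets %in% planted
  bg <- targets[!is_planted]

  ref <- spec$reference_date
  lab <- tibble::tibble(
    target = targets,
    druggability = "none", modality = "none",
    safety = "safe",
    biomarker = vector("list", n),
    novel = FALSE, taxonomy = "n/a",
    lung_expression = "other"
  )
  rowi <- stats::setNames(seq_len(n), targets)

  drugs <- list()
  annotations <- tibble::tibble(
    target = targets,
    has_structure = FALSE, surface_localized = FALSE,
    essential_gene = FALSE, mechanism_known = FALSE,
    last_highif_pub_date = as.Date(NA), last_news_date = as.Date(NA)
  )
  biomarker_rows <- list()
  tissue_rows <- list()
  other_tissues <- c("liver", "kidney", "brain", "heart", "skin")

  add_drug <- function(target, modality, max_phase, status, approved = FALSE,
                       withdrawal = "none", attributed = FALSE) {
    drugs[[length(drugs) + 1]] <<- tibble::tibble(
      drug = sprintf("CMPD%04d", length(drugs) + 1L),
      target = target, modality = modality, max_phase = max_phase,
      status = status, approved = approved, withdrawal = withdrawal,
      reason_target_attributed = attributed
    )
  }
  add_tissue <- function(target, lung, others) {
    tissue_rows[[length(tissue_rows) + 1]] <<- tibble::tibble(
      target = target,
      tissue = c("lung", other_tissues),
      level = c(lung, others)
    )
  }
  add_biomarker <- function(target, cats) {
    biomarker_rows[[length(biomarker_rows) + 1]] <<- tibble::tibble(
      target = target, category = cats,
      citation_id = sprintf("PMID%07d", sample.int(9999999, length(cats)))
    )
  }

  # Planted tops: highly druggable (phase-1 small molecule, structure and
  # surface), safe, diagnostic biomarker, novel known-knowns, lung-high with
  # shared expression, disease-pathway members.
  for (t in planted) {
    i <- rowi[[t]]
    add_drug(t, "small_molecule", 1L, "active")
    annotations$has_structure[i] <- TRUE
    annotations$surface_localized[i] <- TRUE
    annotations$mechanism_known[i] <- TRUE
    annotations$last_highif_pub_date[i] <- ref - sample(30:360, 1)
    annotations$last_news_date[i] <- ref - sample(30:360, 1)
    add_biomarker(t, "diagnostic")
    add_tissue(t, "high", sample(c("medium", "low", "not_detected"), 5, replace = TRUE,
                                 prob = c(0.3, 0.4, 0.3)))
    lab$druggability[i] <- "highly"; lab$modality[i] <- "small_molecule"
    lab$biomarker[[i]] <- "diagnostic"
    lab$novel[i] <- TRUE; lab$taxonomy[i] <- "known_knowns"
    lab$lung_expression[i] <- "high_shared"
  }

  # Background attribute lottery; unsafe / novel / druggable-with-late-phase
  # assignments are kept disjoint so each label is unambiguous.
  n_bg <- length(bg)
  unsafe_pick <- bg[runif(n_bg) < spec$frac_unsafe]
  remaining <- setdiff(bg, unsafe_pick)
  novel_pick <- remaining[runif(length(remaining)) < spec$frac_novel]
  drug_pool <- setdiff(remaining, novel_pick)
  drug_pick <- drug_pool[runif(length(drug_pool)) < spec$frac_druggable]
  biom_pick <- bg[runif(n_bg) < spec$frac_biomarker]

  for (t in unsafe_pick) {
    i <- rowi[[t]]
    kind <- sample(c("market", "clinical", "essential"), 1, prob = c(0.1, 0.1, 0.8))
    if (kind == "market") {
      add_drug(t, "small_molecule", 3L, "terminated", withdrawal = "market",
               attributed = TRUE)
      annotations$has_structure[i] <- TRUE
      lab$safety[i] <- "unsafe_market_withdrawal"
      lab$druggability[i] <- "highly"; lab$modality[i] <- "small_molecule"
    } else if (kind == "clinical") {
      add_drug(t, "antibody", 2L, "withdrawn", withdrawal = "clinical",
               attributed = TRUE)
      annotations$surface_localized[i] <- TRUE
      lab$safety[i] <- "unsafe_clinical_withdrawal"
      lab$druggability[i] <- "highly"; lab$modality[i] <- "antibody"
    } else {
      annotations$essential_gene[i] <- TRUE
      lab$safety[i] <- "unsafe_essential"
    }
  }

  for (t in novel_pick) {
    i <- rowi[[t]]
    annotations$last_highif_pub_date[i] <- ref - sample(30:3000, 1)
    annotations$last_news_date[i] <- ref - sample(30:1500, 1)
    mech <- runif(1) < 0.5
    annotations$mechanism_known[i] <- mech
    if (runif(1) < 0.5) add_drug(t, "small_molecule", 1L, "recruiting")
    lab$novel[i] <- TRUE
    # taxonomy for literature-backed novels; genomics-only novels are
    # re-labelled below once document counts are known
    lab$taxonomy[i] <- if (mech) "known_knowns" else "known_unknowns"
  }

  for (t in drug_pick) {
    i <- rowi[[t]]
    feature <- sample(c("structure", "surface", "both"), 1, prob = c(0.5, 0.3, 0.2))
    if (feature %in% c("structure", "both")) annotations$has_structure[i] <- TRUE
    if (feature %in% c("surface", "both")) annotations$surface_localized[i] <- TRUE
    if (runif(1) < 0.4) {  # highly druggable: clinical precedence exists
      modality <- sample(c("small_molecule", "antibody"), 1)
      add_drug(t, modality, sample(2:4, 1), sample(c("completed", "active"), 1),
               approved = runif(1) < 0.3)
      lab$druggability[i] <- "highly"
      lab$modality[i] <- modality
    } else {
      lab$druggability[i] <- "potentially"
      lab$modality[i] <- switch(feature, structure = "small_molecule",
                                surface = "antibody", both = "both")
    }
  }

  for (t in biom_pick) {
    i <- rowi[[t]]
    cats <- sample(c("diagnostic", "prognostic", "predictive", "therapeutic"),
                   size = if (runif(1) < 0.15) 2 else 1)
    add_biomarker(t, cats)
    existing <- lab$biomarker[[i]]
    lab$biomarker[[i]] <- sort(unique(c(existing, cats)))
  }

  # Stale literature dates for some non-novel targets: outside the novelty
  # windows, so they exercise the date comparisons without flipping labels.
  non_novel_bg <- setdiff(bg, c(novel_pick, unsafe_pick))
  stale <- non_novel_bg[runif(length(non_novel_bg)) < 0.2]
  for (t in stale) {
    i <- rowi[[t]]
    annotations$last_highif_pub_date[i] <- ref - sample(4000:5400, 1)
    annotations$last_news_date[i] <- ref - sample(2000:5400, 1)
  }

  # Tissue classes for background targets.
  bg_tissue_class <- sample(c("exclusive", "high_shared", "other"),
                            length(bg), replace = TRUE,
                            prob = c(0.02, 0.1, 0.88))
  for (k in seq_along(bg)) {
    t <- bg[k]; i <- rowi[[t]]
    cls <- bg_tissue_class[k]
    if (cls == "exclusive") {
      add_tissue(t, sample(c("high", "medium", "low"), 1), rep("not_detected", 5))
    } else if (cls == "high_shared") {
      add_tissue(t, "high", sample(c("low", "medium", "high"), 5, replace = TRUE))
    } else {
      add_tissue(t, sample(c("not_detected", "low", "medium"), 1, prob = c(0.5, 0.35, 0.15)),
                 sample(c("not_detected", "low", "medium", "high"), 5, replace = TRUE))
    }
    lab$lung_expression[i] <- cls
  }

  lab$biomarker <- lapply(lab$biomarker, function(x) if (is.null(x)) character() else x)

  drugs_tbl <- if (length(drugs)) dplyr::bind_rows(drugs) else tibble::tibble(
    drug = character(), target = character(), modality = character(),
    max_phase = integer(), status = character(), approved = logical(),
    withdrawal = character(), reason_target_attributed = logical()
  )
  biom_tbl <- if (length(biomarker_rows)) dplyr::bind_rows(biomarker_rows) else
    tibble::tibble(target = character(), category = character(), citation_id = character())

  list(
    labels = lab,
    annotations = annotations,
    drugs = drugs_tbl,
    tissue = dplyr::bind_rows(tissue_rows),
    biomarker_evidence = biom_tbl,
    novel_background = novel_pick
  )
}

# ---- documents --------------------------------------------------------------

simulate_documents <- function(spec, targets, planted, classes) {
  ref <- spec$reference_date
  rates <- spec$asset_class_rates
  grid <- tidyr::expand_grid(target = targets, asset_class = names(rates))
  grid$n <- rnbinom(nrow(grid), size = 1, mu = rates[grid$asset_class])
  boost <- grid$target %in% planted
  grid$n[boost] <- spec$planted_docs_min +
    rnbinom(sum(boost), size = 2, mu = 5)

  docs <- tidyr::uncount(grid[grid$n > 0, ], weights = .data$n)
  n <- nrow(docs)
  if (n == 0) {
    return(tibble::tibble(
      doc_id = character(), target = character(), asset_class = character(),
      date = as.Date(character()), impact_factor = numeric(),
      citations = integer(), position = character(), phase = numeric(),
      status = character()
    ))
  }
  is_planted <- docs$target %in% planted

  docs$date <- ref - ifelse(is_planted, runif(n, 0, 365), runif(n, 0, 15 * 365.25))
  docs$date <- as.Date(round(as.numeric(docs$date)), origin = "1970-01-01")

  is_pub <- docs$asset_class == "publication"
  docs$impact_factor <- NA_real_
  docs$impact_factor[is_pub & is_planted] <- runif(sum(is_pub & is_planted), 10, 40)
  docs$impact_factor[is_pub & !is_planted] <- rlnorm(sum(is_pub & !is_planted),
                                                     meanlog = log(3), sdlog = 0.8)
  docs$citations <- NA_integer_
  docs$citations[is_pub] <- rnbinom(sum(is_pub), size = 0.5, mu = 20)

  docs$position <- NA_character_
  docs$position[is_planted] <- sample(c("title", "abstract"), sum(is_planted),
                                      replace = TRUE, prob = c(0.7, 0.3))
  docs$position[!is_planted] <- sample(position_levels(), sum(!is_planted),
                                       replace = TRUE,
                                       prob = c(0.1, 0.3, 0.05, 0.05, 0.3, 0.2))

  is_ct <- docs$asset_class == "clinical_trial"
  docs$phase <- NA_real_
  docs$phase[is_ct] <- sample(1:4, sum(is_ct), replace = TRUE,
                              prob = c(0.3, 0.35, 0.25, 0.1))
  docs$phase[is_ct & is_planted] <- sample(3:4, sum(is_ct & is_planted), replace = TRUE)
  docs$status <- NA_character_
  docs$status[is_ct] <- sample(c("completed", "active", "recruiting",
                                 "terminated", "withdrawn"),
                               sum(is_ct), replace = TRUE,
                               prob = c(0.35, 0.2, 0.25, 0.15, 0.05))
  docs$status[is_ct & is_planted] <- "completed"

  docs <- docs[sample.int(n), ]  # shuffle: downstream order-independence is real
  docs$doc_id <- sprintf("DOC%06d", seq_len(n))
  tibble::as_tibble(docs[, c("doc_id", "target", "asset_class", "date",
                             "impact_factor", "citations", "position",
                             "phase", "status")])
}

# ---- pathways ---------------------------------------------------------------

simulate_pathways <- function(spec, targets, planted, classes) {
  disease <- sprintf("DISEASE_PW_%02d", 1:10)
  other <- sprintf("OTHER_PW_%02d", 1:20)
  membership <- stats::setNames(
    lapply(seq_along(targets), function(i) character()), targets)

  for (t in planted) {
    membership[[t]] <- c(sample(disease, 2), sample(other, 1))
  }
  bg <- setdiff(targets, planted)
  in_disease <- runif(length(bg)) < 0.2
  for (k in seq_along(bg)) {
    pws <- character()
    if (in_disease[k]) pws <- sample(disease, 1)
    n_other <- rbinom(1, 3, 0.3)
    if (n_other > 0) pws <- c(pws, sample(other, n_other))
    membership[[bg[k]]] <- pws
  }

  long <- tibble::tibble(
    target = rep(names(membership), lengths(membership)),
    pathway = unlist(membership, use.names = FALSE)
  )
  pathways <- split(long$target, long$pathway)
  # keep empty pathways out; stable order
  pathways <- pathways[order(names(pathways))]
  list(pathways = pathways, disease_pathways = disease)
}

# ---- differential expression ------------------------------------------------

# Table-style DE output: per-gene control/disease means, log2FC, Wald-style
# p-value (here a two-sample t-test on simulated log2 replicates), BH-adjusted
# p-value, |log2FC| and up/down regulation.
simulate_deg_table <- function(spec, targets, planted, n_rep = 5L) {
  n <- length(targets)
  planted_up <- character(); planted_down <- character()
  if (spec$n_de_up > 0) {
    extra_up <- sample(setdiff(targets, planted), spec$n_de_up - length(planted))
    planted_up <- sort(c(planted, extra_up))
  }
  if (spec$n_de_down > 0) {
    planted_down <- sort(sample(setdiff(targets, planted_up), spec$n_de_down))
  }

  base_log2 <- log2(rlnorm(n, meanlog = log(100), sdlog = 1))
  effect <- numeric(n)
  effect[targets %in% planted_up] <- spec$de_effect_log2fc
  effect[targets %in% planted_down] <- -spec$de_effect_log2fc

  ctrl <- matrix(rnorm(n * n_rep, mean = base_log2, sd = spec$de_noise_sd),
                 nrow = n)
  dis <- matrix(rnorm(n * n_rep, mean = base_log2 + effect, sd = spec$de_noise_sd),
                nrow = n)
  p <- vapply(seq_len(n), function(i) t.test(dis[i, ], ctrl[i, ])$p.value,
              numeric(1))
  ctrl_mean <- 2^rowMeans(ctrl)
  dis_mean <- 2^rowMeans(dis)
  lfc <- log2(dis_mean / ctrl_mean)

  tbl <- tibble::tibble(
    gene_symbol = targets,
    control_mean = ctrl_mean,
    disease_mean = dis_mean,
    log2fc = lfc,
    p_value = p,
    p_adj = p.adjust(p, method = "BH")
  )
  tbl <- assign_regulation(tbl)
  list(table = tbl, planted_up = planted_up, planted_down = planted_down)
}

# ---- variants ---------------------------------------------------------------

hard_filter_thresholds <- function() {
  list(QD = 2, FS = 60, MQ = 40, MQRankSum = -12.5, ReadPosRankSum = -8, SOR = 4)
}

draw_passing_metrics <- function(n) {
  tibble::tibble(
    QD = runif(n, 5, 35), FS = runif(n, 1, 50), MQ = runif(n, 42, 60),
    MQRankSum = runif(n, -5, 5), ReadPosRankSum = runif(n, -4, 4),
    SOR = runif(n, 0.2, 3)
  )
}

violate_one_metric <- function(metrics) {
  # flip exactly one metric per row to the failing side of its bound
  fail_draw <- list(
    QD = function(k) runif(k, 0, 1.9), FS = function(k) runif(k, 61, 200),
    MQ = function(k) runif(k, 10, 39), MQRankSum = function(k) runif(k, -20, -13),
    ReadPosRankSum = function(k) runif(k, -15, -8.5),
    SOR = function(k) runif(k, 4.1, 9)
  )
  which_metric <- sample(names(fail_draw), nrow(metrics), replace = TRUE)
  for (m in names(fail_draw)) {
    idx <- which(which_metric == m)
    if (length(idx)) metrics[[m]][idx] <- fail_draw[[m]](length(idx))
  }
  metrics
}

# Expected hard-filter labels, evaluated directly from the printed strict
# inequalities at generation time (missing metric counts as passing).
expected_hard_pass <- function(metrics) {
  th <- hard_filter_thresholds()
  gt <- function(x, t) is.na(x) | x > t
  lt <- function(x, t) is.na(x) | x < t
  gt(metrics$QD, th$QD) & lt(metrics$FS, th$FS) & gt(metrics$MQ, th$MQ) &
    gt(metrics$MQRankSum, th$MQRankSum) &
    gt(metrics$ReadPosRankSum, th$ReadPosRankSum) & lt(metrics$SOR, th$SOR)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

simulate_variants <- function(spec, targets, planted) {
  n <- spec$n_variants
  n_pass <- round(n * spec$variant_pass_fraction)
  metrics <- draw_passing_metrics(n)
  if (n - n_pass > 0 && n > 0) {
    fail_idx <- sample.int(n, n - n_pass)
    metrics[fail_idx, ] <- violate_one_metric(metrics[fail_idx, ])
  }
  # occasional missing rank-sum annotations, as on homozygous sites
  if (n > 0) {
    miss <- runif(n) < 0.08
    metrics$MQRankSum[miss] <- NA_real_
    miss2 <- runif(n) < 0.08
    metrics$ReadPosRankSum[miss2] <- NA_real_
  }

  conseq_pool <- c("missense_variant", "synonymous_variant", "stop_gained",
                   "intron_variant", "3_prime_UTR_variant")
  conseq <- sample(conseq_pool, n, replace = TRUE,
                   prob = c(0.35, 0.15, 0.05, 0.3, 0.15))
  impact <- c(missense_variant = "MODERATE", synonymous_variant = "LOW",
              stop_gained = "HIGH", intron_variant = "MODIFIER",
              `3_prime_UTR_variant` = "MODIFIER")[conseq]

  bg <- tibble::tibble(
    gene = sample(targets, n, replace = TRUE),
    biotype = sample(c("protein_coding", "processed_pseudogene"), n,
                     replace = TRUE, prob = c(0.85, 0.15)),
    consequence = conseq,
    impact = unname(impact),
    AF = ifelse(runif(n) < 0.85, runif(n, 0, 0.005), runif(n, 0.02, 0.2)),
    ExAC_AF = ifelse(runif(n) < 0.85, runif(n, 0, 0.005), runif(n, 0.02, 0.2))
  )
  is_mis <- bg$consequence == "missense_variant"
  bg$SIFT <- NA_character_
  bg$SIFT[is_mis] <- sprintf(
    "%s(%.2f)",
    sample(c("deleterious", "tolerated"), sum(is_mis), replace = TRUE),
    runif(sum(is_mis), 0, 0.4))
  bg$PolyPhen <- NA_character_
  bg$PolyPhen[is_mis] <- sprintf(
    "%s(%.2f)",
    sample(c("probably_damaging", "possibly_damaging", "benign"),
           sum(is_mis), replace = TRUE),
    runif(sum(is_mis), 0, 1))
  bg <- dplyr::bind_cols(bg, metrics)

  # planted variants: one passing HIGH stop-gain plus one passing rare LOF
  # missense per planted-top target
  n_pl <- length(planted)
  if (n_pl > 0) {
    pl <- tibble::tibble(
      gene = rep(planted, each = 2),
      biotype = "protein_coding",
      consequence = rep(c("stop_gained", "missense_variant"), n_pl),
      impact = rep(c("HIGH", "MODERATE"), n_pl),
      AF = runif(2 * n_pl, 0, 0.004),
      ExAC_AF = runif(2 * n_pl, 0, 0.004),
      SIFT = rep(c(NA_character_, "deleterious(0.01)"), n_pl),
      PolyPhen = rep(c(NA_character_, "probably_damaging(0.98)"), n_pl)
    )
    pl <- dplyr::bind_cols(pl, draw_passing_metrics(2 * n_pl))
    bg <- dplyr::bind_rows(bg, pl)
  }

  m <- nrow(bg)
  if (m == 0) {
    empty <- tibble::tibble(
      chrom = character(), pos = integer(), rsid = character(),
      ref = character(), alt = character(), variant_class = character()
    )
    return(list(variants = dplyr::bind_cols(empty, bg),
                expected_pass_keys = character(),
                planted_lof_keys = character()))
  }
  bases <- c("A", "C", "G", "T")
  ref_a <- sample(bases, m, replace = TRUE)
  alt_a <- vapply(ref_a, function(r) sample(setdiff(bases, r), 1), character(1))
  is_indel <- runif(m) < 0.15
  ref_a[is_indel] <- paste0(ref_a[is_indel],
                            sample(bases, sum(is_indel), replace = TRUE))
  bg$variant_class <- ifelse(is_indel, "INDEL", "SNP")
  bg$chrom <- as.character(sample(1:22, m, replace = TRUE))
  bg$pos <- sample.int(5e7, m)
  bg$ref <- ref_a
  bg$alt <- unname(alt_a)
  bg$rsid <- ifelse(runif(m) < 0.4,
                    sprintf("rs%d", sample.int(2e8, m)), NA_character_)
  bg <- dplyr::arrange(bg, as.integer(.data$chrom), .data$pos)
  # keys must be unique to serve as ground-truth identifiers
  stopifnot(!anyDuplicated(variant_key(bg)))

  keys <- variant_key(bg)
  pass <- expected_hard_pass(bg)
  lof_planted <- bg$gene %in% planted & bg$consequence == "missense_variant"

  cols <- c("chrom", "pos", "rsid", "ref", "alt", "variant_class",
            "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR",
            "gene", "biotype", "consequence", "impact", "AF", "ExAC_AF",
            "SIFT", "PolyPhen")
  list(variants = bg[, cols],
       expected_pass_keys = keys[pass],
       planted_lof_keys = keys[lof_planted])
}

#' Generate a boundary-straddling variant fixture
#'
#' Emits a variant table purpose-built to exercise the hard-filter
#' thresholds: for each quality metric, `n_per_metric` variants whose value
#' sits below, exactly at, and above the bound (all other metrics safely
#' passing), plus a grid of missense annotations covering every
#' SIFT x PolyPhen combination used by the loss-of-function rule and a
#' non-missense deleterious/damaging decoy. Each row carries its expected
#' hard-filter verdict computed directly from the printed strict
#' inequalities.
#'
#' @param spec A [cohort_spec()]; only the seed is used.
#' @param n_per_metric Number of boundary variants per quality metric.
#' @return A tibble in the same shape as `simulate_cohort()$variants` with
#'   extra columns `expected_hard_pass` and `boundary_metric`.
#' @export
simulate_variant_fixture <- function(spec, n_per_metric = 10) {
  validate_cohort_spec(spec)
  with_preserved_seed(spec$seed + 1L, build_variant_fixture(spec, n_per_metric))
}

build_variant_fixture <- function(spec, n_per_metric) {
  th <- hard_filter_thresholds()
  offsets <- seq(-0.5, 0.5, length.out = n_per_metric)
  if (!any(offsets == 0)) offsets[ceiling(n_per_metric / 2)] <- 0

  rows <- purrr::map(names(th), function(m) {
    base <- draw_passing_metrics(n_per_metric)
    base[[m]] <- th[[m]] + offsets
    base$boundary_metric <- m
    base
  })
  metrics <- dplyr::bind_rows(rows)

  # LOF rule grid on otherwise clean missense variants
  sift_opts <- c("deleterious(0.02)", "deleterious_low_confidence(0.04)",
                 "tolerated(0.3)")
  pp_opts <- c("probably_damaging(0.98)", "possibly_damaging(0.6)", "benign(0.05)")
  lof_grid <- tidyr::expand_grid(SIFT_v = sift_opts, PolyPhen_v = pp_opts)
  lof_grid <- dplyr::bind_rows(
    dplyr::mutate(lof_grid, consequence = "missense_variant", impact = "MODERATE"),
    tibble::tibble(SIFT_v = "deleterious(0.01)",
                   PolyPhen_v = "probably_damaging(0.99)",
                   consequence = "stop_gained", impact = "HIGH")
  )
  lof_metrics <- draw_passing_metrics(nrow(lof_grid))
  lof_metrics$boundary_metric <- "none"

  n_b <- nrow(metrics)
  n_l <- nrow(lof_grid)
  n <- n_b + n_l
  v <- dplyr::bind_rows(metrics, lof_metrics)
  v$gene <- sprintf("FIX%03d", seq_len(n))
  v$biotype <- "protein_coding"
  v$consequence <- c(rep("missense_variant", n_b), lof_grid$consequence)
  v$impact <- c(rep("MODERATE", n_b), lof_grid$impact)
  v$AF <- runif(n, 0, 0.005)
  v$ExAC_AF <- runif(n, 0, 0.005)
  v$SIFT <- c(rep("tolerated(0.5)", n_b), lof_grid$SIFT_v)
  v$PolyPhen <- c(rep("benign(0.1)", n_b), lof_grid$PolyPhen_v)
  v$chrom <- "1"
  v$pos <- seq(1000L, by = 100L, length.out = n)
  v$ref <- "A"
  v$alt <- "G"
  v$rsid <- NA_character_
  v$variant_class <- "SNP"
  v$expected_hard_pass <- expected_hard_pass(v)
  tibble::as_tibble(v[, c("chrom", "pos", "rsid", "ref", "alt", "variant_class",
                          "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR",
                          "gene", "biotype", "consequence", "impact", "AF",
                          "ExAC_AF", "SIFT", "PolyPhen",
                          "expected_hard_pass", "boundary_metric")])
}

# ---- auxiliary tables -------------------------------------------------------

simulate_db_table <- function(targets, planted) {
  dbs <- c(ClinVar = 0.03, Disgenet = 0.15, `GWAS central` = 0.1, GWAS = 0.08)
  rows <- purrr::imap(dbs, function(rate, db) {
    picked <- targets[runif(length(targets)) < rate]
    picked <- union(picked, if (db == "Disgenet") planted else character())
    if (!length(picked)) return(NULL)
    tibble::tibble(target = sort(picked), database = db)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(tibble::tibble(target = character(), database = character()))
  out
}

simulate_trials <- function(drugs) {
  clin <- dplyr::filter(drugs, .data$max_phase >= 1)
  if (!nrow(clin)) {
    return(tibble::tibble(trial_id = character(), target = character(),
                          drug = character(), sponsor = character(),
                          phase = integer(), status = character()))
  }
  sponsors <- c("Alfa Pharma", "Borealis Bio", "Cardinal Therapeutics",
                "Delta Biologics", "Eastgate Labs")
  n_tr <- sample(1:3, nrow(clin), replace = TRUE)
  out <- tidyr::uncount(dplyr::mutate(clin, n = n_tr), weights = .data$n)
  tibble::tibble(
    trial_id = sprintf("TRIAL%05d", seq_len(nrow(out))),
    target = out$target,
    drug = out$drug,
    sponsor = sample(sponsors, nrow(out), replace = TRUE,
                     prob = c(0.3, 0.25, 0.2, 0.15, 0.1)),
    phase = pmin(out$max_phase, sample(1:4, nrow(out), replace = TRUE)),
    status = sample(c("completed", "active", "recruiting", "terminated"),
                    nrow(out), replace = TRUE)
  )
}
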