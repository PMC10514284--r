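ann_row <- function(target = "T1", has_structure = FALSE,
                    surface_localized = FALSE, essential_gene = FALSE,
                    mechanism_known = FALSE,
                    last_highif_pub_date = as.Date(NA),
                    last_news_date = as.Date(NA)) {
  tibble::tibble(target = target, has_structure = has_structure,
                 surface_localized = surface_localized,
                 essential_gene = essential_gene,
                 mechanism_known = mechanism_known,
                 last_highif_pub_date = last_highif_pub_date,
                 last_news_date = last_news_date)
}

drug_row <- function(target = "T1", modality = "small_molecule",
                     max_phase = 2L, status = "active", approved = FALSE,
                     withdrawal = "none", reason_target_attributed = FALSE) {
  tibble::tibble(drug = paste0("d", target, modality, max_phase),
                 target = target, modality = modality, max_phase = max_phase,
                 status = status, approved = approved,
                 withdrawal = withdrawal,
                 reason_target_attributed = reason_target_attributed)
}

no_drugs <- drug_row()[0, ]

test_that("druggability combines clinical precedence with structural features", {
  both <- classify_druggability(
    ann_row(has_structure = TRUE),
    dplyr::bind_rows(drug_row(modality = "antibody", max_phase = 3L),
                     drug_row(modality = "small_molecule", max_phase = 2L)))
  expect_equal(both$druggability, "highly")
  expect_equal(both$modality, "both")

  pot <- classify_druggability(ann_row(has_structure = TRUE), no_drugs)
  expect_equal(pot$druggability, "potentially")
  expect_equal(pot$modality, "small_molecule")

  surf <- classify_druggability(ann_row(surface_localized = TRUE), no_drugs)
  expect_equal(surf$modality, "antibody")

  # precedence without a structure or localization is not druggable
  prec_only <- classify_druggability(ann_row(), drug_row(max_phase = 3L))
  expect_equal(prec_only$druggability, "none")
  expect_equal(prec_only$modality, "none")

  # preclinical-only drugs (phase 0) give no precedence
  precl <- classify_druggability(ann_row(has_structure = TRUE),
                                 drug_row(max_phase = 0L))
  expect_equal(precl$druggability, "potentially")
})

test_that("safety rules fire in printed order with target attribution", {
  mkt <- classify_safety(ann_row(), drug_row(withdrawal = "market",
                                             reason_target_attributed = TRUE))
  expect_equal(mkt$safety, "unsafe_market_withdrawal")

  # withdrawal not attributed to the target does not flag it
  not_attr <- classify_safety(ann_row(), drug_row(withdrawal = "clinical",
                                                  status = "terminated"))
  expect_equal(not_attr$safety, "safe")

  clin <- classify_safety(ann_row(),
                          drug_row(withdrawal = "clinical", max_phase = 2L,
                                   status = "withdrawn",
                                   reason_target_attributed = TRUE))
  expect_equal(clin$safety, "unsafe_clinical_withdrawal")

  # rescued by another drug ongoing at a higher phase
  rescued <- classify_safety(ann_row(), dplyr::bind_rows(
    drug_row(withdrawal = "clinical", max_phase = 2L, status = "withdrawn",
             reason_target_attributed = TRUE),
    drug_row(modality = "antibody", max_phase = 3L, status = "active")))
  expect_equal(rescued$safety, "safe")

  ess <- classify_safety(ann_row(essential_gene = TRUE), no_drugs)
  expect_equal(ess$safety, "unsafe_essential")

  # first match wins: market withdrawal outranks essentiality
  first <- classify_safety(ann_row(essential_gene = TRUE),
                           drug_row(withdrawal = "market",
                                    reason_target_attributed = TRUE))
  expect_equal(first$safety, "unsafe_market_withdrawal")
})

test_that("biomarker classification unions evidence categories per target", {
  ev <- tibble::tibble(target = c("POSTN", "POSTN", "IL13"),
                       category = c("diagnostic", "prognostic", "diagnostic"),
                       citation_id = c("c1", "c2", "c3"))
  out <- classify_biomarker(ev, c("POSTN", "IL13", "XYZ"))
  expect_equal(out$biomarker_categories[out$target == "POSTN"][[1]],
               c("diagnostic", "prognostic"))
  expect_false(out$is_biomarker[out$target == "XYZ"])
  expect_error(classify_biomarker(
    tibble::tibble(target = "A", category = "theranostic",
                   citation_id = "c"), "A"), "theranostic")

  set.seed(21)
  cats <- c("diagnostic", "prognostic", "predictive", "therapeutic")
  rnd <- tibble::tibble(
    target = sample(sprintf("T%02d", 1:20), 60, replace = TRUE),
    category = sample(cats, 60, replace = TRUE),
    citation_id = sprintf("c%02d", 1:60))
  got <- classify_biomarker(rnd, sprintf("T%02d", 1:20))
  for (cat in cats) {
    n_got <- sum(vapply(got$biomarker_categories, function(x) cat %in% x,
                        logical(1)))
    expect_equal(n_got, length(unique(rnd$target[rnd$category == cat])))
  }
})

test_that("novelty needs recent high-impact discussion, recent news and phase <= 1", {
  today <- as.Date("2023-01-01")
  base <- ann_row(last_highif_pub_date = today - 3 * 365,
                  last_news_date = today - 365)
  nov <- classify_novelty(base, drug_row(max_phase = 1L), today = today)
  expect_true(nov$novel)

  ph2 <- classify_novelty(base, drug_row(max_phase = 2L), today = today)
  expect_false(ph2$novel)
  expect_equal(ph2$novelty_taxonomy, "n/a")

  old_pub <- classify_novelty(
    ann_row(last_highif_pub_date = today - 11 * 365.25,
            last_news_date = today - 365), no_drugs, today = today)
  expect_false(old_pub$novel)

  old_news <- classify_novelty(
    ann_row(last_highif_pub_date = today - 365,
            last_news_date = today - 6 * 365.25), no_drugs, today = today)
  expect_false(old_news$novel)
})

test_that("novelty taxonomy distinguishes literature and genomics provenance", {
  today <- as.Date("2023-01-01")
  base <- ann_row(last_highif_pub_date = today - 100,
                  last_news_date = today - 100)
  genomics_only <- ingest_evidence(deg_targets = "T1")
  expect_equal(classify_novelty(base, no_drugs, genomics_only,
                                today)$novelty_taxonomy, "unknown_knowns")

  lit_ev <- ingest_evidence(make_doc(target = "T1"))
  mech <- dplyr::mutate(base, mechanism_known = TRUE)
  expect_equal(classify_novelty(mech, no_drugs, lit_ev,
                                today)$novelty_taxonomy, "known_knowns")
  expect_equal(classify_novelty(base, no_drugs, lit_ev,
                                today)$novelty_taxonomy, "known_unknowns")
})

test_that("raising a drug phase can never make a target novel", {
  today <- as.Date("2023-01-01")
  set.seed(31)
  for (i in 1:50) {
    ann <- ann_row(
      last_highif_pub_date = today - sample(0:5000, 1),
      last_news_date = today - sample(0:3000, 1))
    ph <- sample(0:3, 1)
    before <- classify_novelty(ann, drug_row(max_phase = ph), today = today)$novel
    after <- classify_novelty(ann, drug_row(max_phase = ph + 1L),
                              today = today)$novel
    expect_true(before | !after)
  }
})

test_that("tissue classes follow the lung-exclusivity definitions", {
  mk <- function(lung, liver) tibble::tibble(
    target = "T1", tissue = c("lung", "liver"), level = c(lung, liver))
  expect_equal(classify_tissue(mk("high", "not_detected"))$lung_expression,
               "exclusive")
  expect_equal(classify_tissue(mk("high", "medium"))$lung_expression,
               "high_shared")
  expect_equal(classify_tissue(mk("low", "high"))$lung_expression, "other")
  expect_equal(classify_tissue(mk("not_detected", "high"))$lung_expression,
               "other")
  # a missing lung row is treated as not detected, with a log message
  no_lung <- tibble::tibble(target = "T1", tissue = "liver", level = "high")
  expect_message(out <- classify_tissue(no_lung), "not detected")
  expect_equal(out$lung_expression, "other")
  expect_error(classify_tissue(mk("soaring", "low")), "soaring")
})

test_that("pathway overlap counts set intersections", {
  expect_equal(pathway_overlap(list(A = c("p1", "p2")), c("p3", "p4"))$
                 pathway_overlap_count, 0L)
  expect_equal(pathway_overlap(list(A = c("p1", "p2", "p3")),
                               c("p1", "p2", "p3"))$pathway_overlap_count, 3L)
  set.seed(41)
  for (i in 1:10) {
    tp <- sample(letters, sample(0:10, 1))
    dp <- sample(letters, sample(0:10, 1))
    got <- pathway_overlap(list(A = tp), dp)$pathway_overlap_count
    expect_equal(got, sum(unique(tp) %in% dp))
  }
})

test_that("hypergeometric enrichment matches direct tail summation", {
  # k=2 overlap, 5 targets, 10-gene set, universe of 100
  universe <- sprintf("U%03d", 1:100)
  gene_set <- universe[1:10]
  targets <- c(universe[1:2], universe[50:52])
  res <- enrich_pathways(targets, list(pw = gene_set), universe)
  tail_sum <- sum(vapply(2:5, function(i) {
    exp(lchoose(10, i) + lchoose(90, 5 - i) - lchoose(100, 5))
  }, numeric(1)))
  expect_equal(res$p_value, tail_sum, tolerance = 1e-12)
  expect_equal(res$k, 2L)

  # a perfectly recovered gene set is the top hit
  sets <- list(perfect = universe[1:8], decoy1 = universe[20:40],
               decoy2 = universe[60:90])
  hit <- enrich_pathways(universe[1:8], sets, universe)
  expect_equal(hit$pathway[1], "perfect")
  expect_equal(hit$p_value[1], min(hit$p_value))
  expect_true(all(hit$p_adj >= hit$p_value))
  expect_true(!is.unsorted(hit$p_adj))

  expect_equal(nrow(enrich_pathways(character(), sets, universe)), 0)
  expect_error(enrich_pathways("NOT_THERE", sets, universe), "subset")
})

test_that("uniformly drawn target sets are not called enriched", {
  set.seed(51)
  universe <- sprintf("U%03d", 1:200)
  gene_set <- list(pw = universe[1:30])
  padj <- replicate(200, {
    enrich_pathways(sample(universe, 20), gene_set, universe)$p_adj
  })
  # adjusted p-values dominate uniform: the small quantiles are not inflated
  for (q in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(padj <= q), q + 0.08)
  }
})
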