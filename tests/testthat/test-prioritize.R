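profile_row <- function(target = "T1", druggability = "none",
                        modality = "none", safety = "safe",
                        biomarker_categories = list(character()),
                        is_biomarker = FALSE, novel = FALSE,
                        novelty_taxonomy = "n/a", lung_expression = "other",
                        pathway_overlap_count = 0L) {
  tibble::tibble(target = target, druggability = druggability,
                 modality = modality, safety = safety,
                 biomarker_categories = biomarker_categories,
                 is_biomarker = is_biomarker, novel = novel,
                 novelty_taxonomy = novelty_taxonomy,
                 lung_expression = lung_expression,
                 pathway_overlap_count = pathway_overlap_count)
}

test_that("default weights satisfy the 40/60/100 split and are validated", {
  w <- weight_config()
  expect_equal(sum(w$literature), 40)
  expect_equal(sum(w$disease), 60)
  expect_equal(sum(w$literature) + sum(w$disease), 100)
  expect_error(weight_config(literature = c(
    publication = 20, congress = 3, clinical_trial = 9, patent = 4,
    grant = 6, news = 6)), "sum to 40")
  expect_error(weight_config(disease = c(
    druggability = 1, pathways = 9, biomarker = 3, safety = 3,
    expression_mutation = 12, tissue_expression = 9, novelty = 12)),
    "sum to 60")
  expect_error(weight_config(literature = c(publication = 40)), "cover")
})

test_that("violated weight sums abort before any scoring", {
  w <- weight_config()
  w$disease["druggability"] <- 50
  scaled <- tibble::tibble(target = "A", asset_class = "publication",
                           raw = 1, scaled = 1)
  params <- disease_parameter_scores(profile_row("A"))
  expect_error(combine_scores(scaled, params, w), "sum to 60")
})

test_that("reweighting honors the strict and normalize policies", {
  w <- reweight(weight_config(policy = "normalize"),
                disease = c(druggability = 24))
  expect_equal(sum(w$disease), 60)
  expect_equal(unname(w$disease["druggability"]), 24 * 60 / 72)

  strict_ok <- reweight(weight_config(),
                        disease = c(druggability = 15, novelty = 9))
  expect_equal(sum(strict_ok$disease), 60)
  expect_error(reweight(weight_config(), disease = c(druggability = 24)),
               "sum to 60")
  expect_error(reweight(weight_config(), disease = c(druggability = -1)),
               "non-negative")
  expect_error(reweight(weight_config(), disease = c(bogus = 5)), "bogus")
})

test_that("disease parameter scores follow the published rule table", {
  p <- disease_parameter_scores(
    profile_row("A", druggability = "highly", safety = "safe"))
  expect_equal(p$druggability, 1)
  expect_equal(p$safety, 1)
  expect_equal(p$pathways + p$biomarker + p$expression_mutation +
                 p$tissue_expression - 0.2 + p$novelty, 0)

  unsafe <- disease_parameter_scores(
    profile_row("B", safety = "unsafe_essential"))
  expect_equal(unsafe$safety, 0)

  rich <- disease_parameter_scores(
    profile_row("C", druggability = "potentially", is_biomarker = TRUE,
                novel = TRUE, lung_expression = "high_shared",
                pathway_overlap_count = 3L),
    deg_targets = "C",
    variant_impact = tibble::tibble(gene = "C", headline_impact = "MODERATE"))
  expect_equal(rich$druggability, 0.5)
  expect_equal(rich$pathways, 3 / 5)
  expect_equal(rich$biomarker, 1)
  expect_equal(rich$expression_mutation, (1 + 0.6) / 2)
  expect_equal(rich$tissue_expression, 0.7)
  expect_equal(rich$novelty, 1)

  # saturation of the pathway overlap score
  sat <- disease_parameter_scores(profile_row("D", pathway_overlap_count = 12L))
  expect_equal(sat$pathways, 1)
})

test_that("random profiles score identically under independent rule re-application", {
  set.seed(61)
  n <- 40
  profs <- purrr::map_dfr(1:n, function(i) profile_row(
    sprintf("T%02d", i),
    druggability = sample(c("highly", "potentially", "none"), 1),
    safety = sample(c("safe", "unsafe_essential", "unsafe_market_withdrawal"), 1),
    is_biomarker = runif(1) < 0.5,
    novel = runif(1) < 0.3,
    lung_expression = sample(c("exclusive", "high_shared", "other"), 1),
    pathway_overlap_count = sample(0:8, 1)))
  deg <- sample(profs$target, 10)
  vi <- tibble::tibble(gene = sample(profs$target, 12),
                       headline_impact = sample(c("HIGH", "MODERATE", "LOW"),
                                                12, replace = TRUE))
  got <- disease_parameter_scores(profs, deg, vi)
  sev_map <- c(HIGH = 1, MODERATE = 0.6, LOW = 0.3)
  for (i in seq_len(n)) {
    t <- profs$target[i]
    sev <- if (t %in% vi$gene) unname(sev_map[vi$headline_impact[vi$gene == t]]) else 0
    expect_equal(got$druggability[i],
                 switch(profs$druggability[i], highly = 1, potentially = 0.5, 0))
    expect_equal(got$pathways[i], min(profs$pathway_overlap_count[i] / 5, 1))
    expect_equal(got$safety[i], as.numeric(profs$safety[i] == "safe"))
    expect_equal(got$expression_mutation[i], ((t %in% deg) + sev) / 2)
    expect_equal(got$tissue_expression[i],
                 switch(profs$lung_expression[i], exclusive = 1,
                        high_shared = 0.7, 0.2))
  }
})

test_that("score combination is the exact weighted sum with saturation bounds", {
  w <- weight_config()
  targets <- c("A", "B")
  scaled <- tidyr::expand_grid(target = targets,
                               asset_class = c("publication", "clinical_trial",
                                               "patent", "grant", "congress",
                                               "news", "thesis"))
  scaled$scaled <- ifelse(scaled$target == "A", 1, 0)
  params <- dplyr::bind_rows(
    dplyr::mutate(disease_parameter_scores(
      profile_row("A", druggability = "highly", is_biomarker = TRUE,
                  novel = TRUE, lung_expression = "exclusive",
                  pathway_overlap_count = 5L),
      deg_targets = "A",
      variant_impact = tibble::tibble(gene = "A", headline_impact = "HIGH"))),
    disease_parameter_scores(
      profile_row("B", safety = "unsafe_essential", lung_expression = "other")))
  # force B's tissue contribution to zero to reach an exact floor
  params$tissue_expression[params$target == "B"] <- 0
  out <- combine_scores(scaled, params, w)
  a <- out[out$target == "A", ]
  expect_equal(a$literature_component, 40)
  expect_equal(a$disease_component, 60)
  expect_equal(a$total, 100)
  b <- out[out$target == "B", ]
  expect_equal(b$literature_component, 0)
  expect_equal(b$total, b$disease_component)
  expect_true(all(out$total == out$literature_component + out$disease_component))
})

test_that("the thesis class carries no prioritization weight", {
  scaled <- tibble::tibble(
    target = "A",
    asset_class = c("publication", "thesis"),
    scaled = c(0, 1))
  params <- disease_parameter_scores(profile_row("A"))
  params$tissue_expression <- 0; params$safety <- 0
  out <- combine_scores(scaled, params, weight_config())
  expect_equal(out$total, 0)
})

test_that("ranking is deterministic with alphabetical tie-break", {
  scores <- tibble::tibble(target = c("ZNF1", "ABC1", "DEF2"),
                           literature_component = 0,
                           disease_component = c(80, 80, 10),
                           total = c(80, 80, 10))
  r <- rank_targets(scores)
  expect_equal(r$target, c("ABC1", "ZNF1", "DEF2"))
  expect_equal(r$rank, 1:3)

  one <- rank_targets(scores[3, ])
  expect_equal(one$rank, 1L)

  set.seed(71)
  rnd <- tibble::tibble(target = sprintf("T%03d", sample(1:100)),
                        literature_component = 0,
                        disease_component = runif(100, 0, 60),
                        total = NA_real_)
  rnd$total <- rnd$disease_component
  r2 <- rank_targets(rnd)
  ord <- order(-rnd$total, rnd$target)
  expect_equal(r2$target, rnd$target[ord])
  expect_equal(r2$rank, seq_len(100))
})

test_that("increasing one parameter score never lowers a total or worsens a rank", {
  set.seed(81)
  w <- weight_config()
  n <- 30
  params <- tibble::tibble(
    target = sprintf("T%02d", 1:n),
    druggability = runif(n), pathways = runif(n), biomarker = runif(n),
    safety = runif(n), expression_mutation = runif(n),
    tissue_expression = runif(n), novelty = runif(n))
  scaled <- tidyr::expand_grid(target = params$target,
                               asset_class = weighted_names <- c(
                                 "publication", "clinical_trial", "patent",
                                 "grant", "congress", "news"))
  scaled$scaled <- runif(nrow(scaled))
  base <- rank_targets(combine_scores(scaled, params, w))
  for (i in 1:40) {
    t <- sample(params$target, 1)
    par <- sample(setdiff(names(params), "target"), 1)
    bumped <- params
    bumped[[par]][bumped$target == t] <-
      min(1, bumped[[par]][bumped$target == t] + runif(1, 0, 0.5))
    new <- rank_targets(combine_scores(scaled, bumped, w))
    expect_gte(new$total[new$target == t], base$total[base$target == t] - 1e-12)
    expect_lte(new$rank[new$target == t], base$rank[base$target == t])
  }
})
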