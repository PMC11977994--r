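test_that("insight qualification counts Mendelian genes and distinct loci", {
  terms <- c("trait1", "trait2", "se1")
  sim <- toy_sim(terms,
                 pairs = tibble::tibble(a = "trait1", b = "se1",
                                        s = 0.85))
  # one OMIM gene is enough
  omim <- tibble::tibble(gene = "G1", trait_term = "trait1",
                         source = "OMIM", chrom = NA_character_,
                         pos_mb = NA_integer_)
  ins <- insight_terms(omim, sim)
  expect_true(all(c("trait1", "se1") %in% ins))  # se1 via sim 0.85
  expect_false("trait2" %in% ins)

  # GWAS hits at (1,10), (1,10), (2,5): only 2 distinct loci, below 3
  gwas <- tibble::tibble(
    gene = c("G1", "G2", "G3"), trait_term = "trait2", source = "OTG",
    chrom = c("1", "1", "2"), pos_mb = c(10L, 10L, 5L)
  )
  expect_false("trait2" %in% insight_terms(gwas, sim))
  # a third distinct locus reaches the threshold
  gwas3 <- dplyr::bind_rows(gwas, tibble::tibble(
    gene = "G4", trait_term = "trait2", source = "OTG", chrom = "3",
    pos_mb = 7L))
  expect_true("trait2" %in% insight_terms(gwas3, sim))

  # burden evidence without loci contributes to neither rule by default
  gb <- tibble::tibble(gene = "G9", trait_term = "trait2",
                       source = "Genebass", chrom = NA_character_,
                       pos_mb = NA_integer_)
  expect_length(insight_terms(gb, sim), 0)
  expect_length(insight_terms(omim[0, ], sim), 0)
})

test_that("insight is monotone in the association set", {
  set.seed(14)
  terms <- sprintf("t%02d", 1:10)
  m <- matrix(runif(100, 0, 0.7), 10, 10,
              dimnames = list(terms, terms))
  m <- (m + t(m)) / 2; diag(m) <- 1
  class(m) <- c("sim_matrix", "matrix")
  pool <- tibble::tibble(
    gene = sprintf("G%d", 1:20),
    trait_term = sample(terms, 20, replace = TRUE),
    source = sample(c("OMIM", "IntOGen"), 20, replace = TRUE),
    chrom = NA_character_, pos_mb = NA_integer_
  )
  for (k in c(5, 10, 15)) {
    small <- insight_terms(pool[1:k, ], m)
    bigger <- insight_terms(pool[1:(k + 5), ], m)
    expect_true(all(small %in% bigger))
  }
})

test_that("evidence flagging disqualifies indication-like associations", {
  # topiramate-like: target trait identical to the SE, indication far
  u <- toy_universe()
  fl <- flag_evidence(u)
  topi <- fl[fl$drug_id == "topi" & fl$se_term == "arrhythmia", ]
  expect_true(topi$has_evidence)
  expect_false(topi$excluded_similar_indication)

  # bisoprolol-like: same association, but the drug is indicated for the
  # SE itself -> the association is disqualified and the pair excluded
  biso <- fl[fl$drug_id == "biso" & fl$se_term == "arrhythmia", ]
  expect_false(biso$has_evidence)
  expect_true(biso$excluded_similar_indication)

  # a sub-threshold best similarity yields no evidence (strict >= 0.9)
  terms <- c("se", "trait", "ind")
  sim89 <- toy_sim(terms, pairs = tibble::tibble(a = "trait", b = "se",
                                                 s = 0.89))
  drugs <- tibble::tibble(drug_id = "d", targets = list("G"),
                          indications = list("ind"))
  ses <- tibble::tibble(drug_id = "d", se_term = "se",
                        freq_numeric = NA_real_,
                        freq_word = NA_character_, placebo = NA,
                        severity_rank = NA_integer_)
  assoc <- tibble::tibble(gene = "G", trait_term = "trait",
                          source = "OMIM", chrom = NA_character_,
                          pos_mb = NA_integer_)
  u89 <- flag_evidence(build_universe(drugs, ses, sim89, assoc))
  expect_false(u89$has_evidence[u89$se_term == "se"])
})

test_that("SEs with no genetic association nearby are excluded (insight)", {
  u <- toy_universe()   # 'chills' has no association to anything similar
  fl <- flag_evidence(u)
  expect_false(any(fl$insight[fl$se_term == "chills"]))
  filt <- apply_filters(fl)
  expect_false("chills" %in% filt$se_term)
})

test_that("filters report inclusion-exclusion counts and compose", {
  # 10 pairs; 4 lack insight (2 observed), 2 similar-indication with an
  # overlap of 1 -> 5 retained
  terms <- c(sprintf("s%d", 1:5), "ind", "ind2")
  sim <- toy_sim(terms, pairs = tibble::tibble(
    a = c("s1", "s5"), b = c("ind", "ind"), s = c(1, 0.95)))
  drugs <- tibble::tibble(drug_id = c("d1", "d2"),
                          targets = list("G1", "G2"),
                          indications = list("ind", "ind2"))
  ses <- tibble::tibble(drug_id = c("d1", "d2"),
                        se_term = c("s2", "s3"),
                        freq_numeric = NA_real_,
                        freq_word = NA_character_, placebo = NA,
                        severity_rank = NA_integer_)
  ses <- dplyr::bind_rows(ses, tibble::tibble(
    drug_id = "d1", se_term = c("s1", "s4", "s5"),
    freq_numeric = NA_real_, freq_word = NA_character_, placebo = NA,
    severity_rank = NA_integer_))
  assocs <- tibble::tibble(gene = c("G1", "G2", "G3"),
                           trait_term = c("s2", "s3", "s1"),
                           source = "OMIM", chrom = NA_character_,
                           pos_mb = NA_integer_)
  u <- build_universe(drugs, ses, sim, assocs)
  expect_equal(nrow(u), 10)
  fl <- flag_evidence(u)
  # insight: s1, s2, s3 qualify directly; ind at sim 1 to s1 but ind is
  # not an SE term; s4, s5 lack insight -> 4 pairs (2 per drug)
  filt <- apply_filters(fl)
  rep <- filter_report(filt)
  expect_equal(rep$n_pairs[rep$filter == "no_insight"], 4)
  # similar indication: d1 pairs with s1 (sim 1) and s5 (0.95) -> 2,
  # overlapping the insight removal in s5
  expect_equal(rep$n_pairs[rep$filter == "similar_indication"], 2)
  expect_equal(rep$n_pairs[rep$filter == "either"], 5)
  expect_equal(nrow(filt), 5)

  # identity transform when both filters are disabled
  off <- filter_config(theta_indic = 1.01, require_insight = FALSE)
  ident <- apply_filters(flag_evidence(u, off), off)
  expect_equal(nrow(ident), nrow(u))

  # the two filters commute: same retained set either way round
  only_ins <- apply_filters(
    flag_evidence(u, filter_config(theta_indic = 1.01)),
    filter_config(theta_indic = 1.01))
  then_both <- only_ins[only_ins$best_indic_sim < 0.9, ]
  expect_setequal(paste(filt$drug_id, filt$se_term),
                  paste(then_both$drug_id, then_both$se_term))
})

test_that("filters and sweeps are monotone in their thresholds", {
  ds <- simulate_dataset(small_config(seed = 5))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  sizes <- vapply(c(0.5, 0.7, 0.9, 1.01), function(th) {
    cfg <- filter_config(theta_indic = th, require_insight = FALSE)
    nrow(apply_filters(flag_evidence(u, cfg), cfg))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))  # higher theta_indic removes less

  evid <- vapply(c(0.3, 0.6, 0.9), function(th) {
    cfg <- filter_config(theta_assoc = th)
    sum(flag_evidence(u, cfg)$has_evidence)
  }, numeric(1))
  expect_true(all(diff(evid) <= 0))  # higher theta_assoc flags less
})

test_that("indication genetic support is an any-over-indications flag", {
  terms <- c("ind1", "ind2", "trait")
  sim <- toy_sim(terms, pairs = tibble::tibble(a = "ind2", b = "trait",
                                               s = 0.85))
  drugs <- tibble::tibble(drug_id = c("d1", "d2"),
                          targets = list("G1", "G2"),
                          indications = list(c("ind1", "ind2"), "ind1"))
  support <- tibble::tibble(drug_id = "d1", trait_term = "trait")
  out <- flag_indication_support(drugs, support, sim)
  expect_equal(out$indication_genetic_support, c(TRUE, FALSE))

  # empty support table flags nobody
  none <- flag_indication_support(drugs, support[0, ], sim)
  expect_false(any(none$indication_genetic_support))
})
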