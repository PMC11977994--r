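test_that("primary enrichment counts the observed-by-evidence table", {
  ds <- simulate_dataset(small_config(seed = 3))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  pe <- primary_enrichment(filt)
  expect_equal(pe$n_pairs, nrow(filt))
  expect_equal(pe$n_observed, sum(filt$observed))
  expect_equal(pe$n_evidence, sum(filt$has_evidence))
  expect_equal(pe$n_evidence_observed,
               sum(filt$has_evidence & filt$observed))
  # PPV by direct counting equals the reported field exactly
  expect_equal(pe$ppv, pe$n_evidence_observed / pe$n_evidence)
  g <- glance(pe)
  expect_equal(g$or, pe$fisher$estimate)
  expect_error(enrichment_from_flags(rep(TRUE, 4), rep(TRUE, 4)),
               "empty margin")
})

test_that("association-threshold sweep is monotone with degenerate ends", {
  ds <- simulate_dataset(small_config(seed = 3))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  sw <- sweep_assoc_threshold(filt, thetas = c(0, 0.25, 0.5, 0.75, 0.9))
  expect_true(all(diff(sw$n_evidence_pairs) <= 0))
  # theta = 0: every pair whose drug has any qualifying association
  qs <- best_qualified_sim(filt, 0.9)
  expect_equal(sw$n_evidence_pairs[1], sum(is.finite(qs)))
  # recount oracle at one interior threshold
  expect_equal(sw$n_evidence_pairs[sw$theta == 0.75],
               sum(qs >= 0.75))
  # consistency with the primary analysis at the default threshold
  pe <- primary_enrichment(filt)
  expect_equal(sw$or[sw$theta == 0.9], pe$fisher$estimate)
})

test_that("indication-threshold sweep retains monotonically with theta", {
  ds <- simulate_dataset(small_config(seed = 3))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  fl <- flag_evidence(u)
  sw <- sweep_indic_threshold(fl, thetas = c(0.3, 0.6, 0.9, 1.01))
  expect_true(all(diff(sw$n_retained_pairs) >= 0))
  # a threshold above 1 removes nothing
  ins <- sum(fl$insight)
  expect_equal(sw$n_retained_pairs[sw$theta == 1.01], ins)
  expect_error(sweep_indic_threshold(apply_filters(fl)),
               "unfiltered")
})

test_that("per-source evidence is a subset of the union over sources", {
  ds <- simulate_dataset(small_config(seed = 13))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  tbl <- by_source(filt)
  all_n <- tbl$n_evidence_pairs[tbl$source == "all"]
  for (s in genetic_sources()) {
    expect_lte(tbl$n_evidence_pairs[tbl$source == s], all_n)
  }
  # union equals pairwise OR of the per-source flags
  per <- sapply(genetic_sources(), function(s)
    best_qualified_sim(filt, 0.9, sources = s) >= 0.9)
  expect_equal(sum(rowSums(per) > 0), all_n)
  expect_error(by_source(filt, sources = "NotASource"), "unknown")

  # with associations from a single source, the others have no evidence
  ds1 <- simulate_dataset(small_config(
    seed = 14, source_mix = c(OMIM = 1, OTG = 0, PICCOLO = 0,
                              Genebass = 0, IntOGen = 0)))
  u1 <- build_universe(ds1$drugs, ds1$ses, ds1$sim, ds1$assocs)
  filt1 <- apply_filters(flag_evidence(u1))
  tbl1 <- by_source(filt1)
  expect_true(all(tbl1$n_evidence_pairs[
    tbl1$source %in% c("OTG", "PICCOLO", "Genebass", "IntOGen")] == 0))
  expect_equal(tbl1$n_evidence_pairs[tbl1$source == "OMIM"],
               tbl1$n_evidence_pairs[tbl1$source == "all"])
})

test_that("interaction logit recovers a planted coefficient", {
  # plant logit(P) = -3 + log(2) e + 0.8 x + 0.7 e x directly
  set.seed(99)
  n <- 40000
  e <- runif(n) < 0.1
  x <- runif(n) < 0.3
  p <- plogis(-3 + log(2) * e + 0.8 * x + 0.7 * e * x)
  dat <- tibble::tibble(observed = runif(n) < p, evidence = e, xcov = x)
  u <- structure(dat, class = c("pair_universe", class(tibble::tibble())),
                 filter_report = tibble::tibble())
  names(u)[2] <- "has_evidence"
  out <- logit_interaction(u, xcov)
  est <- out$estimate[out$term == "evidenceTRUE:xTRUE"]
  se <- out$std.error[out$term == "evidenceTRUE:xTRUE"]
  expect_lt(abs(est - 0.7), 2 * se)

  u$xcov <- 1
  expect_error(logit_interaction(u, xcov), "constant")
})

test_that("conditional logit treats word frequencies as ordinal or rank", {
  set.seed(7)
  words <- default_freq_words()
  n <- 6000
  w <- sample(words, n, replace = TRUE)
  rank <- match(w, words)
  ev <- runif(n) < plogis(-2 + 0.4 * rank)
  dat <- tibble::tibble(observed = TRUE, has_evidence = ev,
                        freq_word = w)
  u <- structure(dat, class = c("pair_universe", class(tibble::tibble())),
                 filter_report = tibble::tibble())
  out_rank <- logit_conditional(u, freq_word, treat = "rank")
  est <- out_rank$estimate[out_rank$term == "x"]
  se <- out_rank$std.error[out_rank$term == "x"]
  expect_lt(abs(est - 0.4), 2 * se)
  out_ord <- logit_conditional(u, freq_word, treat = "ordinal")
  # ordered factor yields polynomial terms: linear plus higher orders
  expect_true("x.L" %in% out_ord$term)
  expect_true(any(grepl("x\\.(Q|C|\\^4)", out_ord$term)))
  expect_error(logit_conditional(u, freq_word, treat = "rank",
                                 levels = words[1:2]),
               "outside")
})

test_that("complete separation is refused with a clear message", {
  dat <- tibble::tibble(observed = rep(c(TRUE, FALSE), each = 50),
                        has_evidence = rep(c(TRUE, FALSE), each = 50),
                        z = rnorm(100))
  u <- structure(dat, class = c("pair_universe", class(tibble::tibble())),
                 filter_report = tibble::tibble())
  expect_error(suppressWarnings(logit_interaction(u, z)), "separation")
})

test_that("stratified test: identical strata are homogeneous, distinct ones are not", {
  same <- tibble::tibble(area = c("x", "y", "z"),
                         a = 20, b = 80, c = 30, d = 270)
  res <- cmh_from_tables(same)
  expect_gt(res$heterogeneity_p, 0.99)
  # MH common OR of identical tables equals the single-table value
  expect_equal(res$common_or, (20 * 270) / (80 * 30), tolerance = 1e-9)

  # ORs 1 vs 8 at n = 200 per stratum: heterogeneity detected
  diff2 <- tibble::tibble(area = c("x", "y"),
                          a = c(20, 48), b = c(80, 52),
                          c = c(20, 12), d = c(80, 88))
  res2 <- cmh_from_tables(diff2)
  expect_lt(res2$heterogeneity_p, 0.01)
  expect_lt(res2$cmh_p, 0.05)

  expect_error(cmh_from_tables(same[1, ]), "at least 2")
})

test_that("area stratification counts multi-area SEs in each stratum", {
  onto <- load_ontology(
    tibble::tibble(child = c("X", "X", "A", "B"),
                   parent = c("A", "B", "R", "R")),
    top_level = c("A", "B")
  )
  expect_setequal(se_area_map(onto, "X")$area, c("A", "B"))
  expect_equal(se_area_map(onto, "R")$area, "unclassified")
})

test_that("target-SE screen flags untestable targets and applies BH", {
  ds <- simulate_dataset(small_config(seed = 9))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  tbl <- target_se_enrichment(u)
  # single-drug targets are flagged untestable with no statistics
  single <- tbl[tbl$n_drugs_target == 1, ]
  expect_true(all(single$untestable))
  expect_true(all(is.na(single$or)))
  testable <- tbl[!tbl$untestable, ]
  expect_equal(testable$fdr,
               p.adjust(testable$p, method = "BH"))
  expect_true(all(testable$enriched ==
                    (testable$or >= 2 & testable$fdr < 0.05)))
  # BH step-up by hand at q = 0.05 over m = 4 tests: the largest k with
  # p(k) <= k q / m is k = 2 for {.01,.02,.04,.9} (0.04 > 3(.05)/4) and
  # k = 3 for {.01,.02,.03,.9}
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.9), "BH") < 0.05,
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.9), "BH") < 0.05,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("pleiotropy correlation matches the closed-form on a toy", {
  terms <- sprintf("t%d", 1:6)
  sim <- toy_sim(terms)
  drugs <- tibble::tibble(
    drug_id = sprintf("d%d", 1:5),
    targets = lapply(sprintf("G%d", 1:5), identity),
    indications = list("t6", "t6", "t6", "t6", "t6")
  )
  # observed SE counts per drug: 1,2,3,1,2 ; trait counts: 1,1,2,3,1
  ses <- tibble::tibble(
    drug_id = c("d1", "d2", "d2", "d3", "d3", "d3", "d4", "d5", "d5"),
    se_term = c("t1", "t1", "t2", "t1", "t2", "t3", "t4", "t4", "t5"),
    freq_numeric = NA_real_, freq_word = NA_character_, placebo = NA,
    severity_rank = NA_integer_
  )
  assocs <- tibble::tibble(
    gene = c("G1", "G2", "G3", "G3", "G4", "G4", "G4", "G5"),
    trait_term = c("t1", "t1", "t1", "t2", "t1", "t2", "t3", "t1"),
    source = "OMIM", chrom = NA_character_, pos_mb = NA_integer_
  )
  u <- build_universe(drugs, ses, sim, assocs)
  out <- pleiotropy_check(u)
  x <- c(1, 2, 3, 1, 2); y <- c(1, 1, 2, 3, 1)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$estimate, r_hand)
  expect_equal(out$n_drugs, 5)
})

test_that("severity-specificity regression recovers slopes", {
  flat <- tibble::tibble(se_term = letters[1:4], n_drugs = 7,
                         severity = 1:4)
  out <- suppressWarnings(severity_specificity_regression(flat))
  expect_equal(out$slope, 0)

  # closed-form slope on 4 hand points
  pts <- tibble::tibble(se_term = letters[1:4],
                        n_drugs = c(20, 10, 5, 2), severity = 1:4)
  out2 <- severity_specificity_regression(pts)
  xs <- 1:4; ys <- log(c(20, 10, 5, 2))
  expect_equal(out2$slope,
               sum((xs - mean(xs)) * (ys - mean(ys))) /
                 sum((xs - mean(xs))^2))
  expect_lt(out2$slope, 0)

  expect_error(severity_specificity_regression(flat[1:2, ]),
               "at least 3")
  expect_error(severity_specificity_regression(
    tibble::tibble(se_term = letters[1:3], n_drugs = 2, severity = 2)),
    "constant")
})
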