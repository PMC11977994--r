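test_that("predictive values are simple count ratios with guarded zeros", {
  expect_equal(round(100 * ppv(31, 40)), 78)
  expect_equal(ppv(0, 12), 0)
  expect_warning(expect_true(is.na(ppv(0, 0))), "undefined")
  expect_error(ppv(5, 3), "exceed")
  expect_equal(npv(88, 100), 0.88)
  expect_warning(expect_true(is.na(npv(0, 0))), "undefined")
})

test_that("random evidence assignment gives PPV near the base rate", {
  set.seed(123)
  n <- 20000
  observed <- runif(n) < 0.08
  ppvs <- replicate(40, {
    evidence <- sample(c(rep(TRUE, 600), rep(FALSE, n - 600)))
    sum(observed & evidence) / 600
  })
  expect_lt(abs(mean(ppvs) - mean(observed)), 0.005)
})

test_that("bin base rates aggregate to the global base rate", {
  ds <- simulate_dataset(small_config(seed = 17))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  for (bins in list(specificity_bins(filt), severity_bins(filt))) {
    expect_equal(
      sum(bins$base_rate * bins$n_pairs) / sum(bins$n_pairs),
      sum(bins$n_observed) / sum(bins$n_pairs)
    )
    # PPV recomputed by direct counting equals the stored field
    expect_equal(bins$ppv,
                 bins$n_evidence_observed / bins$n_evidence)
    expect_true(all(bins$base_rate >= 0 & bins$base_rate <= 1))
  }
})

test_that("specificity bins partition observed SEs by drug count", {
  ds <- simulate_dataset(small_config(seed = 17))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  bins <- specificity_bins(filt, breaks = c(1, 2, 10, 100))
  expect_setequal(setdiff(c("1", "2-9", "10-99", "100+"), bins$bin),
                  setdiff(c("1", "2-9", "10-99", "100+"), bins$bin))
  n_drugs <- tapply(filt$observed, filt$se_term, sum)
  # bin populations sum to the number of pairs whose SE is observed
  expect_equal(sum(bins$n_pairs),
               sum(n_drugs[filt$se_term] >= 1))
  # an SE observed for exactly 2 drugs lands in the 2-9 bin
  two <- names(n_drugs)[n_drugs == 2][1]
  if (!is.na(two)) {
    lab <- specificity_labels(c(1, 2, 10, 100))[findInterval(
      2, c(1, 2, 10, 100))]
    expect_equal(lab, "2-9")
  }
  expect_error(specificity_bins(filt, breaks = c(2, 1)), "increasing")
})

test_that("severity bins use empirical quartiles plus an unassigned bin", {
  ds <- simulate_dataset(small_config(seed = 19))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  bins <- severity_bins(filt)
  expect_true("unassigned" %in% bins$bin)
  ses <- se_summary(filt)
  n_unassigned_pairs <- sum(is.na(
    ses$severity[match(filt$se_term, ses$se_term)]))
  expect_equal(bins$n_pairs[bins$bin == "unassigned"],
               n_unassigned_pairs)
  # quartiles of 1..100 split at 25/50/75
  qs <- stats::quantile(1:100, probs = seq(0, 1, 0.25))
  expect_equal(unname(qs[2:4]), c(25.75, 50.5, 75.25))
})

test_that("area bins count multi-area SEs per area and subset on removal", {
  ds <- simulate_dataset(small_config(seed = 23))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  ab <- area_bins(filt, ds$onto)
  # per-area pair counts match a direct per-SE area enumeration
  amap <- se_area_map(ds$onto, attr(filt, "se_terms"))
  per_se_pairs <- table(filt$se_term)
  for (ar in ab$bin) {
    ses_in <- amap$se_term[amap$area == ar]
    expect_equal(ab$n_pairs[ab$bin == ar],
                 sum(per_se_pairs[names(per_se_pairs) %in% ses_in]))
  }
  # removing same-area-indication drugs never increases a bin
  ab2 <- area_bins(filt, ds$onto, remove_same_area_indication = TRUE)
  both <- intersect(ab$bin, ab2$bin)
  expect_true(all(ab2$n_pairs[match(both, ab2$bin)] <=
                    ab$n_pairs[match(both, ab$bin)]))

  # a one-area toy reduces to the global result
  onto1 <- load_ontology(tibble::tibble(child = c("s", "A"),
                                        parent = c("A", "R")),
                         top_level = "A")
  sim1 <- toy_sim(c("s", "ind"))
  drugs1 <- tibble::tibble(drug_id = c("d1", "d2"),
                           targets = list("G1", "G2"),
                           indications = list("ind", "ind"))
  ses1 <- tibble::tibble(drug_id = "d1", se_term = "s",
                         freq_numeric = NA_real_,
                         freq_word = NA_character_, placebo = NA,
                         severity_rank = NA_integer_)
  assocs1 <- tibble::tibble(gene = "G1", trait_term = "s",
                            source = "OMIM", chrom = NA_character_,
                            pos_mb = NA_integer_)
  u1 <- build_universe(drugs1, ses1, sim1, assocs1)
  cfgoff <- filter_config(require_insight = FALSE)
  f1 <- apply_filters(flag_evidence(u1, cfgoff), cfgoff)
  ab1 <- area_bins(f1, onto1, cfg = cfgoff)
  expect_equal(nrow(ab1), 1)
  expect_equal(ab1$n_pairs, nrow(f1))
  expect_equal(ab1$base_rate, overall_base_rate(f1))
})

test_that("modifier bins use the conditional observed-with-attribute table", {
  ds <- simulate_dataset(small_config(seed = 29))
  u <- build_universe(ds$drugs, ds$ses, ds$sim, ds$assocs)
  filt <- apply_filters(flag_evidence(u))
  mb <- modifier_bins(filt, "freq_numeric")
  defined <- filt$observed & !is.na(filt$freq_numeric)
  expect_equal(sum(mb$n_observed), sum(defined))
  expect_equal(mb$frac_evidence,
               mb$n_evidence_observed / mb$n_observed)
  wb <- modifier_bins(filt, "freq_word")
  expect_true(all(wb$bin %in% default_freq_words()))
  pb <- modifier_bins(filt, "placebo")
  expect_true(all(pb$bin %in% c("placebo", "non-placebo")))

  # constant modifier: a single bin, conditional table still defined
  filt2 <- filt
  filt2$placebo[filt2$observed] <- TRUE
  filt2 <- keep_universe_attrs(filt2, filt)
  pb2 <- modifier_bins(filt2, "placebo")
  expect_equal(pb2$bin, "placebo")
})

test_that("planted frequency-evidence coupling is recovered in bins", {
  # build a universe-like object directly with a frequency trend
  set.seed(77)
  n <- 30000
  ev <- runif(n) < 0.1
  obs <- runif(n) < plogis(-2.6 + log(2) * ev)
  freq <- ifelse(obs, plogis(rnorm(n, -2 + 1.5 * ev, 0.8)), NA)
  dat <- tibble::tibble(observed = obs, has_evidence = ev,
                        freq_numeric = freq)
  u <- structure(dat, class = c("pair_universe", class(tibble::tibble())),
                 filter_report = tibble::tibble())
  mb <- modifier_bins(u, "freq_numeric")
  # enrichment of evidence rises across frequency bins
  expect_true(mb$frac_evidence[nrow(mb)] > mb$frac_evidence[1])
})
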