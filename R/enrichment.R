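#' Counts and exact enrichment from observed/evidence flags
#'
#' @param observed,evidence Parallel logical vectors over drug-SE pairs.
#' @param conf_level Confidence level for the Fisher CI.
#' @return An `se_enrichment` object: counts (`n_pairs`, `n_observed`,
#'   `n_evidence`, `n_evidence_observed`), `base_rate`, `ppv`, `npv` and
#'   the `fisher_or` fit.
#' @export
enrichment_from_flags <- function(observed, evidence, conf_level = 0.95) {
  stopifnot(length(observed) == length(evidence))
  a <- sum(observed & evidence)
  b <- sum(observed & !evidence)
  cc <- sum(!observed & evidence)
  d <- sum(!observed & !evidence)
  fit <- fisher_or(a, b, cc, d, conf_level = conf_level)
  structure(
    list(
      n_pairs = a + b + cc + d,
      n_observed = a + b,
      n_evidence = a + cc,
      n_evidence_observed = a,
      base_rate = (a + b) / (a + b + cc + d),
      ppv = ppv(a, a + cc),
      npv = npv(d, b + d),
      fisher = fit
    ),
    class = "se_enrichment"
  )
}

#' @export
print.se_enrichment <- function(x, ...) {
  cat("<se_enrichment> ", x$n_pairs, " pairs; base rate ",
      signif(100 * x$base_rate, 3), "%; assoc/obs ",
      x$n_evidence_observed, "/", x$n_evidence,
      " (PPV ", signif(100 * x$ppv, 3), "%)\n", sep = "")
  print(x$fisher)
  invisible(x)
}

#' @export
tidy.se_enrichment <- function(x, ...) {
  dplyr::bind_cols(
    tidy(x$fisher),
    tibble::tibble(n_evidence_observed = x$n_evidence_observed,
                   n_evidence = x$n_evidence)
  )
}

#' @export
glance.se_enrichment <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, n_observed = x$n_observed,
    n_evidence = x$n_evidence,
    n_evidence_observed = x$n_evidence_observed,
    base_rate = x$base_rate, ppv = x$ppv, npv = x$npv,
    or = x$fisher$estimate, conf.low = x$fisher$ci_low,
    conf.high = x$fisher$ci_high, p.value = x$fisher$p
  )
}

ensure_filtered <- function(universe, cfg, insight_cfg) {
  if (is.null(attr(universe, "filter_report", exact = TRUE))) {
    universe <- apply_filters(universe, cfg, insight_cfg)
  }
  universe
}

#' Primary enrichment of genetic evidence among observed side effects
#'
#' The study's headline metric: after restricting to SEs with genetic
#' insight and removing pairs whose SE resembles an approved indication,
#' cross-tabulates observed against genetic evidence over the retained
#' drug-SE pairs and computes the exact Fisher odds ratio.
#'
#' @param universe A `pair_universe`; filters are applied if it has not
#'   been filtered yet.
#' @param cfg A [filter_config()].
#' @param insight_cfg An [insight_config()].
#' @param conf_level Confidence level for the Fisher CI.
#' @return An `se_enrichment` object.
#' @export
primary_enrichment <- function(universe, cfg = filter_config(),
                               insight_cfg = insight_config(),
                               conf_level = 0.95) {
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  enrichment_from_flags(universe$observed, universe$has_evidence,
                        conf_level = conf_level)
}

new_se_sweep <- function(tbl, which) {
  structure(tibble::as_tibble(tbl), sweep = which,
            class = c("se_sweep", class(tibble::tibble())))
}

#' Sensitivity of the odds ratio to the SE-trait similarity threshold
#'
#' Holds the similar-indication threshold fixed (at `cfg$theta_indic`) and
#' recomputes the evidence flag and Fisher OR for each SE-trait similarity
#' threshold in `thetas` over the filtered universe.
#'
#' @param universe A `pair_universe`.
#' @param thetas Grid of association-similarity thresholds in `[0, 1]`.
#' @inheritParams primary_enrichment
#' @return An `se_sweep` tibble: `theta`, `n_evidence_pairs`,
#'   `n_evidence_observed`, `or`, `conf.low`, `conf.high`, `p.value`.
#' @export
sweep_assoc_threshold <- function(universe,
                                  thetas = seq(0.05, 0.95, by = 0.05),
                                  cfg = filter_config(),
                                  insight_cfg = insight_config()) {
  stopifnot(all(thetas >= 0), all(thetas <= 1.01))
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  qsim <- universe$best_qualified_sim
  rows <- lapply(thetas, function(th) {
    ev <- qsim >= th
    tab <- flag_counts(universe$observed, ev)
    cbind(theta = th, tab)
  })
  counts <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  fits <- fisher_or_batch(counts$a, counts$b, counts$c, counts$d)
  new_se_sweep(
    tibble::tibble(
      theta = counts$theta,
      n_evidence_pairs = counts$a + counts$c,
      n_evidence_observed = counts$a,
      or = fits$or_mle, conf.low = fits$ci_low,
      conf.high = fits$ci_high, p.value = fits$p
    ),
    which = "assoc"
  )
}

flag_counts <- function(observed, evidence) {
  data.frame(a = sum(observed & evidence),
             b = sum(observed & !evidence),
             c = sum(!observed & evidence),
             d = sum(!observed & !evidence))
}

#' Sensitivity of the odds ratio to the similar-indication threshold
#'
#' Holds the SE-trait similarity threshold fixed (at `cfg$theta_assoc`) and
#' varies the threshold at which pairs are excluded for resembling an
#' approved indication; the same threshold disqualifies indication-like
#' associations from the evidence flag. A threshold above 1 removes
#' nothing.
#'
#' @param universe A `pair_universe` (unfiltered; exclusion is recomputed
#'   per grid point, with the insight filter from `cfg` applied
#'   throughout).
#' @param thetas Grid of indication-similarity thresholds.
#' @inheritParams primary_enrichment
#' @return An `se_sweep` tibble with an `n_retained_pairs` column.
#' @export
sweep_indic_threshold <- function(universe,
                                  thetas = seq(0.1, 1, by = 0.1),
                                  cfg = filter_config(),
                                  insight_cfg = insight_config()) {
  if (!is.null(attr(universe, "filter_report", exact = TRUE))) {
    stop("pass the unfiltered universe: the indication filter is ",
         "recomputed per threshold", call. = FALSE)
  }
  if (!"insight" %in% names(universe)) {
    universe <- flag_evidence(universe, cfg, insight_cfg)
  }
  keep_insight <- if (cfg$require_insight) universe$insight else
    rep(TRUE, nrow(universe))
  rows <- lapply(thetas, function(th) {
    qsim <- best_qualified_sim(universe, theta_indic = th)
    keep <- keep_insight & universe$best_indic_sim < th
    ev <- qsim[keep] >= cfg$theta_assoc
    tab <- flag_counts(universe$observed[keep], ev)
    cbind(theta = th, n_retained_pairs = sum(keep), tab)
  })
  counts <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  fits <- fisher_or_batch(counts$a, counts$b, counts$c, counts$d)
  new_se_sweep(
    tibble::tibble(
      theta = counts$theta,
      n_retained_pairs = counts$n_retained_pairs,
      n_evidence_pairs = counts$a + counts$c,
      n_evidence_observed = counts$a,
      or = fits$or_mle, conf.low = fits$ci_low,
      conf.high = fits$ci_high, p.value = fits$p
    ),
    which = "indic"
  )
}

#' Enrichment by source of genetic evidence
#'
#' Recomputes the evidence flag using only the given source's associations
#' (the filtered universe, including the insight restriction, stays as in
#' the main analysis) and reports the per-source Fisher OR. Sources whose
#' table is degenerate (e.g. no evidence pairs) get `NA` estimates.
#'
#' @param universe A `pair_universe`.
#' @param sources Source labels to test (default: all of
#'   [genetic_sources()] plus the all-source union).
#' @inheritParams primary_enrichment
#' @return Tibble with one row per source.
#' @export
by_source <- function(universe, sources = NULL, cfg = filter_config(),
                      insight_cfg = insight_config()) {
  known <- genetic_sources()
  if (is.null(sources)) {
    sources <- c("all", known)
  }
  bad <- setdiff(sources, c("all", known))
  if (length(bad)) {
    stop("unknown source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  rows <- lapply(sources, function(s) {
    qsim <- best_qualified_sim(universe, cfg$theta_indic,
                               sources = if (s == "all") NULL else s)
    ev <- qsim >= cfg$theta_assoc
    cbind(source = s, flag_counts(universe$observed, ev))
  })
  counts <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  fits <- fisher_or_batch(counts$a, counts$b, counts$c, counts$d)
  tibble::tibble(
    source = counts$source,
    n_evidence_pairs = counts$a + counts$c,
    n_evidence_observed = counts$a,
    or = fits$or_mle, conf.low = fits$ci_low, conf.high = fits$ci_high,
    p.value = fits$p
  )
}

glm_tidy <- function(fit) {
  sm <- stats::summary.glm(fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

check_separation <- function(fit, coefs) {
  if (!fit$converged || any(!is.finite(coefs)) ||
      any(abs(coefs) > 15)) {
    stop("complete or quasi-complete separation detected; an ",
         "unpenalized logistic fit is not identifiable here",
         call. = FALSE)
  }
}

fit_logit <- function(formula, data) {
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  check_separation(fit, stats::coef(fit))
  fit
}

#' Binomial logit of SE occurrence on evidence and a covariate
#'
#' Fits `observed ~ has_evidence * covariate` with a binomial logit over
#' the (filtered) universe: main effects and their interaction, reported
#' with Wald standard errors and p-values. Used to test whether a per-pair
#' attribute modulates the evidence enrichment.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param covariate Column of `universe` to interact with the evidence
#'   flag (tidy evaluation). Pairs with a missing covariate are dropped.
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return Tibble of coefficients with attribute `model` (the `glm` fit).
#' @export
logit_interaction <- function(universe, covariate,
                              cfg = filter_config(),
                              insight_cfg = insight_config()) {
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  cov <- dplyr::pull(universe, {{ covariate }})
  dat <- data.frame(observed = universe$observed,
                    evidence = universe$has_evidence,
                    x = cov)
  dat <- dat[!is.na(dat$x), , drop = FALSE]
  if (length(unique(dat$x)) < 2) {
    stop("covariate is constant; the interaction is inestimable",
         call. = FALSE)
  }
  fit <- fit_logit(observed ~ evidence * x, dat)
  out <- glm_tidy(fit)
  attr(out, "model") <- fit
  out
}

#' Binomial logit of genetic evidence on an observed-only attribute
#'
#' For attributes only defined when an SE is observed (numeric frequency,
#' frequency words, placebo basis), fits `has_evidence ~ covariate` over
#' the observed pairs carrying the attribute. A character/factor covariate
#' can be treated as an ordinal factor (polynomial contrasts give linear
#' and higher-order terms) or as its numeric rank within `levels`.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param covariate Column of `universe` (tidy evaluation).
#' @param treat `"numeric"` (use as is), `"ordinal"` (ordered factor) or
#'   `"rank"` (integer rank within `levels`).
#' @param levels Level ordering for `"ordinal"`/`"rank"` treatment
#'   (default [default_freq_words()]).
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return Tibble of coefficients with attribute `model`.
#' @export
logit_conditional <- function(universe, covariate,
                              treat = c("numeric", "ordinal", "rank"),
                              levels = default_freq_words(),
                              cfg = filter_config(),
                              insight_cfg = insight_config()) {
  treat <- match.arg(treat)
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  cov <- dplyr::pull(universe, {{ covariate }})
  keep <- universe$observed & !is.na(cov)
  x <- cov[keep]
  if (treat %in% c("ordinal", "rank")) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) {
      stop("covariate value(s) outside the supplied level ordering: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    x <- if (treat == "ordinal") {
      factor(as.character(x), levels = levels, ordered = TRUE)
    } else {
      match(as.character(x), levels)
    }
  }
  dat <- data.frame(evidence = universe$has_evidence[keep], x = x)
  if (length(unique(dat$x)) < 2) {
    stop("covariate is constant among observed pairs; inestimable",
         call. = FALSE)
  }
  dat$x <- droplevels_if_factor(dat$x)
  fit <- fit_logit(evidence ~ x, dat)
  out <- glm_tidy(fit)
  attr(out, "model") <- fit
  out
}

droplevels_if_factor <- function(x) if (is.factor(x)) droplevels(x) else x

#' Default ordered vocabulary of label frequency words
#'
#' Frequency descriptors as an ordered vocabulary, least to most frequent.
#' The ordering of such words is an empirical matter (survey-based); this
#' default is configurable wherever it is consumed.
#' @return Character vector, least frequent first.
#' @export
default_freq_words <- function() {
  c("very rare", "rare", "uncommon", "common", "very common")
}

#' Stratified enrichment across disease areas
#'
#' Builds one 2x2 (observed by evidence) table per top-level heading of the
#' SE terms (an SE under several headings counts in each; SEs under none
#' form an "unclassified" stratum), then reports the Mantel-Haenszel
#' common odds ratio with its chi-square test of common association, and
#' the Breslow-Day test (with Tarone correction) for heterogeneity of the
#' odds ratios across strata. Strata with an empty margin are dropped with
#' a message.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param onto The `ontology` supplying top-level headings.
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return A `cmh_result`: list with `common_or`, `cmh_p`,
#'   `heterogeneity_p`, `heterogeneity_stat`, `df`, and `strata` (tibble
#'   of per-area cell counts and ORs).
#' @export
cmh_across_areas <- function(universe, onto, cfg = filter_config(),
                             insight_cfg = insight_config()) {
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  area_map <- se_area_map(onto, universe_attr(universe, "se_terms"))
  expanded <- dplyr::inner_join(
    tibble::as_tibble(universe[, c("se_term", "observed",
                                   "has_evidence")]),
    area_map, by = "se_term", relationship = "many-to-many"
  )
  counts <- dplyr::group_by(expanded, .data$area)
  counts <- dplyr::summarise(
    counts,
    a = sum(.data$observed & .data$has_evidence),
    b = sum(.data$observed & !.data$has_evidence),
    c = sum(!.data$observed & .data$has_evidence),
    d = sum(!.data$observed & !.data$has_evidence),
    .groups = "drop"
  )
  cmh_from_tables(counts)
}

# strata: tibble with columns area, a, b, c, d
cmh_from_tables <- function(strata) {
  ok <- with(strata, (a + b) > 0 & (c + d) > 0 & (a + c) > 0 &
               (b + d) > 0)
  if (any(!ok)) {
    message("dropping ", sum(!ok),
            " stratum/strata with an empty margin")
    strata <- strata[ok, , drop = FALSE]
  }
  if (nrow(strata) < 2) {
    stop("need at least 2 non-degenerate strata for a stratified test",
         call. = FALSE)
  }
  arr <- array(
    t(as.matrix(strata[, c("a", "c", "b", "d")])),
    dim = c(2, 2, nrow(strata))
  )
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  bd <- breslow_day(strata, unname(mh$estimate))
  per <- fisher_or_batch(strata$a, strata$b, strata$c, strata$d)
  strata$or <- per$or_mle
  strata$conf.low <- per$ci_low
  strata$conf.high <- per$ci_high
  structure(
    list(common_or = unname(mh$estimate), cmh_p = mh$p.value,
         heterogeneity_stat = bd$stat, heterogeneity_p = bd$p,
         df = bd$df, strata = tibble::as_tibble(strata)),
    class = "cmh_result"
  )
}

# Breslow-Day homogeneity test with Tarone correction, against the
# Mantel-Haenszel common OR. Expected cell a under the common OR solves a
# quadratic in each stratum.
breslow_day <- function(strata, psi, tarone = TRUE) {
  ea <- va <- numeric(nrow(strata))
  for (i in seq_len(nrow(strata))) {
    a <- strata$a[i]; b <- strata$b[i]
    cc <- strata$c[i]; d <- strata$d[i]
    r1 <- a + b; c1 <- a + cc; N <- a + b + cc + d
    if (abs(psi - 1) < 1e-12) {
      E <- r1 * c1 / N
    } else {
      A <- 1 - psi
      B <- N - r1 - c1 + psi * (r1 + c1)
      C <- -psi * r1 * c1
      disc <- sqrt(B^2 - 4 * A * C)
      roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
      lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
      E <- roots[roots >= lo - 1e-9 & roots <= hi + 1e-9][1]
    }
    ea[i] <- E
    va[i] <- 1 / (1 / E + 1 / (r1 - E) + 1 / (c1 - E) +
                    1 / (N - r1 - c1 + E))
  }
  stat <- sum((strata$a - ea)^2 / va)
  if (tarone) stat <- stat - sum(strata$a - ea)^2 / sum(va)
  df <- nrow(strata) - 1
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf(
    "Mantel-Haenszel common OR = %.3g (chi-square P = %.3g) across %d strata\n",
    x$common_or, x$cmh_p, nrow(x$strata)))
  cat(sprintf(
    "Breslow-Day-Tarone heterogeneity: X2 = %.3g, df = %d, P = %.3g\n",
    x$heterogeneity_stat, x$df, x$heterogeneity_p))
  invisible(x)
}

#' @export
glance.cmh_result <- function(x, ...) {
  tibble::tibble(common_or = x$common_or, cmh_p = x$cmh_p,
                 heterogeneity_stat = x$heterogeneity_stat,
                 heterogeneity_p = x$heterogeneity_p, df = x$df,
                 n_strata = nrow(x$strata))
}

# area assignment for SE terms: every designated top-level ancestor, or
# "unclassified" when there is none
se_area_map <- function(onto, se_terms) {
  rows <- lapply(se_terms, function(t) {
    areas <- top_level_headings(onto, t)
    if (!length(areas)) areas <- "unclassified"
    tibble::tibble(se_term = t, area = areas)
  })
  dplyr::bind_rows(rows)
}

#' Per-target, per-SE enrichment screen
#'
#' For each (target gene, SE term) combination, cross-tabulates drugs with
#' and without the target against drugs with and without the SE reported,
#' and applies a Fisher exact test. P-values are Benjamini-Hochberg
#' adjusted over all tested combinations; a combination is called enriched
#' at OR >= `or_min` and FDR < `fdr_max`. Targets carried by a single drug
#' cannot be assessed and are flagged `untestable`.
#'
#' @param universe A `pair_universe` (the screen uses observed status only
#'   and ignores genetic-evidence flags).
#' @param or_min Minimum conditional-MLE OR to call enrichment (default 2).
#' @param fdr_max FDR ceiling to call enrichment (default 0.05).
#' @return Tibble with one row per (target, SE): cell counts, `or`, `p`,
#'   `fdr`, `enriched`, `untestable`.
#' @export
target_se_enrichment <- function(universe, or_min = 2, fdr_max = 0.05) {
  drugs <- universe_attr(universe, "drugs")
  se_terms <- universe_attr(universe, "se_terms")
  if (nrow(drugs) < 2) {
    stop("need at least 2 drugs to assess target enrichment",
         call. = FALSE)
  }
  obs <- matrix(FALSE, nrow(drugs), length(se_terms),
                dimnames = list(drugs$drug_id, se_terms))
  obs_rows <- universe[universe$observed, c("drug_id", "se_term")]
  obs[cbind(obs_rows$drug_id, obs_rows$se_term)] <- TRUE
  target_drugs <- tidyr::unnest(
    dplyr::select(drugs, "drug_id", "targets"), cols = "targets"
  )
  targets <- sort(unique(target_drugs$targets))
  res <- lapply(targets, function(g) {
    in_g <- drugs$drug_id %in%
      target_drugs$drug_id[target_drugs$targets == g]
    n_g <- sum(in_g)
    a <- colSums(obs[in_g, , drop = FALSE])
    cc <- colSums(obs[!in_g, , drop = FALSE])
    tibble::tibble(
      target = g, se_term = se_terms, n_drugs_target = n_g,
      a = a, b = n_g - a, c = cc, d = sum(!in_g) - cc,
      untestable = n_g < 2
    )
  })
  res <- dplyr::bind_rows(res)
  testable <- !res$untestable
  fits <- fisher_or_batch(res$a[testable], res$b[testable],
                          res$c[testable], res$d[testable])
  res$or <- res$p <- NA_real_
  res$or[testable] <- fits$or_mle
  res$p[testable] <- fits$p
  res$fdr <- NA_real_
  res$fdr[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  res$enriched <- !res$untestable & !is.na(res$or) &
    res$or >= or_min & res$fdr < fdr_max
  res
}

#' Pleiotropy check: drug SE count versus target trait count
#'
#' Pearson correlation, over drugs, of the number of observed SEs against
#' the number of distinct traits genetically associated to the drug's
#' targets. A strong correlation would suggest that pleiotropic targets
#' drive the enrichment; the study design expects none.
#'
#' @param universe A `pair_universe`.
#' @return Tibble with `estimate` (Pearson r), `p.value`, `n_drugs`.
#' @export
pleiotropy_check <- function(universe) {
  drugs <- universe_attr(universe, "drugs")
  drug_assoc <- universe_attr(universe, "drug_assoc")
  n_se <- tapply(universe$observed, universe$drug_id, sum)
  n_traits <- tapply(drug_assoc$trait_term, drug_assoc$drug_id,
                     function(x) length(unique(x)))
  x <- as.numeric(n_se[drugs$drug_id])
  y <- as.numeric(n_traits[drugs$drug_id])
  y[is.na(y)] <- 0
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance in per-drug counts",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n_drugs = length(x))
}

#' Per-SE summary of drug specificity and severity
#'
#' @param universe A `pair_universe`.
#' @return Tibble with one row per SE term observed for at least one drug:
#'   `se_term`, `n_drugs` (observed drug count), `severity` (the SE's
#'   severity rank, `NA` when unassigned).
#' @export
se_summary <- function(universe) {
  obs <- universe[universe$observed, , drop = FALSE]
  out <- dplyr::group_by(tibble::as_tibble(obs), .data$se_term)
  dplyr::summarise(out, n_drugs = dplyr::n(),
                   severity = first_defined(.data$severity_rank),
                   .groups = "drop")
}

#' Regression of SE drug specificity on severity
#'
#' Fits `lm(log(n_drugs) ~ severity)` over SEs with a severity rank: do
#' more severe side effects tend to be reported for fewer drugs?
#'
#' @param se_tbl Tibble with columns `n_drugs` (positive) and `severity`,
#'   e.g. from [se_summary()]. Rows with missing severity are dropped.
#' @return Tibble with `slope`, `std.error`, `p.value`, `n`; the `lm` fit
#'   is attached as attribute `model`.
#' @export
severity_specificity_regression <- function(se_tbl) {
  dat <- se_tbl[!is.na(se_tbl$severity), , drop = FALSE]
  if (nrow(dat) < 3) {
    stop("need at least 3 SEs with a severity rank", call. = FALSE)
  }
  if (any(dat$n_drugs < 1)) {
    stop("n_drugs must be >= 1", call. = FALSE)
  }
  if (stats::var(dat$severity) == 0) {
    stop("degenerate design: severity is constant", call. = FALSE)
  }
  fit <- stats::lm(log(n_drugs) ~ severity, data = dat)
  sm <- stats::summary.lm(fit)$coefficients
  out <- tibble::tibble(slope = sm["severity", 1],
                        std.error = sm["severity", 2],
                        p.value = sm["severity", 4],
                        n = nrow(dat))
  attr(out, "model") <- fit
  out
}
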