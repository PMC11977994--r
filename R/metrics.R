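#' Positive predictive value from counts
#'
#' The number of drug-SE pairs where the SE was observed and supported by
#' genetic evidence, divided by the number of pairs where the target had
#' genetic evidence.
#'
#' @param n_evidence_observed Count of evidence-bearing pairs that were
#'   observed.
#' @param n_evidence Count of evidence-bearing pairs.
#' @return Fraction in `[0, 1]`; `NA` with a warning when `n_evidence` is
#'   zero.
#' @export
ppv <- function(n_evidence_observed, n_evidence) {
  if (any(n_evidence_observed > n_evidence, na.rm = TRUE)) {
    stop("n_evidence_observed cannot exceed n_evidence", call. = FALSE)
  }
  out <- ifelse(n_evidence > 0, n_evidence_observed / n_evidence,
                NA_real_)
  if (anyNA(out)) {
    warning("PPV undefined for zero evidence pairs", call. = FALSE)
  }
  out
}

#' Negative predictive value from counts
#'
#' Among pairs without genetic evidence, the fraction not observed.
#'
#' @param n_noevidence_unobserved Count of evidence-free pairs that were
#'   not observed.
#' @param n_noevidence Count of evidence-free pairs.
#' @return Fraction in `[0, 1]`; `NA` with a warning on a zero
#'   denominator.
#' @export
npv <- function(n_noevidence_unobserved, n_noevidence) {
  if (any(n_noevidence_unobserved > n_noevidence, na.rm = TRUE)) {
    stop("numerator cannot exceed denominator", call. = FALSE)
  }
  out <- ifelse(n_noevidence > 0,
                n_noevidence_unobserved / n_noevidence, NA_real_)
  if (anyNA(out)) {
    warning("NPV undefined for zero non-evidence pairs", call. = FALSE)
  }
  out
}

# Summarise a set of universe rows per bin into BinResult columns.
# `bin` is a character/factor vector parallel to the rows.
summarize_bins <- function(observed, evidence, bin,
                           bin_levels = NULL) {
  stopifnot(length(observed) == length(evidence),
            length(bin) == length(observed))
  dat <- tibble::tibble(bin = as.character(bin), observed = observed,
                        evidence = evidence)
  grp <- dplyr::group_by(dat, .data$bin)
  counts <- dplyr::summarise(
    grp,
    n_pairs = dplyr::n(),
    n_observed = sum(.data$observed),
    n_evidence = sum(.data$evidence),
    n_evidence_observed = sum(.data$observed & .data$evidence),
    .groups = "drop"
  )
  if (!is.null(bin_levels)) {
    counts <- counts[order(match(counts$bin, bin_levels)), ,
                     drop = FALSE]
  }
  counts$base_rate <- counts$n_observed / counts$n_pairs
  counts$ppv <- suppressWarnings(
    ppv(counts$n_evidence_observed, counts$n_evidence))
  counts$npv <- suppressWarnings(npv(
    (counts$n_pairs - counts$n_evidence) -
      (counts$n_observed - counts$n_evidence_observed),
    counts$n_pairs - counts$n_evidence
  ))
  fits <- fisher_or_batch(
    counts$n_evidence_observed,
    counts$n_observed - counts$n_evidence_observed,
    counts$n_evidence - counts$n_evidence_observed,
    (counts$n_pairs - counts$n_observed) -
      (counts$n_evidence - counts$n_evidence_observed)
  )
  counts$or <- fits$or_mle
  counts$conf.low <- fits$ci_low
  counts$conf.high <- fits$ci_high
  counts$p.value <- fits$p
  structure(counts, class = c("bin_results", class(tibble::tibble())))
}

#' Enrichment binned by drug specificity of the side effect
#'
#' Each SE term is assigned to a bin by the number of distinct drugs for
#' which it is observed (its drug specificity); SEs observed for no drug
#' are excluded. Within each bin the observed-by-evidence table, base
#' rate, PPV and NPV are computed over the drug-SE pairs whose SE falls in
#' the bin.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param breaks Increasing lower bin edges over the positive integers
#'   (default `c(1, 2, 10, 100)` giving bins 1, 2-9, 10-99, 100+).
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return A `bin_results` tibble, one row per non-empty bin.
#' @export
specificity_bins <- function(universe, breaks = c(1, 2, 10, 100),
                             cfg = filter_config(),
                             insight_cfg = insight_config()) {
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 1) {
    stop("breaks must be strictly increasing lower edges starting at 1",
         call. = FALSE)
  }
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  labels <- specificity_labels(breaks)
  n_drugs <- tapply(universe$observed, universe$se_term, sum)
  se_bin <- labels[findInterval(n_drugs, breaks)]
  names(se_bin) <- names(n_drugs)
  keep <- n_drugs[universe$se_term] >= 1
  summarize_bins(universe$observed[keep],
                 universe$has_evidence[keep],
                 se_bin[universe$se_term[keep]],
                 bin_levels = labels)
}

specificity_labels <- function(breaks) {
  uppers <- c(breaks[-1] - 1, Inf)
  ifelse(is.infinite(uppers), paste0(breaks, "+"),
         ifelse(uppers == breaks, as.character(breaks),
                paste0(breaks, "-", uppers)))
}

#' Enrichment binned by SE severity quartile
#'
#' SE terms carrying a severity rank are cut into quartiles of the
#' empirical rank distribution (quartile 1 = least severe); SEs without a
#' rank form an explicit "unassigned" bin. Per-bin summaries are over the
#' drug-SE pairs whose SE falls in the bin.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param n_bins Number of severity bins (default 4, quartiles).
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return A `bin_results` tibble.
#' @export
severity_bins <- function(universe, n_bins = 4, cfg = filter_config(),
                          insight_cfg = insight_config()) {
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  ses <- se_summary(universe)
  ranked <- ses[!is.na(ses$severity), , drop = FALSE]
  if (length(unique(ranked$severity)) < n_bins) {
    stop("need at least ", n_bins,
         " distinct severity values among ranked SEs", call. = FALSE)
  }
  qs <- stats::quantile(ranked$severity,
                        probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  labels <- paste0("Q", seq_len(n_bins))
  bin_of <- stats::setNames(
    labels[cut(ranked$severity, qs, labels = FALSE,
               include.lowest = TRUE)],
    ranked$se_term
  )
  se_bin <- bin_of[universe$se_term]
  se_bin[is.na(se_bin)] <- "unassigned"
  summarize_bins(universe$observed, universe$has_evidence, se_bin,
                 bin_levels = c(labels, "unassigned"))
}

#' Enrichment binned by disease area (top-level heading)
#'
#' Pairs are keyed by the SE term's top-level headings in the ontology; an
#' SE under several headings contributes to each area, and SEs under none
#' form an "unclassified" bin. With `remove_same_area_indication = TRUE`,
#' within each area any drug with any approved indication mapping to that
#' area is removed before summarising, controlling for drugs prescribed in
#' the same organ system as the SE.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param onto The `ontology` supplying top-level headings.
#' @param remove_same_area_indication Drop drugs indicated in the SE's
#'   area (default `FALSE`).
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return A `bin_results` tibble keyed by area.
#' @export
area_bins <- function(universe, onto,
                      remove_same_area_indication = FALSE,
                      cfg = filter_config(),
                      insight_cfg = insight_config()) {
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  area_map <- se_area_map(onto, universe_attr(universe, "se_terms"))
  expanded <- dplyr::inner_join(
    tibble::as_tibble(universe[, c("drug_id", "se_term", "observed",
                                   "has_evidence")]),
    area_map, by = "se_term", relationship = "many-to-many"
  )
  if (remove_same_area_indication) {
    drugs <- universe_attr(universe, "drugs")
    drug_areas <- lapply(drugs$indications, function(inds) {
      unique(unlist(lapply(inds, top_level_headings, onto = onto)))
    })
    names(drug_areas) <- drugs$drug_id
    same_area <- mapply(function(d, a) a %in% drug_areas[[d]],
                        expanded$drug_id, expanded$area)
    expanded <- expanded[!same_area, , drop = FALSE]
  }
  summarize_bins(expanded$observed, expanded$has_evidence,
                 expanded$area,
                 bin_levels = sort(unique(expanded$area)))
}

#' Enrichment by side-effect modifier, conditional form
#'
#' For attributes defined only when an SE is observed (numeric frequency,
#' frequency word, placebo basis), each bin's 2x2 table contrasts pairs
#' observed *with the stated attribute value* against all other pairs in
#' the universe, crossed with genetic evidence. The reported OR is thus
#' the enrichment of genetic evidence conditioned on an SE being observed
#' with the given modifier.
#'
#' @param universe A flagged/filtered `pair_universe`.
#' @param modifier One of `"freq_numeric"`, `"freq_word"`, `"placebo"`.
#' @param breaks For `freq_numeric`: increasing cut points in `[0, 1]`
#'   (default `c(0, 0.01, 0.1, 1)` giving bins <=1%, 1-10%, >10%).
#' @param levels For `freq_word`: the ordered vocabulary (default
#'   [default_freq_words()]).
#' @param cfg,insight_cfg Filter configuration, applied if needed.
#' @return A `bin_results` tibble; here `n_pairs`/`n_observed` count the
#'   observed-with-attribute pairs in the bin, while the OR columns use
#'   the conditional 2x2 against the rest of the universe. Empty bins are
#'   skipped with a message.
#' @export
modifier_bins <- function(universe,
                          modifier = c("freq_numeric", "freq_word",
                                       "placebo"),
                          breaks = c(0, 0.01, 0.1, 1),
                          levels = default_freq_words(),
                          cfg = filter_config(),
                          insight_cfg = insight_config()) {
  modifier <- match.arg(modifier)
  universe <- ensure_filtered(universe, cfg, insight_cfg)
  x <- universe[[modifier]]
  defined <- universe$observed & !is.na(x)
  bin <- rep(NA_character_, nrow(universe))
  if (modifier == "freq_numeric") {
    stopifnot(!is.unsorted(breaks, strictly = TRUE))
    labs <- paste0("(", utils::head(breaks, -1) * 100, "%,",
                   utils::tail(breaks, -1) * 100, "%]")
    bin[defined] <- labs[cut(x[defined], breaks, labels = FALSE,
                             include.lowest = TRUE)]
    bin_levels <- labs
  } else if (modifier == "freq_word") {
    bin[defined] <- as.character(x[defined])
    bin_levels <- levels
  } else {
    bin[defined] <- ifelse(x[defined], "placebo", "non-placebo")
    bin_levels <- c("non-placebo", "placebo")
  }
  present <- intersect(bin_levels, unique(bin[defined]))
  skipped <- setdiff(bin_levels, present)
  if (length(skipped)) {
    message("skipping empty modifier bin(s): ",
            paste(skipped, collapse = ", "))
  }
  ev <- universe$has_evidence
  rows <- lapply(present, function(v) {
    with_attr <- defined & bin == v
    tibble::tibble(
      bin = v,
      n_observed = sum(with_attr),
      n_evidence_observed = sum(with_attr & ev),
      a = sum(with_attr & ev), b = sum(with_attr & !ev),
      c = sum(!with_attr & ev), d = sum(!with_attr & !ev)
    )
  })
  counts <- dplyr::bind_rows(rows)
  fits <- fisher_or_batch(counts$a, counts$b, counts$c, counts$d)
  # Fig-2-style assoc/obs fraction: among pairs observed with the
  # attribute, the share carrying genetic evidence
  counts$frac_evidence <- counts$n_evidence_observed / counts$n_observed
  counts$or <- fits$or_mle
  counts$conf.low <- fits$ci_low
  counts$conf.high <- fits$ci_high
  counts$p.value <- fits$p
  counts <- counts[, setdiff(names(counts), c("a", "b", "c", "d"))]
  structure(counts, class = c("bin_results", class(tibble::tibble())))
}
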