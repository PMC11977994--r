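#' Simulate a dataset and write it to disk
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory for the TSVs.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(cfg = generator_config(), out_dir) {
  ds <- simulate_dataset(cfg)
  paths <- write_dataset(ds, out_dir)
  message("wrote synthetic dataset (", nrow(ds$drugs), " drugs, ",
          length(unique(ds$ses$se_term)), " SE terms, ",
          nrow(ds$assocs), " associations) to ", out_dir)
  invisible(paths)
}

#' Compute and write a similarity matrix from ontology and corpus TSVs
#'
#' @param ontology_tsv Path to a `child<TAB>parent` edge TSV.
#' @param corpus_tsv Path to a `term<TAB>count` TSV.
#' @param out Output path for the three-column similarity TSV.
#' @param top_level Top-level heading IDs (optional here; headings do not
#'   affect similarity).
#' @param smooth Laplace smoothing for information content.
#' @return The `sim_matrix`, invisibly.
#' @export
run_similarity <- function(ontology_tsv, corpus_tsv, out,
                           top_level = character(), smooth = TRUE) {
  onto <- load_ontology(read_ontology_edges(ontology_tsv),
                        top_level = top_level)
  corpus <- read_corpus(corpus_tsv)
  sim <- similarity_matrix(onto, corpus, smooth = smooth)
  write_sim_matrix(sim, out)
  message("similarity matrix over ", nrow(sim), " terms written to ",
          out, " (Resnik multiplier ",
          signif(attr(sim, "multiplier"), 4), ")")
  invisible(sim)
}

#' Run the full enrichment analysis and write result tables
#'
#' Loads the three analytic tables and the similarity matrix, builds the
#' pair universe, applies the genetic-insight and similar-indication
#' filters, and writes: the primary enrichment, both threshold sweeps, the
#' per-source breakdown, specificity/severity/area/modifier bins, the
#' per-target-SE screen, and a run summary with the filter removal
#' counts. Every number in the summary is recomputable from the emitted
#' tables.
#'
#' @param drug_tsv,se_tsv,assoc_tsv,sim_tsv Input paths (see the
#'   `read_*` functions for schemas). `sim_tsv` may also be a
#'   `sim_matrix` object.
#' @param out_dir Output directory.
#' @param cfg A [filter_config()].
#' @param insight_cfg An [insight_config()].
#' @param ontology_tsv,top_level_tsv Optional ontology edge/top-level
#'   TSVs; when supplied, area-binned results and the stratified
#'   heterogeneity test are included.
#' @param assoc_grid,indic_grid Threshold grids for the two sweeps.
#' @return List of all result objects, invisibly.
#' @export
run_enrichment <- function(drug_tsv, se_tsv, assoc_tsv, sim_tsv,
                           out_dir,
                           cfg = filter_config(),
                           insight_cfg = insight_config(),
                           ontology_tsv = NULL, top_level_tsv = NULL,
                           assoc_grid = seq(0.05, 0.95, by = 0.05),
                           indic_grid = seq(0.1, 1, by = 0.1)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- load_tables(drug_tsv, se_tsv, assoc_tsv)
  sim <- if (inherits(sim_tsv, "sim_matrix")) sim_tsv else
    read_sim_matrix(sim_tsv)
  universe <- build_universe(tabs$drugs, tabs$ses, sim, tabs$assocs)
  flagged <- flag_evidence(universe, cfg, insight_cfg)
  filtered <- apply_filters(flagged, cfg, insight_cfg)

  primary <- primary_enrichment(filtered)
  sweep_a <- sweep_assoc_threshold(filtered, assoc_grid, cfg,
                                   insight_cfg)
  sweep_i <- sweep_indic_threshold(flagged, indic_grid, cfg,
                                   insight_cfg)
  sources <- by_source(filtered, cfg = cfg, insight_cfg = insight_cfg)
  spec_bins <- specificity_bins(filtered)
  sev_bins <- tryCatch(severity_bins(filtered), error = function(e) {
    message("severity bins skipped: ", conditionMessage(e)); NULL
  })
  target_tbl <- target_se_enrichment(filtered)

  onto <- NULL
  area_tbl <- NULL
  cmh <- NULL
  if (!is.null(ontology_tsv)) {
    top_level <- if (!is.null(top_level_tsv)) {
      readr::read_tsv(top_level_tsv,
                      col_types = readr::cols(term = "c"),
                      progress = FALSE)$term
    } else character()
    onto <- load_ontology(read_ontology_edges(ontology_tsv),
                          top_level = top_level)
    area_tbl <- area_bins(filtered, onto)
    cmh <- tryCatch(cmh_across_areas(filtered, onto),
                    error = function(e) {
                      message("stratified test skipped: ",
                              conditionMessage(e))
                      NULL
                    })
  }

  out <- function(name) file.path(out_dir, name)
  readr::write_tsv(glance(primary), out("primary_enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(sweep_a, out("sweep_assoc_threshold.tsv"),
                   progress = FALSE)
  readr::write_tsv(sweep_i, out("sweep_indic_threshold.tsv"),
                   progress = FALSE)
  readr::write_tsv(sources, out("by_source.tsv"), progress = FALSE)
  readr::write_tsv(spec_bins, out("specificity_bins.tsv"),
                   progress = FALSE)
  if (!is.null(sev_bins)) {
    readr::write_tsv(sev_bins, out("severity_bins.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(target_tbl, out("target_se_enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(filter_report(filtered), out("filter_report.tsv"),
                   progress = FALSE)
  if (!is.null(area_tbl)) {
    readr::write_tsv(area_tbl, out("area_bins.tsv"), progress = FALSE)
  }
  if (!is.null(cmh)) {
    readr::write_tsv(glance(cmh), out("cmh_areas.tsv"),
                     progress = FALSE)
  }
  summary_tbl <- tibble::tibble(
    quantity = c("n_pairs_universe", "n_observed_universe",
                 "base_rate_percent", "n_pairs_retained",
                 "n_observed_retained", "primary_or", "primary_ci_low",
                 "primary_ci_high", "primary_p", "ppv_percent",
                 "npv_percent"),
    value = c(nrow(universe), sum(universe$observed),
              100 * overall_base_rate(universe), primary$n_pairs,
              primary$n_observed, primary$fisher$estimate,
              primary$fisher$ci_low, primary$fisher$ci_high,
              primary$fisher$p, 100 * primary$ppv, 100 * primary$npv)
  )
  readr::write_tsv(summary_tbl, out("run_summary.tsv"),
                   progress = FALSE)
  message("primary OR ", signif(primary$fisher$estimate, 3),
          " (95% CI ", signif(primary$fisher$ci_low, 3), "-",
          signif(primary$fisher$ci_high, 3), "), base rate ",
          signif(100 * overall_base_rate(universe), 3), "%")
  invisible(list(universe = universe, flagged = flagged,
                 filtered = filtered, primary = primary,
                 sweep_assoc = sweep_a, sweep_indic = sweep_i,
                 by_source = sources, specificity_bins = spec_bins,
                 severity_bins = sev_bins, area_bins = area_tbl,
                 cmh = cmh, target_se = target_tbl,
                 summary = summary_tbl))
}
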