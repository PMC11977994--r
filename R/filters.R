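#' Configuration for the genetic-insight filter
#'
#' A trait counts as genetically studied ("has insight") if it, or another
#' trait with similarity at or above `sim_threshold`, is associated to at
#' least `min_mendelian_genes` distinct Mendelian/somatic-driver genes
#' (sources in `mendelian_sources`), or to at least `min_gwas_loci` GWAS
#' hits at distinct loci (chromosome plus megabase bin) from
#' `gwas_sources`. Side effects without insight are excluded from
#' enrichment, controlling for the confounder that genetically studied
#' traits might simply be reported more often.
#'
#' Gene-burden evidence (Genebass) carries no locus and by default counts
#' toward neither rule; add it to a source set to change that.
#'
#' @param sim_threshold Similarity at which insight propagates between
#'   traits (default 0.8).
#' @param min_mendelian_genes Minimum distinct Mendelian/somatic genes
#'   (default 1).
#' @param min_gwas_loci Minimum distinct GWAS loci (default 3).
#' @param mendelian_sources,gwas_sources Source labels counting toward each
#'   rule.
#' @return An `insight_config` list.
#' @export
insight_config <- function(sim_threshold = 0.8,
                           min_mendelian_genes = 1L,
                           min_gwas_loci = 3L,
                           mendelian_sources = c("OMIM", "IntOGen"),
                           gwas_sources = c("OTG", "PICCOLO")) {
  stopifnot(sim_threshold >= 0, sim_threshold <= 1,
            min_mendelian_genes >= 1, min_gwas_loci >= 1)
  structure(
    list(sim_threshold = sim_threshold,
         min_mendelian_genes = as.integer(min_mendelian_genes),
         min_gwas_loci = as.integer(min_gwas_loci),
         mendelian_sources = mendelian_sources,
         gwas_sources = gwas_sources),
    class = "insight_config"
  )
}

#' Configuration for evidence flagging and confounder filters
#'
#' @param theta_assoc Minimum SE-trait similarity for a genetic association
#'   to count as evidence for the SE (default 0.9, inclusive).
#' @param theta_indic Similarity at or above which (a) an association whose
#'   trait resembles one of the drug's approved indications is disqualified
#'   as evidence, and (b) a drug-SE pair whose SE resembles an approved
#'   indication is excluded from analysis (default 0.9, inclusive).
#' @param require_insight Restrict the analysis to SEs with genetic insight
#'   (default `TRUE`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(theta_assoc = 0.9, theta_indic = 0.9,
                          require_insight = TRUE) {
  stopifnot(theta_assoc >= 0, theta_indic >= 0)
  structure(
    list(theta_assoc = theta_assoc, theta_indic = theta_indic,
         require_insight = isTRUE(require_insight)),
    class = "filter_config"
  )
}

#' Terms with genetic insight
#'
#' Determines which trait terms qualify directly (enough Mendelian genes or
#' GWAS loci) and then propagates insight to every term whose similarity to
#' a qualifying trait meets the configured threshold (a term is similar to
#' itself at 1).
#'
#' @param assocs Genetic-association tibble (`gene`, `trait_term`,
#'   `source`, `chrom`, `pos_mb`).
#' @param sim A `sim_matrix` covering the candidate terms and all trait
#'   terms.
#' @param cfg An [insight_config()].
#' @param terms Candidate terms to classify (default: all terms in `sim`).
#' @return Character vector: the subset of `terms` with genetic insight.
#' @export
insight_terms <- function(assocs, sim, cfg = insight_config(),
                          terms = rownames(sim)) {
  assocs <- validate_assocs(assocs)
  if (nrow(assocs) == 0) return(character(0))
  mend <- dplyr::filter(assocs, .data$source %in% cfg$mendelian_sources)
  mend_n <- dplyr::count(dplyr::distinct(mend, .data$trait_term,
                                         .data$gene),
                         .data$trait_term)
  gwas <- dplyr::filter(assocs, .data$source %in% cfg$gwas_sources)
  if (nrow(gwas) && (anyNA(gwas$chrom) || anyNA(gwas$pos_mb))) {
    stop("GWAS-type associations must carry a locus (chrom, pos_mb) for ",
         "insight counting", call. = FALSE)
  }
  gwas_n <- dplyr::count(dplyr::distinct(gwas, .data$trait_term,
                                         .data$chrom, .data$pos_mb),
                         .data$trait_term)
  qualifying <- union(
    mend_n$trait_term[mend_n$n >= cfg$min_mendelian_genes],
    gwas_n$trait_term[gwas_n$n >= cfg$min_gwas_loci]
  )
  if (!length(qualifying)) return(character(0))
  qualifying <- intersect(qualifying, rownames(sim))
  best <- col_max(sim[qualifying, terms, drop = FALSE])
  terms[best >= cfg$sim_threshold]
}

# Per-pair best qualified association similarity: the drug-level maximum of
# sim(trait, SE) over associations whose trait does NOT resemble one of the
# drug's approved indications (trait-indication similarity < theta_indic).
# Optionally restricted to a subset of evidence sources.
best_qualified_sim <- function(universe, theta_indic, sources = NULL) {
  drug_assoc <- universe_attr(universe, "drug_assoc")
  sim <- universe_attr(universe, "sim")
  se_terms <- universe_attr(universe, "se_terms")
  if (!is.null(sources)) {
    drug_assoc <- drug_assoc[drug_assoc$source %in% sources, ,
                             drop = FALSE]
  }
  drug_assoc <- drug_assoc[drug_assoc$trait_indic_sim < theta_indic, ,
                           drop = FALSE]
  # -Inf marks pairs whose drug has no qualifying association at all, so
  # they never count as evidence, whatever the threshold
  out <- rep(-Inf, nrow(universe))
  if (!nrow(drug_assoc)) return(out)
  traits_by_drug <- split(drug_assoc$trait_term, drug_assoc$drug_id)
  for (d in names(traits_by_drug)) {
    rows <- which(universe$drug_id == d)
    if (!length(rows)) next
    traits <- unique(traits_by_drug[[d]])
    best <- col_max(sim[traits, se_terms, drop = FALSE])
    out[rows] <- best[match(universe$se_term[rows], se_terms)]
  }
  out
}

#' Flag genetic evidence, insight and indication exclusion on a universe
#'
#' Adds three logical columns to the pair universe. `has_evidence` marks
#' pairs where some association of the drug's targets has similarity at or
#' above `theta_assoc` to the SE, after disqualifying (per association,
#' before taking the drug-level maximum) associations whose trait also has
#' similarity at or above `theta_indic` to one of the drug's approved
#' indications. `excluded_similar_indication` marks pairs whose SE
#' resembles an approved indication of the drug (`best_indic_sim >=
#' theta_indic`). `insight` marks pairs whose SE term has genetic insight
#' (see [insight_terms()]).
#'
#' @param universe A `pair_universe` from [build_universe()].
#' @param cfg A [filter_config()].
#' @param insight_cfg An [insight_config()].
#' @return The universe with columns `has_evidence`,
#'   `excluded_similar_indication`, `insight` added/updated.
#' @export
flag_evidence <- function(universe, cfg = filter_config(),
                          insight_cfg = insight_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  qsim <- best_qualified_sim(universe, cfg$theta_indic)
  out <- universe
  out$best_qualified_sim <- qsim
  out$has_evidence <- qsim >= cfg$theta_assoc
  out$excluded_similar_indication <-
    universe$best_indic_sim >= cfg$theta_indic
  ins <- insight_terms(universe_attr(universe, "assocs"),
                       universe_attr(universe, "sim"),
                       insight_cfg,
                       terms = universe_attr(universe, "se_terms"))
  out$insight <- out$se_term %in% ins
  keep_universe_attrs(out, universe,
                      extra = list(filter_config = cfg,
                                   insight_config = insight_cfg))
}

#' Apply the confounder filters to a flagged universe
#'
#' Retains pairs whose SE has genetic insight (unless
#' `cfg$require_insight` is `FALSE`) and whose SE does not resemble one of
#' the drug's approved indications. Attaches a `filter_report` attribute
#' with removal counts by each filter separately and jointly, over all
#' pairs and over observed pairs.
#'
#' @param universe A `pair_universe`; flagged with [flag_evidence()] first
#'   if the flag columns are absent.
#' @inheritParams flag_evidence
#' @return The retained `pair_universe` subset.
#' @export
apply_filters <- function(universe, cfg = filter_config(),
                          insight_cfg = insight_config()) {
  if (!all(c("has_evidence", "insight",
             "excluded_similar_indication") %in% names(universe))) {
    universe <- flag_evidence(universe, cfg, insight_cfg)
  }
  no_insight <- cfg$require_insight & !universe$insight
  similar_ind <- universe$excluded_similar_indication
  keep <- !no_insight & !similar_ind
  report <- tibble::tibble(
    filter = c("no_insight", "similar_indication", "either", "retained"),
    n_pairs = c(sum(no_insight), sum(similar_ind), sum(!keep), sum(keep)),
    n_observed = c(sum(no_insight & universe$observed),
                   sum(similar_ind & universe$observed),
                   sum(!keep & universe$observed),
                   sum(keep & universe$observed))
  )
  if (!any(keep)) {
    stop("all pairs removed by filters; review theta_indic and the ",
         "insight configuration", call. = FALSE)
  }
  out <- universe[keep, , drop = FALSE]
  keep_universe_attrs(out, universe,
                      extra = list(filter_report = report))
}

#' Filter removal report
#'
#' @param universe A filtered `pair_universe` from [apply_filters()].
#' @return Tibble of removal counts (pairs and observed pairs) per filter.
#' @export
filter_report <- function(universe) {
  universe_attr(universe, "filter_report")
}

#' Flag drugs whose approved indication has genetic support
#'
#' A drug is genetically supported when any of its approved indications has
#' similarity at or above `threshold` to a trait with genetic support for
#' that drug's target.
#'
#' @param drugs Drug tibble (list-columns `targets`, `indications`).
#' @param support_table Tibble of genetically supported traits per drug:
#'   columns `drug_id`, `trait_term`.
#' @param sim A `sim_matrix` covering indication and trait terms.
#' @param threshold Indication-trait similarity threshold (default 0.8,
#'   inclusive).
#' @return Tibble with columns `drug_id`, `indication_genetic_support`.
#' @export
flag_indication_support <- function(drugs, support_table, sim,
                                    threshold = 0.8) {
  drugs <- validate_drugs(drugs)
  stopifnot(all(c("drug_id", "trait_term") %in% names(support_table)))
  supported_by_drug <- split(support_table$trait_term,
                             support_table$drug_id)
  flag <- vapply(seq_len(nrow(drugs)), function(i) {
    traits <- unique(supported_by_drug[[drugs$drug_id[i]]])
    if (is.null(traits) || !length(traits)) return(FALSE)
    inds <- drugs$indications[[i]]
    max(sim[traits, inds]) >= threshold
  }, logical(1))
  tibble::tibble(drug_id = drugs$drug_id,
                 indication_genetic_support = flag)
}
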