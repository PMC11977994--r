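#' Read the drug table
#'
#' Expects a TSV with header `drug_id`, `targets`, `indications`; the latter
#' two are `;`-separated lists. Drugs lacking a target or an indication are
#' dropped (the analysis requires at least one human target and one approved
#' indication per drug), with a message reporting how many were removed.
#'
#' @param path Path to the drug TSV.
#' @return Tibble with columns `drug_id` and list-columns `targets`,
#'   `indications`.
#' @export
read_drug_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("drug_id", "targets", "indications")
  if (!all(need %in% names(raw))) {
    stop("drug TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_drugs(tibble::tibble(
    drug_id = raw$drug_id,
    targets = split_list_col(raw$targets),
    indications = split_list_col(raw$indications)
  ))
}

split_list_col <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) unique(v[nzchar(v)]))
}

validate_drugs <- function(drugs) {
  stopifnot(is.data.frame(drugs),
            all(c("drug_id", "targets", "indications") %in% names(drugs)))
  dup <- duplicated(drugs$drug_id)
  if (any(dup)) {
    message("dropped ", sum(dup), " duplicate drug record(s)")
    drugs <- drugs[!dup, , drop = FALSE]
  }
  no_target <- lengths(drugs$targets) == 0
  no_indic <- lengths(drugs$indications) == 0
  bad <- no_target | no_indic
  if (any(bad)) {
    message("dropped ", sum(no_target), " drug(s) lacking a target and ",
            sum(no_indic), " lacking an indication (", sum(bad),
            " removed)")
    drugs <- drugs[!bad, , drop = FALSE]
  }
  tibble::as_tibble(drugs)
}

#' Read the drug side-effect table
#'
#' Expects a TSV with header `drug_id`, `se_term`, `freq_numeric`,
#' `freq_word`, `placebo`, `severity_rank`; empty fields denote missing
#' modifiers. Duplicate (drug, SE) rows collapse to a single observed pair,
#' keeping the first non-missing value of each modifier.
#'
#' @param path Path to the side-effect TSV.
#' @return Tibble of observed drug-SE records.
#' @export
read_se_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      drug_id = "c", se_term = "c", freq_numeric = "d",
      freq_word = "c", placebo = "l", severity_rank = "i"
    ),
    progress = FALSE
  )
  validate_ses(raw)
}

validate_ses <- function(ses) {
  need <- c("drug_id", "se_term")
  if (!all(need %in% names(ses))) {
    stop("side-effect table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (col in c("freq_numeric", "freq_word", "placebo", "severity_rank")) {
    if (!col %in% names(ses)) ses[[col]] <- NA
  }
  if (any(ses$freq_numeric < 0 | ses$freq_numeric > 1, na.rm = TRUE)) {
    stop("freq_numeric must lie in [0, 1]", call. = FALSE)
  }
  if (any(ses$severity_rank < 1, na.rm = TRUE)) {
    stop("severity_rank must be >= 1", call. = FALSE)
  }
  if (nrow(ses) == 0) {
    warning("side-effect table is empty; downstream universe will have ",
            "no observed pairs", call. = FALSE)
  }
  ses <- dplyr::group_by(tibble::as_tibble(ses), .data$drug_id,
                         .data$se_term)
  ses <- dplyr::summarise(
    ses,
    freq_numeric = first_defined(.data$freq_numeric),
    freq_word = first_defined(.data$freq_word),
    placebo = first_defined(.data$placebo),
    severity_rank = first_defined(.data$severity_rank),
    .groups = "drop"
  )
  ses
}

first_defined <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[[1]] else x[NA_integer_]
}

#' Known genetic-evidence source labels
#' @export
genetic_sources <- function() {
  c("OMIM", "OTG", "PICCOLO", "Genebass", "IntOGen")
}

#' Read the gene-trait genetic association table
#'
#' Expects a TSV with header `gene`, `trait_term`, `source`, `chrom`,
#' `pos_mb`. `source` must come from [genetic_sources()]. `chrom`/`pos_mb`
#' give the locus for GWAS-type sources, with position already binned to
#' the nearest megabase (see [mb_bin()]); they may be empty for
#' Mendelian/burden sources.
#'
#' @param path Path to the association TSV.
#' @return Tibble of associations.
#' @export
read_assoc_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(gene = "c", trait_term = "c", source = "c",
                            chrom = "c", pos_mb = "i"),
    progress = FALSE
  )
  validate_assocs(raw)
}

validate_assocs <- function(assocs) {
  need <- c("gene", "trait_term", "source")
  if (!all(need %in% names(assocs))) {
    stop("association table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"chrom" %in% names(assocs)) assocs$chrom <- NA_character_
  if (!"pos_mb" %in% names(assocs)) assocs$pos_mb <- NA_integer_
  bad <- setdiff(unique(assocs$source), genetic_sources())
  if (length(bad)) {
    stop("unknown genetic-evidence source label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(assocs)
}

#' Bin a base-pair position to the nearest megabase
#'
#' GWAS hits are deduplicated by locus, proxied by chromosome and position
#' rounded to the nearest megabase.
#'
#' @param pos_bp Numeric base-pair positions.
#' @return Integer megabase bins.
#' @export
mb_bin <- function(pos_bp) as.integer(round(pos_bp / 1e6))

#' Load the three analytic tables
#'
#' @param drug_tsv,se_tsv,assoc_tsv File paths (see [read_drug_table()],
#'   [read_se_table()], [read_assoc_table()] for schemas).
#' @return Named list with elements `drugs`, `ses`, `assocs`.
#' @export
load_tables <- function(drug_tsv, se_tsv, assoc_tsv) {
  list(
    drugs = read_drug_table(drug_tsv),
    ses = read_se_table(se_tsv),
    assocs = read_assoc_table(assoc_tsv)
  )
}

#' Build the universe of drug by side-effect pairs
#'
#' The unit of analysis is the cross product of retained drugs and the
#' distinct side-effect terms appearing in the SE table. A pair is
#' *observed* when the SE occurs on that drug's label. Each pair carries
#' the best (maximum) similarity between the SE and any trait genetically
#' associated to any of the drug's targets (`best_assoc_sim`), and between
#' the SE and any of the drug's approved indications (`best_indic_sim`);
#' both are 0 when no candidate exists.
#'
#' @param drugs Drug tibble (list-columns `targets`, `indications`), as
#'   from [read_drug_table()] or [validate_drugs()].
#' @param ses Observed side-effect tibble, as from [read_se_table()].
#' @param sim A `sim_matrix` covering every SE, indication and trait term.
#' @param assocs Genetic-association tibble, as from [read_assoc_table()].
#' @return A `pair_universe`: a tibble with one row per (drug, SE term) and
#'   columns `drug_id`, `se_term`, `observed`, `best_assoc_sim`,
#'   `best_indic_sim`, plus the observed pairs' modifier columns. Carries
#'   the inputs as attributes for downstream flagging and sweeps.
#' @export
build_universe <- function(drugs, ses, sim, assocs) {
  drugs <- validate_drugs(drugs)
  ses <- validate_ses(ses)
  assocs <- validate_assocs(assocs)
  se_terms <- sort(unique(ses$se_term))
  indic_terms <- unique(unlist(drugs$indications))
  trait_terms <- unique(assocs$trait_term)
  missing_terms <- setdiff(c(se_terms, indic_terms, trait_terms),
                           rownames(sim))
  if (length(missing_terms)) {
    stop("term(s) missing from similarity matrix: ",
         paste(utils::head(missing_terms, 10), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(unique(ses$drug_id), drugs$drug_id)
  if (length(orphan)) {
    message(length(orphan),
            " drug(s) in the SE table have no drug record; their SE ",
            "records are ignored")
    ses <- ses[!ses$drug_id %in% orphan, , drop = FALSE]
  }

  # per-drug association traits (union over the drug's targets), with each
  # trait's maximum similarity to the drug's approved indications -- used
  # to disqualify indication-like associations at evidence flagging time
  gene_traits <- dplyr::distinct(assocs, .data$gene, .data$trait_term,
                                 .data$source)
  drug_assoc <- tidyr::unnest(
    dplyr::select(drugs, "drug_id", "targets"),
    cols = "targets"
  )
  drug_assoc <- dplyr::inner_join(drug_assoc, gene_traits,
                                  by = c(targets = "gene"),
                                  relationship = "many-to-many")
  drug_assoc <- dplyr::distinct(drug_assoc, .data$drug_id,
                                .data$trait_term, .data$source)
  ind_map <- stats::setNames(drugs$indications, drugs$drug_id)
  if (nrow(drug_assoc)) {
    drug_assoc$trait_indic_sim <- vapply(seq_len(nrow(drug_assoc)),
      function(i) {
        inds <- ind_map[[drug_assoc$drug_id[i]]]
        max(sim[drug_assoc$trait_term[i], inds])
      }, numeric(1))
  } else {
    drug_assoc$trait_indic_sim <- numeric(0)
  }

  universe <- tidyr::expand_grid(drug_id = drugs$drug_id,
                                 se_term = se_terms)
  obs <- dplyr::mutate(ses, observed = TRUE)
  universe <- dplyr::left_join(universe, obs,
                               by = c("drug_id", "se_term"))
  universe$observed <- !is.na(universe$observed)

  n_se <- length(se_terms)
  best_assoc <- numeric(nrow(universe))
  best_indic <- numeric(nrow(universe))
  assoc_by_drug <- split(drug_assoc$trait_term, drug_assoc$drug_id)
  for (i in seq_len(nrow(drugs))) {
    d <- drugs$drug_id[i]
    rows <- which(universe$drug_id == d)
    traits <- unique(assoc_by_drug[[d]])
    if (length(traits)) {
      best_assoc[rows] <- col_max(sim[traits, se_terms, drop = FALSE])
    }
    best_indic[rows] <- col_max(sim[drugs$indications[[i]], se_terms,
                                    drop = FALSE])
  }
  universe$best_assoc_sim <- best_assoc
  universe$best_indic_sim <- best_indic
  universe <- universe[, c("drug_id", "se_term", "observed",
                           "best_assoc_sim", "best_indic_sim",
                           "freq_numeric", "freq_word", "placebo",
                           "severity_rank")]
  new_pair_universe(universe, drugs = drugs, ses = ses, assocs = assocs,
                    sim = sim, drug_assoc = drug_assoc,
                    se_terms = se_terms)
}

col_max <- function(m) {
  if (nrow(m) == 0) return(rep(0, ncol(m)))
  apply(m, 2, max)
}

new_pair_universe <- function(tbl, drugs, ses, assocs, sim, drug_assoc,
                              se_terms) {
  structure(
    tibble::as_tibble(tbl),
    drugs = drugs, ses = ses, assocs = assocs, sim = sim,
    drug_assoc = drug_assoc, se_terms = se_terms,
    class = c("pair_universe", class(tibble::tibble()))
  )
}

# carry universe attributes across dplyr-style subsetting
keep_universe_attrs <- function(new, old, extra = NULL) {
  for (a in c("drugs", "ses", "assocs", "sim", "drug_assoc", "se_terms",
              "filter_config", "insight_config", "filter_report")) {
    attr(new, a) <- attr(old, a)
  }
  for (a in names(extra)) attr(new, a) <- extra[[a]]
  class(new) <- unique(c("pair_universe", class(new)))
  new
}

universe_attr <- function(universe, what) {
  out <- attr(universe, what, exact = TRUE)
  if (is.null(out)) {
    stop("pair universe is missing attribute '", what,
         "'; build it with build_universe()", call. = FALSE)
  }
  out
}

#' Overall base rate of a pair universe
#'
#' The marginal probability of an SE being observed for a given drug:
#' observed pairs divided by all pairs.
#'
#' @param universe A `pair_universe` (or any data frame with a logical
#'   `observed` column).
#' @return Scalar fraction in `[0, 1]`.
#' @export
overall_base_rate <- function(universe) {
  if (nrow(universe) == 0) stop("empty pair universe", call. = FALSE)
  mean(universe$observed)
}

#' @export
print.pair_universe <- function(x, ...) {
  cat("<pair_universe> ", nrow(x), " drug-SE pairs (",
      sum(x$observed), " observed; base rate ",
      signif(100 * mean(x$observed), 3), "%)\n", sep = "")
  NextMethod()
}
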