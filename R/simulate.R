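#' Configuration for the synthetic pharmacovigilance generator
#'
#' Defines a complete synthetic study: a layered random ontology with an
#' annotation corpus, genes, drugs with targets and approved indications,
#' gene-trait genetic associations with source labels and loci, and
#' label-style side-effect records sampled from a logistic model with a
#' planted on-target effect. The defaults emulate the coarse structure of
#' the real joined data: an overall base rate around 5.4%, genetic
#' evidence on a few percent of pairs, a conditional odds ratio of 2 for
#' evidence-bearing pairs, and indication-correlated SEs as the planted
#' confounder.
#'
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   byte for byte.
#' @param n_terms Ontology size (default 300).
#' @param dag_depth Number of layers below the root (default 5).
#' @param n_top_level Terms in the first layer, used as disease-area
#'   headings (default 8).
#' @param max_parents Maximum parents per term (1 or 2; default 2).
#' @param n_genes,n_drugs Population sizes (defaults 200 and 150).
#' @param targets_per_drug,indications_per_drug Integer ranges sampled
#'   uniformly per drug (defaults 1:3 and 1:3).
#' @param assocs_per_gene_mean Poisson mean of associations per gene
#'   (default 3).
#' @param source_mix Named proportions over [genetic_sources()].
#' @param se_term_fraction Fraction of eligible (non-root, non-top-level)
#'   terms that can appear as side effects (default 0.75).
#' @param alpha Baseline logit intercept for SE observation
#'   (default `qlogis(0.05)`).
#' @param beta_evidence Planted conditional log-OR for observation given
#'   on-target genetic evidence (default `log(2)`).
#' @param gamma_indic Planted log-OR for observation given an
#'   indication-similar SE: the confounding-by-indication effect (default
#'   `log(3)`).
#' @param evidence_sim_threshold Similarity at which the generator deems a
#'   trait/indication "similar" to an SE when planting effects (default
#'   0.9, matching the analysis default).
#' @param severity_coupling Slope linking an SE's latent severity to
#'   log drug-specificity; negative means more severe SEs are observed
#'   for fewer drugs (default -0.5).
#' @param severity_missing,freq_numeric_present,freq_word_present,
#'   placebo_present Modifier availability rates on observed records.
#' @param freq_words Ordered frequency vocabulary.
#' @param smooth Laplace smoothing for information content.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_terms = 300L,
                             dag_depth = 5L,
                             n_top_level = 8L,
                             max_parents = 2L,
                             n_genes = 200L,
                             n_drugs = 150L,
                             targets_per_drug = 1:3,
                             indications_per_drug = 1:3,
                             assocs_per_gene_mean = 3,
                             source_mix = c(OMIM = 0.25, OTG = 0.35,
                                            PICCOLO = 0.15,
                                            Genebass = 0.10,
                                            IntOGen = 0.15),
                             se_term_fraction = 0.75,
                             alpha = stats::qlogis(0.05),
                             beta_evidence = log(2),
                             gamma_indic = log(3),
                             evidence_sim_threshold = 0.9,
                             severity_coupling = -0.5,
                             severity_missing = 0.25,
                             freq_numeric_present = 0.4,
                             freq_word_present = 0.3,
                             placebo_present = 0.5,
                             freq_words = default_freq_words(),
                             smooth = TRUE) {
  stopifnot(n_terms >= 2, n_drugs >= 2, n_genes >= 1,
            dag_depth >= 2, n_top_level >= 1,
            max_parents %in% 1:2,
            abs(sum(source_mix) - 1) < 1e-8,
            all(names(source_mix) %in% genetic_sources()),
            se_term_fraction > 0, se_term_fraction <= 1,
            evidence_sim_threshold >= 0, evidence_sim_threshold <= 1)
  structure(as.list(environment()), class = "generator_config")
}

# layered random DAG: root, then n_top_level headings, then geometric
# layers; each deeper term attaches to 1..max_parents members of the
# previous layer
simulate_ontology <- function(cfg) {
  n <- cfg$n_terms
  ids <- sprintf("T%04d", seq_len(n))
  root <- ids[1]
  layer_sizes <- c(1L, cfg$n_top_level)
  remaining <- n - 1L - cfg$n_top_level
  if (remaining < cfg$dag_depth - 1L) {
    stop("n_terms too small for the requested depth and top level",
         call. = FALSE)
  }
  grow <- cfg$dag_depth - 1L
  weights <- 1.6^seq_len(grow)
  sizes <- pmax(1L, round(remaining * weights / sum(weights)))
  sizes[grow] <- remaining - sum(sizes[-grow])
  layer_sizes <- c(layer_sizes, sizes)
  layer_of <- rep(seq_along(layer_sizes), layer_sizes)
  edges_child <- character(0)
  edges_parent <- character(0)
  for (i in which(layer_of > 1)) {
    prev <- ids[layer_of == layer_of[i] - 1L]
    k <- sample(seq_len(min(cfg$max_parents, length(prev))), 1)
    parents <- sample(prev, k)
    edges_child <- c(edges_child, rep(ids[i], k))
    edges_parent <- c(edges_parent, parents)
  }
  list(
    edges = tibble::tibble(child = edges_child, parent = edges_parent),
    top_level = ids[layer_of == 2],
    ids = ids,
    layer_of = layer_of,
    root = root
  )
}

#' Generate a complete synthetic dataset
#'
#' Builds every input the analysis consumes, with known ground truth. The
#' ontology and corpus determine a combined Lin-Resnik similarity matrix
#' (the same metric the pipeline uses, so planted "similar" pairs are
#' defined self-consistently). Each drug-SE pair's observation probability
#' follows `logit(P) = alpha + beta_evidence * E + gamma_indic * I`, where
#' `E` indicates a target association with similarity at or above the
#' evidence threshold to the SE and `I` an approved indication similarly
#' close to the SE. Modifiers are sampled for observed records only.
#'
#' @param cfg A [generator_config()].
#' @return List with tibbles `ontology_edges`, `corpus`, `drugs`, `ses`,
#'   `assocs`, the `top_level` IDs, the `sim` matrix, the `onto` object,
#'   and `truth` (planted parameters plus per-pair latent flags).
#' @export
simulate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sk <- simulate_ontology(cfg)
  onto <- load_ontology(sk$edges, top_level = sk$top_level)

  # long-tailed annotation corpus
  corpus <- tibble::tibble(
    term = sk$ids,
    count = as.integer(round(stats::rlnorm(length(sk$ids),
                                           meanlog = 1.5, sdlog = 1.3)))
  )
  sim <- similarity_matrix(onto, corpus, smooth = cfg$smooth)

  disease_terms <- sk$ids[sk$layer_of >= 3]
  se_candidates <- sort(sample(disease_terms,
                               ceiling(cfg$se_term_fraction *
                                         length(disease_terms))))

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  drugs <- tibble::tibble(
    drug_id = sprintf("D%04d", seq_len(cfg$n_drugs)),
    targets = lapply(seq_len(cfg$n_drugs), function(i) {
      sample(genes, sample(cfg$targets_per_drug, 1))
    }),
    indications = lapply(seq_len(cfg$n_drugs), function(i) {
      sample(disease_terms, sample(cfg$indications_per_drug, 1))
    })
  )

  n_assoc <- stats::rpois(cfg$n_genes, cfg$assocs_per_gene_mean)
  assocs <- tibble::tibble(
    gene = rep(genes, n_assoc),
    trait_term = sample(disease_terms, sum(n_assoc), replace = TRUE),
    source = sample(names(cfg$source_mix), sum(n_assoc),
                    replace = TRUE, prob = cfg$source_mix)
  )
  gwas <- assocs$source %in% c("OTG", "PICCOLO")
  assocs$chrom <- ifelse(gwas,
                         as.character(sample(1:22, nrow(assocs),
                                             replace = TRUE)),
                         NA_character_)
  assocs$pos_mb <- ifelse(gwas,
                          sample(0:249, nrow(assocs), replace = TRUE),
                          NA_integer_)
  assocs <- dplyr::distinct(assocs)

  # latent per-pair flags from the generator's own similarity metric
  lat <- tidyr::expand_grid(drug_id = drugs$drug_id,
                            se_term = se_candidates)
  gene_traits <- dplyr::distinct(assocs, .data$gene, .data$trait_term)
  traits_by_gene <- split(gene_traits$trait_term, gene_traits$gene)
  ev <- logical(nrow(lat))
  ind <- logical(nrow(lat))
  thr <- cfg$evidence_sim_threshold
  for (i in seq_len(nrow(drugs))) {
    rows <- which(lat$drug_id == drugs$drug_id[i])
    traits <- unique(unlist(traits_by_gene[drugs$targets[[i]]]))
    if (length(traits)) {
      ev[rows] <- col_max(sim[traits, se_candidates,
                              drop = FALSE]) >= thr
    }
    ind[rows] <- col_max(sim[drugs$indications[[i]], se_candidates,
                             drop = FALSE]) >= thr
  }
  lat$evidence_latent <- ev
  lat$indic_latent <- ind
  lat$p_observed <- stats::plogis(cfg$alpha +
                                    cfg$beta_evidence * ev +
                                    cfg$gamma_indic * ind)
  lat$observed <- stats::runif(nrow(lat)) < lat$p_observed
  if (!any(lat$observed)) {
    stop("configuration yielded no observed drug-SE pairs", call. = FALSE)
  }

  obs <- lat[lat$observed, c("drug_id", "se_term")]
  # per-SE severity: latent severity couples to (log) drug specificity
  se_obs_n <- table(obs$se_term)
  se_tbl <- tibble::tibble(se_term = names(se_obs_n),
                           n_drugs = as.integer(se_obs_n))
  latent_sev <- cfg$severity_coupling * log(se_tbl$n_drugs) +
    stats::rnorm(nrow(se_tbl))
  se_tbl$severity_rank <- rank(latent_sev, ties.method = "first")
  se_tbl$severity_rank[stats::runif(nrow(se_tbl)) <
                         cfg$severity_missing] <- NA_integer_

  n_obs <- nrow(obs)
  freq <- stats::rbeta(n_obs, 1.2, 8)
  has_num <- stats::runif(n_obs) < cfg$freq_numeric_present
  has_word <- stats::runif(n_obs) < cfg$freq_word_present
  word_bin <- cut(freq, breaks = stats::quantile(
    freq, probs = seq(0, 1, length.out = length(cfg$freq_words) + 1)),
    labels = FALSE, include.lowest = TRUE)
  has_pla <- stats::runif(n_obs) < cfg$placebo_present
  ses <- tibble::tibble(
    drug_id = obs$drug_id,
    se_term = obs$se_term,
    freq_numeric = ifelse(has_num, round(freq, 4), NA_real_),
    freq_word = ifelse(has_word, cfg$freq_words[word_bin],
                       NA_character_),
    placebo = ifelse(has_pla, stats::runif(n_obs) < 0.5, NA),
    severity_rank = se_tbl$severity_rank[match(obs$se_term,
                                               se_tbl$se_term)]
  )
  ses <- dplyr::arrange(ses, .data$drug_id, .data$se_term)

  truth <- list(
    params = cfg,
    n_pairs = nrow(lat),
    n_observed = n_obs,
    latent = lat
  )
  list(
    ontology_edges = sk$edges,
    top_level = sk$top_level,
    corpus = corpus,
    drugs = drugs,
    ses = ses,
    assocs = assocs,
    sim = sim,
    onto = onto,
    truth = truth
  )
}

#' Write a synthetic dataset as the pipeline's TSV inputs
#'
#' Emits `ontology.tsv`, `top_level.tsv`, `corpus.tsv`, `drugs.tsv`,
#' `side_effects.tsv`, `associations.tsv`, `similarity.tsv`, and the
#' ground truth as `truth_params.tsv` (key-value) plus
#' `truth_latent.tsv` (per-pair latent flags).
#'
#' @param ds Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ontology = file.path(dir, "ontology.tsv"),
    top_level = file.path(dir, "top_level.tsv"),
    corpus = file.path(dir, "corpus.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    ses = file.path(dir, "side_effects.tsv"),
    assocs = file.path(dir, "associations.tsv"),
    sim = file.path(dir, "similarity.tsv"),
    truth_params = file.path(dir, "truth_params.tsv"),
    truth_latent = file.path(dir, "truth_latent.tsv")
  )
  readr::write_tsv(ds$ontology_edges, paths[["ontology"]],
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(term = ds$top_level),
                   paths[["top_level"]], progress = FALSE)
  readr::write_tsv(ds$corpus, paths[["corpus"]], progress = FALSE)
  drugs_flat <- tibble::tibble(
    drug_id = ds$drugs$drug_id,
    targets = vapply(ds$drugs$targets, paste, "", collapse = ";"),
    indications = vapply(ds$drugs$indications, paste, "",
                         collapse = ";")
  )
  readr::write_tsv(drugs_flat, paths[["drugs"]], progress = FALSE)
  readr::write_tsv(ds$ses, paths[["ses"]], progress = FALSE)
  readr::write_tsv(ds$assocs, paths[["assocs"]], progress = FALSE)
  write_sim_matrix(ds$sim, paths[["sim"]])
  par <- ds$truth$params
  scal <- vapply(par, function(v) length(v) == 1 && !is.list(v),
                 logical(1))
  readr::write_tsv(
    tibble::tibble(key = names(par)[scal],
                   value = vapply(par[scal], function(v)
                     format(v, digits = 15), "")),
    paths[["truth_params"]], progress = FALSE
  )
  readr::write_tsv(ds$truth$latent, paths[["truth_latent"]],
                   progress = FALSE)
  invisible(paths)
}

#' Evaluate pipeline recovery against generator ground truth
#'
#' Compares the pipeline's evidence flags and enrichment estimate with the
#' generator's planted values: the log-OR bias against `beta_evidence`,
#' whether the CI covers the planted odds ratio, and the confusion of the
#' pipeline's `has_evidence` flag against the latent evidence indicator.
#'
#' @param truth The `truth` element of [simulate_dataset()].
#' @param universe A flagged `pair_universe` built from the same dataset.
#' @param enrichment An `se_enrichment` for the same universe (default:
#'   computed from the universe's flags as given).
#' @return Tibble with `beta_true`, `log_or_hat`, `bias`, `covered`,
#'   and evidence-flag confusion counts.
#' @export
truth_eval <- function(truth, universe, enrichment = NULL) {
  lat <- truth$latent
  key_u <- paste(universe$drug_id, universe$se_term)
  key_l <- paste(lat$drug_id, lat$se_term)
  idx <- match(key_u, key_l)
  if (anyNA(idx)) {
    stop("universe does not match the truth record's pair universe",
         call. = FALSE)
  }
  if (is.null(enrichment)) {
    enrichment <- enrichment_from_flags(universe$observed,
                                        universe$has_evidence)
  }
  ev_true <- lat$evidence_latent[idx]
  ev_hat <- universe$has_evidence
  beta <- truth$params$beta_evidence
  tibble::tibble(
    beta_true = beta,
    log_or_hat = log(enrichment$fisher$estimate),
    bias = log(enrichment$fisher$estimate) - beta,
    covered = enrichment$fisher$ci_low <= exp(beta) &
      exp(beta) <= enrichment$fisher$ci_high,
    n_true_pos = sum(ev_hat & ev_true),
    n_false_pos = sum(ev_hat & !ev_true),
    n_false_neg = sum(!ev_hat & ev_true),
    n_true_neg = sum(!ev_hat & !ev_true)
  )
}
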