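# Shared toy fixtures built in code.

# the 4-term diamond-free toy: C -> A -> R, B -> R
toy_onto <- function() {
  load_ontology(
    tibble::tibble(child = c("C", "A", "B"), parent = c("A", "R", "R")),
    top_level = c("A", "B")
  )
}

toy_corpus_uniform <- function() {
  tibble::tibble(term = c("R", "A", "B", "C"), count = rep(1L, 4))
}

# a hand-built analytic scenario: two disease branches under one root,
# with one drug whose target's association matches an SE exactly
# (topiramate-like) and one whose SE equals its indication
# (bisoprolol-like). Similarities come from an identity-style matrix over
# the terms so thresholds behave predictably.
toy_sim <- function(terms, pairs = NULL) {
  m <- diag(length(terms))
  dimnames(m) <- list(terms, terms)
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      m[pairs$a[i], pairs$b[i]] <- pairs$s[i]
      m[pairs$b[i], pairs$a[i]] <- pairs$s[i]
    }
  }
  class(m) <- c("sim_matrix", "matrix")
  m
}

toy_drugs <- function() {
  tibble::tibble(
    drug_id = c("topi", "biso"),
    targets = list("SCN5A", "ADRB1"),
    indications = list("migraine", "arrhythmia")
  )
}

toy_ses <- function() {
  tibble::tibble(
    drug_id = c("topi", "biso"),
    se_term = c("arrhythmia", "arrhythmia"),
    freq_numeric = c(0.05, NA),
    freq_word = c(NA_character_, "rare"),
    placebo = c(TRUE, NA),
    severity_rank = c(5L, 5L)
  )
}

toy_assocs <- function() {
  tibble::tibble(
    gene = c("SCN5A", "ADRB1"),
    trait_term = c("arrhythmia", "arrhythmia"),
    source = c("OMIM", "OMIM"),
    chrom = NA_character_,
    pos_mb = NA_integer_
  )
}

toy_universe <- function() {
  terms <- c("arrhythmia", "migraine", "chills")
  sim <- toy_sim(terms)
  ses <- dplyr::bind_rows(
    toy_ses(),
    tibble::tibble(drug_id = "topi", se_term = "chills",
                   freq_numeric = NA_real_, freq_word = NA_character_,
                   placebo = NA, severity_rank = NA_integer_)
  )
  build_universe(toy_drugs(), ses, sim, toy_assocs())
}

# small synthetic dataset for pipeline-level tests
small_config <- function(seed = 11, ...) {
  generator_config(seed = seed, n_terms = 120L, dag_depth = 4L,
                   n_top_level = 5L, n_genes = 60L, n_drugs = 50L, ...)
}
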