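#' Build a validated ontology from a child-parent edge table
#'
#' Constructs a directed acyclic graph of ontology terms from an edge list.
#' Edges point from child to parent; a term may have several parents. Roots
#' are the terms that never appear as a child-side origin of an edge, i.e.
#' have no parent. A subset of terms can be designated as top-level headings
#' (disease areas), used later to bin side effects by affected organ system.
#'
#' @param edges Data frame with columns `child` and `parent` (term IDs as
#'   character), or a path to a two-column TSV with a `child<TAB>parent`
#'   header. Duplicate rows are collapsed.
#' @param top_level Character vector of term IDs to mark as top-level
#'   headings. Must all be present in the ontology.
#' @return An object of class `ontology`: a list with elements `terms`,
#'   `edges` (deduplicated tibble), `roots`, `top_level` and the underlying
#'   `igraph` graph (edges directed child to parent).
#' @examples
#' edges <- tibble::tibble(child = c("C", "A", "B"), parent = c("A", "R", "R"))
#' onto <- load_ontology(edges, top_level = c("A", "B"))
#' onto$roots
#' @export
load_ontology <- function(edges, top_level = character()) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- read_ontology_edges(edges)
  }
  stopifnot(is.data.frame(edges))
  if (!all(c("child", "parent") %in% names(edges))) {
    stop("edge table must have columns 'child' and 'parent'", call. = FALSE)
  }
  if (nrow(edges) == 0) stop("edge table is empty", call. = FALSE)
  edges <- dplyr::distinct(
    tibble::tibble(
      child = as.character(edges$child),
      parent = as.character(edges$parent)
    )
  )
  if (anyNA(edges$child) || anyNA(edges$parent)) {
    stop("edge table contains missing term IDs", call. = FALSE)
  }
  loops <- edges$child == edges$parent
  if (any(loops)) {
    stop("cycle detected in ontology: term '", edges$child[which(loops)[1]],
         "' is its own parent", call. = FALSE)
  }
  terms <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = terms)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop("cycle detected in ontology involving term '", bad[1], "'",
         call. = FALSE)
  }
  roots <- setdiff(terms, edges$child)
  top_level <- unique(as.character(top_level))
  unknown <- setdiff(top_level, terms)
  if (length(unknown)) {
    stop("unknown top-level term ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(terms = terms, edges = edges, roots = roots,
         top_level = top_level, graph = g),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", length(x$terms), " terms, ", nrow(x$edges),
      " edges, ", length(x$roots), " root(s), ", length(x$top_level),
      " top-level heading(s)\n", sep = "")
  invisible(x)
}

#' Read an ontology edge table from TSV
#'
#' @param path Path to a TSV with header `child<TAB>parent`.
#' @return Tibble with columns `child`, `parent`.
#' @export
read_ontology_edges <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c("child", "parent") %in% names(edges))) {
    stop("ontology TSV must have header columns 'child' and 'parent'",
         call. = FALSE)
  }
  edges
}

#' Read an annotation corpus from TSV
#'
#' @param path Path to a TSV with header `term<TAB>count`.
#' @return Tibble with columns `term` (character) and `count` (integer).
#' @export
read_corpus <- function(path) {
  corpus <- readr::read_tsv(
    path,
    col_types = readr::cols(term = "c", count = "i"),
    progress = FALSE
  )
  validate_corpus(corpus)
  corpus
}

validate_corpus <- function(corpus) {
  if (!all(c("term", "count") %in% names(corpus))) {
    stop("corpus must have columns 'term' and 'count'", call. = FALSE)
  }
  if (any(corpus$count < 0, na.rm = TRUE)) {
    stop("corpus counts must be non-negative", call. = FALSE)
  }
  invisible(corpus)
}

# Boolean ancestor matrix: A[i, j] is TRUE when term j is an ancestor of
# term i or i itself (edges run child -> parent, so ancestors are the set
# reachable along edge direction).
ancestor_matrix <- function(onto) {
  d <- igraph::distances(onto$graph, mode = "out", weights = NA)
  A <- is.finite(d)
  idx <- match(onto$terms, rownames(A))
  A[idx, idx, drop = FALSE]
}

#' Ancestors of a term (including the term itself)
#'
#' @param onto An `ontology` object.
#' @param term A term ID present in the ontology.
#' @return Character vector of ancestor term IDs, including `term`.
#' @export
term_ancestors <- function(onto, term) {
  if (!term %in% onto$terms) {
    stop("unknown term: ", term, call. = FALSE)
  }
  out <- igraph::subcomponent(onto$graph, term, mode = "out")
  sort(names(out))
}

#' Top-level headings (disease areas) of a term
#'
#' Returns the designated top-level ancestors of a term. A term that is
#' itself a top-level heading is included in the result. A term outside any
#' top-level subtree returns an empty vector; per-area analyses place such
#' terms in an "unclassified" bin.
#'
#' @inheritParams term_ancestors
#' @return Character vector (possibly empty) of top-level term IDs.
#' @export
top_level_headings <- function(onto, term) {
  intersect(term_ancestors(onto, term), onto$top_level)
}

#' Information content of ontology terms from an annotation corpus
#'
#' The annotation probability of a term is the cumulative count of the term
#' and all of its descendants divided by the corpus total; information
#' content is the negative natural logarithm of that probability, so a root
#' annotated by the whole corpus has IC 0 and rarer, more specific terms
#' have higher IC. By default every term's direct count receives add-one
#' (Laplace) smoothing so that IC is defined for all terms in the ontology;
#' with `smooth = FALSE`, terms with zero cumulative count get `NA` IC and
#' are excluded from similarity.
#'
#' @param onto An `ontology` object.
#' @param corpus Data frame with columns `term` and `count` (non-negative
#'   integers). Terms absent from the corpus have direct count 0; corpus
#'   terms absent from the ontology are ignored with a warning.
#' @param smooth Add 1 to every term's direct count (default `TRUE`).
#' @return Tibble with columns `term`, `n_direct`, `n_cumulative`, `p`,
#'   `ic`, one row per ontology term.
#' @export
information_content <- function(onto, corpus, smooth = TRUE) {
  stopifnot(inherits(onto, "ontology"))
  validate_corpus(corpus)
  extra <- setdiff(corpus$term, onto$terms)
  if (length(extra)) {
    warning(length(extra), " corpus term(s) not in ontology ignored",
            call. = FALSE)
    corpus <- corpus[corpus$term %in% onto$terms, , drop = FALSE]
  }
  direct <- stats::setNames(rep(0, length(onto$terms)), onto$terms)
  direct[corpus$term] <- corpus$count
  if (smooth) direct <- direct + 1
  total <- sum(direct)
  if (total <= 0) stop("corpus total must be positive", call. = FALSE)
  A <- ancestor_matrix(onto)
  # n_cumulative[j] = sum of direct counts over descendants of j incl. j
  n_cum <- as.numeric(crossprod(A, direct))
  p <- n_cum / total
  ic <- ifelse(n_cum > 0, -log(p), NA_real_)
  tibble::tibble(
    term = onto$terms,
    n_direct = as.numeric(direct),
    n_cumulative = n_cum,
    p = p,
    ic = ic
  )
}

ic_vector <- function(ic) {
  if (is.numeric(ic) && !is.null(names(ic))) return(ic)
  stopifnot(is.data.frame(ic), all(c("term", "ic") %in% names(ic)))
  stats::setNames(ic$ic, ic$term)
}

#' Resnik similarity of two terms
#'
#' IC of the most informative common ancestor (MICA); a term counts as its
#' own ancestor. Terms with no common ancestor (disjoint multi-root
#' forests) have similarity 0.
#'
#' @param onto An `ontology` object.
#' @param ic Result of [information_content()] (or a named IC vector).
#' @param a,b Term IDs.
#' @return Non-negative scalar.
#' @export
resnik_similarity <- function(onto, ic, a, b) {
  icv <- ic_vector(ic)
  anc <- intersect(term_ancestors(onto, a), term_ancestors(onto, b))
  if (!length(anc)) return(0)
  vals <- icv[anc]
  if (anyNA(vals)) {
    stop("IC undefined for ancestor term(s); enable smoothing or enrich ",
         "the corpus", call. = FALSE)
  }
  max(vals)
}

#' Lin similarity of two terms
#'
#' `2 * IC(MICA) / (IC(a) + IC(b))`, clamped to `[0, 1]`. When both terms
#' have IC 0 the ratio is 0/0: a root compared with itself is defined as 1;
#' every other zero-IC pair is 0. Terms with no common ancestor score 0.
#'
#' @inheritParams resnik_similarity
#' @return Scalar in `[0, 1]`.
#' @export
lin_similarity <- function(onto, ic, a, b) {
  icv <- ic_vector(ic)
  if (anyNA(icv[c(a, b)])) {
    stop("IC undefined for term(s) ", a, ", ", b, call. = FALSE)
  }
  denom <- icv[[a]] + icv[[b]]
  if (denom == 0) {
    if (a == b && a %in% onto$roots) return(1)
    return(0)
  }
  anc <- intersect(term_ancestors(onto, a), term_ancestors(onto, b))
  if (!length(anc)) return(0)
  mica <- max(icv[anc])
  min(1, max(0, 2 * mica / denom))
}

# All-pairs Resnik matrix over the given terms. Iterates candidate
# ancestors in decreasing IC order; the first shared ancestor encountered
# for a pair is its MICA. Pairs sharing no ancestor stay at 0.
resnik_matrix <- function(A, icv) {
  n <- nrow(A)
  terms <- rownames(A)
  R <- matrix(NA_real_, n, n, dimnames = list(terms, terms))
  for (j in order(icv, decreasing = TRUE)) {
    idx <- which(A[, j])
    if (!length(idx)) next
    sub <- R[idx, idx, drop = FALSE]
    miss <- is.na(sub)
    if (any(miss)) {
      sub[miss] <- icv[j]
      R[idx, idx] <- sub
    }
    if (!anyNA(R)) break
  }
  R[is.na(R)] <- 0
  R
}

#' Combined Lin-Resnik similarity matrix
#'
#' Computes Lin and Resnik similarities for every pair of terms, rescales
#' Resnik onto the Lin scale, and averages the two. Both scores are floored
#' at 0. The rescaling multiplier `m` is the zero-intercept least-squares
#' slope of Lin on Resnik over all unordered term pairs (including the
#' diagonal), `m = sum(lin * resnik) / sum(resnik^2)`; rescaled Resnik is
#' capped at 1, and the combined score is `(lin + min(1, m * resnik)) / 2`.
#'
#' @param onto An `ontology` object.
#' @param corpus Annotation corpus data frame (see [information_content()]),
#'   or `NULL` if `ic` is supplied.
#' @param terms Terms to include (default: all ontology terms with defined
#'   IC).
#' @param smooth Passed to [information_content()].
#' @param ic Optional precomputed result of [information_content()].
#' @return A `sim_matrix`: symmetric numeric matrix with values in
#'   `[0, 1]`, with attributes `multiplier` (the fitted `m`) and `ic`.
#' @export
similarity_matrix <- function(onto, corpus = NULL, terms = NULL,
                              smooth = TRUE, ic = NULL) {
  stopifnot(inherits(onto, "ontology"))
  if (is.null(ic)) {
    if (is.null(corpus)) stop("supply either corpus or ic", call. = FALSE)
    ic <- information_content(onto, corpus, smooth = smooth)
  }
  icv <- ic_vector(ic)
  usable <- names(icv)[!is.na(icv)]
  dropped <- setdiff(names(icv), usable)
  if (length(dropped)) {
    warning(length(dropped),
            " term(s) with undefined IC excluded from similarity",
            call. = FALSE)
  }
  if (is.null(terms)) terms <- usable
  bad <- setdiff(terms, usable)
  if (length(bad)) {
    stop("terms without defined IC requested: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  A <- ancestor_matrix(onto)[terms, , drop = FALSE]
  icv_all <- icv[colnames(A)]
  icv_all[is.na(icv_all)] <- -Inf  # never selected as MICA
  R <- resnik_matrix(A, icv_all)
  icv_t <- icv[terms]
  denom <- outer(icv_t, icv_t, "+")
  L <- ifelse(denom > 0, 2 * R / denom, 0)
  zz <- which(denom == 0, arr.ind = TRUE)
  if (nrow(zz)) {
    is_root_diag <- terms[zz[, 1]] == terms[zz[, 2]] &
      terms[zz[, 1]] %in% onto$roots
    L[zz[is_root_diag, , drop = FALSE]] <- 1
  }
  L <- pmin(pmax(L, 0), 1)
  combine_similarities(L, R)
}

#' Combine Lin and Resnik scores into a single similarity
#'
#' @param lin,resnik Symmetric matrices (same dimnames) of Lin and Resnik
#'   scores, or plain numeric vectors of paired scores.
#' @return For matrix input, a `sim_matrix` of combined scores in `[0, 1]`
#'   with attribute `multiplier`; for vector input, a numeric vector with
#'   the same attribute.
#' @export
combine_similarities <- function(lin, resnik) {
  stopifnot(length(lin) == length(resnik))
  lin <- pmax(lin, 0)
  resnik <- pmax(resnik, 0)
  if (is.matrix(resnik)) {
    keep <- upper.tri(resnik, diag = TRUE)
    x <- resnik[keep]
    y <- lin[keep]
  } else {
    x <- as.numeric(resnik)
    y <- as.numeric(lin)
  }
  if (length(x) < 2 || sum(x^2) == 0 || stats::var(x) == 0) {
    stop("degenerate Resnik scores (no variance); enrich the annotation ",
         "corpus before combining similarities", call. = FALSE)
  }
  m <- sum(y * x) / sum(x^2)
  combined <- (lin + pmin(m * resnik, 1)) / 2
  combined <- pmin(pmax(combined, 0), 1)
  attr(combined, "multiplier") <- m
  if (is.matrix(combined)) class(combined) <- c("sim_matrix", "matrix")
  combined
}

#' Look up pairwise similarities in a similarity matrix
#'
#' @param sim A `sim_matrix`.
#' @param a,b Character vectors of term IDs (recycled against each other).
#' @return Numeric vector of combined similarity scores.
#' @export
sim_lookup <- function(sim, a, b) {
  missing_terms <- setdiff(unique(c(a, b)), rownames(sim))
  if (length(missing_terms)) {
    stop("term(s) missing from similarity matrix: ",
         paste(utils::head(missing_terms, 5), collapse = ", "),
         call. = FALSE)
  }
  sim[cbind(a, b)]
}

#' Write a similarity matrix as a three-column TSV
#'
#' Stores the upper triangle plus diagonal as `term_a<TAB>term_b<TAB>sim`.
#'
#' @param sim A `sim_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "sim_matrix"))
  keep <- which(upper.tri(sim, diag = TRUE), arr.ind = TRUE)
  tbl <- tibble::tibble(
    term_a = rownames(sim)[keep[, 1]],
    term_b = colnames(sim)[keep[, 2]],
    sim = sim[keep]
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_sim_matrix()]
#'
#' @param path Path to a `term_a<TAB>term_b<TAB>sim` TSV.
#' @return A `sim_matrix` (symmetrised from the stored upper triangle).
#' @export
read_sim_matrix <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(term_a = "c", term_b = "c", sim = "d"),
    progress = FALSE
  )
  terms <- sort(unique(c(tbl$term_a, tbl$term_b)))
  m <- matrix(0, length(terms), length(terms),
              dimnames = list(terms, terms))
  m[cbind(tbl$term_a, tbl$term_b)] <- tbl$sim
  m[cbind(tbl$term_b, tbl$term_a)] <- tbl$sim
  class(m) <- c("sim_matrix", "matrix")
  m
}

#' @export
tidy.sim_matrix <- function(x, ...) {
  keep <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    term_a = rownames(x)[keep[, 1]],
    term_b = colnames(x)[keep[, 2]],
    sim = x[keep]
  )
}
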