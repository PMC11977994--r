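# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: ancestor sets by edge-list closure (not igraph),
# Fisher quantities by direct enumeration over the fixed-margin support
# with choose() weights and plain bisection.

# --- ontology oracles -----------------------------------------------------

oracle_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    parents <- edges$parent[edges$child %in% anc]
    new <- setdiff(parents, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  sort(anc)
}

# cumulative counts / probabilities / IC by descendant enumeration
oracle_ic <- function(edges, counts, smooth = TRUE) {
  terms <- sort(unique(c(edges$child, edges$parent, names(counts))))
  direct <- setNames(rep(0, length(terms)), terms)
  direct[names(counts)] <- counts
  if (smooth) direct <- direct + 1
  total <- sum(direct)
  anc_sets <- lapply(terms, oracle_ancestors, edges = edges)
  names(anc_sets) <- terms
  cum <- vapply(terms, function(t) {
    descendants <- terms[vapply(anc_sets, function(a) t %in% a,
                                logical(1))]
    sum(direct[descendants])
  }, numeric(1))
  ic <- ifelse(cum > 0, -log(cum / total), NA_real_)
  list(ic = ic, p = cum / total, cum = cum, total = total,
       anc_sets = anc_sets)
}

oracle_resnik <- function(edges, icv, anc_sets, a, b) {
  common <- intersect(anc_sets[[a]], anc_sets[[b]])
  if (!length(common)) return(0)
  max(icv[common])
}

oracle_lin <- function(edges, icv, anc_sets, a, b, roots) {
  denom <- icv[[a]] + icv[[b]]
  if (denom == 0) {
    if (a == b && a %in% roots) return(1)
    return(0)
  }
  common <- intersect(anc_sets[[a]], anc_sets[[b]])
  if (!length(common)) return(0)
  min(1, max(0, 2 * max(icv[common]) / denom))
}

# random layered DAG for property tests (independent of the package's
# generator): layer 1 is a single root, each later term attaches to 1-2
# members of the previous layer
random_dag <- function(n_terms, n_layers = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n_terms))
  layer <- sort(c(1, sample(2:n_layers, n_terms - 1, replace = TRUE)))
  layer[2] <- 2  # ensure layer 2 nonempty
  child <- parent <- character(0)
  for (i in which(layer > 1)) {
    prev <- ids[layer == layer[i] - 1]
    if (!length(prev)) prev <- ids[layer < layer[i]]
    k <- sample(1:min(2, length(prev)), 1)
    p <- sample(prev, k)
    child <- c(child, rep(ids[i], k))
    parent <- c(parent, p)
  }
  tibble::tibble(child = child, parent = parent)
}

random_corpus <- function(edges, seed = NULL, max_count = 20) {
  if (!is.null(seed)) set.seed(seed)
  terms <- sort(unique(c(edges$child, edges$parent)))
  tibble::tibble(term = terms,
                 count = as.integer(sample(0:max_count, length(terms),
                                           replace = TRUE)))
}

# --- Fisher oracle --------------------------------------------------------

oracle_fisher <- function(a, b, c, d, conf_level = 0.95) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  s <- lo:hi
  w <- choose(m, s) * choose(n, k - s)  # enumeration of all tables
  pr <- w / sum(w)
  p <- sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)])
  logw <- log(w)
  pmf <- function(t) {
    z <- logw + s * t
    z <- exp(z - max(z))
    z / sum(z)
  }
  alpha2 <- (1 - conf_level) / 2
  solve_t <- function(f, target, increasing) {
    lo_t <- -745; hi_t <- 745
    for (i in 1:70) {
      mid <- 0.5 * (lo_t + hi_t)
      v <- f(mid) - target
      if (xor(increasing, v >= 0)) lo_t <- mid else hi_t <- mid
    }
    0.5 * (lo_t + hi_t)
  }
  or <- if (a == lo) 0 else if (a == hi) Inf else
    exp(solve_t(function(t) sum(s * pmf(t)), a, TRUE))
  ci_lo <- if (a == lo) 0 else
    exp(solve_t(function(t) sum(pmf(t)[s >= a]), alpha2, TRUE))
  ci_hi <- if (a == hi) Inf else
    exp(solve_t(function(t) sum(pmf(t)[s <= a]), alpha2, FALSE))
  c(or = or, ci_low = ci_lo, ci_high = ci_hi, p = p)
}

# relative difference that treats matching infinities as equal
rel_diff <- function(x, y) {
  d <- abs(x - y) / pmax(1, abs(y))
  d[is.infinite(x) & is.infinite(y) & sign(x) == sign(y)] <- 0
  d
}
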