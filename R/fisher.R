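#' Exact Fisher odds ratio for a 2x2 contingency table
#'
#' Conditional exact inference for the odds ratio of a 2x2 table: the
#' conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model, the exact two-sided p-value (summing outcomes no
#' more likely than the observed one at odds 1), and the exact confidence
#' interval from inverting the one-sided tails at `(1 - conf_level) / 2`.
#' Tables with a zero cell yield an estimate of 0 or `Inf` with the
#' corresponding one-sided CI bound; tables with an empty margin are
#' undefined and raise an error. The crude sample odds ratio `(a d)/(b c)`
#' is reported alongside for transparency.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` observed with
#'   evidence, `b` observed without, `c` unobserved with, `d` unobserved
#'   without. Alternatively `a` may be a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `fisher_or`: list with `estimate`
#'   (conditional MLE), `sample_or`, `ci_low`, `ci_high`, `p`,
#'   `conf_level` and the input `table`.
#' @examples
#' fisher_or(10, 90, 5, 895)
#' @export
fisher_or <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (is.matrix(a) || is.table(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
    b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]; a <- tab[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  check_cells(cells)
  res <- fisher_or_batch(a, b, c, d, conf_level = conf_level)
  structure(
    list(estimate = res$or_mle, sample_or = res$sample_or,
         ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
         conf_level = conf_level,
         table = matrix(cells, 2, 2, byrow = TRUE,
                        dimnames = list(c("observed", "unobserved"),
                                        c("evidence", "no_evidence")))),
    class = "fisher_or"
  )
}

check_cells <- function(cells) {
  if (anyNA(cells) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8)) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  a <- cells[["a"]]; b <- cells[["b"]]
  cc <- cells[["c"]]; d <- cells[["d"]]
  if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) {
    stop("odds ratio undefined: the table has an empty margin",
         call. = FALSE)
  }
  invisible(cells)
}

#' Vectorised exact Fisher odds ratios
#'
#' Batch form of [fisher_or()] over parallel vectors of cell counts.
#' Degenerate tables (an empty margin) get `NA` results rather than an
#' error, so screens over many tables can proceed.
#'
#' @inheritParams fisher_or
#' @return Tibble with columns `or_mle`, `ci_low`, `ci_high`, `p`,
#'   `sample_or`.
#' @export
fisher_or_batch <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(length(b) == length(a), length(c) == length(a),
            length(d) == length(a))
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0 &
    !is.na(a + b + c + d)
  out <- matrix(NA_real_, length(a), 5)
  colnames(out) <- c("or_mle", "ci_low", "ci_high", "p", "sample_or")
  if (any(ok)) {
    out[ok, ] <- .fisher_exact_batch(as.numeric(a[ok]), as.numeric(b[ok]),
                                     as.numeric(c[ok]), as.numeric(d[ok]),
                                     conf_level)
  }
  tibble::as_tibble(out)
}

#' @export
print.fisher_or <- function(x, ...) {
  cat(sprintf(
    "Fisher exact OR = %.3g (%d%% CI %.3g-%.3g), P = %.3g\n",
    x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high, x$p))
  cat(sprintf("  (conditional MLE; sample OR = %.3g)\n", x$sample_or))
  invisible(x)
}

#' @export
tidy.fisher_or <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    sample_or = x$sample_or,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$p,
    method = "Fisher exact (conditional MLE)"
  )
}
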