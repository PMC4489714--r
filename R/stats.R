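# Concordance and homogeneity statistics used when comparing manual and
# automated calls.

#' Cohen's kappa for two paired categorical raters
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o`
#' the observed agreement and `p_e` the agreement expected from the two
#' raters' marginal label frequencies. When both raters are constant and
#' identical (`p_e = 1`, `p_o = 1`) kappa is 1 by convention.
#'
#' @param a,b equal-length vectors of categorical labels over a shared
#'   label space.
#' @return kappa (dimensionless, at most 1).
#' @export
#' @examples
#' cohens_kappa(c("D", "D", "N", "N"), c("D", "N", "N", "N"))  # 0.5
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  if (length(a) == 0L) stop("empty input")
  a <- as.character(a)
  b <- as.character(b)
  if (anyNA(a) || anyNA(b)) stop("labels must not contain NA")
  lev <- union(a, b)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum((table(factor(a, lev)) / n) * (table(factor(b, lev)) / n))
  if (1 - p_e < .Machine$double.eps) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Concordance between two sets of paired calls
#'
#' Percent agreement plus Cohen's kappa, banded as `poor` (kappa < 0.6),
#' `good` (0.6 to 0.8) or `high` (kappa > 0.8).
#'
#' @param a,b equal-length label vectors (e.g. case categories from two
#'   analysis sources).
#' @return an object of class `fish_concordance` with `n_pairs`, `n_agree`,
#'   `percent_agreement`, `kappa` and `band`.
#' @export
#' @examples
#' agreement(rep("CODELETION", 5), c(rep("CODELETION", 4), "NORMAL"))
agreement <- function(a, b) {
  k <- cohens_kappa(a, b)
  n <- length(a)
  n_agree <- sum(as.character(a) == as.character(b))
  band <- if (k > 0.8) "high" else if (k >= 0.6) "good" else "poor"
  structure(
    list(n_pairs = n, n_agree = n_agree,
         percent_agreement = 100 * n_agree / n, kappa = k, band = band),
    class = "fish_concordance"
  )
}

#' @export
print.fish_concordance <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d (%s%%) - kappa = %s (%s agreement)\n",
              x$n_agree, x$n_pairs,
              formatC(x$percent_agreement, format = "f", digits = 2),
              formatC(x$kappa, format = "f", digits = 3), x$band))
  invisible(x)
}

#' Pearson chi-square test of homogeneity
#'
#' Group comparison on an r x c contingency table of counts, without
#' continuity correction, with the asymptotic p-value. Tables with a zero
#' row or column margin are rejected (expected counts undefined).
#'
#' @param table matrix (at least 2 x 2) of non-negative counts.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' chi_square_homogeneity(matrix(c(25, 15, 15, 25), 2))
chi_square_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table must be at least 2 x 2")
  }
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: expected counts are undefined; ",
         "drop the empty category before testing")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
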