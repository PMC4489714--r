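#' @keywords internal
"_PACKAGE"

# Nucleus classes, arm statuses and case categories used throughout.
NUCLEUS_CLASSES <- c("DELETION", "NORMAL", "IMBALANCED", "UNCLASSIFIED")
ARM_STATUSES <- c("DELETED", "NORMAL", "IMBALANCED", "UNDETERMINED")
CASE_CATEGORIES <- c(
  "CODELETION", "DELETION_1P", "DELETION_19Q", "NORMAL",
  "CO_IMBALANCE", "IMBALANCE_1P", "IMBALANCE_19Q", "UNDETERMINED"
)

#' Format green/red signal counts as "G/R" combination keys
#'
#' Combinations are written green-first ("G/R"), e.g. a nucleus with two
#' green (reference) and one red (marker) signal is `"2/1"`.
#'
#' @param green,red non-negative integer vectors of equal length.
#' @return character vector of `"G/R"` keys.
#' @export
#' @examples
#' combo_key(2, 1)
#' combo_key(c(2, 4), c(2, 2))
combo_key <- function(green, red) {
  check_counts(green, red)
  paste(green, red, sep = "/")
}

#' Parse "G/R" combination keys back into counts
#'
#' @param key character vector of `"G/R"` strings (green first).
#' @return data.frame with integer columns `green` and `red`.
#' @export
#' @examples
#' parse_combo(c("2/1", "4/2"))
parse_combo <- function(key) {
  parts <- strsplit(as.character(key), "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  mat <- suppressWarnings(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  bad <- bad | is.na(mat[1, ]) | is.na(mat[2, ]) | mat[1, ] < 0 | mat[2, ] < 0
  if (any(bad)) {
    stop("malformed combination key(s): ",
         paste(unique(key[bad]), collapse = ", "),
         " (expected \"G/R\" with non-negative integers)")
  }
  data.frame(green = mat[1, ], red = mat[2, ])
}

# Validate paired signal-count vectors. Counts must be non-negative
# integer-valued and of equal length.
check_counts <- function(green, red) {
  if (length(green) != length(red)) {
    stop("'green' and 'red' must have the same length")
  }
  for (nm in c("green", "red")) {
    x <- get(nm)
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != trunc(x))) {
      stop("'", nm, "' must contain non-negative integer counts")
    }
  }
  invisible(TRUE)
}

# Restore the RNG state on exit when a seed is supplied, so seeded calls do
# not perturb the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
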