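# Rule sets map per-nucleus G/R signal combinations to a nucleus class
# (DELETION / NORMAL / IMBALANCED / UNCLASSIFIED) and carry the case-level
# percentage cutoffs bound to that rule set.

# The 24 combinations of the fixed lookup, by class.
ALG2_CLASSES <- list(
  DELETION   = c("2/0", "2/1", "3/0", "3/1", "4/1", "4/2", "5/2", "6/2", "6/3"),
  NORMAL     = c("2/2", "1/2"),
  IMBALANCED = c("1/3", "1/4", "2/3", "2/4", "2/5", "3/3", "3/4",
                 "4/3", "4/4", "4/5", "5/4", "5/5", "5/6")
)

#' Construct a custom rule set
#'
#' A rule set is a named mapping from `"G/R"` signal combinations to nucleus
#' classes, plus the deletion and imbalance percentage cutoffs used when
#' calling an arm by the combination method. Combinations not listed are
#' classified `UNCLASSIFIED` (closed lookup). Use [ruleset_algorithm1()] for
#' the open ISPO-style grid.
#'
#' @param name identifier for the rule set.
#' @param classes named list with (any of) components `DELETION`, `NORMAL`,
#'   `IMBALANCED`, each a character vector of `"G/R"` keys (green first).
#' @param deletion_cutoff percentage of nuclei above which an arm is called
#'   deleted.
#' @param imbalance_cutoff percentage cutoff for the imbalanced call.
#' @return an object of class `fish_ruleset`.
#' @seealso [ruleset_algorithm1()], [ruleset_algorithm2()],
#'   [classify_combination()]
#' @export
#' @examples
#' rs <- fish_ruleset("mini", list(DELETION = "2/1", NORMAL = "2/2"), 55, 20)
#' classify_combination(c(2, 2, 3), c(1, 2, 3), rs)
fish_ruleset <- function(name, classes, deletion_cutoff, imbalance_cutoff) {
  stopifnot(is.character(name), length(name) == 1L)
  bad <- setdiff(names(classes), setdiff(NUCLEUS_CLASSES, "UNCLASSIFIED"))
  if (length(bad)) {
    stop("unknown class name(s) in 'classes': ", paste(bad, collapse = ", "))
  }
  keys <- unlist(classes, use.names = FALSE)
  parse_combo(keys)  # validates key syntax
  if (anyDuplicated(keys)) {
    stop("combination(s) assigned to more than one class: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  if ("0/0" %in% keys) stop("the 0/0 combination is never classified")
  check_cutoff(deletion_cutoff)
  check_cutoff(imbalance_cutoff)
  table <- rep(names(classes), lengths(classes))
  names(table) <- keys
  structure(
    list(name = name, kind = "lookup", table = table,
         deletion_cutoff = deletion_cutoff, imbalance_cutoff = imbalance_cutoff),
    class = "fish_ruleset"
  )
}

check_cutoff <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 100) {
    stop("cutoffs must be single percentages in [0, 100]")
  }
  invisible(TRUE)
}

#' Algorithm 1: the open ISPO-style analysis grid
#'
#' Classifies every combination except 0/0:
#' * `DELETION` when the red/green ratio is at most 0.5 (covers both simple
#'   deletion, red <= 1 as in 2/1 or 3/1, and relative deletion on a
#'   polysomic background, as in 4/2 or 6/3). The bound is inclusive:
#'   the grid's canonical exemplars (2/1, 4/2, 6/3) sit exactly at 0.5.
#' * `NORMAL` only for 2/2 (two intact copies, ratio 1).
#' * `IMBALANCED` for everything else (ratio above 0.5 but not 2/2).
#'   Nuclei with no green signal but red signals present have an undefined
#'   ratio, treated as exceeding every threshold, hence imbalanced.
#'
#' Case-level cutoffs are 55% (deletion) and 30% (imbalance).
#'
#' @return a `fish_ruleset` of kind `"grid"`.
#' @export
#' @examples
#' rs <- ruleset_algorithm1()
#' classify_combination(c(2, 4, 2, 4), c(1, 2, 2, 4), rs)
ruleset_algorithm1 <- function() {
  structure(
    list(name = "ALG1", kind = "grid", ratio_max = 0.5, normal = "2/2",
         deletion_cutoff = 55, imbalance_cutoff = 30),
    class = "fish_ruleset"
  )
}

#' Algorithm 2: the fixed 24-combination lookup
#'
#' The closed rule set retaining only combinations discriminant for one
#' chromosomal status subgroup: 9 deletion, 2 normal (2/2 and the truncation
#' product 1/2) and 13 imbalanced combinations (including the balanced
#' polysomies 3/3, 4/4, 5/5). Common but non-discriminant combinations
#' (1/1, 3/2) and all others fall to `UNCLASSIFIED`. Case-level cutoffs are
#' 55% (deletion) and 20% (imbalance).
#'
#' @return a `fish_ruleset` of kind `"lookup"` with 24 classified entries.
#' @export
#' @examples
#' rs <- ruleset_algorithm2()
#' classify_combination(c(2, 1, 1, 5), c(1, 2, 1, 5), rs)
ruleset_algorithm2 <- function() {
  rs <- fish_ruleset("ALG2", ALG2_CLASSES,
                     deletion_cutoff = 55, imbalance_cutoff = 20)
  rs
}

#' The 31-combination candidate table behind the fixed lookup
#'
#' The candidate set screened when deriving the 24-combination rule set:
#' combinations significantly associated with a chromosomal status subgroup
#' in at least one analysis source, grouped by their presumptive class under
#' the open-grid guidelines (10 deletion, 1 normal, 17 imbalanced and 3
#' unclassified combinations).
#'
#' @return data.frame with columns `combo` and `presumed_class` (31 rows).
#' @export
algorithm1_candidates <- function() {
  groups <- list(
    DELETION = c("2/0", "2/1", "3/0", "3/1", "4/1", "4/2", "5/1",
                 "5/2", "6/2", "6/3"),
    NORMAL = "2/2",
    IMBALANCED = c("1/2", "1/3", "1/4", "2/3", "2/4", "2/5", "3/2", "3/3",
                   "3/4", "4/3", "4/4", "4/5", "5/3", "5/4", "5/5", "5/6",
                   "6/4"),
    UNCLASSIFIED = c("0/2", "0/3", "1/1")
  )
  data.frame(
    combo = unlist(groups, use.names = FALSE),
    presumed_class = rep(names(groups), lengths(groups))
  )
}

#' Classify nuclei by their G/R signal combination
#'
#' Applies a rule set to paired per-nucleus signal counts. Nuclei with no
#' signal at all (0 green, 0 red) are never classified and are rejected here;
#' tallying functions exclude them before calling.
#'
#' @param green,red non-negative integer vectors of signal counts.
#' @param ruleset a [fish_ruleset] (see [ruleset_algorithm1()],
#'   [ruleset_algorithm2()]).
#' @return character vector of nucleus classes (`DELETION`, `NORMAL`,
#'   `IMBALANCED`, `UNCLASSIFIED`).
#' @export
#' @examples
#' classify_combination(2, 1, ruleset_algorithm2())
#' classify_combination(c(1, 3, 5), c(1, 2, 5), ruleset_algorithm2())
classify_combination <- function(green, red, ruleset) {
  stopifnot(inherits(ruleset, "fish_ruleset"))
  check_counts(green, red)
  if (any(green == 0 & red == 0)) {
    stop("uncounted nucleus: combination 0/0 is never classified ",
         "(exclude such nuclei before classification)")
  }
  if (ruleset$kind == "grid") {
    cls <- rep("IMBALANCED", length(green))
    # green == 0 leaves the ratio undefined -> treated as above any
    # threshold, so those nuclei stay in the residual imbalanced class.
    del <- green > 0 & (red / green) <= ruleset$ratio_max
    cls[del] <- "DELETION"
    cls[!del & combo_key(green, red) %in% ruleset$normal] <- "NORMAL"
    cls
  } else {
    cls <- unname(ruleset$table[combo_key(green, red)])
    cls[is.na(cls)] <- "UNCLASSIFIED"
    cls
  }
}

#' @export
print.fish_ruleset <- function(x, ...) {
  cat("FISH rule set:", x$name, sprintf("(%s)\n", x$kind))
  if (x$kind == "grid") {
    cat(sprintf("  DELETION  : R/G <= %g\n", x$ratio_max))
    cat(sprintf("  NORMAL    : %s\n", paste(x$normal, collapse = ", ")))
    cat("  IMBALANCED: all other combinations\n")
  } else {
    for (cl in intersect(NUCLEUS_CLASSES, unique(x$table))) {
      cat(sprintf("  %-10s: %s\n", cl,
                  paste(names(x$table)[x$table == cl], collapse = ", ")))
    }
    cat(sprintf("  (%d combinations classified; all others UNCLASSIFIED)\n",
                length(x$table)))
  }
  cat(sprintf("  cutoffs: deletion > %g%%, imbalance %g%%\n",
              x$deletion_cutoff, x$imbalance_cutoff))
  invisible(x)
}
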