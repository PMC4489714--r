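# Arm- and case-level calling: tally classified nuclei, apply the
# combination / ratio / combination+ratio counting methods, and combine the
# two arms into the case category.

CALL_METHODS <- c("combination", "ratio", "combination_ratio")

#' Tally classified nuclei for one chromosome arm
#'
#' Classifies each nucleus under the rule set and reports per-class
#' percentages and total signal sums. Nuclei with no signals (0/0) are
#' excluded from both numerator and denominator and reported separately.
#'
#' @param green,red per-nucleus signal counts for one case and arm.
#' @param ruleset a [fish_ruleset].
#' @param denominator `"counted"` (default: all non-0/0 nuclei, including
#'   unclassified ones, mirroring manual scoring of a fixed number of nuclei)
#'   or `"classified"` (unclassified nuclei also removed from the
#'   denominator).
#' @return an object of class `fish_tally`: counts and percentages per
#'   nucleus class, `n_counted`, `n_excluded`, `sum_green`, `sum_red`.
#' @export
#' @examples
#' t <- tally_arm(c(rep(2, 60), rep(2, 40)), c(rep(1, 60), rep(2, 40)),
#'                ruleset_algorithm2())
#' t$pct["DELETION"]
tally_arm <- function(green, red, ruleset,
                      denominator = c("counted", "classified")) {
  denominator <- match.arg(denominator)
  check_counts(green, red)
  keep <- !(green == 0 & red == 0)
  n_excluded <- sum(!keep)
  green <- green[keep]
  red <- red[keep]
  if (length(green) == 0L) {
    stop("no countable nuclei (all nuclei were 0/0 or input was empty)")
  }
  cls <- classify_combination(green, red, ruleset)
  counts <- vapply(NUCLEUS_CLASSES, function(k) sum(cls == k), integer(1))
  denom <- if (denominator == "classified") {
    sum(counts[setdiff(NUCLEUS_CLASSES, "UNCLASSIFIED")])
  } else {
    length(green)
  }
  if (denom == 0L) {
    stop("no countable nuclei (all nuclei unclassified under the ",
         "'classified' denominator)")
  }
  pct <- 100 * counts / denom
  if (denominator == "classified") pct["UNCLASSIFIED"] <- NA_real_
  structure(
    list(n_counted = length(green), n_excluded = n_excluded,
         denominator = denominator, n = counts, pct = pct,
         sum_green = sum(green), sum_red = sum(red)),
    class = "fish_tally"
  )
}

#' @export
print.fish_tally <- function(x, ...) {
  cat(sprintf("FISH arm tally: %d nuclei counted (%d excluded as 0/0)\n",
              x$n_counted, x$n_excluded))
  for (k in NUCLEUS_CLASSES) {
    cat(sprintf("  %-12s %4d  (%s%%)\n", k, x$n[[k]],
                formatC(x$pct[[k]], format = "f", digits = 2)))
  }
  cat(sprintf("  signals: %d green, %d red (R/G = %s)\n", x$sum_green,
              x$sum_red,
              if (x$sum_green > 0)
                formatC(x$sum_red / x$sum_green, format = "f", digits = 3)
              else "undefined"))
  invisible(x)
}

#' Arm status by the combination method
#'
#' Applies the rule set's percentage cutoffs to a tally. The imbalance
#' override comes first: an arm with more imbalanced nuclei than the
#' imbalance cutoff is imbalanced independently of its deletion status.
#' Otherwise the arm is deleted when the deleted-nucleus percentage strictly
#' exceeds the deletion cutoff; normal when deleted plus imbalanced nuclei
#' stay strictly below the imbalance cutoff; imbalanced otherwise.
#'
#' @param tally a [tally_arm()] result.
#' @param ruleset the [fish_ruleset] supplying the cutoffs.
#' @return one of `"DELETED"`, `"NORMAL"`, `"IMBALANCED"`.
#' @export
call_combination <- function(tally, ruleset) {
  stopifnot(inherits(tally, "fish_tally"), inherits(ruleset, "fish_ruleset"))
  pd <- tally$pct[["DELETION"]]
  pi <- tally$pct[["IMBALANCED"]]
  if (pi > ruleset$imbalance_cutoff) {
    "IMBALANCED"
  } else if (pd > ruleset$deletion_cutoff) {
    "DELETED"
  } else if (pd + pi < ruleset$imbalance_cutoff) {
    "NORMAL"
  } else {
    "IMBALANCED"
  }
}

#' Red/green signal ratio of a tally
#'
#' @param tally a [tally_arm()] result.
#' @return `sum_red / sum_green`, or `NA` when no green signal was counted.
#' @export
signal_ratio <- function(tally) {
  stopifnot(inherits(tally, "fish_tally"))
  if (tally$sum_green > 0) tally$sum_red / tally$sum_green else NA_real_
}

#' Arm status by the ratio method
#'
#' The total red/green signal ratio over all counted nuclei: a ratio of at
#' most 0.8 indicates deletion, a ratio in (0.8, 1.15] a normal arm, and a
#' ratio above 1.15 polysomy (imbalanced). With no green signals the ratio is
#' undefined and the arm is `UNDETERMINED`.
#'
#' @param tally a [tally_arm()] result.
#' @return one of `"DELETED"`, `"NORMAL"`, `"IMBALANCED"`, `"UNDETERMINED"`.
#' @export
call_ratio <- function(tally) {
  r <- signal_ratio(tally)
  if (is.na(r)) return("UNDETERMINED")
  if (r <= 0.8) "DELETED" else if (r <= 1.15) "NORMAL" else "IMBALANCED"
}

#' Merge combination- and ratio-method statuses
#'
#' Symmetric merge used by the combination+ratio method: equal statuses keep
#' that status; deleted in one method and normal in the other is deleted;
#' imbalanced in one method and deleted or normal in the other is imbalanced.
#' An undetermined input propagates.
#'
#' @param a,b arm statuses from the two methods.
#' @return the merged arm status.
#' @export
#' @examples
#' merge_methods("DELETED", "NORMAL")
#' merge_methods("IMBALANCED", "DELETED")
merge_methods <- function(a, b) {
  stopifnot(a %in% ARM_STATUSES, b %in% ARM_STATUSES)
  if (a == "UNDETERMINED" || b == "UNDETERMINED") return("UNDETERMINED")
  if (a == b) return(a)
  if ("IMBALANCED" %in% c(a, b)) return("IMBALANCED")
  "DELETED"  # the remaining mixed pair {DELETED, NORMAL}
}

#' Call the status of one chromosome arm
#'
#' Tallies the nuclei and dispatches to the requested counting method. Fails
#' the quality gate (status `UNDETERMINED`, with a diagnostic flag) when
#' fewer than `min_nuclei` countable nuclei are available — the failure mode
#' of faded archival slides — or, for the ratio leg, when no green signal was
#' counted.
#'
#' @param green,red per-nucleus signal counts for one case and arm.
#' @param ruleset a [fish_ruleset].
#' @param method `"combination"`, `"ratio"` or `"combination_ratio"`.
#' @param min_nuclei minimum countable nuclei required for a determinate
#'   call (default 100, the conventional manual scoring depth).
#' @param arm optional arm label (`"1p"` or `"19q"`) carried into the result.
#' @param denominator passed to [tally_arm()].
#' @return an object of class `fish_arm_call`: the tally, ratio, method,
#'   status and any QC flag.
#' @export
#' @examples
#' g <- c(rep(2, 120), rep(2, 80)); r <- c(rep(1, 120), rep(2, 80))
#' call_arm(g, r, ruleset_algorithm2(), "combination_ratio")$status
call_arm <- function(green, red, ruleset, method = CALL_METHODS,
                     min_nuclei = 100, arm = NA_character_,
                     denominator = "counted") {
  method <- match.arg(method, CALL_METHODS)
  tally <- tally_arm(green, red, ruleset, denominator = denominator)
  qc <- NA_character_
  if (tally$n_counted < min_nuclei) {
    qc <- sprintf("insufficient nuclei (%d < %d)", tally$n_counted, min_nuclei)
    status <- "UNDETERMINED"
  } else {
    status <- switch(method,
      combination = call_combination(tally, ruleset),
      ratio = call_ratio(tally),
      combination_ratio = merge_methods(call_combination(tally, ruleset),
                                        call_ratio(tally))
    )
    if (method != "combination" && tally$sum_green == 0) {
      qc <- "no green signals: ratio undefined"
    }
  }
  structure(
    list(arm = arm, method = method, tally = tally,
         ratio = signal_ratio(tally), status = status, qc = qc),
    class = "fish_arm_call"
  )
}

#' @export
print.fish_arm_call <- function(x, ...) {
  cat(sprintf("FISH arm call%s: %s (method: %s)\n",
              if (is.na(x$arm)) "" else paste0(" [", x$arm, "]"),
              x$status, x$method))
  if (!is.na(x$qc)) cat("  QC:", x$qc, "\n")
  print(x$tally)
  invisible(x)
}

#' Combine the two arm statuses into the case category
#'
#' Seven determinate categories partition the status pairs; an undetermined
#' arm makes the whole case undetermined. Mixed deleted/imbalanced pairs are
#' reported as imbalance of the imbalanced arm (the deletion on the other arm
#' remains visible in the per-arm calls).
#'
#' @param status_1p,status_19q arm statuses for 1p and 19q.
#' @return one of the case categories (`"CODELETION"`, `"DELETION_1P"`, ...).
#' @export
#' @examples
#' combine_arms("DELETED", "DELETED")
#' combine_arms("NORMAL", "IMBALANCED")
combine_arms <- function(status_1p, status_19q) {
  stopifnot(status_1p %in% ARM_STATUSES, status_19q %in% ARM_STATUSES)
  if (status_1p == "UNDETERMINED" || status_19q == "UNDETERMINED") {
    return("UNDETERMINED")
  }
  key <- paste(substr(status_1p, 1, 1), substr(status_19q, 1, 1))
  switch(key,
    "D D" = "CODELETION",
    "D N" = "DELETION_1P",
    "N D" = "DELETION_19Q",
    "N N" = "NORMAL",
    "I I" = "CO_IMBALANCE",
    "I N" = "IMBALANCE_1P",
    "N I" = "IMBALANCE_19Q",
    "D I" = "IMBALANCE_19Q",
    "I D" = "IMBALANCE_1P"
  )
}

#' Score a whole nucleus table
#'
#' Calls every case, source and arm in a nucleus table (see
#' [read_nucleus_table()] for the format) under one rule set and counting
#' method, then combines arms into case categories.
#'
#' @param nuclei data.frame with columns `case_id`, `arm` (`1p`/`19q`),
#'   `source` (`manual`/`automated`), `green`, `red` — one row per nucleus.
#' @param ruleset a [fish_ruleset].
#' @param method counting method, as in [call_arm()].
#' @param min_nuclei,denominator passed to [call_arm()].
#' @return an object of class `fish_report`: `arm_calls` (one row per case
#'   x source x arm) and `case_calls` (one row per case x source), plus the
#'   rule set and method used.
#' @export
score_series <- function(nuclei, ruleset, method = "combination_ratio",
                         min_nuclei = 100, denominator = "counted") {
  method <- match.arg(method, CALL_METHODS)
  nuclei <- validate_nucleus_table(nuclei)
  groups <- unique(nuclei[c("case_id", "source", "arm")])
  groups <- groups[order(groups$case_id, groups$source, groups$arm), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- nuclei$case_id == groups$case_id[i] &
      nuclei$source == groups$source[i] & nuclei$arm == groups$arm[i]
    ac <- call_arm(nuclei$green[sel], nuclei$red[sel], ruleset,
                   method = method, min_nuclei = min_nuclei,
                   arm = groups$arm[i], denominator = denominator)
    data.frame(
      case_id = groups$case_id[i], source = groups$source[i],
      arm = groups$arm[i], n_counted = ac$tally$n_counted,
      n_excluded = ac$tally$n_excluded,
      pct_deletion = ac$tally$pct[["DELETION"]],
      pct_normal = ac$tally$pct[["NORMAL"]],
      pct_imbalanced = ac$tally$pct[["IMBALANCED"]],
      pct_unclassified = ac$tally$pct[["UNCLASSIFIED"]],
      sum_green = ac$tally$sum_green, sum_red = ac$tally$sum_red,
      ratio = ac$ratio, status = ac$status, qc = ac$qc
    )
  })
  arm_calls <- do.call(rbind, rows)
  cases <- unique(arm_calls[c("case_id", "source")])
  case_rows <- lapply(seq_len(nrow(cases)), function(i) {
    sub <- arm_calls[arm_calls$case_id == cases$case_id[i] &
                       arm_calls$source == cases$source[i], ]
    s1p <- sub$status[sub$arm == "1p"]
    s19q <- sub$status[sub$arm == "19q"]
    if (length(s1p) != 1L) s1p <- "UNDETERMINED"
    if (length(s19q) != 1L) s19q <- "UNDETERMINED"
    data.frame(case_id = cases$case_id[i], source = cases$source[i],
               status_1p = s1p, status_19q = s19q,
               category = combine_arms(s1p, s19q))
  })
  structure(
    list(arm_calls = arm_calls, case_calls = do.call(rbind, case_rows),
         ruleset = ruleset, method = method, min_nuclei = min_nuclei),
    class = "fish_report"
  )
}

#' @export
print.fish_report <- function(x, ...) {
  cat(sprintf("FISH scoring report: %d case(s), rule set %s, method %s\n",
              length(unique(x$case_calls$case_id)), x$ruleset$name, x$method))
  print(x$case_calls, row.names = FALSE)
  invisible(x)
}

#' Triage manual/automated discordances in a scored report
#'
#' Compares the manual and automated arm statuses case by case. For a
#' discordant arm whose manual count is below `extend_to` nuclei, the
#' recommendation is to extend the manual count (the escalation that resolves
#' most discordances); an undetermined arm is flagged as having insufficient
#' cells; concordant arms accept the automated result.
#'
#' @param report a [score_series()] report containing both `manual` and
#'   `automated` sources (hence the same rule set and method on both sides).
#' @param extend_to manual count depth recommended for discordant cases
#'   (default 200 nuclei).
#' @return data.frame with one row per case x arm: statuses, concordance
#'   flag and recommendation.
#' @export
triage_discordance <- function(report, extend_to = 200) {
  stopifnot(inherits(report, "fish_report"))
  ac <- report$arm_calls
  if (!all(c("manual", "automated") %in% ac$source)) {
    stop("report must contain both 'manual' and 'automated' sources")
  }
  man <- ac[ac$source == "manual", ]
  aut <- ac[ac$source == "automated", ]
  key <- function(d) paste(d$case_id, d$arm)
  common <- intersect(key(man), key(aut))
  man <- man[match(common, key(man)), ]
  aut <- aut[match(common, key(aut)), ]
  concordant <- man$status == aut$status
  recommendation <- ifelse(
    man$status == "UNDETERMINED" | aut$status == "UNDETERMINED",
    "insufficient cells",
    ifelse(!concordant & man$n_counted < extend_to,
           sprintf("extend manual count to %d cells", extend_to),
           ifelse(!concordant, "review case", "accept automated result"))
  )
  data.frame(
    case_id = man$case_id, arm = man$arm,
    manual_status = man$status, automated_status = aut$status,
    manual_n = man$n_counted, automated_n = aut$n_counted,
    concordant = concordant, recommendation = recommendation
  )
}
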