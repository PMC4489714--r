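# Cutoff calibration from a non-neoplastic control series: a case is called
# abnormal only when its abnormal-nucleus percentage exceeds the mean + 3 SD
# of the same percentage across control tissue.

#' Mean + 3 SD cutoff from control percentages
#'
#' @param values per-control-case percentages of abnormal (deletion-class or
#'   imbalanced-class) nuclei. At least two controls are required for a
#'   defined standard deviation.
#' @return `mean(values) + 3 * sd(values)` (sample SD, n - 1 denominator).
#' @export
#' @examples
#' calibrate_cutoff(c(1, 2, 3))  # 2 + 3 * 1 = 5
calibrate_cutoff <- function(values) {
  if (!is.numeric(values) || any(is.na(values))) {
    stop("'values' must be numeric percentages without NA")
  }
  if (length(values) < 2L) {
    stop("insufficient controls: at least 2 values are needed for an SD")
  }
  mean(values) + 3 * stats::sd(values)
}

#' Recalibrate a rule set's cutoffs against a control series
#'
#' Tallies each control case per arm under the rule set, derives a
#' mean + 3 SD cutoff from the per-case deletion-class percentages and
#' another from the imbalanced-class percentages, and — since one shared
#' cutoff is used for both 1p and 19q — takes the maximum across arms.
#' The input rule set is not modified.
#'
#' @param controls nucleus table of non-neoplastic control cases (same
#'   format as [read_nucleus_table()]; the `source` column is ignored, all
#'   rows of a case/arm are pooled).
#' @param ruleset the [fish_ruleset] to recalibrate.
#' @param denominator passed to [tally_arm()].
#' @return a copy of `ruleset` with `deletion_cutoff` and `imbalance_cutoff`
#'   replaced; the per-arm calibration detail is attached as attribute
#'   `"calibration"`.
#' @export
calibrate_ruleset <- function(controls, ruleset, denominator = "counted") {
  stopifnot(inherits(ruleset, "fish_ruleset"))
  controls <- validate_nucleus_table(controls, require_source = FALSE)
  arms <- unique(controls$arm)
  per_arm <- lapply(arms, function(a) {
    sub <- controls[controls$arm == a, ]
    cases <- unique(sub$case_id)
    if (length(cases) < 2L) {
      stop("insufficient controls for arm ", a,
           ": at least 2 control cases are needed")
    }
    pct <- t(vapply(cases, function(cid) {
      tl <- tally_arm(sub$green[sub$case_id == cid],
                      sub$red[sub$case_id == cid],
                      ruleset, denominator = denominator)
      c(deletion = tl$pct[["DELETION"]], imbalanced = tl$pct[["IMBALANCED"]])
    }, numeric(2)))
    data.frame(arm = a, n_controls = length(cases),
               deletion_cutoff = calibrate_cutoff(pct[, "deletion"]),
               imbalance_cutoff = calibrate_cutoff(pct[, "imbalanced"]))
  })
  detail <- do.call(rbind, per_arm)
  out <- ruleset
  out$deletion_cutoff <- max(detail$deletion_cutoff)
  out$imbalance_cutoff <- max(detail$imbalance_cutoff)
  attr(out, "calibration") <- detail
  out
}
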