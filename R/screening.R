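# Per-combination association screening: the procedure that reduces the open
# candidate grid to a closed, discriminant rule set. Each G/R combination's
# per-case frequency is regressed (univariate logistic, one subgroup vs the
# rest) on membership of each chromosomal status subgroup, separately for
# the manual and the automated source; only combinations significant (with a
# positive effect) for the same subgroup in BOTH sources are retained.

#' Screen G/R combinations for association with chromosomal status
#'
#' For every combination, status subgroup and analysis source, fits a
#' univariate logistic regression of subgroup membership (one-vs-rest) on
#' the combination's per-case frequency and takes the likelihood-ratio
#' p-value. Complete or quasi-complete separation (common at small case
#' counts) is detected and that test falls back to a Fisher exact test on
#' the frequency dichotomized at its median. A combination is selected when
#' some subgroup reaches `p < alpha` with a positive association in both the
#' manual and the automated analysis; its assigned subgroup is the one with
#' the strongest consistent association (smallest worse-source p).
#'
#' @param freqs long data.frame with columns `case_id`, `source` (`manual` /
#'   `automated`), `status` (the case's chromosomal status subgroup),
#'   `combo` (`"G/R"` key) and `freq` (percent of the case's nuclei showing
#'   that combination). Missing case/combo pairs are treated as frequency 0.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default, plain per-test threshold) or `"BH"`
#'   (Benjamini-Hochberg within each source and subgroup).
#' @param deletion_cutoff,imbalance_cutoff cutoffs given to the drafted rule
#'   set (defaults 55 and 20; recalibrate with [calibrate_ruleset()]).
#' @return an object of class `fish_screening`: `tests` (one row per combo x
#'   subgroup x source: p-value, direction, separation flag), `selected`
#'   (one row per combo: selected flag, assigned subgroup) and `ruleset`
#'   (draft [fish_ruleset] built from the assignments).
#' @export
screen_combinations <- function(freqs, alpha = 0.05,
                                adjust = c("none", "BH"),
                                deletion_cutoff = 55, imbalance_cutoff = 20) {
  adjust <- match.arg(adjust)
  need <- c("case_id", "source", "status", "combo", "freq")
  if (!all(need %in% names(freqs))) {
    stop("'freqs' must have columns ", paste(need, collapse = ", "))
  }
  statuses <- sort(unique(as.character(freqs$status)))
  if (length(statuses) < 2L) stop("at least 2 status subgroups are required")
  sources <- sort(unique(as.character(freqs$source)))
  combos <- sort(unique(as.character(freqs$combo)))
  parse_combo(combos)

  tests <- list()
  for (src in sources) {
    sub <- freqs[freqs$source == src, ]
    cases <- unique(sub$case_id)
    status_of <- sub$status[match(cases, sub$case_id)]
    # case x combo frequency matrix, absent pairs = 0
    fm <- matrix(0, length(cases), length(combos),
                 dimnames = list(cases, combos))
    fm[cbind(match(sub$case_id, cases), match(sub$combo, combos))] <- sub$freq
    for (cb in combos) {
      x <- fm[, cb]
      for (st in statuses) {
        y <- as.integer(status_of == st)
        tests[[length(tests) + 1L]] <-
          cbind(data.frame(combo = cb, subgroup = st, source = src),
                combo_association(x, y))
      }
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- tests$p
  if (adjust == "BH") {
    for (src in sources) {
      for (st in statuses) {
        sel <- tests$source == src & tests$subgroup == st
        tests$p_adj[sel] <- stats::p.adjust(tests$p[sel], "BH")
      }
    }
  }

  # Selection: p < alpha with positive direction in every source, same
  # subgroup; assignment minimizes the worse-source p.
  selected <- data.frame(combo = combos, selected = FALSE,
                         subgroup = NA_character_, p_max = NA_real_)
  for (i in seq_along(combos)) {
    tc <- tests[tests$combo == combos[i], ]
    best_p <- Inf
    best_st <- NA_character_
    for (st in statuses) {
      ts <- tc[tc$subgroup == st, ]
      ok <- all(ts$p_adj < alpha & ts$direction > 0)
      if (ok && max(ts$p_adj) < best_p) {
        best_p <- max(ts$p_adj)
        best_st <- st
      }
    }
    if (!is.na(best_st)) {
      selected$selected[i] <- TRUE
      selected$subgroup[i] <- best_st
      selected$p_max[i] <- best_p
    }
  }

  class_of <- c(DELETED = "DELETION", NORMAL = "NORMAL",
                IMBALANCED = "IMBALANCED")
  sel <- selected[selected$selected & selected$subgroup %in% names(class_of), ]
  classes <- split(sel$combo, class_of[sel$subgroup])
  ruleset <- if (length(classes)) {
    fish_ruleset("screened", classes, deletion_cutoff, imbalance_cutoff)
  } else NULL
  structure(list(tests = tests, selected = selected, ruleset = ruleset,
                 alpha = alpha, adjust = adjust),
            class = "fish_screening")
}

# One univariate association test: logistic LRT, Fisher fallback under
# separation. x = per-case frequency (%), y = 0/1 subgroup membership.
combo_association <- function(x, y) {
  if (stats::var(x) == 0) {
    # constant frequency carries no information
    return(data.frame(p = 1, direction = 0, separation = FALSE,
                      test = "degenerate"))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coef_x <- stats::coef(fit)[["x"]]
  if (separated || abs(coef_x) > 15) {
    tab <- table(factor(x > stats::median(x), c(FALSE, TRUE)),
                 factor(y, c(0, 1)))
    ft <- stats::fisher.test(tab)
    return(data.frame(p = ft$p.value,
                      direction = sign(log(unname(ft$estimate))),
                      separation = TRUE, test = "fisher"))
  }
  lrt <- fit$null.deviance - fit$deviance
  data.frame(p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
             direction = sign(coef_x), separation = FALSE, test = "logistic")
}

#' @export
print.fish_screening <- function(x, ...) {
  n_sel <- sum(x$selected$selected)
  cat(sprintf("Combination screening: %d/%d combinations selected (alpha = %g%s)\n",
              n_sel, nrow(x$selected), x$alpha,
              if (x$adjust == "BH") ", BH-adjusted" else ""))
  if (n_sel) {
    sel <- x$selected[x$selected$selected, ]
    for (st in unique(sel$subgroup)) {
      cat(sprintf("  %-10s: %s\n", st,
                  paste(sel$combo[sel$subgroup == st], collapse = ", ")))
    }
  }
  invisible(x)
}
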