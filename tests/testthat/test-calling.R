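rs2 <- ruleset_algorithm2()

test_that("tallies report per-class percentages and signal sums", {
  x <- expand_counts("2/2", 100)
  t <- tally_arm(x$green, x$red, rs2)
  expect_equal(t$pct[["NORMAL"]], 100)
  expect_equal(c(t$sum_green, t$sum_red), c(200, 200))

  x <- expand_counts(c("2/1", "2/2"), c(60, 40))
  t <- tally_arm(x$green, x$red, rs2)
  expect_equal(t$pct[["DELETION"]], 60)
  expect_equal(t$pct[["NORMAL"]], 40)

  x <- expand_counts(c("2/1", "1/1", "2/2"), c(50, 30, 20))
  t <- tally_arm(x$green, x$red, rs2)
  expect_equal(t$pct[["DELETION"]], 50)
  expect_equal(t$pct[["UNCLASSIFIED"]], 30)
  expect_equal(t$pct[["NORMAL"]], 20)
  expect_equal(sum(t$pct), 100)

  expect_error(tally_arm(integer(0), integer(0), rs2), "no countable nuclei")
  expect_error(tally_arm(c(0, 0), c(0, 0), rs2), "no countable nuclei")
})

test_that("combination-method clauses fire as specified", {
  mk <- function(pd, pi) {
    # fabricate a tally with the requested percentages on a 100-nucleus arm
    x <- expand_counts(c("2/1", "3/3", "2/2"), c(pd, pi, 100 - pd - pi))
    tally_arm(x$green, x$red, rs2)
  }
  expect_equal(call_combination(mk(60, 5), rs2), "DELETED")
  expect_equal(call_combination(mk(10, 25), rs2), "IMBALANCED")  # override
  expect_equal(call_combination(mk(5, 5), rs2), "NORMAL")
  expect_equal(call_combination(mk(40, 10), rs2), "IMBALANCED")
})

test_that("combination truth table is exhaustive at 1% resolution", {
  # clause oracle, written out independently of the implementation
  oracle <- function(pd, pi, dc, ic) {
    fired <- c(imb_override = pi > ic,
               deleted = !(pi > ic) && pd > dc,
               normal = !(pi > ic) && !(pd > dc) && (pd + pi < ic),
               residual = !(pi > ic) && !(pd > dc) && !(pd + pi < ic))
    expect_equal(sum(fired), 1L)
    c("IMBALANCED", "DELETED", "NORMAL", "IMBALANCED")[which(fired)]
  }
  grid <- expand.grid(pd = seq(0, 100, 1), pi = seq(0, 100, 1))
  grid <- grid[grid$pd + grid$pi <= 100, ]
  for (i in seq_len(nrow(grid))) {
    pd <- grid$pd[i]; pi <- grid$pi[i]
    x <- expand_counts(c("2/1", "3/3", "2/2"), c(pd, pi, 100 - pd - pi))
    t <- tally_arm(x$green, x$red, rs2)
    expect_equal(call_combination(t, rs2),
                 oracle(pd, pi, rs2$deletion_cutoff, rs2$imbalance_cutoff))
  }
})

test_that("ratio-method thresholds are inclusive at 0.8 and 1.15", {
  mk <- function(green_total, red_total) {
    # one polysomic nucleus carrying all signals keeps sums exact
    tally_arm(green_total, red_total, rs2)
  }
  expect_equal(call_ratio(mk(100, 80)), "DELETED")    # ratio exactly 0.8
  expect_equal(call_ratio(mk(100, 81)), "NORMAL")
  expect_equal(call_ratio(mk(200, 200)), "NORMAL")    # ratio 1
  expect_equal(call_ratio(mk(100, 115)), "NORMAL")    # ratio exactly 1.15
  expect_equal(call_ratio(mk(100, 116)), "IMBALANCED")
  expect_equal(call_ratio(tally_arm(0, 3, rs2)), "UNDETERMINED")
})

test_that("method merge follows its two rules on all determined pairs", {
  det <- c("DELETED", "NORMAL", "IMBALANCED")
  for (a in det) for (b in det) {
    expected <- if (a == b) a
      else if ("IMBALANCED" %in% c(a, b)) "IMBALANCED"
      else "DELETED"
    expect_equal(merge_methods(a, b), expected)
    expect_equal(merge_methods(a, b), merge_methods(b, a))  # symmetric
    expect_equal(merge_methods(a, a), a)                    # idempotent
  }
  expect_equal(merge_methods("UNDETERMINED", "DELETED"), "UNDETERMINED")
  expect_equal(merge_methods("NORMAL", "UNDETERMINED"), "UNDETERMINED")
})

test_that("arm calls dispatch methods and apply the nucleus quality gate", {
  x <- expand_counts(c("2/1", "2/2"), c(120, 80))
  ac <- call_arm(x$green, x$red, rs2, "combination_ratio")
  # pct_deletion 60 > 55 -> deleted; ratio (120+160)/(240+160) = 0.7 -> deleted
  expect_equal(ac$status, "DELETED")
  expect_equal(ac$ratio, 280 / 400)

  x <- expand_counts("2/1", 50)
  ac <- call_arm(x$green, x$red, rs2, "combination", min_nuclei = 100)
  expect_equal(ac$status, "UNDETERMINED")
  expect_match(ac$qc, "insufficient nuclei")

  x <- expand_counts("2/2", 100)
  for (m in c("combination", "ratio", "combination_ratio")) {
    expect_equal(call_arm(x$green, x$red, rs2, m)$status, "NORMAL")
  }
  expect_error(call_arm(x$green, x$red, rs2, "banana"), "arg")
})

test_that("arm-status pairs map onto the seven case categories", {
  expect_equal(combine_arms("DELETED", "DELETED"), "CODELETION")
  expect_equal(combine_arms("DELETED", "NORMAL"), "DELETION_1P")
  expect_equal(combine_arms("NORMAL", "DELETED"), "DELETION_19Q")
  expect_equal(combine_arms("NORMAL", "NORMAL"), "NORMAL")
  expect_equal(combine_arms("IMBALANCED", "IMBALANCED"), "CO_IMBALANCE")
  expect_equal(combine_arms("IMBALANCED", "NORMAL"), "IMBALANCE_1P")
  expect_equal(combine_arms("NORMAL", "IMBALANCED"), "IMBALANCE_19Q")
  # mixed deleted/imbalanced pairs report the imbalanced arm
  expect_equal(combine_arms("DELETED", "IMBALANCED"), "IMBALANCE_19Q")
  expect_equal(combine_arms("IMBALANCED", "DELETED"), "IMBALANCE_1P")
  expect_equal(combine_arms("UNDETERMINED", "DELETED"), "UNDETERMINED")
})

test_that("0/0 nuclei change no percentage and no call", {
  x <- expand_counts(c("2/1", "2/2", "3/3"), c(120, 60, 20))
  base <- call_arm(x$green, x$red, rs2, "combination_ratio")
  padded <- rbind(x, data.frame(green = rep(0, 57), red = rep(0, 57)))
  with0 <- call_arm(padded$green, padded$red, rs2, "combination_ratio")
  expect_equal(with0$status, base$status)
  expect_equal(with0$tally$pct, base$tally$pct)
  expect_equal(with0$tally$n_excluded, 57)
})

test_that("duplicating every nucleus leaves ratio and status unchanged", {
  x <- expand_counts(c("2/1", "2/2", "4/4"), c(80, 30, 10))
  base <- call_arm(x$green, x$red, rs2, "ratio")
  dup <- rbind(x, x)
  doubled <- call_arm(dup$green, dup$red, rs2, "ratio")
  expect_equal(doubled$ratio, base$ratio)
  expect_equal(doubled$status, base$status)
})

test_that("arm logic is symmetric: swapping arm labels swaps the category", {
  sim <- simulate_series(n_per_status = 1, n_nuclei = 150, seed = 11)
  nuc <- sim$nuclei
  rep1 <- score_series(nuc, rs2)
  swapped <- nuc
  swapped$arm <- ifelse(nuc$arm == "1p", "19q", "1p")
  rep2 <- score_series(swapped, rs2)
  m <- match(paste(rep1$case_calls$case_id, rep1$case_calls$source),
             paste(rep2$case_calls$case_id, rep2$case_calls$source))
  expect_equal(rep1$case_calls$status_1p, rep2$case_calls$status_19q[m])
  swap_cat <- function(x) {
    chartr_map <- c(CODELETION = "CODELETION", DELETION_1P = "DELETION_19Q",
                    DELETION_19Q = "DELETION_1P", NORMAL = "NORMAL",
                    CO_IMBALANCE = "CO_IMBALANCE",
                    IMBALANCE_1P = "IMBALANCE_19Q",
                    IMBALANCE_19Q = "IMBALANCE_1P",
                    UNDETERMINED = "UNDETERMINED")
    unname(chartr_map[x])
  }
  expect_equal(swap_cat(rep1$case_calls$category), rep2$case_calls$category[m])
})

test_that("discordance triage recommends the 200-cell escalation", {
  rs <- rs2
  # concordant case: both sources deleted on both arms
  del <- expand_counts("2/1", 100)
  nrm <- expand_counts("2/2", 100)
  mk <- function(case, arm, source, counts) {
    data.frame(case_id = case, arm = arm, source = source, counts)
  }
  nuc <- rbind(
    mk("A", "1p", "manual", del), mk("A", "1p", "automated", del),
    mk("A", "19q", "manual", del), mk("A", "19q", "automated", del),
    # discordant arm, manual scored at only 100 nuclei
    mk("B", "1p", "manual", nrm), mk("B", "1p", "automated", del),
    mk("B", "19q", "manual", del), mk("B", "19q", "automated", del),
    # automated side with too few identifiable cells
    mk("C", "1p", "manual", del), mk("C", "1p", "automated", del[1:40, ]),
    mk("C", "19q", "manual", del), mk("C", "19q", "automated", del)
  )
  tri <- triage_discordance(score_series(nuc, rs, "combination_ratio"))
  get <- function(case, arm) tri$recommendation[tri$case_id == case & tri$arm == arm]
  expect_equal(get("A", "1p"), "accept automated result")
  expect_equal(get("B", "1p"), "extend manual count to 200 cells")
  expect_false(tri$concordant[tri$case_id == "B" & tri$arm == "1p"])
  expect_equal(get("C", "1p"), "insufficient cells")

  only_manual <- nuc[nuc$source == "manual", ]
  expect_error(triage_discordance(score_series(only_manual, rs)),
               "both 'manual' and 'automated'")
})
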