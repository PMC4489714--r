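rs1 <- ruleset_algorithm1()
rs2 <- ruleset_algorithm2()

test_that("the fixed lookup classifies exactly 24 combinations, 9/2/13", {
  expect_length(rs2$table, 24)
  expect_equal(sum(rs2$table == "DELETION"), 9)
  expect_equal(sum(rs2$table == "NORMAL"), 2)
  expect_equal(sum(rs2$table == "IMBALANCED"), 13)
  expect_setequal(names(rs2$table)[rs2$table == "DELETION"],
                  c("2/0", "2/1", "3/0", "3/1", "4/1", "4/2", "5/2", "6/2", "6/3"))
  expect_setequal(names(rs2$table)[rs2$table == "NORMAL"], c("2/2", "1/2"))
  expect_setequal(names(rs2$table)[rs2$table == "IMBALANCED"],
                  c("1/3", "1/4", "2/3", "2/4", "2/5", "3/3", "3/4",
                    "4/3", "4/4", "4/5", "5/4", "5/5", "5/6"))
  expect_equal(c(rs2$deletion_cutoff, rs2$imbalance_cutoff), c(55, 20))
  expect_equal(c(rs1$deletion_cutoff, rs1$imbalance_cutoff), c(55, 30))
})

test_that("lookup classification matches its published exemplars", {
  expect_equal(classify_combination(2, 1, rs2), "DELETION")
  expect_equal(classify_combination(1, 2, rs2), "NORMAL")
  expect_equal(classify_combination(1, 1, rs2), "UNCLASSIFIED")
  expect_equal(classify_combination(3, 2, rs2), "UNCLASSIFIED")
  expect_equal(classify_combination(5, 5, rs2), "IMBALANCED")
})

test_that("the open grid covers every non-0/0 combination", {
  g <- expand.grid(green = 0:8, red = 0:8)
  g <- g[!(g$green == 0 & g$red == 0), ]
  cls <- classify_combination(g$green, g$red, rs1)
  expect_true(all(cls %in% c("DELETION", "NORMAL", "IMBALANCED")))
  # deletion iff the ratio is defined and at most 0.5 (inclusive bound:
  # the canonical exemplars 2/1, 4/2, 6/3 sit exactly at 0.5)
  expect_equal(cls == "DELETION", g$green > 0 & g$red / g$green <= 0.5)
  # the only normal combination is 2/2
  expect_equal(which(cls == "NORMAL"), which(g$green == 2 & g$red == 2))
  # undefined ratio (no green signal) falls to the imbalanced residual
  expect_true(all(cls[g$green == 0] == "IMBALANCED"))
})

test_that("grid classification matches its published exemplars", {
  expect_equal(classify_combination(2, 1, rs1), "DELETION")
  expect_equal(classify_combination(4, 2, rs1), "DELETION")
  expect_equal(classify_combination(6, 3, rs1), "DELETION")
  expect_equal(classify_combination(1, 0, rs1), "DELETION")
  expect_equal(classify_combination(2, 2, rs1), "NORMAL")
  expect_equal(classify_combination(4, 4, rs1), "IMBALANCED")
  expect_equal(classify_combination(0, 2, rs1), "IMBALANCED")
})

test_that("lookup agrees with the grid except for its documented redefinitions", {
  g <- expand.grid(green = 0:8, red = 0:8)
  g <- g[!(g$green == 0 & g$red == 0), ]
  c1 <- classify_combination(g$green, g$red, rs1)
  c2 <- classify_combination(g$green, g$red, rs2)
  keys <- combo_key(g$green, g$red)
  classified <- c2 != "UNCLASSIFIED"
  # every deletion combination of the lookup is deletion under the grid too
  expect_true(all(c1[c2 == "DELETION"] == "DELETION"))
  expect_equal(c2[keys == "2/2"], c1[keys == "2/2"])
  # the balanced polysomies 3/3, 4/4, 5/5 are imbalanced under both rule
  # sets (the grid's residual clause already covers them), so the only
  # classified disagreement is the redefinition of 1/2 (imbalanced -> normal)
  expect_equal(keys[classified & c1 != c2], "1/2")
  expect_true(all(c2[keys %in% c("3/3", "4/4", "5/5")] == "IMBALANCED"))
  # candidate combinations dropped by the lookup
  cand <- algorithm1_candidates()
  expect_setequal(setdiff(cand$combo, names(rs2$table)),
                  c("5/1", "3/2", "5/3", "6/4", "0/2", "0/3", "1/1"))
})

test_that("the candidate table holds 31 combinations in its four groups", {
  cand <- algorithm1_candidates()
  expect_equal(nrow(cand), 31)
  expect_equal(as.vector(table(cand$presumed_class)[c(
    "DELETION", "NORMAL", "IMBALANCED", "UNCLASSIFIED")]), c(10L, 1L, 17L, 3L))
  expect_false(anyDuplicated(cand$combo) > 0)
})

test_that("classification is pure and vectorization-consistent", {
  g <- expand.grid(green = 0:6, red = 0:6)
  g <- g[!(g$green == 0 & g$red == 0), ]
  for (rs in list(rs1, rs2)) {
    v1 <- classify_combination(g$green, g$red, rs)
    v2 <- classify_combination(g$green, g$red, rs)
    expect_identical(v1, v2)
    one_by_one <- mapply(function(gg, rr) classify_combination(gg, rr, rs),
                         g$green, g$red)
    expect_equal(v1, unname(one_by_one))
  }
})

test_that("0/0 and invalid counts are rejected", {
  expect_error(classify_combination(0, 0, rs2), "uncounted nucleus")
  expect_error(classify_combination(c(2, 0), c(1, 0), rs1), "uncounted")
  expect_error(classify_combination(-1, 2, rs2), "non-negative")
  expect_error(classify_combination(1.5, 2, rs2), "non-negative")
})

test_that("custom rule sets validate their construction", {
  rs <- fish_ruleset("custom", list(DELETION = c("2/1"), NORMAL = "2/2"),
                     50, 25)
  expect_equal(classify_combination(2, 1, rs), "DELETION")
  expect_equal(classify_combination(7, 7, rs), "UNCLASSIFIED")
  expect_error(fish_ruleset("x", list(DELETION = "2/1", NORMAL = "2/1"),
                            55, 20), "more than one class")
  expect_error(fish_ruleset("x", list(DELETION = "0/0"), 55, 20), "0/0")
  expect_error(fish_ruleset("x", list(BAD = "2/1"), 55, 20), "unknown class")
  expect_error(fish_ruleset("x", list(DELETION = "2-1"), 55, 20), "malformed")
})
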