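# Independent oracles and small fixture builders shared across tests.

# Closed-form Pearson chi-square statistic for a 2x2 table, computed from
# first principles (no chisq.test).
pearson_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}

# Cohen's kappa from a 2x2 agreement table, by the textbook marginal
# formula (independent of the package's label-vector implementation).
kappa_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (1 - p_e < .Machine$double.eps) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

# Expand a 2x2 agreement table into two paired label vectors.
labels_from_2x2 <- function(a, b, c, d) {
  list(
    a = c(rep("X", a + b), rep("Y", c + d)),
    b = c(rep("X", a), rep("Y", b), rep("X", c), rep("Y", d))
  )
}

# Replicate per-nucleus counts: n_of[i] nuclei with combination combos[i].
expand_counts <- function(combos, n_of) {
  gr <- parse_combo(combos)
  data.frame(green = rep(gr$green, n_of), red = rep(gr$red, n_of))
}

# Two-sample permutation test on a difference in group means; oracle for
# the association screening.
perm_test <- function(x, member, n_perm = 2000, seed = 1) {
  stat <- abs(mean(x[member]) - mean(x[!member]))
  set.seed(seed)
  null <- replicate(n_perm, {
    p <- sample(member)
    abs(mean(x[p]) - mean(x[!p]))
  })
  mean(c(null, stat) >= stat)
}
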