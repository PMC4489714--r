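# Synthetic FISH-count generator. Emulates per-nucleus G/R counts from
# paraffin sections: clonal tumor genotypes mixed with contaminating normal
# (2,2) cells, per-signal Bernoulli loss for nuclear truncation, and a small
# per-nucleus chance of one spurious extra signal. Every experiment in the
# test suite runs against this generator, with known ground truth.

SIM_STATUSES <- c("DELETED", "NORMAL", "IMBALANCED")

# Default tumor-clone genotypes per true arm status: simple deletion 2/1,
# intact 2/2, balanced polysomy 3/3.
default_clones <- function(status) {
  switch(status,
    DELETED = list(genotypes = matrix(c(2, 1), 1), fractions = 1),
    NORMAL = list(genotypes = matrix(c(2, 2), 1), fractions = 1),
    IMBALANCED = list(genotypes = matrix(c(3, 3), 1), fractions = 1),
    stop("unknown status: ", status)
  )
}

#' Simulate observed signal counts for nuclei of one genotype
#'
#' Each true signal is retained independently with probability
#' `1 - p_loss` (nuclear truncation removes part of the nucleus and the
#' signals in it); with probability `p_gain` one spurious extra signal of a
#' uniformly chosen color is added (hybridization noise, signal splitting).
#'
#' @param n number of nuclei to draw.
#' @param genotype length-2 integer vector `c(green, red)` of true copy
#'   numbers.
#' @param p_loss per-signal loss probability in `[0, 1)`.
#' @param p_gain per-nucleus probability of one extra signal.
#' @return data.frame with integer columns `green` and `red` (`n` rows).
#' @export
#' @examples
#' simulate_nuclei(5, c(2, 2), p_loss = 0, p_gain = 0)  # all 2/2
simulate_nuclei <- function(n, genotype, p_loss = 0.07, p_gain = 0.02) {
  stopifnot(length(genotype) == 2L, n >= 0)
  check_counts(genotype[1], genotype[2])
  if (p_loss < 0 || p_loss >= 1 || p_gain < 0 || p_gain >= 1) {
    stop("'p_loss' and 'p_gain' must lie in [0, 1)")
  }
  green <- stats::rbinom(n, genotype[1], 1 - p_loss)
  red <- stats::rbinom(n, genotype[2], 1 - p_loss)
  gain <- stats::runif(n) < p_gain
  to_green <- gain & stats::runif(n) < 0.5
  green <- green + as.integer(to_green)
  red <- red + as.integer(gain & !to_green)
  data.frame(green = green, red = red)
}

#' Simulate one case's nucleus table
#'
#' Draws `n_nuclei` nuclei per arm from a mixture of tumor clones (fraction
#' `tumor_fraction`) and contaminating normal 2/2 cells, each passed through
#' the truncation/gain noise model. Arms are simulated independently with
#' their own true status.
#'
#' @param case_id case identifier.
#' @param status_1p,status_19q true arm status (`DELETED`, `NORMAL`,
#'   `IMBALANCED`).
#' @param n_nuclei nuclei per arm.
#' @param tumor_fraction proportion of tumor nuclei; the rest are normal
#'   (2,2) cells.
#' @param p_loss,p_gain noise parameters, see [simulate_nuclei()].
#' @param clones optional named list (`"1p"`, `"19q"`) of clone structures
#'   `list(genotypes = <k x 2 matrix>, fractions = <k>)`; defaults per
#'   status: deleted 2/1, normal 2/2, imbalanced 3/3.
#' @param source label written into the `source` column.
#' @return list with `nuclei` (case_id, arm, source, green, red) and
#'   `truth` (case_id, arm, true_status).
#' @export
simulate_case <- function(case_id, status_1p, status_19q, n_nuclei = 300,
                          tumor_fraction = 0.7, p_loss = 0.07, p_gain = 0.02,
                          clones = NULL, source = "automated") {
  statuses <- c("1p" = match.arg(status_1p, SIM_STATUSES),
                "19q" = match.arg(status_19q, SIM_STATUSES))
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop("'tumor_fraction' must lie in [0, 1]")
  }
  arms <- lapply(names(statuses), function(arm) {
    cl <- if (!is.null(clones) && !is.null(clones[[arm]])) clones[[arm]]
          else default_clones(statuses[[arm]])
    if (abs(sum(cl$fractions) - 1) > 1e-8 || any(cl$fractions < 0)) {
      stop("clone fractions must be non-negative and sum to 1")
    }
    n_tumor <- stats::rbinom(1, n_nuclei, tumor_fraction)
    clone_of <- if (nrow(cl$genotypes) == 1L) rep(1L, n_tumor) else
      sample.int(nrow(cl$genotypes), n_tumor, replace = TRUE,
                 prob = cl$fractions)
    parts <- lapply(seq_len(nrow(cl$genotypes)), function(k) {
      simulate_nuclei(sum(clone_of == k), cl$genotypes[k, ], p_loss, p_gain)
    })
    parts <- c(parts,
               list(simulate_nuclei(n_nuclei - n_tumor, c(2, 2),
                                    p_loss, p_gain)))
    counts <- do.call(rbind, parts)
    data.frame(case_id = case_id, arm = arm, source = source, counts)
  })
  truth <- data.frame(case_id = case_id, arm = names(statuses),
                      true_status = unname(statuses))
  list(nuclei = do.call(rbind, arms), truth = truth)
}

#' Simulate a multi-case series with manual and automated views
#'
#' Generates a balanced series (`n_per_status` cases per true status, the
#' same status on both arms of a case) and emits two views of each case: the
#' full `automated` table (`n_nuclei` nuclei per arm, emulating software
#' screening of whole sections) and a `manual` view subsampled to
#' `manual_n` nuclei per arm (the conventional 100-nucleus manual count).
#' Reproducible under a fixed seed.
#'
#' @param n_per_status cases per status group.
#' @param statuses status groups to include.
#' @param n_nuclei automated nuclei per arm.
#' @param manual_n nuclei per arm in the manual view (capped at `n_nuclei`).
#' @param tumor_fraction,p_loss,p_gain,clones passed to [simulate_case()].
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @return an object of class `fish_sim`: `nuclei` (both sources) and
#'   `truth` tables, plus the generating parameters.
#' @export
#' @examples
#' sim <- simulate_series(n_per_status = 2, n_nuclei = 150, seed = 1)
#' table(sim$truth$true_status)
simulate_series <- function(n_per_status = 10, statuses = SIM_STATUSES,
                            n_nuclei = 300, manual_n = 100,
                            tumor_fraction = 0.7, p_loss = 0.07,
                            p_gain = 0.02, clones = NULL, seed = NULL) {
  with_seed(seed, {
    statuses <- match.arg(statuses, SIM_STATUSES, several.ok = TRUE)
    grid <- data.frame(status = rep(statuses, each = n_per_status))
    grid$case_id <- sprintf("case_%03d", seq_len(nrow(grid)))
    out <- lapply(seq_len(nrow(grid)), function(i) {
      simulate_case(grid$case_id[i], grid$status[i], grid$status[i],
                    n_nuclei = n_nuclei, tumor_fraction = tumor_fraction,
                    p_loss = p_loss, p_gain = p_gain, clones = clones)
    })
    auto <- do.call(rbind, lapply(out, `[[`, "nuclei"))
    manual <- do.call(rbind, lapply(split(auto, auto[c("case_id", "arm")]),
      function(d) d[sample.int(nrow(d), min(manual_n, nrow(d))), ]))
    manual$source <- "manual"
    nuclei <- rbind(auto, manual)
    rownames(nuclei) <- NULL
    nuclei <- nuclei[order(nuclei$case_id, nuclei$source, nuclei$arm), ]
    rownames(nuclei) <- NULL
    truth <- do.call(rbind, lapply(out, `[[`, "truth"))
    rownames(truth) <- NULL
    structure(
      list(nuclei = nuclei, truth = truth,
           params = list(n_per_status = n_per_status, n_nuclei = n_nuclei,
                         manual_n = manual_n, tumor_fraction = tumor_fraction,
                         p_loss = p_loss, p_gain = p_gain, seed = seed)),
      class = "fish_sim"
    )
  })
}

#' @export
print.fish_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated FISH series: %d case(s), %d nuclei rows (p_loss = %g, p_gain = %g, tumor_fraction = %g)\n",
    length(unique(x$truth$case_id)), nrow(x$nuclei),
    x$params$p_loss, x$params$p_gain, x$params$tumor_fraction))
  print(table(truth = x$truth$true_status))
  invisible(x)
}

#' Per-status mean combination-frequency profiles for screening experiments
#'
#' Mean percent-of-nuclei profiles (columns sum to 100) over G/R
#' combinations for deleted, normal and imbalanced cases, emulating the
#' frequency structure seen in scored oligodendroglial series: simple and
#' relative deletion combinations enriched in deleted cases, 2/2 and its
#' truncation product 1/2 in normal cases, polysomic combinations in
#' imbalanced cases. The common truncation artifacts 1/1 and 3/2 (and the
#' single-signal classes 1/0, 0/1) are given identical frequencies in all
#' three subgroups, i.e. carry no planted association. Rare discriminant
#' combinations are floored at 0.5% in their home subgroup so that every
#' combination of the 24-entry lookup carries a detectable planted effect.
#'
#' @return matrix (combinations x statuses `DELETED`, `NORMAL`,
#'   `IMBALANCED`) of mean percentages, each column summing to 100.
#' @export
screening_profiles <- function() {
  p <- rbind(
    # combo       DELETED NORMAL IMBALANCED
    "2/0" = c(2.6, 0.9, 0.5),
    "2/1" = c(33, 12, 8),
    "3/0" = c(1.0, 0.1, 0.2),
    "3/1" = c(10, 0.9, 3),
    "4/1" = c(2.2, 0.3, 0.6),
    "4/2" = c(6.7, 0.4, 3.0),
    "5/2" = c(1.3, 0.1, 0.1),
    "6/2" = c(0.6, 0.05, 0.1),
    "6/3" = c(0.5, 0.05, 0.1),
    "2/2" = c(10, 42, 22),
    "1/2" = c(3.7, 14, 6.9),
    "1/3" = c(0.2, 0.9, 2.5),
    "1/4" = c(0.05, 0.05, 0.6),
    "2/3" = c(0.7, 2.1, 5.4),
    "2/4" = c(0.05, 0.2, 1.3),
    "2/5" = c(0.05, 0.05, 0.5),
    "3/3" = c(0.7, 1.4, 6.1),
    "3/4" = c(0.1, 0.2, 3.9),
    "4/3" = c(0.6, 0.6, 4.2),
    "4/4" = c(0.1, 0.6, 4.6),
    "4/5" = c(0.05, 0.05, 0.6),
    "5/4" = c(0.05, 0.1, 1.6),
    "5/5" = c(0.05, 0.05, 0.5),
    "5/6" = c(0.05, 0.05, 0.5),
    # null (non-discriminant) combinations: identical across subgroups
    "1/1" = c(13, 13, 13),
    "3/2" = c(7.5, 7.5, 7.5),
    "1/0" = c(1.2, 1.2, 1.2),
    "0/1" = c(1.0, 1.0, 1.0)
  )
  colnames(p) <- SIM_STATUSES
  # residual artifact mass (0/2) absorbs the remainder so columns sum to 100
  resid <- 100 - colSums(p)
  stopifnot(all(resid >= 0))
  rbind(p, "0/2" = resid)
}

#' Simulate per-case combination-frequency data for screening
#'
#' Emulates a labeled tumor series for [screen_combinations()]: each case's
#' expected combination profile is drawn from a Dirichlet distribution
#' centered on its status profile (between-case biological variability), and
#' observed counts are multinomial draws of `n_manual` (manual view) and
#' `n_automated` (automated view) nuclei from case-specific profiles drawn
#' independently per source.
#'
#' @param n_cases named vector of case counts per status; the default (26
#'   deleted, 8 normal, 19 imbalanced) mirrors a typical retrospective
#'   series of 53 oligodendroglial tumors.
#' @param profiles mean profile matrix, see [screening_profiles()]. A
#'   `NULL`-association (null) series can be simulated by passing a matrix
#'   whose columns are identical.
#' @param concentration Dirichlet concentration (sum of the parameter
#'   vector); larger = less between-case variability. Default 150.
#' @param n_manual,n_automated nuclei per case in the two views.
#' @param seed optional RNG seed.
#' @return long data.frame with columns `case_id`, `source`, `status`,
#'   `combo`, `freq` (percent of nuclei), ready for [screen_combinations()].
#' @export
simulate_screening_series <- function(n_cases = c(DELETED = 26, NORMAL = 8,
                                                  IMBALANCED = 19),
                                      profiles = screening_profiles(),
                                      concentration = 150,
                                      n_manual = 100, n_automated = 300,
                                      seed = NULL) {
  with_seed(seed, {
    stopifnot(all(names(n_cases) %in% colnames(profiles)))
    combos <- rownames(profiles)
    rows <- list()
    cid <- 0L
    for (st in names(n_cases)) {
      base <- profiles[, st] / sum(profiles[, st])
      for (i in seq_len(n_cases[[st]])) {
        cid <- cid + 1L
        case <- sprintf("case_%03d", cid)
        for (src in c("manual", "automated")) {
          n <- if (src == "manual") n_manual else n_automated
          g <- stats::rgamma(length(base), shape = concentration * base)
          prof <- g / sum(g)
          cnt <- stats::rmultinom(1, n, prof)[, 1]
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = case, source = src, status = st,
            combo = combos, freq = 100 * cnt / n)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
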