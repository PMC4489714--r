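# Delimited-text readers/writers for nucleus tables and rule-set
# configuration files, and the TSV+JSON report writer.

NUCLEUS_COLUMNS <- c("case_id", "arm", "source", "green", "red")

# Shared validation for in-memory nucleus tables. Checks vocabularies and
# count invariants; used by the reader (row-wise, tolerant) and by functions
# accepting data.frames directly (strict).
validate_nucleus_table <- function(x, require_source = TRUE) {
  need <- if (require_source) NUCLEUS_COLUMNS else setdiff(NUCLEUS_COLUMNS, "source")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("nucleus table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(x$arm %in% c("1p", "19q"))) {
    stop("'arm' must be '1p' or '19q'")
  }
  if (require_source && !all(x$source %in% c("manual", "automated"))) {
    stop("'source' must be 'manual' or 'automated'")
  }
  check_counts(x$green, x$red)
  x
}

#' Read a per-nucleus signal-count table
#'
#' Reads a delimited text file with header columns `case_id`, `arm`
#' (`1p`/`19q`), `source` (`manual`/`automated`), `green`, `red` — one row
#' per nucleus. Tab- and comma-delimited files are auto-detected. Extra
#' columns are ignored with a warning. Malformed rows (negative or
#' non-integer counts, unknown arm/source) are dropped with a warning; the
#' offending rows and their file line numbers are attached as attribute
#' `"problems"`. Rows with 0 green and 0 red signals are kept: they are
#' counted and reported as excluded downstream, never silently dropped.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return validated data.frame of nuclei.
#' @export
read_nucleus_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  missing <- setdiff(NUCLEUS_COLUMNS, names(raw))
  if (length(missing)) {
    stop("nucleus table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), NUCLEUS_COLUMNS)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
    raw <- raw[NUCLEUS_COLUMNS]
  }
  green <- suppressWarnings(as.numeric(raw$green))
  red <- suppressWarnings(as.numeric(raw$red))
  problem <- character(nrow(raw))
  bad_count <- function(x) is.na(x) | x < 0 | x != trunc(x)
  problem[bad_count(green) | bad_count(red)] <- "non-integer or negative count"
  problem[!(raw$arm %in% c("1p", "19q"))] <- "unknown arm"
  problem[!(raw$source %in% c("manual", "automated"))] <- "unknown source"
  bad <- problem != ""
  out <- data.frame(case_id = raw$case_id, arm = raw$arm,
                    source = raw$source, green = green, red = red)[!bad, ]
  rownames(out) <- NULL
  if (any(bad)) {
    problems <- data.frame(line = which(bad) + 1L, reason = problem[bad],
                           raw[bad, ], row.names = NULL)
    warning(sum(bad), " malformed row(s) rejected (see attr(., 'problems')); ",
            "first at line ", problems$line[1], ": ", problems$reason[1])
    attr(out, "problems") <- problems
  }
  out$green <- as.integer(out$green)
  out$red <- as.integer(out$red)
  validate_nucleus_table(out)
}

#' Write a nucleus table
#'
#' @param x nucleus table (see [read_nucleus_table()] for columns).
#' @param path output file; `.csv` extension selects comma, anything else
#'   tab delimiters.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(x, path) {
  x <- validate_nucleus_table(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x[NUCLEUS_COLUMNS], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rule-set configuration file
#'
#' YAML (or JSON, a YAML subset) with fields `name`, `deletion_cutoff`,
#' `imbalance_cutoff` and either `kind: grid` with `ratio_max` and `normal`
#' (the open-grid parameters) or `classes:` with explicit `"G/R"` entries
#' per class (a closed lookup). Bundled configurations for the two standard
#' algorithms ship with the package:
#' `system.file("extdata", "alg1.yaml", package = "fish1p19q")` and
#' `"alg2.yaml"`.
#'
#' @param path configuration file.
#' @return a [fish_ruleset].
#' @export
read_ruleset <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "deletion_cutoff", "imbalance_cutoff")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("rule-set config is missing field(s): ",
         paste(missing, collapse = ", "))
  }
  if (identical(cfg$kind, "grid")) {
    rs <- ruleset_algorithm1()
    rs$name <- cfg$name
    if (!is.null(cfg$ratio_max)) rs$ratio_max <- cfg$ratio_max
    if (!is.null(cfg$normal)) rs$normal <- unlist(cfg$normal)
    rs$deletion_cutoff <- cfg$deletion_cutoff
    rs$imbalance_cutoff <- cfg$imbalance_cutoff
    check_cutoff(rs$deletion_cutoff)
    check_cutoff(rs$imbalance_cutoff)
    rs
  } else {
    if (is.null(cfg$classes)) stop("lookup rule-set config needs 'classes'")
    fish_ruleset(cfg$name, lapply(cfg$classes, unlist),
                 cfg$deletion_cutoff, cfg$imbalance_cutoff)
  }
}

#' Write a rule-set configuration file
#'
#' @param ruleset a [fish_ruleset].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "fish_ruleset"))
  cfg <- if (ruleset$kind == "grid") {
    list(name = ruleset$name, kind = "grid", ratio_max = ruleset$ratio_max,
         normal = as.list(ruleset$normal),
         deletion_cutoff = ruleset$deletion_cutoff,
         imbalance_cutoff = ruleset$imbalance_cutoff)
  } else {
    classes <- lapply(split(names(ruleset$table), ruleset$table), as.list)
    list(name = ruleset$name, kind = "lookup", classes = classes,
         deletion_cutoff = ruleset$deletion_cutoff,
         imbalance_cutoff = ruleset$imbalance_cutoff)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a scoring report to disk
#'
#' Writes `arm_calls.tsv` (one row per case x source x arm, percentages to
#' two decimals), `case_calls.tsv` and `summary.json` (per-case categories,
#' QC flags, rule-set name and cutoffs, package version) into a directory.
#' Re-running on the same input reproduces identical files.
#'
#' @param report a [score_series()] result.
#' @param dir output directory (created if needed).
#' @param seed optional seed to record in the JSON summary (for simulated
#'   inputs).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, seed = NULL) {
  stopifnot(inherits(report, "fish_report"))
  if (nrow(report$arm_calls) == 0L) stop("report contains no calls")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arm <- report$arm_calls
  for (col in grep("^(pct_|ratio)", names(arm), value = TRUE)) {
    arm[[col]] <- round(arm[[col]], 2)
  }
  f1 <- file.path(dir, "arm_calls.tsv")
  utils::write.table(arm, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "case_calls.tsv")
  utils::write.table(report$case_calls, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  qc <- report$arm_calls[!is.na(report$arm_calls$qc),
                         c("case_id", "source", "arm", "qc")]
  summary <- list(
    ruleset = list(name = report$ruleset$name,
                   deletion_cutoff = report$ruleset$deletion_cutoff,
                   imbalance_cutoff = report$ruleset$imbalance_cutoff),
    method = report$method,
    min_nuclei = report$min_nuclei,
    n_cases = length(unique(report$case_calls$case_id)),
    categories = stats::setNames(
      as.list(report$case_calls$category),
      paste(report$case_calls$case_id, report$case_calls$source, sep = ":")),
    qc_flags = if (nrow(qc)) qc else list(),
    software_version = as.character(utils::packageVersion("fish1p19q"))
  )
  if (!is.null(seed)) summary$seed <- seed
  f3 <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, f3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(f1, f2, f3))
}
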