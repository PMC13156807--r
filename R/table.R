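#' Read a long-format table of scored observations
#'
#' Ingests already-scored observations: one row per person x trial (or
#' split) x occasion x fixed-facet condition, with a numeric score column
#' (microvolts, ms-squared, microsiemens, ... depending on modality). Wide
#' layouts must be pre-melted; long format keeps per-person unbalance from
#' artifact rejection explicit. The CSV/TSV dialect is UTF-8 with a header
#' row; the delimiter is sniffed (comma or tab); decimal point only.
#' Rows with missing or non-numeric scores are dropped (never imputed) and
#' counted in the `dropped` attribute.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param schema Named list mapping canonical roles to file column names,
#'   e.g. `list(person = "subj", trial = "trialnr", score = "amp")`.
#'   Recognized roles: `person`, `score` (required); `trial`, `split`,
#'   `occasion`, `measure` (optional); any other entry is kept as a
#'   fixed-facet column under its role name (e.g. `task = "paradigm"`).
#' @return A `gt_table`: a data frame with canonical column names, a
#'   `dropped` attribute (number of rows removed for missing scores), and
#'   the original row count in `n_read`.
#' @export
read_long_table <- function(path, schema = list(person = "person", score = "score",
                                                trial = "trial")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!all(c("person", "score") %in% names(schema)))
    stop("schema must map at least 'person' and 'score'")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(unlist(schema), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) not present in file: ", paste(missing_cols, collapse = ", "))
  out <- raw[, unlist(schema), drop = FALSE]
  names(out) <- names(schema)
  as_gt_table(out, n_read = nrow(raw))
}

#' Construct a validated observation table from a data frame
#'
#' @param data Data frame already using canonical column names (`person`,
#'   `score`, and any of `trial`, `split`, `occasion`, `measure`,
#'   fixed-facet columns).
#' @param n_read Internal: row count before dropping, for drop accounting.
#' @return A `gt_table`.
#' @export
as_gt_table <- function(data, n_read = nrow(data)) {
  if (!all(c("person", "score") %in% names(data)))
    stop("observation tables need 'person' and 'score' columns")
  data$score <- suppressWarnings(as.numeric(data$score))
  keep <- !is.na(data$person) & is.finite(data$score)
  dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) stop("no usable rows: every row had a missing person id or score")
  if (dropped > 0L)
    message(dropped, " row(s) with missing/non-numeric scores dropped at ingest")
  for (col in intersect(c("trial", "split"), names(data))) {
    v <- suppressWarnings(as.integer(data[[col]]))
    if (anyNA(v) || any(v < 1L))
      stop("'", col, "' must hold positive integer indices")
    data[[col]] <- v
  }
  key_cols <- setdiff(names(data), "score")
  if (anyDuplicated(data[key_cols]))
    stop("duplicate (person, facet condition, measure) combinations found")
  if (all(c("trial", "split") %in% names(data))) {
    per_trial <- unique(data[c("person", "trial", "split")])
    agg <- aggregate(split ~ person + trial, per_trial, function(s) length(unique(s)))
    if (any(agg$split > 1L))
      stop("each trial index must be nested within exactly one split")
  }
  rownames(data) <- NULL
  structure(data, dropped = dropped, n_read = n_read,
            class = c("gt_table", "data.frame"))
}

#' Validate an observation table against a design
#'
#' Checks identifiability, balance, and hidden facets. A facet observed at
#' a single condition cannot have its variance estimated: person and facet
#' effects are confounded, and any reliability computed is conditional on
#' the condition used. Such facets must be declared hidden in the design,
#' never modeled. Persons who lose all observations in some condition of a
#' modeled facet (e.g., after artifact rejection) are surfaced in the
#' report; the package does not prescribe their exclusion.
#'
#' @param table A `gt_table`.
#' @param design A `gt_design`.
#' @return A `gt_validation` list: `hidden` (facets with one observed
#'   condition and warnings), `balanced` (logical), `counts` (per-person
#'   observation counts by facet), `cell_counts`, `persons_missing_cells`.
#'   The input table is not modified.
#' @export
validate_design <- function(table, design) {
  stopifnot(inherits(table, "gt_table"), inherits(design, "gt_design"))
  modeled <- names(design$facets)
  missing_cols <- setdiff(modeled, names(table))
  if (length(missing_cols))
    stop("design facet(s) not present in table: ", paste(missing_cols, collapse = ", "))

  hidden <- list()
  for (f in modeled) {
    n_cond <- length(unique(table[[f]]))
    if (n_cond < 2L)
      stop("identifiability error: facet '", f, "' has a single observed condition ",
           "and cannot be modeled; declare it hidden (its variance is unidentifiable ",
           "and reliability is conditional on it)")
  }
  for (h in design$hidden) {
    hidden[[h]] <- paste0("facet '", h, "' is hidden (single sampled condition): its ",
                          "variance is unidentifiable and reported reliability is ",
                          "conditional on the condition used")
  }

  # per-person replicate counts within every random facet (reported)
  counts <- list()
  for (f in random_facets(design)) {
    tab <- base::table(table$person, table[[f]])
    counts[[f]] <- rowSums(tab > 0)
  }
  # balance = every person carries every observed facet-condition tuple with
  # equal counts (tuples, not the full cross-product, so nesting is respected)
  cells <- table[intersect(c("person", modeled), names(table))]
  cell_counts <- aggregate(rep(1L, nrow(cells)), cells, sum)
  names(cell_counts)[ncol(cell_counts)] <- "n"
  tuples <- unique(cells[setdiff(names(cells), "person")])
  expected_cells <- length(unique(table$person)) * nrow(tuples)
  balanced <- nrow(cell_counts) == expected_cells && length(unique(cell_counts$n)) == 1L

  # persons with no usable observations in some condition of a modeled facet
  missing_persons <- character()
  for (f in modeled) {
    tab <- base::table(table$person, table[[f]])
    bad <- rownames(tab)[rowSums(tab == 0) > 0]
    missing_persons <- union(missing_persons, bad)
  }

  structure(list(hidden = hidden, balanced = balanced, counts = counts,
                 cell_counts = cell_counts,
                 persons_missing_cells = missing_persons),
            class = "gt_validation")
}

#' @export
print.gt_validation <- function(x, ...) {
  cat("<gt_validation> balanced:", x$balanced, "\n")
  for (msg in x$hidden) cat("  warning:", msg, "\n")
  if (length(x$persons_missing_cells))
    cat("  persons missing entire facet conditions:",
        paste(x$persons_missing_cells, collapse = ", "), "\n")
  invisible(x)
}

#' Assign trials to equal-length splits
#'
#' Groups consecutive trials into splits of a fixed size, identically for
#' every person, so split length is consistent across persons. Trial order
#' carries no substantive meaning (trials are exchangeable); the recorded
#' order is used only as a grouping device. A trailing partial split is
#' dropped and logged.
#'
#' @param table A `gt_table` with a `trial` column.
#' @param trials_per_split Positive integer split size. Size 1 degenerates
#'   to crossed trials (split index equals trial rank).
#' @return A `gt_table` with a `split` column added; attribute
#'   `split_dropped` counts removed trailing trials.
#' @export
enforce_split_convention <- function(table, trials_per_split) {
  stopifnot(inherits(table, "gt_table"))
  if (!"trial" %in% names(table)) stop("table has no 'trial' column")
  trials_per_split <- as.integer(trials_per_split)
  stopifnot(length(trials_per_split) == 1L, trials_per_split >= 1L)
  pieces <- split(seq_len(nrow(table)), table$person)
  n_trials <- vapply(pieces, length, integer(1))
  short <- names(pieces)[n_trials < trials_per_split]
  if (length(short))
    stop("trials_per_split (", trials_per_split, ") exceeds the trial count of person ",
         short[1])
  out <- table
  out$split <- NA_integer_
  keep <- logical(nrow(table))
  for (ix in pieces) {
    ord <- ix[order(table$trial[ix])]
    rank <- seq_along(ord)
    spl <- (rank - 1L) %/% trials_per_split + 1L
    complete <- spl <= length(ord) %/% trials_per_split
    out$split[ord] <- spl
    keep[ord] <- complete
  }
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " trailing trial(s) dropped to keep splits equal-length")
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, dropped = attr(table, "dropped"), n_read = attr(table, "n_read"),
            split_dropped = dropped, class = c("gt_table", "data.frame"))
}

#' Write an observation table back to CSV
#'
#' @param table A `gt_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
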