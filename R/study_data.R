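#' Construct a per-cycle aggregate study dataset
#'
#' A `study_dataset` holds the per-cycle aggregate counts of a prospective
#' conception study: for each menstrual cycle, the number of women starting
#' the cycle, the number of hCG-detected pregnancies (which may be unobserved
#' in some cycles), the number of clinical pregnancies, and the numbers of
#' women finishing the study non-pregnant or withdrawing at cycle end.
#' Optionally it carries a long-horizon record: the number of women still not
#' clinically pregnant after a larger number of cycles (e.g. 14 women after
#' 24 cycles in a 221-woman cohort).
#'
#' hCG counts are interpreted as the superset of clinical pregnancies in the
#' same cycle (every clinical pregnancy was first an hCG pregnancy), so
#' `preg_hcg < preg_clin` is flagged as a warning rather than an error by
#' [validate_dataset()]. An `NA` in `preg_hcg` means the study did not report
#' hCG outcomes for that cycle; it is distinct from a zero count and
#' contributes no observation to a fit.
#'
#' @param cycles data frame with columns `cycle`, `n_start`, `preg_hcg`,
#'   `preg_clin`, `finished`, `dropped`; one row per cycle, `cycle` contiguous
#'   from 1. `preg_hcg` may contain `NA` for cycles without hCG reporting.
#' @param study_name label for the study.
#' @param nonpreg_horizon optional list or named vector with elements
#'   `horizon_cycles` and `nonpreg_count`: the number of women never
#'   clinically pregnant after `horizon_cycles` cycles.
#' @param real_valued set `TRUE` for datasets of real-valued expected counts
#'   (produced by [expected_counts()] with `rounding = "none"`); integrality
#'   checks are then skipped.
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `study_name`, `n_initial`, `cycles` (tibble), `hcg_observed_cycles`,
#'   `nonpreg_horizon` (or `NULL`), `real_valued`.
#' @seealso [read_study_csv()], [write_study_csv()], [validate_dataset()]
#' @export
#' @examples
#' d <- study_dataset(
#'   cycles = data.frame(
#'     cycle = 1:3, n_start = c(100, 80, 65),
#'     preg_hcg = c(25, 18, NA), preg_clin = c(18, 13, 10),
#'     finished = c(0, 0, 52), dropped = c(2, 2, 3)
#'   ),
#'   study_name = "example"
#' )
#' validate_dataset(d)
study_dataset <- function(cycles, study_name = "study",
                          nonpreg_horizon = NULL, real_valued = FALSE) {
  required <- c("cycle", "n_start", "preg_hcg", "preg_clin", "finished", "dropped")
  missing_cols <- setdiff(required, names(cycles))
  if (length(missing_cols) > 0L) {
    stop("cycles is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cycles <- tibble::as_tibble(cycles)[required]
  if (nrow(cycles) == 0L) stop("cycles must contain at least one row", call. = FALSE)
  for (col in required) cycles[[col]] <- as.numeric(cycles[[col]])
  if (!is.null(nonpreg_horizon)) {
    nonpreg_horizon <- as.list(nonpreg_horizon)
    if (!all(c("horizon_cycles", "nonpreg_count") %in% names(nonpreg_horizon))) {
      stop("nonpreg_horizon needs elements 'horizon_cycles' and 'nonpreg_count'",
           call. = FALSE)
    }
    nonpreg_horizon <- list(
      horizon_cycles = as.numeric(nonpreg_horizon$horizon_cycles),
      nonpreg_count = as.numeric(nonpreg_horizon$nonpreg_count)
    )
  }
  structure(
    list(
      study_name = as.character(study_name),
      n_initial = cycles$n_start[1L],
      cycles = cycles,
      hcg_observed_cycles = cycles$cycle[!is.na(cycles$preg_hcg)],
      nonpreg_horizon = nonpreg_horizon,
      real_valued = isTRUE(real_valued)
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  k <- nrow(x$cycles)
  cat(sprintf("<study_dataset> %s: N(1) = %g, %d cycles", x$study_name,
              x$n_initial, k))
  if (!is.null(x$nonpreg_horizon)) {
    cat(sprintf(", %g never pregnant after %g cycles",
                x$nonpreg_horizon$nonpreg_count,
                x$nonpreg_horizon$horizon_cycles))
  }
  cat("\n")
  print(x$cycles, ...)
  invisible(x)
}

# default column names of the canonical on-disk schema
.default_schema <- c(cycle = "cycle", n_start = "n_start", preg_hcg = "preg_hcg",
                     preg_clin = "preg_clin", finished = "finished",
                     dropped = "dropped")

#' Read a per-cycle aggregate study table from CSV
#'
#' Reads the canonical comma-separated layout written by [write_study_csv()]:
#' a header row, one row per cycle, empty `preg_hcg` cells for cycles whose
#' hCG outcomes were not reported, and optional `# key: value` comment lines
#' carrying the study name and long-horizon metadata. Files with different
#' column names can be read by supplying `schema_options`, a named character
#' vector mapping canonical names to the file's column names.
#'
#' @param path file to read.
#' @param schema_options named character vector; names are the canonical
#'   columns (`cycle`, `n_start`, `preg_hcg`, `preg_clin`, `finished`,
#'   `dropped`), values the corresponding column names in the file. Unmapped
#'   columns keep their canonical names.
#' @param validate run [validate_dataset()] on the result and raise the first
#'   error-severity violation (warning-severity ones are signalled as
#'   warnings). Set `FALSE` to load a known-inconsistent file for inspection.
#' @return A [study_dataset()].
#' @export
read_study_csv <- function(path, schema_options = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)

  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("malformed file (no data rows): ", path, call. = FALSE)

  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, strip.white = TRUE)

  schema <- .default_schema
  if (!is.null(schema_options)) {
    bad <- setdiff(names(schema_options), names(schema))
    if (length(bad) > 0L) {
      stop("unknown schema_options entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    schema[names(schema_options)] <- schema_options
  }
  for (canon in names(schema)) {
    if (!schema[[canon]] %in% names(df)) {
      stop(sprintf("column '%s' (for '%s') not found in %s",
                   schema[[canon]], canon, path), call. = FALSE)
    }
  }
  out <- df[unname(schema)]
  names(out) <- names(schema)

  # counts must be numeric and, where present, non-negative integers
  for (col in names(out)) {
    v <- out[[col]]
    if (is.character(v)) {
      v_trim <- trimws(v)
      v <- suppressWarnings(as.numeric(ifelse(v_trim == "", NA, v_trim)))
      bad <- which(!is.na(v_trim) & v_trim != "" & is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s', data row %d", col, bad[1L]),
             call. = FALSE)
      }
      out[[col]] <- v
    }
    neg <- which(out[[col]] < 0)
    if (length(neg) > 0L) {
      stop(sprintf("negative count in column '%s', data row %d", col, neg[1L]),
           call. = FALSE)
    }
    if (col != "preg_hcg" && anyNA(out[[col]])) {
      stop(sprintf("missing value in required column '%s'", col), call. = FALSE)
    }
  }

  nonpreg_horizon <- NULL
  if (!is.null(meta$horizon_cycles) || !is.null(meta$nonpreg_count)) {
    if (is.null(meta$horizon_cycles) || is.null(meta$nonpreg_count)) {
      stop("horizon metadata requires both 'horizon_cycles' and 'nonpreg_count'",
           call. = FALSE)
    }
    nonpreg_horizon <- list(horizon_cycles = as.numeric(meta$horizon_cycles),
                            nonpreg_count = as.numeric(meta$nonpreg_count))
  }

  ds <- study_dataset(
    cycles = out,
    study_name = if (!is.null(meta$study_name)) meta$study_name else "study",
    nonpreg_horizon = nonpreg_horizon,
    real_valued = identical(meta$real_valued, "true")
  )
  if (isTRUE(validate)) {
    v <- validate_dataset(ds)
    hard <- v[v$severity == "error", , drop = FALSE]
    if (nrow(hard) > 0L) stop(hard$message[1L], call. = FALSE)
    for (msg in v$message[v$severity == "warning"]) warning(msg, call. = FALSE)
  }
  ds
}

#' Write a study dataset to CSV
#'
#' Emits the canonical layout read by [read_study_csv()]: leading `# key:
#' value` comment lines for the study name and any long-horizon metadata,
#' then a header row and one row per cycle. Unobserved hCG cells are written
#' as empty fields.
#'
#' @param dataset a [study_dataset()] that passes [validate_dataset()]
#'   without errors.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (nrow(dataset$cycles) == 0L) stop("refusing to write a dataset with no cycles",
                                       call. = FALSE)
  viol <- validate_dataset(dataset)
  hard <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(hard) > 0L) {
    stop("dataset fails validation: ", hard$message[1L], call. = FALSE)
  }
  meta <- c(sprintf("# study_name: %s", dataset$study_name))
  if (isTRUE(dataset$real_valued)) meta <- c(meta, "# real_valued: true")
  if (!is.null(dataset$nonpreg_horizon)) {
    meta <- c(meta,
              sprintf("# horizon_cycles: %g", dataset$nonpreg_horizon$horizon_cycles),
              sprintf("# nonpreg_count: %g", dataset$nonpreg_horizon$nonpreg_count))
  }
  cy <- dataset$cycles
  fmt <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
  rows <- paste(fmt(cy$cycle), fmt(cy$n_start), fmt(cy$preg_hcg),
                fmt(cy$preg_clin), fmt(cy$finished), fmt(cy$dropped), sep = ",")
  header <- paste(names(.default_schema), collapse = ",")
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Validate a study dataset
#'
#' Checks every structural invariant of a per-cycle aggregate table and
#' returns the violations instead of raising: counts non-negative and (unless
#' the dataset is flagged real-valued) integral; cycle indices contiguous
#' from 1; `preg_clin` and observed `preg_hcg` not exceeding `n_start`;
#' conservation between consecutive cycles,
#' `n_start[k+1] = n_start[k] - preg_clin[k] - finished[k] - dropped[k]`;
#' horizon metadata consistent with the reported cycles. An observed
#' `preg_hcg < preg_clin` is reported with severity `"warning"` (hCG counts
#' are normally the superset of clinical ones, but reporting conventions
#' differ); everything else is severity `"error"`.
#'
#' @param dataset a [study_dataset()].
#' @return A tibble with columns `severity`, `cycle_index`, `message`; zero
#'   rows when all invariants hold.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  cy <- dataset$cycles
  out <- list()
  add <- function(severity, cycle_index, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      severity = severity, cycle_index = as.numeric(cycle_index), message = message)
  }

  k <- nrow(cy)
  if (!isTRUE(all.equal(cy$cycle, seq_len(k)))) {
    add("error", NA, "cycle indices are not contiguous 1..K")
  }
  tol <- 1e-9
  for (i in seq_len(k)) {
    for (col in c("n_start", "preg_clin", "finished", "dropped")) {
      v <- cy[[col]][i]
      if (is.na(v) || v < 0) {
        add("error", i, sprintf("%s is missing or negative in cycle %d", col, i))
      } else if (!dataset$real_valued && abs(v - round(v)) > tol) {
        add("error", i, sprintf("%s is non-integral in cycle %d", col, i))
      }
    }
    h <- cy$preg_hcg[i]
    if (!is.na(h)) {
      if (h < 0) add("error", i, sprintf("preg_hcg negative in cycle %d", i))
      else if (!dataset$real_valued && abs(h - round(h)) > tol) {
        add("error", i, sprintf("preg_hcg is non-integral in cycle %d", i))
      }
      if (!is.na(h) && h > cy$n_start[i] + tol) {
        add("error", i, sprintf("preg_hcg exceeds n_start in cycle %d", i))
      }
      if (!is.na(h) && h < cy$preg_clin[i] - tol) {
        add("warning", i,
            sprintf("preg_hcg < preg_clin in cycle %d (hCG usually a superset)", i))
      }
    }
    if (cy$preg_clin[i] > cy$n_start[i] + tol) {
      add("error", i, sprintf("preg_clin exceeds n_start in cycle %d", i))
    }
  }
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      expected <- cy$n_start[i] - cy$preg_clin[i] - cy$finished[i] - cy$dropped[i]
      if (abs(cy$n_start[i + 1L] - expected) > 1e-6) {
        add("error", i + 1L,
            sprintf("conservation broken at cycle %d: expected n_start %g, found %g",
                    i + 1L, expected, cy$n_start[i + 1L]))
        break  # downstream cycles inherit the break; report the first only
      }
    }
  }
  if (!is.null(dataset$nonpreg_horizon)) {
    if (dataset$nonpreg_horizon$horizon_cycles < k) {
      add("error", NA, "nonpreg_horizon horizon_cycles is smaller than the number of reported cycles")
    }
    if (dataset$nonpreg_horizon$nonpreg_count < 0 ||
        dataset$nonpreg_horizon$nonpreg_count > dataset$n_initial) {
      add("error", NA, "nonpreg_count outside [0, n_initial]")
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(severity = character(), cycle_index = numeric(),
                   message = character())
  } else {
    do.call(rbind, out)
  }
}
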