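#' Table layout of a time-course file
#'
#' Describes how a gel-quantification export maps onto a [timecourse()]:
#' delimiter, the name of the time column and the column name of each band.
#' TSV is the canonical dialect (quantification software exports
#' tab-separated tables); comma is accepted as an alternative.
#'
#' @param delimiter `"tab"` (default) or `"comma"`.
#' @param time_column Name of the time column (minutes since CHX addition).
#' @param band_columns Named character vector mapping band labels to column
#'   names; `A` and `B` must be mapped, `PP` is optional.
#' @param decimal Decimal mark; only `"point"` is supported.
#' @return An object of class `table_dialect`.
#' @examples
#' table_dialect(delimiter = "comma", time_column = "t")
#' @export
table_dialect <- function(delimiter = c("tab", "comma"),
                          time_column = "time_min",
                          band_columns = c(PP = "PP", A = "A", B = "B"),
                          decimal = "point") {
  delimiter <- match.arg(delimiter)
  if (!identical(decimal, "point")) {
    stop("only decimal = \"point\" is supported", call. = FALSE)
  }
  if (!is.character(band_columns) || is.null(names(band_columns)) ||
      !all(c("A", "B") %in% names(band_columns))) {
    stop("'band_columns' must be a named character vector mapping at ",
         "least bands A and B", call. = FALSE)
  }
  if (!is.character(time_column) || length(time_column) != 1L ||
      !nzchar(time_column)) {
    stop("'time_column' must be a single non-empty column name",
         call. = FALSE)
  }
  structure(list(delimiter = delimiter,
                 sep = if (delimiter == "tab") "\t" else ",",
                 time_column = time_column,
                 band_columns = band_columns,
                 decimal = decimal),
            class = "table_dialect")
}

#' Read a chase time course from a delimited table
#'
#' Parses a TSV/CSV table of band intensities into a validated
#' [timecourse()].  Rows are sorted by time; duplicate time points, missing
#' required columns and non-numeric cells are rejected with informative
#' errors.
#'
#' @param path Path to the table.
#' @param dialect A [table_dialect()].
#' @return An unnormalized [timecourse()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_timecourse(simulate_chase(chase_scenarios(sigma = 0)[["mcx1"]]), tf)
#' read_timecourse(tf)
#' @export
read_timecourse <- function(path, dialect = table_dialect()) {
  if (!inherits(dialect, "table_dialect")) {
    stop("'dialect' must be a table_dialect object", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- read.table(path, header = TRUE, sep = dialect$sep,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE)
  if (!(dialect$time_column %in% names(raw))) {
    stop(sprintf("schema error: missing time column '%s'",
                 dialect$time_column), call. = FALSE)
  }
  need <- dialect$band_columns[c("A", "B")]
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("schema error: missing band column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  to_num <- function(nm) {
    col <- raw[[nm]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                   col[bad[1L]], nm, bad[1L]), call. = FALSE)
    }
    v
  }
  tm <- to_num(dialect$time_column)
  if (anyDuplicated(tm)) {
    stop("validation error: duplicate time points", call. = FALSE)
  }
  o <- order(tm)
  pp_col <- if ("PP" %in% names(dialect$band_columns) &&
                dialect$band_columns[["PP"]] %in% names(raw)) {
    to_num(dialect$band_columns[["PP"]])[o]
  }
  timecourse(tm[o],
             A = to_num(dialect$band_columns[["A"]])[o],
             B = to_num(dialect$band_columns[["B"]])[o],
             PP = pp_col, normalized = FALSE)
}

#' Write a chase time course to a delimited table
#'
#' @param tc A [timecourse()].
#' @param path Output path.
#' @param dialect A [table_dialect()] controlling delimiter and column
#'   names.  Values are written with full double precision so that a
#'   write/read round trip is lossless.
#' @return `path`, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_timecourse(simulate_chase(chase_scenarios(sigma = 0)[["mcx1"]]), tf)
#' @export
write_timecourse <- function(tc, path, dialect = table_dialect()) {
  if (!inherits(tc, "timecourse")) {
    stop("'tc' must be a timecourse object", call. = FALSE)
  }
  if (!inherits(dialect, "table_dialect")) {
    stop("'dialect' must be a table_dialect object", call. = FALSE)
  }
  df <- data.frame(format(tc$time, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- dialect$time_column
  for (b in tc_bands(tc)) {
    nm <- if (b %in% names(dialect$band_columns)) {
      dialect$band_columns[[b]]
    } else {
      b
    }
    df[[nm]] <- format(tc[[b]], digits = 17, trim = TRUE)
  }
  write.table(df, path, sep = dialect$sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

report_fields <- function(fit) {
  list(model = fit$model,
       converged = fit$converged,
       rss = fit$rss,
       n_obs = fit$n_obs,
       fit_bands = fit$fit_bands,
       params = lapply(unclass(fit$params), as.numeric),
       init = lapply(unclass(fit$init), as.numeric),
       half_lives = as.list(fit$half_lives))
}

#' Write a fit or model-comparison report
#'
#' TSV reports mirror the layout of a turnover table: columns ordered
#' `k_ab`, `tau_A`, `k_bx`, `tau_B` (plus `k_pa`, `k_pb` for a branched
#' fit), rates at 3 significant figures and half-lives as integer minutes.
#' JSON reports carry the full-precision parameters plus metadata (model,
#' rss, convergence, package version) and are the machine interface.
#'
#' @param fit A `chase_fit` or `model_comparison` object.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' tc <- simulate_chase(chase_scenarios(sigma = 0)[["wild-type"]])
#' fit <- fit_sequential(normalize_to_reference(tc))
#' write_report(fit, tempfile(fileext = ".tsv"))
#' @export
write_report <- function(fit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(fit, "chase_fit")) {
    if (format == "tsv") {
      tab <- report_half_lives(fit)
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      payload <- c(report_fields(fit),
                   list(package = paste0("chasekin ",
                                         as.character(utils::packageVersion(
                                           "chasekin")))))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  } else if (inherits(fit, "model_comparison")) {
    if (format == "tsv") {
      rows <- lapply(c("sequential", "branched"), function(m) {
        tab <- report_half_lives(fit[[m]])
        tab$k_pa <- fit[[m]]$params$k_pa
        tab$k_pb <- fit[[m]]$params$k_pb
        tab$model <- fit[[m]]$model
        tab$selected <- identical(fit$selected, m)
        tab
      })
      write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      payload <- list(
        criterion = fit$criterion,
        criterion_values = as.list(fit$criterion_values),
        selected = fit$selected,
        inconclusive = fit$inconclusive,
        sequential = report_fields(fit$sequential),
        branched = report_fields(fit$branched))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  } else {
    stop("'fit' must be a chase_fit or model_comparison object",
         call. = FALSE)
  }
  invisible(path)
}
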