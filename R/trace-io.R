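#' Parse a titrant concentration from a column header
#'
#' Column headers in kinetic-trace CSV files each contain a number giving the
#' titrant (substrate, inhibitor or activator) concentration. The first maximal
#' numeric token is taken, with decimals and scientific notation supported
#' (`"2.5e-2"` parses as 0.025). A digit that is glued to the end of a word
#' (the "1" in `"kinase1"`) is not a token, so `"kinase1 40 uM"` parses as 40.
#' Any sign is stripped: concentrations are non-negative.
#'
#' @param header Character vector of column headers.
#' @return Numeric vector of non-negative concentrations.
#' @export
#' @examples
#' parse_concentration(c("320", "inhibitor_2.5e-2_mM", "kinase1 40 uM"))
parse_concentration <- function(header) {
  stopifnot(is.character(header))
  pat <- "(?<![A-Za-z0-9.])[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  tok <- stringr::str_extract(header, stringr::regex(pat))
  bad <- is.na(tok)
  if (any(bad)) {
    stop("no numeric token in column header(s): ",
         paste(sQuote(header[bad]), collapse = ", "), call. = FALSE)
  }
  abs(as.numeric(tok))
}

#' Read a kinetic-trace CSV file
#'
#' Reads the plate-reader time-course dialect: the first column is time
#' (seconds or minutes), every further column is one signal trace whose header
#' contains the titrant concentration (see [parse_concentration()]). Rows with
#' any non-numeric cell are dropped (with a warning) so all traces share one
#' time vector. Returns the dataset in long form, one row per (trace, time)
#' observation.
#'
#' @param source Path to a CSV file, or a literal character vector of CSV
#'   lines (handy for in-memory round trips).
#' @param time_unit Optional, `"seconds"` or `"minutes"`; carried as an
#'   attribute only, never converted.
#' @return A tibble with columns `label`, `concentration`, `time`, `signal`,
#'   ordered by file column then time; attribute `time_unit` records the unit.
#' @export
read_kinetic_csv <- function(source, time_unit = NULL) {
  if (!is.null(time_unit)) {
    time_unit <- match.arg(time_unit, c("seconds", "minutes"))
  }
  raw <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2) stop("need a time column plus at least one trace column", call. = FALSE)
  labels <- make_unique_labels(names(raw)[-1])
  conc <- parse_concentration(names(raw)[-1])

  num <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L)
  keep <- stats::complete.cases(num)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with non-numeric cells dropped", call. = FALSE)
  }
  num <- num[keep, , drop = FALSE]
  if (nrow(num) < 3) stop("fewer than 3 usable rows", call. = FALSE)
  time <- num[, 1]
  if (any(diff(time) <= 0)) stop("time column must be strictly increasing", call. = FALSE)

  out <- purrr::map2_dfr(seq_along(labels), conc, function(j, cc) {
    tibble::tibble(label = labels[j], concentration = cc,
                   time = time, signal = num[, j + 1])
  })
  attr(out, "time_unit") <- if (is.null(time_unit)) "unspecified" else time_unit
  out
}

make_unique_labels <- function(labels) {
  if (anyDuplicated(labels)) {
    dup <- stats::ave(seq_along(labels), labels, FUN = seq_along)
    labels <- ifelse(dup > 1, paste0(labels, "_", dup), labels)
  }
  labels
}

#' Apply a signal transform to a kinetic dataset
#'
#' Converts measured signal into substrate concentration via a user-supplied
#' arithmetic expression in one free variable `x` (the measured signal), e.g.
#' `"x/(6220*0.55)"` for an extinction-coefficient conversion. The expression
#' grammar is restricted to numbers, `x`, `+ - * / ^` and parentheses; nothing
#' else evaluates. With `invert = TRUE` the transformed signal is additionally
#' multiplied by -1, the convention for product-accumulation data entering the
#' Schnell-Mendoza substrate-depletion fit.
#'
#' @param data Long kinetic dataset from [read_kinetic_csv()] (columns `label`,
#'   `time`, `signal` at minimum).
#' @param expression Transform as a character scalar, in the variable `x`.
#' @param invert Multiply the transformed signal by -1 (default `FALSE`).
#' @return `data` with `signal` replaced; all other columns untouched.
#' @export
apply_transform <- function(data, expression, invert = FALSE) {
  stopifnot(is.data.frame(data), is.character(expression), length(expression) == 1)
  expr <- parse_transform(expression)
  new_sig <- eval(expr, envir = list(x = data$signal), enclos = baseenv())
  new_sig <- rep_len(new_sig, length(data$signal))
  if (invert) new_sig <- -new_sig
  if (any(!is.finite(new_sig))) {
    i <- which(!is.finite(new_sig))[1]
    stop("transform gave a non-finite value for trace ", sQuote(data$label[i]),
         " at time ", data$time[i], call. = FALSE)
  }
  data$signal <- new_sig
  data
}

# Restricted parser: R's own parser builds the AST, then a whitelist walk
# rejects any symbol other than `x` and any call other than the arithmetic
# operators. No general code evaluation is possible.
parse_transform <- function(expression) {
  expr <- tryCatch(str2lang(expression),
                   error = function(e) stop("cannot parse transform expression: ",
                                            conditionMessage(e), call. = FALSE))
  check_node <- function(node) {
    if (is.numeric(node) || is.integer(node)) return(invisible(TRUE))
    if (is.symbol(node)) {
      if (!identical(as.character(node), "x")) {
        stop("transform may only reference the signal variable 'x', not ",
             sQuote(as.character(node)), call. = FALSE)
      }
      return(invisible(TRUE))
    }
    if (is.call(node)) {
      op <- as.character(node[[1]])
      if (!op %in% c("+", "-", "*", "/", "^", "(")) {
        stop("operator ", sQuote(op), " not allowed in transform", call. = FALSE)
      }
      for (k in as.list(node)[-1]) check_node(k)
      return(invisible(TRUE))
    }
    stop("unsupported token in transform expression", call. = FALSE)
  }
  check_node(expr)
  expr
}

#' Write / read a rate table as CSV
#'
#' The rate-table export contract: columns `label`, `concentration`, `rate`,
#' `rate_stderr`, `mode`, `window_start`, `window_end`; numeric fields are
#' serialized at 12 significant digits so a write/read cycle is lossless to
#' 1e-10 relative.
#'
#' @param table Rate table tibble (see [initial_rates()]).
#' @param path Output path.
#' @return `path`, invisibly (`write_rate_table_csv`); the rate-table tibble
#'   (`read_rate_table_csv`).
#' @export
write_rate_table_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("rate table is empty", call. = FALSE)
  cols <- c("label", "concentration", "rate", "rate_stderr", "mode",
            "window_start", "window_end")
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("rate table lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  out <- table[cols]
  for (nm in setdiff(cols, c("label", "mode"))) {
    out[[nm]] <- sprintf("%.12g", out[[nm]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rate_table_csv
#' @export
read_rate_table_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(),
    concentration = readr::col_double(),
    rate = readr::col_double(),
    rate_stderr = readr::col_double(),
    mode = readr::col_character(),
    window_start = readr::col_double(),
    window_end = readr::col_double()
  ), progress = FALSE)
}

# Split a long dataset into per-trace tibbles, preserving file order.
split_traces <- function(data) {
  stopifnot(all(c("label", "time", "signal") %in% names(data)))
  split(data, factor(data$label, levels = unique(data$label)))
}
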