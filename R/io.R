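#' Read a backbone-amide peak list
#'
#' Reads assigned backbone amide peaks into a tidy table with one row per
#' residue. Two dialects are supported: delimited text (CSV/TSV with columns
#' `residue, aa, dH, dN[, intensity]`) and Sparky-style lists whose lines
#' read `assignment w1 w2 [height]`, where the assignment follows the
#' backbone-amide grammar `XnnN-H` (e.g. `I72N-H`), `w1` is the 15N shift
#' and `w2` the 1H shift, both in ppm.
#'
#' @param path Path to the peak list.
#' @param dialect `"auto"` (by extension: `.csv`, `.tsv`/`.txt`, `.list`),
#'   `"csv"`, `"tsv"` or `"sparky"`.
#' @return A tibble with columns `residue` (integer), `aa` (one-letter
#'   code), `dH`, `dN` (ppm) and `intensity` (arbitrary units, `NA` when
#'   absent; a missing peak is encoded as an absent row or `NA`, never 0).
#' @export
#' @examples
#' f <- tempfile(fileext = ".list")
#' writeLines(c("I72N-H 121.4 8.12 1000000", "S36N-H 118.0 8.40 950000"), f)
#' read_peaklist(f)
read_peaklist <- function(path, dialect = c("auto", "csv", "tsv", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("peak list not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                      list = "sparky",
                      abort(sprintf("cannot infer peak-list dialect from extension '.%s'", ext)))
  }
  if (dialect == "sparky") {
    out <- parse_sparky(path)
  } else {
    delim <- if (dialect == "csv") "," else "\t"
    raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                             progress = FALSE, show_col_types = FALSE)
    if (!all(c("residue", "aa", "dH", "dN") %in% names(raw)) && ncol(raw) >= 4) {
      # headerless: positional columns residue, aa, dH, dN[, intensity]
      raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                               col_types = readr::cols(), progress = FALSE,
                               show_col_types = FALSE)
      names(raw)[1:4] <- c("residue", "aa", "dH", "dN")
      if (ncol(raw) >= 5) names(raw)[5] <- "intensity"
    }
    require_columns(raw, c("residue", "aa", "dH", "dN"), path)
    out <- tibble(
      residue = as.integer(raw$residue),
      aa = as.character(raw$aa),
      dH = as.numeric(raw$dH),
      dN = as.numeric(raw$dN),
      intensity = if ("intensity" %in% names(raw)) as.numeric(raw$intensity) else NA_real_
    )
  }
  assert_residue_ids(out$residue, out$aa, path)
  if (anyDuplicated(out$residue)) {
    abort(sprintf("%s: duplicate residue index: %s", path,
                  paste(unique(out$residue[duplicated(out$residue)]), collapse = ", ")))
  }
  if (any(!is.finite(out$dH)) || any(!is.finite(out$dN))) {
    abort(sprintf("%s: non-finite chemical shift", path))
  }
  if (any(out$intensity < 0, na.rm = TRUE)) {
    abort(sprintf("%s: negative intensity", path))
  }
  arrange(out, .data$residue)
}

parse_sparky <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # skip an optional Sparky header line
  lines <- lines[!grepl("^Assignment", lines, ignore.case = TRUE)]
  pat <- "^([A-Z])([0-9]+)N-H$"
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "\\s+")[[1]]
    if (length(parts) < 3 || !grepl(pat, parts[[1]])) {
      abort(sprintf("%s: unparseable Sparky assignment on line %d: '%s'",
                    path, i, lines[[i]]))
    }
    tibble(
      residue = as.integer(sub(pat, "\\2", parts[[1]])),
      aa = sub(pat, "\\1", parts[[1]]),
      dN = as.numeric(parts[[2]]),
      dH = as.numeric(parts[[3]]),
      intensity = if (length(parts) >= 4) as.numeric(parts[[4]]) else NA_real_
    )
  })
  select(bind_rows(rows), "residue", "aa", "dH", "dN", "intensity")
}

#' Read a per-residue series table (time, denaturant, temperature, ...)
#'
#' Reads a long-format table with columns `residue, aa, x, y[, y_err]` and
#' converts the abscissa to the package's canonical units: seconds for
#' time, Kelvin for temperature, molar for concentrations. The original
#' unit is retained as an attribute, and conversion is applied exactly
#' once at this boundary.
#'
#' @param path Path to a CSV/TSV file (delimiter by extension).
#' @param x_unit Unit of the `x` column in the file: `"s"`, `"min"`,
#'   `"K"`, `"C"`, `"M"`, `"mM"` or `"uM"`.
#' @return A tibble `(residue, aa, x, y[, y_err])` sorted by residue and
#'   `x`, with attributes `x_unit` (canonical unit) and `x_unit_input`.
#'   Unsorted `x` within a residue is sorted stably with a warning.
#' @export
read_series <- function(path, x_unit = c("s", "min", "K", "C", "M", "mM", "uM")) {
  x_unit <- match.arg(x_unit)
  if (!file.exists(path)) abort(sprintf("series table not found: %s", path))
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  require_columns(raw, c("residue", "aa", "x", "y"), path)
  if ("x_unit" %in% names(raw) && length(unique(raw$x_unit)) > 1) {
    abort(sprintf("%s: mixed x units within one file", path))
  }
  df <- tibble(
    residue = as.integer(raw$residue),
    aa = as.character(raw$aa),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y)
  )
  if ("y_err" %in% names(raw)) df$y_err <- as.numeric(raw$y_err)
  if (nrow(df) == 0 || all(is.na(df$y))) abort(sprintf("%s: empty y column", path))
  assert_residue_ids(df$residue, df$aa, path)
  conv <- convert_x(df$x, x_unit)
  df$x <- conv$x
  unsorted <- any(vapply(split(seq_len(nrow(df)), df$residue), function(idx) {
    is.unsorted(df$x[idx])
  }, logical(1)))
  if (unsorted) warn(sprintf("%s: unsorted x values; sorting stably", path))
  df <- arrange(df, .data$residue, .data$x)
  attr(df, "x_unit") <- conv$unit
  attr(df, "x_unit_input") <- x_unit
  df
}

# min -> s (x60), C -> K (+273.15), mM/uM -> M; already-canonical passes through
convert_x <- function(x, unit) {
  switch(unit,
    s   = list(x = x, unit = "s"),
    min = list(x = x * 60, unit = "s"),
    K   = list(x = x, unit = "K"),
    C   = list(x = x + 273.15, unit = "K"),
    M   = list(x = x, unit = "M"),
    mM  = list(x = x / 1e3, unit = "M"),
    uM  = list(x = x / 1e6, unit = "M")
  )
}

#' Write and read per-residue score tables
#'
#' Serializes per-residue scalar scores (logP, free energies, CSPs,
#' relaxation rates, ...) to delimited text with a fixed column order
#' `residue, aa, value, error, flag`; flags are written as 0/1. The
#' round trip `read_scores(write_scores(x))` preserves every field to at
#' least 12 significant digits.
#'
#' @param scores A data frame with columns `residue`, `aa`, `value` and
#'   optionally `error` (numeric) and `flag` (logical).
#' @param path Output CSV path.
#' @return `write_scores` returns `path` invisibly; `read_scores` returns
#'   the scores tibble.
#' @export
write_scores <- function(scores, path) {
  require_columns(scores, c("residue", "aa", "value"), "scores")
  if (nrow(scores) == 0) abort("scores: no records to write")
  out <- tibble(
    residue = as.integer(scores$residue),
    aa = as.character(scores$aa),
    value = as.numeric(scores$value),
    error = if ("error" %in% names(scores)) as.numeric(scores$error) else NA_real_,
    flag = if ("flag" %in% names(scores)) as.integer(scores$flag) else 0L
  )
  lines <- c("residue,aa,value,error,flag",
             sprintf("%d,%s,%.15g,%.15g,%d",
                     out$residue, out$aa, out$value, out$error, out$flag))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- readr::read_csv(path, col_types = "icddi", progress = FALSE)
  mutate(as_tibble(df), flag = .data$flag == 1L)
}
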