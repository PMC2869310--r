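# Table and configuration I/O.  Interchange format is TSV (UTF-8, '.'
# decimal); every file written carries a provenance comment header.

#' Read and validate a TSV table
#'
#' Reads a tab-separated table (comment lines starting with `#` ignored)
#' and validates it against a column schema.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`, `"logical"`).  Columns
#'   not in the schema are kept as read.
#' @param unique_key Optional column name whose values must be unique
#'   (e.g. `"gene_id"`).
#' @return The validated data.frame; the row count is reported via
#'   `message()`.
#' @export
read_table <- function(path, schema = NULL, unique_key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), names(df))
    if (length(missing_cols) > 0) {
      stop("missing column(s) in ", basename(path), ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (cn in names(schema)) {
      df[[cn]] <- switch(schema[[cn]],
                         character = as.character(df[[cn]]),
                         numeric = as.numeric(df[[cn]]),
                         integer = as.integer(df[[cn]]),
                         logical = as.logical(df[[cn]]),
                         stop("unknown schema type: ", schema[[cn]], call. = FALSE))
      if (schema[[cn]] != "character" && anyNA(df[[cn]]) ) {
        stop("column '", cn, "' in ", basename(path),
             " contains non-", schema[[cn]], " values", call. = FALSE)
      }
    }
  }
  if (!is.null(unique_key) && anyDuplicated(df[[unique_key]])) {
    stop("duplicate values in key column '", unique_key, "' of ",
         basename(path), call. = FALSE)
  }
  message("read ", nrow(df), " row(s) from ", basename(path))
  df
}

#' Write a TSV table with a provenance header
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param provenance A named list recorded as `# key=value` comment lines
#'   (a package version line is always included); `NULL` writes no header.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, provenance = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    ver <- as.character(utils::packageVersion("costex"))
    writeLines(sprintf("# costex %s", ver), con)
    for (nm in names(provenance)) {
      writeLines(sprintf("# %s=%s", nm, format(provenance[[nm]])), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Minimal YAML-style format: one `key: value` per line, `#` comments and
#' blank lines ignored.  Values are parsed as numbers when possible,
#' `true`/`false` as logicals, everything else as strings.
#'
#' @param path File path.
#' @param known Optional character vector of allowed keys; unknown keys
#'   raise an error.
#' @return A named list.
#' @export
read_config <- function(path, known = NULL) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed config line: '", ln, "'", call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (!is.null(known) && !key %in% known) {
      stop("unknown config key: '", key, "'", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
    else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config A named list of scalar values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  scal <- vapply(config, function(v) length(v) == 1 && is.atomic(v), logical(1))
  lines <- sprintf("%s: %s", names(config)[scal],
                   vapply(config[scal], function(v) format(v, scientific = FALSE),
                          character(1)))
  writeLines(lines, path)
  invisible(path)
}
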