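# Minimal TOML-subset reader/writer used for run configuration files.
#
# Supported subset: top-level and [table] sections, key = value pairs with
# string, number, boolean, and single-line homogeneous array values, plus
# '#' comments.  This covers everything a run configuration needs; nested
# tables beyond one level and multi-line values are not supported.

#' Read a configuration file in TOML form
#'
#' Parses the TOML subset used by [write_toml()]: flat `key = value`
#' assignments grouped under optional `[section]` headers.
#'
#' @param path Path to the file.
#' @return A named list; each `[section]` becomes a named sub-list.
#' @seealso [write_toml()], [read_config()]
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (k in seq_along(lines)) {
    line <- strip_toml_comment(lines[k])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      stop2(sprintf("%s:%d: cannot parse line: %s", path, k, lines[k]))
    }
    key <- m[2]
    val <- parse_toml_value(m[3], path, k)
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

parse_toml_value <- function(txt, path = "<string>", lineno = NA) {
  txt <- trimws(txt)
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- substr(txt, 2, nchar(txt) - 1)
    if (trimws(inner) == "") return(list())
    parts <- strsplit_quoted(inner)
    vals <- lapply(parts, parse_toml_value, path = path, lineno = lineno)
    return(unlist(vals))
  }
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop2(sprintf("%s:%s: cannot parse TOML value: %s", path, lineno, txt))
}

# drop a trailing comment, but only a '#' outside double quotes
strip_toml_comment <- function(line) {
  chars <- strsplit(line, "")[[1]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == '"') inq <- !inq
    if (chars[i] == "#" && !inq) return(substr(line, 1, i - 1))
  }
  line
}

# split on commas that are outside double quotes
strsplit_quoted <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  parts <- character(0)
  buf <- ""
  inq <- FALSE
  for (ch in chars) {
    if (ch == '"') inq <- !inq
    if (ch == "," && !inq) {
      parts <- c(parts, buf)
      buf <- ""
    } else buf <- paste0(buf, ch)
  }
  c(parts, buf)
}

format_toml_value <- function(v) {
  if (is.character(v)) {
    one <- function(s) paste0('"', s, '"')
  } else if (is.logical(v)) {
    one <- function(s) if (s) "true" else "false"
  } else {
    one <- function(s) format(s, digits = 15, scientific = FALSE, trim = TRUE)
  }
  if (length(v) == 1 && is.null(names(v))) return(one(v))
  paste0("[", paste(vapply(unname(v), one, ""), collapse = ", "), "]")
}

#' Write a configuration list as a TOML file
#'
#' Inverse of [read_toml()] for the supported subset.  Named sub-lists are
#' written as `[section]` tables; scalar entries in a named vector are
#' written as an inline array.
#'
#' @param x Named list to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toml <- function(x, path) {
  lines <- character(0)
  tables <- vapply(x, function(v) is.list(v), TRUE)
  for (key in names(x)[!tables]) {
    lines <- c(lines, paste0(key, " = ", format_toml_value(x[[key]])))
  }
  for (key in names(x)[tables]) {
    lines <- c(lines, "", paste0("[", key, "]"))
    tab <- x[[key]]
    for (k2 in names(tab)) {
      lines <- c(lines, paste0(k2, " = ", format_toml_value(tab[[k2]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
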