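#' Read a run/analysis configuration file
#'
#' JSON (via jsonlite) or a TOML subset are accepted, chosen by extension.
#' The TOML subset supports `[section]` / `[section.sub]` headers,
#' `key = value` with strings, numbers, booleans and flat arrays, and `#`
#' comments -- enough for run configurations; no CRAN TOML parser is
#' assumed to be installed.
#'
#' @param path file path (`.json`, `.toml`)
#' @return nested named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  if (ext != "toml") stop("unsupported config format: ", ext)
  lines <- readLines(path)
  out <- list()
  section <- character(0)
  parse_value <- function(v, ln) {
    v <- trimws(v)
    if (grepl("^\\[", v)) { # flat array
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (!nzchar(trimws(inner))) return(list())
      parts <- strsplit(inner, ",")[[1]]
      return(unlist(lapply(parts, parse_value, ln = ln)))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (grepl("^'.*'$", v)) return(gsub("^'|'$", "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    parse_fail(path, ln, paste("cannot parse value:", v))
  }
  for (ln in seq_along(lines)) {
    l <- sub("#.*$", "", lines[ln])
    l <- trimws(l)
    if (!nzchar(l)) next
    if (grepl("^\\[.*\\]$", l)) {
      section <- strsplit(gsub("[][]", "", l), "\\.")[[1]]
      next
    }
    kv <- regmatches(l, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", l))[[1]]
    if (length(kv) != 3) parse_fail(path, ln, "expected 'key = value'")
    keypath <- c(section, kv[2])
    out <- assign_path(out, keypath, parse_value(kv[3], ln))
  }
  out
}

# recursive list assignment along a key path, creating levels as needed
assign_path <- function(lst, path, value) {
  if (length(path) == 1) {
    lst[[path]] <- value
    return(lst)
  }
  if (is.null(lst[[path[1]]])) lst[[path[1]]] <- list()
  lst[[path[1]]] <- assign_path(lst[[path[1]]], path[-1], value)
  lst
}

# stable short hash of a plan (FNV-1a over its deparsed form)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
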