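#' Select an atom group by a small keyword expression
#'
#' Grammar (case-sensitive keywords, whitespace-separated tokens):
#' \preformatted{
#'   expr    := term ( "or" term )*
#'   term    := factor ( "and" factor )*
#'   factor  := "not" factor | "(" expr ")" | primitive
#'   primitive := "resname" NAME | "element" SYMBOL | "molid" N | "molid" N:M
#' }
#' e.g. `"resname API"`, `"element O and not resname POL"`,
#' `"molid 1:10 or resname NPX"`.
#'
#' @param sys an [md_system()]
#' @param spec selection expression (string)
#' @param label group label (default: the expression itself)
#' @return A `group_selection`: list with `label`, `atom_indices` (1-based,
#'   sorted) and `molecule_ids`.  Empty selections are an error: silently
#'   empty groups are forbidden.
#' @export
select_group <- function(sys, spec, label = spec) {
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  toks <- unlist(strsplit(toks, "(?=[()])", perl = TRUE))
  toks <- toks[nzchar(toks)]
  atoms <- sys$atoms
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  eat <- function() { t <- peek(); pos <<- pos + 1L; t }
  primitive <- function() {
    t <- eat()
    if (is.na(t)) stop("selection ended unexpectedly: ", spec)
    if (t == "(") {
      v <- expr()
      if (!identical(eat(), ")")) stop("missing ')' in selection: ", spec)
      return(v)
    }
    if (t == "not") return(!primitive())
    arg <- eat()
    if (is.na(arg)) stop("keyword '", t, "' needs an argument")
    switch(t,
      resname = atoms$resname == arg,
      element = atoms$element == arg,
      molid = {
        if (grepl(":", arg)) {
          rng <- as.integer(strsplit(arg, ":")[[1]])
          atoms$molid >= rng[1] & atoms$molid <= rng[2]
        } else atoms$molid == as.integer(arg)
      },
      stop("unknown selection keyword: ", t))
  }
  factor_ <- function() {
    if (identical(peek(), "not")) { eat(); return(!factor_()) }
    primitive()
  }
  term <- function() {
    v <- factor_()
    while (identical(peek(), "and")) { eat(); v <- v & factor_() }
    v
  }
  expr <- function() {
    v <- term()
    while (identical(peek(), "or")) { eat(); v <- v | term() }
    v
  }
  mask <- expr()
  if (pos <= length(toks)) stop("trailing tokens in selection: ", spec)
  idx <- which(mask)
  if (!length(idx)) stop("selection matched no atoms: ", spec)
  structure(list(label = label, atom_indices = idx,
                 molecule_ids = sort(unique(atoms$molid[idx]))),
            class = "group_selection")
}

#' @export
print.group_selection <- function(x, ...) {
  cat(sprintf("<group_selection> '%s': %d atoms in %d molecules\n",
              x$label, length(x$atom_indices), length(x$molecule_ids)))
  invisible(x)
}

check_groups_disjoint <- function(a, b) {
  if (length(intersect(a$atom_indices, b$atom_indices)))
    stop("groups '", a$label, "' and '", b$label, "' share atoms")
  invisible(TRUE)
}
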