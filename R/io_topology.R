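#' Read / write the dispermd topology text format
#'
#' A small sectioned text format (1-based indices, `;` comments):
#' \preformatted{
#'   [defaults]
#'   f14_lj 0.5
#'   f14_coul 0.5
#'   [atoms]
#'   ; index name element resname molid charge sigma epsilon mass donor acceptor
#'   1 C1 C NPX 1 -0.115 0.355 0.29288 12.011 0 0
#'   [bonds]
#'   ; i j r0(nm) k(kJ/mol/nm^2)
#'   [angles]
#'   ; i j k theta0(deg) ktheta(kJ/mol/rad^2)
#'   [pairs14]
#'   ; i j
#' }
#' `pairs14` may be omitted, in which case 1-4 pairs are derived from the
#' bond graph.
#'
#' @param path file path
#' @return an [md_system()]
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  section <- ""
  at <- list(); bd <- list(); an <- list(); p14 <- list()
  f14 <- c(lj = 0.5, coul = 0.5)
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(l)) next
    if (grepl("^\\[", l)) {
      section <- gsub("[][]", "", l)
      next
    }
    tok <- strsplit(l, "\\s+")[[1]]
    bad <- function(what) parse_fail(path, ln, what)
    switch(section,
      defaults = {
        if (length(tok) != 2) bad("expected 'key value' in [defaults]")
        if (tok[1] == "f14_lj") f14["lj"] <- as.numeric(tok[2])
        else if (tok[1] == "f14_coul") f14["coul"] <- as.numeric(tok[2])
        else bad(paste("unknown default:", tok[1]))
      },
      atoms = {
        if (length(tok) < 9) bad("atom line needs >= 9 fields")
        v <- suppressWarnings(as.numeric(tok[c(1, 5, 6, 7, 8, 9)]))
        if (anyNA(v)) bad("malformed numeric field in [atoms]")
        at[[length(at) + 1L]] <- data.frame(
          name = tok[2], element = tok[3], resname = tok[4],
          molid = as.integer(tok[5]), charge = v[3], sigma = v[4],
          epsilon = v[5], mass = v[6],
          donor = length(tok) >= 10 && tok[10] == "1",
          acceptor = length(tok) >= 11 && tok[11] == "1")
      },
      bonds = {
        v <- suppressWarnings(as.numeric(tok))
        if (length(v) != 4 || anyNA(v)) bad("bond line needs 'i j r0 k'")
        bd[[length(bd) + 1L]] <- data.frame(i = as.integer(v[1]),
                                            j = as.integer(v[2]),
                                            r0 = v[3], k = v[4])
      },
      angles = {
        v <- suppressWarnings(as.numeric(tok))
        if (length(v) != 5 || anyNA(v)) bad("angle line needs 'i j k theta0 ktheta'")
        an[[length(an) + 1L]] <- data.frame(i = as.integer(v[1]),
                                            j = as.integer(v[2]),
                                            k = as.integer(v[3]),
                                            theta0 = v[4], ktheta = v[5])
      },
      pairs14 = {
        v <- suppressWarnings(as.integer(tok))
        if (length(v) != 2 || anyNA(v)) bad("pairs14 line needs 'i j'")
        p14[[length(p14) + 1L]] <- data.frame(i = v[1], j = v[2])
      },
      bad(paste("content outside a known section:", l)))
  }
  if (!length(at)) stop("no [atoms] section in ", path)
  suppressWarnings(md_system(
    do.call(rbind, at),
    bonds = if (length(bd)) do.call(rbind, bd) else NULL,
    angles = if (length(an)) do.call(rbind, an) else NULL,
    pairs14 = if (length(p14)) do.call(rbind, p14) else NULL,
    f14_lj = f14[["lj"]], f14_coul = f14[["coul"]]))
}

#' @rdname read_topology
#' @param sys an [md_system()]
#' @export
write_topology <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("; dispermd topology")
  w("[defaults]")
  w("f14_lj %g", sys$f14_lj)
  w("f14_coul %g", sys$f14_coul)
  w("[atoms]")
  w("; index name element resname molid charge sigma epsilon mass donor acceptor")
  a <- sys$atoms
  for (i in seq_len(nrow(a)))
    w("%d %s %s %s %d %.6f %.6f %.6f %.6f %d %d", i, a$name[i], a$element[i],
      a$resname[i], a$molid[i], a$charge[i], a$sigma[i], a$epsilon[i],
      a$mass[i], as.integer(a$donor[i]), as.integer(a$acceptor[i]))
  w("[bonds]")
  b <- sys$bonds
  for (i in seq_len(nrow(b))) w("%d %d %.6f %.2f", b$i[i], b$j[i], b$r0[i], b$k[i])
  w("[angles]")
  g <- sys$angles
  for (i in seq_len(nrow(g)))
    w("%d %d %d %.4f %.2f", g$i[i], g$j[i], g$k[i], g$theta0[i], g$ktheta[i])
  w("[pairs14]")
  p <- sys$pairs14
  for (i in seq_len(nrow(p))) w("%d %d", p$i[i], p$j[i])
  invisible(path)
}
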