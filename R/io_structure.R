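#' Read a structure file (PDB, GRO or XYZ)
#'
#' Coordinates are converted to the internal nm convention at the boundary:
#' PDB and XYZ files are in Angstrom, GRO in nm.  PDB boxes come from the
#' CRYST1 record, GRO boxes from the final box line; XYZ carries no box
#' (the returned box is `NULL` and must be supplied by the caller).
#'
#' @param path file path
#' @param format one of `"pdb"`, `"gro"`, `"xyz"`; default guessed from the
#'   file extension
#' @return list with `atoms` (data.frame: name, element, resname, molid,
#'   x, y, z in nm) and `box` (a [simulation_box()] or `NULL`)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         pdb = read_pdb(path),
         gro = read_gro(path),
         xyz = read_xyz(path),
         stop("unsupported structure format: ", format))
}

#' Write a structure file
#'
#' @param atoms data.frame as returned by [read_structure()], or an
#'   `md_system` plus `positions`
#' @param path output path
#' @param format `"pdb"`, `"gro"` or `"xyz"`
#' @param box a [simulation_box()] (required for gro; optional CRYST1 for pdb)
#' @param positions optional N x 3 matrix (nm) overriding `atoms$x/y/z`
#' @export
write_structure <- function(atoms, path, format = c("pdb", "gro", "xyz"),
                            box = NULL, positions = NULL) {
  format <- match.arg(format)
  if (inherits(atoms, "md_system")) {
    a <- atoms$atoms
    atoms <- data.frame(name = a$name, element = a$element,
                        resname = a$resname, molid = a$molid,
                        x = NA_real_, y = NA_real_, z = NA_real_)
  }
  if (!is.null(positions)) {
    atoms$x <- positions[, 1]; atoms$y <- positions[, 2]; atoms$z <- positions[, 3]
  }
  switch(format,
         pdb = write_pdb(atoms, path, box),
         gro = write_gro(atoms, path, box),
         xyz = write_xyz(atoms, path))
  invisible(path)
}

parse_fail <- function(path, lineno, what) {
  stop(sprintf("parse error in %s, line %d: %s", path, lineno, what))
}

read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  rec <- list()
  k <- 0L
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    tag <- substr(l, 1, 6)
    if (tag == "CRYST1") {
      v <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                         substr(l, 25, 33), substr(l, 34, 40),
                                         substr(l, 41, 47), substr(l, 48, 54))))
      if (anyNA(v)) parse_fail(path, ln, "malformed CRYST1 record")
      box <- simulation_box(lengths = v[1:3] / 10, angles = v[4:6])
    } else if (tag == "ATOM  " || tag == "HETATM") {
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                           substr(l, 47, 54))))
      if (anyNA(xyz)) parse_fail(path, ln, "malformed coordinates in ATOM record")
      k <- k + 1L
      el <- trimws(substr(l, 77, 78))
      nm <- trimws(substr(l, 13, 16))
      if (!nzchar(el)) el <- substr(gsub("[0-9]", "", nm), 1, 1)
      molid <- suppressWarnings(as.integer(substr(l, 23, 26)))
      if (is.na(molid)) parse_fail(path, ln, "malformed residue number")
      rec[[k]] <- data.frame(name = nm, element = el,
                             resname = trimws(substr(l, 18, 21)),
                             molid = molid,
                             x = xyz[1] / 10, y = xyz[2] / 10, z = xyz[3] / 10)
    }
  }
  if (!k) stop("no ATOM/HETATM records in ", path)
  list(atoms = do.call(rbind, rec), box = box)
}

write_pdb <- function(atoms, path, box = NULL, con = NULL, model = NULL) {
  own <- is.null(con)
  if (own) con <- file(path, "w")
  if (!is.null(box)) {
    p <- box_parameters(box)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       p$a * 10, p$b * 10, p$c * 10, p$alpha, p$beta, p$gamma),
               con)
  }
  if (!is.null(model)) writeLines(sprintf("MODEL     %4d", model), con)
  n <- nrow(atoms)
  ser <- ((seq_len(n) - 1L) %% 99999L) + 1L
  res <- ((atoms$molid - 1L) %% 9999L) + 1L
  writeLines(sprintf("ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     ser, substr(atoms$name, 1, 4), substr(atoms$resname, 1, 4),
                     res, atoms$x * 10, atoms$y * 10, atoms$z * 10,
                     substr(atoms$element, 1, 2)), con)
  if (!is.null(model)) writeLines("ENDMDL", con)
  if (own) { writeLines("END", con); close(con) }
  invisible(path)
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) parse_fail(path, 2, "atom count expected")
  if (length(lines) < n + 3) parse_fail(path, length(lines), "truncated atom block")
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    l <- lines[i + 2]
    molid <- suppressWarnings(as.integer(substr(l, 1, 5)))
    resname <- trimws(substr(l, 6, 10))
    name <- trimws(substr(l, 11, 15))
    xyz <- suppressWarnings(as.numeric(c(substr(l, 21, 28), substr(l, 29, 36),
                                         substr(l, 37, 44))))
    if (is.na(molid) || anyNA(xyz))
      parse_fail(path, i + 2, "malformed GRO atom line")
    el <- substr(gsub("[0-9]", "", name), 1, 1)
    rec[[i]] <- data.frame(name = name, element = el, resname = resname,
                           molid = molid, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  bl <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (anyNA(bl) || !(length(bl) %in% c(3, 9)))
    parse_fail(path, n + 3, "malformed box line (expect 3 or 9 numbers, nm)")
  box <- if (length(bl) == 3) {
    simulation_box(lengths = bl)
  } else {
    # v1(x) v2(y) v3(z) v1(y) v1(z) v2(x) v2(z) v3(x) v3(y)
    v <- matrix(0, 3, 3)
    v[1, ] <- c(bl[1], bl[4], bl[5])
    v[2, ] <- c(bl[6], bl[2], bl[7])
    v[3, ] <- c(bl[8], bl[9], bl[3])
    simulation_box(vectors = v)
  }
  list(atoms = do.call(rbind, rec), box = box)
}

write_gro <- function(atoms, path, box) {
  if (is.null(box)) stop("GRO format requires a box")
  con <- file(path, "w")
  writeLines("generated by dispermd", con)
  writeLines(sprintf("%5d", nrow(atoms)), con)
  n <- nrow(atoms)
  ser <- ((seq_len(n) - 1L) %% 99999L) + 1L
  res <- ((atoms$molid - 1L) %% 99999L) + 1L
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res, substr(atoms$resname, 1, 5),
                     substr(atoms$name, 1, 5), ser,
                     atoms$x, atoms$y, atoms$z), con)
  v <- box$vectors
  if (all(v[upper.tri(v) | lower.tri(v)] == 0)) {
    writeLines(sprintf("%10.5f%10.5f%10.5f", v[1, 1], v[2, 2], v[3, 3]), con)
  } else {
    writeLines(paste(sprintf("%10.5f", c(v[1, 1], v[2, 2], v[3, 3],
                                         v[1, 2], v[1, 3], v[2, 1],
                                         v[2, 3], v[3, 1], v[3, 2])),
                     collapse = ""), con)
  }
  close(con)
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) parse_fail(path, 1, "atom count expected")
  if (length(lines) < n + 2) parse_fail(path, length(lines), "truncated XYZ")
  toks <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  el <- vapply(toks, `[[`, character(1), 1)
  xyz <- t(vapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk[2:4]))
    v
  }, numeric(3)))
  if (anyNA(xyz)) {
    bad <- which(apply(is.na(xyz), 1, any))[1]
    parse_fail(path, bad + 2, "malformed XYZ coordinate line")
  }
  list(atoms = data.frame(name = el, element = el, resname = "MOL",
                          molid = 1L,
                          x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10),
       box = NULL)
}

write_xyz <- function(atoms, path, con = NULL, comment = "") {
  own <- is.null(con)
  if (own) con <- file(path, "w")
  writeLines(as.character(nrow(atoms)), con)
  writeLines(comment, con)
  writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", atoms$element,
                     atoms$x * 10, atoms$y * 10, atoms$z * 10), con)
  if (own) close(con)
  invisible(path)
}
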