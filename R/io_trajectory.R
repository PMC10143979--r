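#' Write a trajectory (multi-frame XYZ, multi-model PDB, or binary)
#'
#' The binary format (`"bin"`) is little-endian and documented here:
#' \preformatted{
#'   magic   4 bytes  "DMDT"
#'   version int32    1
#'   n_atoms int32
#'   has_vel int32    0 or 1
#'   n_frame int32
#'   then per frame:
#'     time  float64 (ps)
#'     box   9 x float64 (lattice vectors, row-major, nm)
#'     pos   3N x float64 (x1 y1 z1 x2 ..., nm)
#'     vel   3N x float64 (only if has_vel = 1, nm/ps)
#' }
#' Text formats use Angstrom (XYZ, PDB) with the time stamp in the comment
#' line / MODEL records; the binary format round-trips bit-exactly.
#'
#' @param traj an [md_trajectory()]
#' @param path output path
#' @param format `"multi_xyz"`, `"multi_pdb"` or `"bin"`
#' @param atoms optional atom table (for element/residue columns of the text
#'   formats); single-letter carbon placeholders are used if absent
#' @export
write_trajectory <- function(traj, path,
                             format = c("bin", "multi_xyz", "multi_pdb"),
                             atoms = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "md_trajectory"))
  n <- nrow(traj$frames[[1]]$positions)
  if (is.null(atoms))
    atoms <- data.frame(name = rep("C", n), element = rep("C", n),
                        resname = rep("MOL", n), molid = rep(1L, n))
  if (inherits(atoms, "md_system")) atoms <- atoms$atoms
  switch(format,
    bin = {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(charToRaw("DMDT"), con)
      has_vel <- !is.null(traj$frames[[1]]$velocities)
      writeBin(as.integer(c(1L, n, has_vel, length(traj$frames))), con,
               size = 4, endian = "little")
      for (f in traj$frames) {
        writeBin(as.numeric(f$time), con, size = 8, endian = "little")
        bv <- if (is.null(f$box)) diag(0, 3) else f$box$vectors
        writeBin(as.numeric(t(bv)), con, size = 8, endian = "little")
        writeBin(as.numeric(t(f$positions)), con, size = 8, endian = "little")
        if (has_vel) {
          if (is.null(f$velocities)) stop("inconsistent velocity presence across frames")
          writeBin(as.numeric(t(f$velocities)), con, size = 8, endian = "little")
        }
      }
    },
    multi_xyz = {
      con <- file(path, "w")
      on.exit(close(con))
      for (f in traj$frames) {
        a <- atoms
        a$x <- f$positions[, 1]; a$y <- f$positions[, 2]; a$z <- f$positions[, 3]
        write_xyz(a, path, con = con, comment = sprintf("t= %.6f ps", f$time))
      }
    },
    multi_pdb = {
      con <- file(path, "w")
      on.exit(close(con))
      i <- 0L
      for (f in traj$frames) {
        i <- i + 1L
        a <- atoms
        a$x <- f$positions[, 1]; a$y <- f$positions[, 2]; a$z <- f$positions[, 3]
        writeLines(sprintf("REMARK   t= %.6f ps", f$time), con)
        write_pdb(a, path, box = f$box, con = con, model = i)
      }
      writeLines("END", con)
    })
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path input path
#' @param format `"bin"`, `"multi_xyz"` or `"multi_pdb"` (default from
#'   content sniffing: binary magic, else extension)
#' @param box fallback [simulation_box()] for formats without one (multi_xyz)
#' @return an [md_trajectory()]
#' @export
read_trajectory <- function(path, format = c("auto", "bin", "multi_xyz",
                                             "multi_pdb"),
                            box = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    magic <- readBin(path, "raw", 4)
    format <- if (identical(rawToChar(magic), "DMDT")) "bin"
              else if (grepl("pdb$", path)) "multi_pdb" else "multi_xyz"
  }
  frames <- switch(format,
    bin = {
      con <- file(path, "rb")
      on.exit(close(con))
      magic <- rawToChar(readBin(con, "raw", 4))
      if (magic != "DMDT") stop("not a dispermd binary trajectory: ", path)
      hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
      if (hdr[1] != 1L) stop("unsupported binary trajectory version ", hdr[1])
      n <- hdr[2]; has_vel <- hdr[3] == 1L; nf <- hdr[4]
      lapply(seq_len(nf), function(i) {
        tm <- readBin(con, "numeric", 1, size = 8, endian = "little")
        bv <- matrix(readBin(con, "numeric", 9, size = 8, endian = "little"),
                     3, 3, byrow = TRUE)
        pos <- matrix(readBin(con, "numeric", 3 * n, size = 8, endian = "little"),
                      n, 3, byrow = TRUE)
        vel <- if (has_vel)
          matrix(readBin(con, "numeric", 3 * n, size = 8, endian = "little"),
                 n, 3, byrow = TRUE) else NULL
        bx <- if (all(bv == 0)) box else simulation_box(vectors = bv)
        md_frame(pos, box = bx, time = tm, velocities = vel)
      })
    },
    multi_xyz = {
      lines <- readLines(path)
      frames <- list()
      i <- 1L; k <- 0L
      while (i <= length(lines)) {
        n <- suppressWarnings(as.integer(trimws(lines[i])))
        if (is.na(n)) parse_fail(path, i, "atom count expected")
        cm <- lines[i + 1]
        tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", cm)))
        if (is.na(tm)) tm <- k
        toks <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
        xyz <- t(vapply(toks, function(tk)
          suppressWarnings(as.numeric(tk[2:4])), numeric(3)))
        if (anyNA(xyz)) parse_fail(path, i + 2, "malformed coordinate line")
        k <- k + 1L
        frames[[k]] <- md_frame(xyz / 10, box = box, time = tm)
        i <- i + 2L + n
      }
      frames
    },
    multi_pdb = {
      lines <- readLines(path)
      frames <- list()
      cur <- list(); k <- 0L; tm <- NA_real_; bx <- box
      flush_model <- function() {
        if (!length(cur)) return()
        xyz <- do.call(rbind, cur)
        k <<- k + 1L
        frames[[k]] <<- md_frame(xyz, box = bx,
                                 time = if (is.na(tm)) k - 1 else tm)
        cur <<- list()
      }
      for (ln in seq_along(lines)) {
        l <- lines[ln]
        tag <- substr(l, 1, 6)
        if (startsWith(l, "REMARK") && grepl("t=", l)) {
          tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", l)))
        } else if (tag == "CRYST1") {
          v <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33),
                            substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)))
          bx <- simulation_box(lengths = v[1:3] / 10, angles = v[4:6])
        } else if (tag == "ATOM  " || tag == "HETATM") {
          xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                               substr(l, 47, 54))))
          if (anyNA(xyz)) parse_fail(path, ln, "malformed ATOM record")
          cur[[length(cur) + 1L]] <- xyz / 10
        } else if (startsWith(l, "ENDMDL")) {
          flush_model()
        }
      }
      flush_model()
      frames
    })
  md_trajectory(frames)
}
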