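#' Periodic simulation box
#'
#' A triclinic periodic box represented by a 3x3 matrix of lattice vectors
#' (rows a, b, c, in nm).  Lattice parameters a, b, c (nm) and alpha, beta,
#' gamma (degrees) are derived on demand; the vector and parameter forms are
#' inter-convertible up to a rigid rotation (the parameter form is rebuilt in
#' the standard crystallographic orientation with a along x and b in the
#' x-y plane).
#'
#' @param vectors 3x3 numeric matrix of lattice vectors in nm (rows a, b, c),
#'   or `NULL` if `lengths` is given.
#' @param lengths length-3 vector of cell edge lengths a, b, c in nm.
#' @param angles length-3 vector of cell angles alpha, beta, gamma in degrees
#'   (default all 90).
#' @return An object of class `simulation_box`.
#' @examples
#' b <- simulation_box(lengths = c(6, 6, 6))
#' box_volume(b)           # 216 nm^3
#' box_parameters(b)$a     # 6
#' @export
simulation_box <- function(vectors = NULL, lengths = NULL,
                           angles = c(90, 90, 90)) {
  if (is.null(vectors)) {
    if (is.null(lengths)) stop("supply either lattice vectors or edge lengths")
    stopifnot(length(lengths) == 3, length(angles) == 3)
    a <- lengths[1]; b <- lengths[2]; cc <- lengths[3]
    al <- angles[1] * pi / 180
    be <- angles[2] * pi / 180
    ga <- angles[3] * pi / 180
    # standard orientation: a along x, b in xy-plane
    v <- matrix(0, 3, 3)
    v[1, ] <- c(a, 0, 0)
    v[2, ] <- c(b * cos(ga), b * sin(ga), 0)
    cx <- cc * cos(be)
    cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
    cz2 <- cc^2 - cx^2 - cy^2
    if (cz2 <= 0) stop("degenerate cell: angles incompatible with a positive volume")
    v[3, ] <- c(cx, cy, sqrt(cz2))
    # snap tiny numerical noise so orthorhombic cells are exactly diagonal
    v[abs(v) < 1e-12] <- 0
    vectors <- v
  }
  vectors <- as.matrix(vectors)
  stopifnot(all(dim(vectors) == c(3, 3)), all(is.finite(vectors)))
  if (det(vectors) <= 0) stop("box has non-positive volume")
  structure(list(vectors = unname(vectors)), class = "simulation_box")
}

#' @rdname simulation_box
#' @param box a `simulation_box`
#' @export
box_volume <- function(box) {
  det(box$vectors)
}

#' @rdname simulation_box
#' @export
box_parameters <- function(box) {
  v <- box$vectors
  a <- sqrt(sum(v[1, ]^2)); b <- sqrt(sum(v[2, ]^2)); cc <- sqrt(sum(v[3, ]^2))
  ang <- function(u, w) acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
  list(a = a, b = b, c = cc,
       alpha = ang(v[2, ], v[3, ]),
       beta  = ang(v[1, ], v[3, ]),
       gamma = ang(v[1, ], v[2, ]))
}

#' @rdname simulation_box
#' @export
is_cubic <- function(box) {
  p <- box_parameters(box)
  isTRUE(all.equal(c(p$a, p$b), c(p$b, p$c), tolerance = 1e-9)) &&
    max(abs(c(p$alpha, p$beta, p$gamma) - 90)) < 1e-7
}

#' @export
print.simulation_box <- function(x, ...) {
  p <- box_parameters(x)
  cat(sprintf("<simulation_box> a=%.4f b=%.4f c=%.4f nm  alpha=%.2f beta=%.2f gamma=%.2f deg  V=%.4f nm^3\n",
              p$a, p$b, p$c, p$alpha, p$beta, p$gamma, box_volume(x)))
  invisible(x)
}

# wrap a displacement matrix (n x 3) to the minimum image
minimum_image <- function(d, box) {
  v <- box$vectors
  if (all(v[upper.tri(v) | lower.tri(v)] == 0)) {
    L <- diag(v)
    for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  } else {
    s <- d %*% solve(v)
    s <- s - round(s)
    d <- s %*% v
  }
  d
}

# wrap absolute positions into the primary cell [0, L)
wrap_positions <- function(pos, box) {
  v <- box$vectors
  s <- pos %*% solve(v)
  s <- s - floor(s)
  s %*% v
}
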