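#' System topology: atoms, parameters, bonded terms, exclusions
#'
#' The central container tying atom identities (name, element, residue,
#' molecule) to nonbonded parameters (charge e, sigma nm, epsilon kJ/mol,
#' mass g/mol), bonded terms (harmonic bonds and angles), scaled 1-4 pairs
#' and the nonbonded exclusion list.  1-2 and 1-3 pairs are always excluded;
#' 1-4 pairs are excluded from the plain nonbonded sum and re-added with the
#' OPLS scaling factors (default 0.5 for both LJ and Coulomb).
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `molid`, `charge`, `sigma`, `epsilon`, `mass` and optional logical
#'   `donor` (hydrogen-bond donor hydrogen) and `acceptor`.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `r0` (nm), `k` (kJ/mol/nm^2); may have zero rows.
#' @param angles data.frame with columns `i`, `j`, `k` (vertex `j`),
#'   `theta0` (degrees), `ktheta` (kJ/mol/rad^2); may have zero rows.
#' @param pairs14 optional data.frame with columns `i`, `j`; if `NULL`,
#'   derived from the bond graph (all pairs at graph distance 3).
#' @param f14_lj,f14_coul 1-4 scaling factors in `[0, 1]`.
#' @return An object of class `md_system`.
#' @export
md_system <- function(atoms, bonds = NULL, angles = NULL, pairs14 = NULL,
                      f14_lj = 0.5, f14_coul = 0.5) {
  atoms <- as.data.frame(atoms)
  need <- c("name", "element", "resname", "molid", "charge", "sigma",
            "epsilon", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1) stop("empty atom table")
  if (any(!nzchar(atoms$element))) stop("element must be non-empty")
  if (any(atoms$sigma <= 0)) stop("sigma must be > 0")
  if (any(atoms$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(atoms$mass <= 0)) stop("mass must be > 0")
  if (any(!is.finite(atoms$charge))) stop("charges must be finite")
  if (is.null(atoms$donor)) atoms$donor <- FALSE
  if (is.null(atoms$acceptor)) atoms$acceptor <- FALSE
  empty_b <- data.frame(i = integer(), j = integer(),
                        r0 = numeric(), k = numeric())
  empty_a <- data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), ktheta = numeric())
  if (is.null(bonds)) bonds <- empty_b
  if (is.null(angles)) angles <- empty_a
  bonds <- as.data.frame(bonds); angles <- as.data.frame(angles)
  if (nrow(bonds) && (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)))
    stop("bond index out of range")
  if (nrow(bonds) && any(bonds$r0 < 0 | bonds$k < 0))
    stop("bond r0 and k must be >= 0")
  if (nrow(angles) && any(c(angles$i, angles$j, angles$k) < 1 |
                          c(angles$i, angles$j, angles$k) > n))
    stop("angle index out of range")
  if (!(f14_lj >= 0 && f14_lj <= 1 && f14_coul >= 0 && f14_coul <= 1))
    stop("1-4 scaling factors must lie in [0, 1]")

  adj <- bond_adjacency(n, bonds)
  dist3 <- bonded_neighbourhoods(adj)
  if (is.null(pairs14)) pairs14 <- dist3$pairs14
  pairs14 <- as.data.frame(pairs14)
  if (is.null(pairs14$i)) pairs14 <- data.frame(i = integer(), j = integer())

  sys <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        pairs14 = pairs14[, c("i", "j"), drop = FALSE],
                        exclusions = dist3$excl,
                        f14_lj = f14_lj, f14_coul = f14_coul),
                   class = "md_system")
  qnet <- sum(atoms$charge)
  if (abs(qnet) > 1e-6)
    warning(sprintf("system has non-zero net charge %+.4f e", qnet))
  sys
}

# adjacency list from bond table
bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# pairs at bond-graph distance 1-2 (exclusions also collect 1-4, which are
# removed from the plain sum and re-added scaled)
bonded_neighbourhoods <- function(adj) {
  n <- length(adj)
  ex_i <- integer(); ex_j <- integer()
  p14_i <- integer(); p14_j <- integer()
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    if (!length(d1)) next
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    for (j in c(d1, d2)) if (j > i) { ex_i <- c(ex_i, i); ex_j <- c(ex_j, j) }
    for (j in d3) if (j > i) { p14_i <- c(p14_i, i); p14_j <- c(p14_j, j) }
  }
  list(excl = data.frame(i = ex_i, j = ex_j),
       pairs14 = data.frame(i = p14_i, j = p14_j))
}

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf("<md_system> %d atoms, %d molecules, %d bonds, %d angles, %d 1-4 pairs\n",
              nrow(x$atoms), length(unique(x$atoms$molid)),
              nrow(x$bonds), nrow(x$angles), nrow(x$pairs14)))
  cat(sprintf("  residues: %s; net charge %+.3f e\n",
              paste(unique(x$atoms$resname), collapse = ", "),
              sum(x$atoms$charge)))
  invisible(x)
}

#' Number of atoms in a system
#' @param sys an `md_system`
#' @export
n_atoms <- function(sys) nrow(sys$atoms)

#' Total molar mass of a system or of one molecule (g/mol)
#' @param sys an `md_system`
#' @param molid optional molecule id
#' @export
system_mass <- function(sys, molid = NULL) {
  if (is.null(molid)) sum(sys$atoms$mass)
  else sum(sys$atoms$mass[sys$atoms$molid == molid])
}

# flatten to the list the C++ kernels expect (0-based indices)
topology_for_kernel <- function(sys) {
  ex <- rbind(as.matrix(sys$exclusions), as.matrix(sys$pairs14[, c("i", "j")]))
  if (is.null(dim(ex)) || nrow(ex) == 0) ex <- matrix(integer(), 0, 2)
  bonds <- if (nrow(sys$bonds))
    cbind(sys$bonds$i - 1L, sys$bonds$j - 1L, sys$bonds$r0, sys$bonds$k)
  else matrix(numeric(), 0, 4)
  angles <- if (nrow(sys$angles))
    cbind(sys$angles$i - 1L, sys$angles$j - 1L, sys$angles$k - 1L,
          sys$angles$theta0 * pi / 180, sys$angles$ktheta)
  else matrix(numeric(), 0, 5)
  p14 <- if (nrow(sys$pairs14))
    cbind(sys$pairs14$i - 1L, sys$pairs14$j - 1L)
  else matrix(integer(), 0, 2)
  list(sigma = sys$atoms$sigma, epsilon = sys$atoms$epsilon,
       charge = sys$atoms$charge, mass = sys$atoms$mass,
       molid = as.integer(sys$atoms$molid),
       exclusions = matrix(as.integer(ex - 1L), ncol = 2),
       bonds = bonds, angles = angles,
       pairs14 = matrix(as.integer(p14), ncol = 2),
       f14_lj = sys$f14_lj, f14_coul = sys$f14_coul)
}

#' Combine several molecular systems into one
#'
#' Replicates and concatenates systems (e.g. many copies of an API template
#' plus polymer chains), renumbering atom and molecule indices.
#'
#' @param pieces list of lists with elements `system` (an `md_system`) and
#'   `count` (number of copies)
#' @return An `md_system` containing all copies in order.
#' @export
combine_systems <- function(pieces) {
  at <- list(); bd <- list(); an <- list(); p14 <- list()
  off <- 0L; mol_off <- 0L; k <- 1L
  for (p in pieces) {
    s <- p$system
    for (cnt in seq_len(p$count)) {
      a <- s$atoms
      a$molid <- a$molid + mol_off
      at[[k]] <- a
      if (nrow(s$bonds)) {
        b <- s$bonds; b$i <- b$i + off; b$j <- b$j + off; bd[[k]] <- b
      }
      if (nrow(s$angles)) {
        g <- s$angles; g$i <- g$i + off; g$j <- g$j + off; g$k <- g$k + off
        an[[k]] <- g
      }
      if (nrow(s$pairs14)) {
        q <- s$pairs14; q$i <- q$i + off; q$j <- q$j + off; p14[[k]] <- q
      }
      off <- off + nrow(s$atoms)
      mol_off <- mol_off + length(unique(s$atoms$molid))
      k <- k + 1L
    }
  }
  suppressWarnings(md_system(do.call(rbind, at),
                             bonds = if (length(bd)) do.call(rbind, bd) else NULL,
                             angles = if (length(an)) do.call(rbind, an) else NULL,
                             pairs14 = if (length(p14)) do.call(rbind, p14) else NULL))
}
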