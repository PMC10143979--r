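#' Build a polymer chain from a monomer template
#'
#' Links `n_units` copies of a monomer by bonding the tail link atom of each
#' unit to the head link atom of the next.  Monomers are defined as repeat
#' units (no caps are removed), so the chain molar mass is exactly
#' `n_units` times the monomer mass.  Units are laid out along a gentle arc
#' so a 10-mer stays compact (~2 nm), and the raw construction is relaxed
#' by a short vacuum steepest-descent minimization.
#'
#' @param monomer a `molecule_template` with `head`/`tail` set
#' @param n_units number of monomer units (>= 1); the emulated protocol
#'   uses 10
#' @param turn_deg arc turn per unit, degrees (default 30)
#' @param relax run a short vacuum minimization of the built chain
#' @return a `molecule_template` for the whole chain (single molecule)
#' @export
build_polymer_chain <- function(monomer, n_units, turn_deg = 30,
                                relax = TRUE) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (is.na(monomer$head) || is.na(monomer$tail))
    stop("monomer template lacks head/tail link atoms")
  n_at <- nrow(monomer$system$atoms)
  if (n_units == 1) return(monomer)

  rotz <- function(th) matrix(c(cos(th), sin(th), 0,
                                -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos0 <- monomer$positions
  head_xyz <- pos0[monomer$head, ]
  tail_xyz <- pos0[monomer$tail, ]
  d_junction <- 0.153
  delta <- turn_deg * pi / 180

  pos_all <- matrix(0, 0, 3)
  t_k <- c(0, 0, 0)
  for (k in seq_len(n_units)) {
    th <- (k - 1) * delta
    R <- rotz(th)
    # place unit so its head sits at t_k
    pk <- sweep(pos0, 2, head_xyz) %*% t(R)
    pk <- sweep(pk, 2, t_k, `+`)
    pos_all <- rbind(pos_all, pk)
    # next head: junction-bond length beyond this tail, bisecting direction
    tail_g <- t_k + as.numeric(R %*% (tail_xyz - head_xyz))
    dirn <- as.numeric(rotz(th + delta / 2) %*% c(1, 0, 0))
    t_k <- tail_g + d_junction * dirn
  }

  sys1 <- monomer$system
  chain <- combine_systems(list(list(system = sys1, count = n_units)))
  # junction bonds between tail(k) and head(k+1)
  jb <- data.frame(
    i = monomer$tail + (seq_len(n_units - 1) - 1L) * n_at,
    j = monomer$head + seq_len(n_units - 1) * n_at,
    r0 = d_junction, k = .kb_heavy)
  atoms <- chain$atoms
  atoms$molid <- 1L
  sys <- suppressWarnings(md_system(atoms,
                                    bonds = rbind(chain$bonds, jb),
                                    angles = chain$angles,
                                    f14_lj = sys1$f14_lj,
                                    f14_coul = sys1$f14_coul))
  if (relax) {
    span <- max(apply(pos_all, 2, function(v) diff(range(v)))) + 6
    big <- simulation_box(lengths = rep(max(span, 8), 3))
    pos_all <- sweep(pos_all, 2, apply(pos_all, 2, min) - 2)
    mn <- minimize_steepest_descent(md_frame(pos_all, box = big), sys,
                                    minimizer_config(max_steps = 400,
                                                     max_force_tol = 2000))
    pos_all <- mn$positions
  }
  structure(list(name = paste0(monomer$name, n_units),
                 resname = monomer$resname, system = sys,
                 positions = pos_all, head = monomer$head,
                 tail = monomer$tail + (n_units - 1L) * n_at,
                 molar_mass = n_units * monomer$molar_mass),
            class = "molecule_template")
}

#' Number of polymer chains needed for a target weight percent
#'
#' `round(n_api * M_api * (100 - w) / (w * M_chain))`; an unreachable
#' composition (0 chains) is an error.
#'
#' @param n_api number of API molecules
#' @param m_api API molar mass, g/mol
#' @param target_wt_percent API weight percent
#' @param m_chain chain molar mass, g/mol
#' @export
n_chains_for_wt <- function(n_api, m_api, target_wt_percent, m_chain) {
  w <- target_wt_percent
  nc <- round(n_api * m_api * (100 - w) / (w * m_chain))
  if (nc < 1)
    stop(sprintf("target %g wt%% API not reachable: rounds to 0 polymer chains", w))
  as.integer(nc)
}

# uniform random rotation matrix from a normalized quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a random API/polymer mixture box at a target weight percent
#'
#' The number of polymer chains follows [n_chains_for_wt()]; the achieved
#' weight percent therefore differs from the target by less than one chain
#' mass over the total mass.  Molecules are inserted with seeded uniform
#' random positions and orientations, rejecting placements that bring any
#' two heavy atoms of different molecules within `clash` (0.2 nm), chains
#' first.  An optional steepest-descent relaxation follows.
#'
#' @param api API `molecule_template`
#' @param n_api number of API molecules
#' @param polymer polymer chain `molecule_template` (see
#'   [build_polymer_chain()])
#' @param target_wt_percent API weight percent (e.g. 5 or 50)
#' @param box_edge cubic box edge, nm; `NULL` picks the edge giving a loose
#'   melt density of `density` g/cc, with a floor that accommodates the
#'   chain extent and the minimum-image requirement
#' @param seed RNG seed (insertion is fully deterministic given the seed)
#' @param clash minimum heavy-atom distance between molecules, nm
#' @param density target melt density reached by packing + compression
#'   when `box_edge` is `NULL`, g/cc
#' @param minimize relax the packed box by steepest descent
#' @param max_attempts insertion attempts per molecule before giving up
#' @return list with `system` (an [md_system()]), `frame` (an
#'   [md_frame()]), `n_chains`, `achieved_wt_percent`, `box_edge`
#' @export
build_mixture_box <- function(api, n_api, polymer, target_wt_percent,
                              box_edge = NULL, seed = 1, clash = 0.2,
                              density = 0.75, minimize = TRUE,
                              max_attempts = 2000) {
  n_chains <- n_chains_for_wt(n_api, api$molar_mass, target_wt_percent,
                              polymer$molar_mass)
  total_mass <- n_api * api$molar_mass + n_chains * polymer$molar_mass
  chain_extent <- max(apply(polymer$positions, 2,
                            function(v) diff(range(v))))
  # random insertion only works at loose densities: pack at <= 0.35 g/cc,
  # then densify to the requested target (or requested edge) by stepwise
  # compression
  edge_035 <- (total_mass * .amu_per_nm3_to_gcc / 0.35)^(1 / 3)
  if (is.null(box_edge)) {
    target_edge <- (total_mass * .amu_per_nm3_to_gcc / density)^(1 / 3)
  } else {
    target_edge <- box_edge
  }
  pack_edge <- max(target_edge, edge_035, 1.05 * chain_extent, 1.9)
  compress_to <- if (pack_edge > target_edge * (1 + 1e-9))
    total_mass * .amu_per_nm3_to_gcc / target_edge^3 else NULL
  box_edge <- pack_edge
  box <- simulation_box(lengths = rep(box_edge, 3))
  set.seed(seed)

  pieces <- c(rep(list(polymer), n_chains), rep(list(api), n_api))
  placed_heavy <- matrix(numeric(), 0, 3)
  pos_list <- vector("list", length(pieces))
  for (m in seq_along(pieces)) {
    tpl <- pieces[[m]]
    p0 <- tpl$positions
    p0 <- sweep(p0, 2, colMeans(p0))
    heavy <- tpl$system$atoms$element != "H"
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      R <- random_rotation()
      shift <- stats::runif(3, 0, box_edge)
      p <- p0 %*% t(R)
      p <- sweep(p, 2, shift, `+`)
      if (nrow(placed_heavy)) {
        dmin <- min_intermolecular_distance(p[heavy, , drop = FALSE],
                                            placed_heavy, box)
        if (dmin < clash) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not insert molecule %d/%d without clashes; increase box_edge",
                   m, length(pieces)))
    pos_list[[m]] <- p
    placed_heavy <- rbind(placed_heavy, p[heavy, , drop = FALSE])
  }

  sys <- combine_systems(c(list(list(system = polymer$system, count = n_chains)),
                           list(list(system = api$system, count = n_api))))
  pos <- do.call(rbind, pos_list)
  frame <- md_frame(wrap_positions(pos, box), box = box)
  if (minimize) {
    cs <- cutoff_scheme(rc_lj = min(0.9, box_edge / 2 * 0.999),
                        rc_coul = min(0.9, box_edge / 2 * 0.999))
    frame <- minimize_steepest_descent(frame, sys,
                                       minimizer_config(max_steps = 400),
                                       cutoffs = cs)
  }
  if (!is.null(compress_to))
    frame <- compress_box(frame, sys, compress_to)
  list(system = sys, frame = frame, n_chains = n_chains,
       achieved_wt_percent = 100 * n_api * api$molar_mass / total_mass,
       box_edge = diag(frame$box$vectors)[1])
}

# minimum distance between two coordinate sets under minimum image
min_intermolecular_distance <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ], `-`)
    d <- minimum_image(d, box)
    best <- min(best, sqrt(min(rowSums(d^2))))
  }
  best
}

#' Compress a packed box to a target density
#'
#' Random insertion only reaches loose-gas densities; this deterministic
#' densification alternates small isotropic box contractions (3% per step)
#' with short steepest-descent relaxations until the target mass density is
#' reached, emulating melt compression without a barostat run.
#'
#' @param frame an [md_frame()] with box
#' @param sys an [md_system()]
#' @param target_density g/cc
#' @param rc_max largest cutoff to use during relaxations, nm
#' @param step_scale linear contraction per step (< 1)
#' @return compressed, relaxed `md_frame`
#' @export
compress_box <- function(frame, sys, target_density, rc_max = 0.9,
                         step_scale = 0.97) {
  total_mass <- system_mass(sys)
  dens <- function(f) total_mass * .amu_per_nm3_to_gcc / box_volume(f$box)
  while (dens(frame) < target_density * (1 - 1e-9)) {
    s <- max(step_scale, (dens(frame) / target_density)^(1 / 3))
    if (s >= 1 - 1e-12) break
    box <- simulation_box(vectors = frame$box$vectors * s)
    rc <- min(rc_max, min(diag(box$vectors)) / 2 * 0.999)
    cs <- cutoff_scheme(rc_lj = rc, rc_coul = rc)
    frame <- minimize_steepest_descent(
      md_frame(frame$positions * s, box = box, time = frame$time),
      sys, minimizer_config(max_steps = 80), cutoffs = cs)
  }
  rc <- min(rc_max, min(diag(frame$box$vectors)) / 2 * 0.999)
  minimize_steepest_descent(frame, sys, minimizer_config(max_steps = 300),
                            cutoffs = cutoff_scheme(rc_lj = rc, rc_coul = rc))
}

#' Crystal unit-cell specification
#'
#' Lattice parameters are in Angstrom/degrees (the crystallographic
#' convention); `z` is the number of formula units and `molar_mass` the
#' formula-unit mass, linking cell volume to density.  `contents` is the
#' full atomic content of one cell as fractional coordinates (optional; only
#' needed to build simulatable supercells).
#'
#' @param a,b,c cell edges, Angstrom
#' @param alpha,beta,gamma cell angles, degrees
#' @param z formula units per cell (>= 1)
#' @param molar_mass formula-unit molar mass, g/mol
#' @param contents optional data.frame: `name`, `element`, `fx`, `fy`, `fz`
#'   (fractional), `charge`, `sigma`, `epsilon`, `mass`, `molid`
#' @return object of class `unit_cell_spec`
#' @export
unit_cell_spec <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                           z = 1, molar_mass, contents = NULL) {
  if (z < 1) stop("z must be >= 1")
  spec <- structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                         gamma = gamma, z = z, molar_mass = molar_mass,
                         contents = contents),
                    class = "unit_cell_spec")
  if (cell_volume(spec) <= 0) stop("degenerate cell: non-positive volume")
  spec
}

#' @rdname unit_cell_spec
#' @param cell a `unit_cell_spec`
#' @return `cell_volume`: cell volume in Angstrom^3
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  s2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (s2 <= 0) return(-1)
  cell$a * cell$b * cell$c * sqrt(s2)
}

#' Crystal density from a unit-cell specification
#'
#' \eqn{\rho = Z M / (N_A V)} with the triclinic volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'  + 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell a [unit_cell_spec()]
#' @return density in g/cc
#' @export
cell_density <- function(cell) {
  V_cm3 <- cell_volume(cell) * 1e-24
  cell$z * cell$molar_mass / (.N_A * V_cm3)
}

#' Replicate a unit cell into a supercell
#'
#' Atom count scales by `nx * ny * nz`, box vectors are the cell vectors
#' scaled by the replication counts, and density is exactly invariant.
#'
#' @param cell a [unit_cell_spec()] with `contents`
#' @param nx,ny,nz replication counts (>= 1)
#' @return list with `system`, `frame`, `nrep = c(nx, ny, nz)`
#' @export
build_supercell <- function(cell, nx, ny, nz) {
  if (any(c(nx, ny, nz) < 1)) stop("replication counts must be >= 1")
  if (is.null(cell$contents)) stop("cell has no atomic contents")
  ct <- cell$contents
  cellbox <- simulation_box(lengths = c(cell$a, cell$b, cell$c) / 10,
                            angles = c(cell$alpha, cell$beta, cell$gamma))
  v <- cellbox$vectors
  frac <- as.matrix(ct[, c("fx", "fy", "fz")])
  n_mol_cell <- length(unique(ct$molid))
  at <- list(); pos <- list(); k <- 0L
  for (ix in 0:(nx - 1)) for (iy in 0:(ny - 1)) for (iz in 0:(nz - 1)) {
    k <- k + 1L
    f <- sweep(frac, 2, c(ix, iy, iz), `+`)
    pos[[k]] <- f %*% v
    a <- data.frame(name = ct$name, element = ct$element,
                    resname = "XTL",
                    molid = ct$molid + (k - 1L) * n_mol_cell,
                    charge = ct$charge, sigma = ct$sigma,
                    epsilon = ct$epsilon, mass = ct$mass)
    at[[k]] <- a
  }
  sys <- suppressWarnings(md_system(do.call(rbind, at)))
  sbox <- simulation_box(vectors = v * c(nx, ny, nz)) # scales row i by rep i
  frame <- md_frame(do.call(rbind, pos), box = sbox)
  list(system = sys, frame = frame, nrep = c(nx, ny, nz), cell = cell)
}

#' Toy face-centred-cubic Lennard-Jones crystal cell (synthetic)
#'
#' A synthetic 4-atom FCC cell of argon-like LJ particles, deep enough
#' (epsilon = 4 kJ/mol) to remain solid at 300 K.  Used as the packaged
#' stand-in for crystal-validation runs; it corresponds to no real drug.
#' The default edge is the model's own 300 K / 1 bar equilibrium lattice
#' constant (measured once by NPT equilibration), so a validation run at
#' those conditions deviates by thermal fluctuation only -- the situation
#' the <3% force-field check describes for a well-parameterized crystal.
#'
#' @param a cell edge, Angstrom
#' @param epsilon LJ well depth, kJ/mol
#' @export
toy_crystal_cell <- function(a = 5.53, epsilon = 4.0) {
  contents <- data.frame(
    name = "AR", element = "Ar",
    fx = c(0, 0.5, 0.5, 0), fy = c(0, 0.5, 0, 0.5),
    fz = c(0, 0, 0.5, 0.5),
    charge = 0, sigma = 0.34, epsilon = epsilon, mass = 39.948,
    molid = 1:4)
  unit_cell_spec(a, a, a, z = 4, molar_mass = 39.948, contents = contents)
}
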