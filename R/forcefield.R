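#' Pairwise Lennard-Jones energy
#'
#' \eqn{E = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}.
#'
#' @param r separation, nm (> 0)
#' @param sigma LJ diameter, nm
#' @param epsilon well depth, kJ/mol
#' @return energy in kJ/mol
#' @export
lj_pair_energy <- function(r, sigma, epsilon) {
  if (any(r <= 0)) stop("r must be > 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Pairwise Coulomb energy
#'
#' \eqn{E = f q_i q_j / r} with \eqn{f = 138.935458} kJ mol^-1 nm e^-2.
#'
#' @param r separation, nm (> 0)
#' @param qi,qj charges, e
#' @return energy in kJ/mol
#' @export
coulomb_pair_energy <- function(r, qi, qj) {
  if (any(r <= 0)) stop("r must be > 0")
  .f_coul * qi * qj / r
}

#' OPLS geometric combining rules
#'
#' \eqn{\sigma_{ij} = \sqrt{\sigma_i\sigma_j}},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}}.
#'
#' @param sigma_i,sigma_j per-atom sigma, nm
#' @param epsilon_i,epsilon_j per-atom epsilon, kJ/mol
#' @return list with `sigma` and `epsilon`
#' @export
combine_params <- function(sigma_i, epsilon_i, sigma_j, epsilon_j) {
  if (anyNA(c(sigma_i, epsilon_i, sigma_j, epsilon_j)))
    stop("missing nonbonded parameters")
  list(sigma = sqrt(sigma_i * sigma_j), epsilon = sqrt(epsilon_i * epsilon_j))
}

#' Cutoff scheme for nonbonded interactions
#'
#' Defaults follow the simulation protocol emulated by the package: LJ
#' truncated at 1.4 nm (14 Angstrom); Coulomb treated by cutoff at 1.4 nm
#' with an energy shift so the potential is continuous at the cutoff (a
#' desk-scale stand-in for mesh Ewald electrostatics).  Pairs at exactly
#' r = r_c are included (closed interval).
#'
#' @param rc_lj LJ cutoff, nm
#' @param rc_coul Coulomb cutoff, nm
#' @param shift_lj shift LJ energy to zero at the cutoff (used by the
#'   integrator for energy conservation; off for plain analysis sums)
#' @param shift_coul shift Coulomb energy to zero at the cutoff
#' @param use_cells use a linked-cell neighbour search when the box allows
#'   (results are identical to the O(N^2) path)
#' @param dispersion_correction add the homogeneous-fluid LJ tail correction
#'   (off by default; the emulated protocol uses plain truncation)
#' @return list of class `cutoff_scheme`
#' @export
cutoff_scheme <- function(rc_lj = 1.4, rc_coul = 1.4,
                          shift_lj = FALSE, shift_coul = TRUE,
                          use_cells = TRUE, dispersion_correction = FALSE) {
  stopifnot(rc_lj > 0, rc_coul > 0)
  structure(list(rc_lj = rc_lj, rc_coul = rc_coul,
                 shift_lj = shift_lj, shift_coul = shift_coul,
                 use_cells = use_cells,
                 dispersion_correction = dispersion_correction),
            class = "cutoff_scheme")
}

opts_for_kernel <- function(cutoffs, sys = NULL, box = NULL) {
  disp <- 0
  if (isTRUE(cutoffs$dispersion_correction)) {
    if (is.null(sys) || is.null(box))
      stop("dispersion correction needs system and box")
    # homogeneous-fluid tail using system-average sigma^3, epsilon
    n <- n_atoms(sys)
    V <- box_volume(box)
    sig3 <- mean(sys$atoms$sigma^3)
    epsm <- mean(sys$atoms$epsilon)
    rc <- cutoffs$rc_lj
    sbar <- mean(sys$atoms$sigma)
    disp <- (8 * pi * n^2 * epsm * sig3 / (3 * V)) *
      ((sbar / rc)^9 / 3 - (sbar / rc)^3)
  }
  list(rc_lj = cutoffs$rc_lj, rc_coul = cutoffs$rc_coul,
       shift_lj = cutoffs$shift_lj, shift_coul = cutoffs$shift_coul,
       use_cells = cutoffs$use_cells, disp_corr = disp)
}

#' Potential energy (and forces) of a configuration
#'
#' Sums pairwise LJ and Coulomb terms over non-excluded pairs within the
#' cutoff under the minimum-image convention, scaled 1-4 pairs, plus
#' harmonic bond and angle terms.  Errors if any box dimension is below
#' twice the cutoff (minimum image invalid).
#'
#' @param frame an [md_frame()] (its box is used; must be present)
#' @param sys an [md_system()]
#' @param cutoffs a [cutoff_scheme()]
#' @param forces also return the analytic forces (kJ/mol/nm)
#' @return list of class `energy_breakdown` with `e_coul`, `e_lj`,
#'   `e_bonded`, `e_total` (= e_coul + e_lj + e_bonded), `virial`, and
#'   optionally `forces`
#' @export
system_potential <- function(frame, sys, cutoffs = cutoff_scheme(),
                             forces = FALSE) {
  if (is.null(frame$box)) stop("frame has no box; supply one")
  r <- cpp_potential(frame$positions, frame$box$vectors,
                     topology_for_kernel(sys),
                     opts_for_kernel(cutoffs, sys, frame$box),
                     forces)
  out <- list(e_coul = r$e_coul, e_lj = r$e_lj, e_bonded = r$e_bonded,
              e_total = r$e_coul + r$e_lj + r$e_bonded,
              virial = r$virial)
  if (forces) out$forces <- r$forces
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> E_coul=%.4f E_LJ=%.4f E_bonded=%.4f E_total=%.4f kJ/mol\n",
              x$e_coul, x$e_lj, x$e_bonded, x$e_total))
  invisible(x)
}

#' Plain Ewald Coulomb energy (small systems)
#'
#' Real-space + reciprocal-space + self-term Ewald sum without a mesh, for
#' cross-checking the cutoff electrostatics on systems of up to 3000 atoms
#' in orthorhombic boxes.  Energy only.
#'
#' @param frame an [md_frame()]
#' @param sys an [md_system()]
#' @param alpha splitting parameter, 1/nm (default 5/box min edge x 1.0)
#' @param kmax reciprocal-space cutoff (integer shells)
#' @param r_cut real-space cutoff, nm
#' @return Coulomb energy, kJ/mol (all pairs, no exclusions)
#' @export
ewald_energy <- function(frame, sys, alpha = NULL, kmax = 8, r_cut = NULL) {
  L <- diag(frame$box$vectors)
  if (is.null(r_cut)) r_cut <- min(L) / 2 * 0.999
  if (is.null(alpha)) alpha <- 3.0 / r_cut
  cpp_ewald_energy(frame$positions, frame$box$vectors,
                   sys$atoms$charge, alpha, as.integer(kmax), r_cut)
}
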