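#' Radial distribution function g(r)
#'
#' Histogram of pair distances (atoms j around atoms i) under minimum
#' image, normalized by the ideal-gas shell count:
#' \deqn{g_{ij}(r) = \frac{N_{ij}(r, r+\Delta r)\, V}{4\pi r^2 \Delta r\, N_i N_j}}
#' averaged over frames.  Distances are reported in Angstrom (the
#' crystallographic/reporting convention); internally everything is nm.
#' By default intramolecular pairs are included ("based on all atoms", so
#' bonded-distance peaks near ~1 Angstrom appear for same-species RDFs);
#' set `include_intramolecular = FALSE` for the intermolecular-only mode.
#'
#' @param traj an [md_trajectory()]
#' @param sys an [md_system()]
#' @param group_i,group_j [select_group()] selections (may be identical)
#' @param r_max maximum distance, Angstrom; default half the smallest box
#'   edge.  Must not exceed half the smallest box dimension.
#' @param dr bin width, Angstrom (default 0.02)
#' @param include_intramolecular include same-molecule pairs
#' @return `rdf_profile`: data.frame-backed object with `r` (bin centres,
#'   Angstrom) and `g`, plus `n_frames`, `dr`
#' @export
rdf <- function(traj, sys, group_i, group_j, r_max = NULL, dr = 0.02,
                include_intramolecular = TRUE) {
  box0 <- traj$frames[[1]]$box
  half_min <- min(vapply(1:3, function(k) sqrt(sum(box0$vectors[k, ]^2)),
                         numeric(1))) / 2 * 10 # Angstrom
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    stop(sprintf("r_max = %.2f A exceeds half the smallest box dimension (%.2f A)",
                 r_max, half_min))
  r_max_nm <- r_max / 10; dr_nm <- dr / 10
  nb <- ceiling(r_max_nm / dr_nm)
  molid <- as.integer(sys$atoms$molid)
  counts <- numeric(nb)
  vsum <- 0
  for (f in traj$frames) {
    h <- cpp_rdf_hist(f$positions, f$box$vectors,
                      group_i$atom_indices - 1L, group_j$atom_indices - 1L,
                      r_max_nm, dr_nm, molid, !include_intramolecular)
    counts <- counts + as.numeric(h)
    vsum <- vsum + box_volume(f$box)
  }
  nf <- n_frames(traj)
  V <- vsum / nf
  rc <- (seq_len(nb) - 0.5) * dr_nm
  ni <- length(group_i$atom_indices); nj <- length(group_j$atom_indices)
  g <- counts * V / (4 * pi * rc^2 * dr_nm * ni * nj * nf)
  structure(list(r = rc * 10, g = g, dr = dr, n_frames = nf,
                 group_i = group_i$label, group_j = group_j$label,
                 counts = counts, n_i = ni, n_j = nj, volume = V),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("<rdf_profile> %s around %s, %d bins of %.3f A over %d frames; max g = %.2f at r = %.2f A\n",
              x$group_j, x$group_i, length(x$r), x$dr, x$n_frames,
              x$g[pk], x$r[pk]))
  invisible(x)
}

#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is counted when (1) the donor-acceptor heavy-atom
#' distance is at most `d_max` and (2) the hydrogen-donor-acceptor angle
#' (vertex at the donor) is at most `alpha_max`.  Both boundaries are
#' inclusive.
#'
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5)
#' @param alpha_max hydrogen-donor-acceptor angle cutoff, degrees
#'   (default 30)
#' @export
hbond_criteria <- function(d_max = 3.5, alpha_max = 30) {
  stopifnot(d_max > 0, alpha_max > 0, alpha_max <= 180)
  structure(list(d_max = d_max, alpha_max = alpha_max),
            class = "hbond_criteria")
}

# donor table: (heavy donor D, hydrogen H) pairs; H flagged donor or any H
# bonded to O/N; acceptors: flagged, or any O/N
hbond_roles <- function(sys) {
  a <- sys$atoms
  don_d <- integer(); don_h <- integer()
  if (nrow(sys$bonds)) {
    for (r in seq_len(nrow(sys$bonds))) {
      i <- sys$bonds$i[r]; j <- sys$bonds$j[r]
      for (p in list(c(i, j), c(j, i))) {
        h <- p[1]; d <- p[2]
        if (a$element[h] == "H" &&
            (a$donor[h] || a$element[d] %in% c("O", "N"))) {
          don_d <- c(don_d, d); don_h <- c(don_h, h)
        }
      }
    }
  }
  acc <- which(a$acceptor | a$element %in% c("O", "N"))
  list(donors = data.frame(d = don_d, h = don_h), acceptors = acc)
}

#' Detect hydrogen bonds between two groups
#'
#' Donors (O-H, N-H hydrogens with their heavy atom) and acceptors (O, N)
#' are identified from the topology (element + bonding, overridable by the
#' per-atom `donor`/`acceptor` flags).  A bond is counted when the donor is
#' in `group_a` and the acceptor in `group_b` or vice versa, under the
#' [hbond_criteria()].  Pairs within the same molecule are never counted.
#'
#' @param traj an [md_trajectory()]
#' @param sys an [md_system()]
#' @param group_a,group_b [select_group()] selections
#' @param criteria a [hbond_criteria()]
#' @return `hbond_result`: `per_frame` counts, `mean_count`,
#'   `per_molecule_a` (mean count divided by the number of molecules in
#'   `group_a`), and the bond list of the first frame
#' @export
detect_hbonds <- function(traj, sys, group_a, group_b,
                          criteria = hbond_criteria()) {
  roles <- hbond_roles(sys)
  in_a <- function(i) i %in% group_a$atom_indices
  mask_a <- logical(n_atoms(sys)); mask_a[group_a$atom_indices] <- TRUE
  mask_b <- logical(n_atoms(sys)); mask_b[group_b$atom_indices] <- TRUE
  molid <- sys$atoms$molid
  d_max <- criteria$d_max / 10 # nm
  cos_min <- cos(criteria$alpha_max * pi / 180) - 1e-12
  dirs <- list(list(dm = mask_a, am = mask_b), list(dm = mask_b, am = mask_a))
  if (identical(group_a$atom_indices, group_b$atom_indices))
    dirs <- dirs[1]
  counts <- integer(n_frames(traj))
  first_bonds <- NULL
  if (nrow(roles$donors) == 0 || length(roles$acceptors) == 0) {
    warning("no donors or no acceptors identifiable; zero hydrogen bonds")
  } else {
    for (fi in seq_len(n_frames(traj))) {
      f <- traj$frames[[fi]]
      pos <- f$positions; box <- f$box
      nb <- 0L
      bonds_here <- list()
      for (dd in dirs) {
        sel <- dd$dm[roles$donors$d]
        dsub <- roles$donors[sel, , drop = FALSE]
        acc <- roles$acceptors[dd$am[roles$acceptors]]
        if (!nrow(dsub) || !length(acc)) next
        for (r in seq_len(nrow(dsub))) {
          D <- dsub$d[r]; H <- dsub$h[r]
          acc_ok <- acc[molid[acc] != molid[D]]
          if (!length(acc_ok)) next
          da <- sweep(pos[acc_ok, , drop = FALSE], 2, pos[D, ], `-`)
          da <- minimum_image(da, box)
          dist <- sqrt(rowSums(da^2))
          near <- which(dist <= d_max + 1e-12)
          if (!length(near)) next
          hv <- minimum_image(matrix(pos[H, ] - pos[D, ], 1, 3), box)[1, ]
          hn <- sqrt(sum(hv^2))
          cosang <- (da[near, , drop = FALSE] %*% hv) / (dist[near] * hn)
          hit <- near[cosang >= cos_min]
          nb <- nb + length(hit)
          if (fi == 1 && length(hit))
            bonds_here[[length(bonds_here) + 1L]] <-
              data.frame(donor = D, hydrogen = H, acceptor = acc_ok[hit])
        }
      }
      counts[fi] <- nb
      if (fi == 1)
        first_bonds <- if (length(bonds_here)) do.call(rbind, bonds_here)
                       else data.frame(donor = integer(), hydrogen = integer(),
                                       acceptor = integer())
    }
  }
  structure(list(per_frame = counts, mean_count = mean(counts),
                 per_molecule_a = mean(counts) / length(group_a$molecule_ids),
                 first_frame_bonds = first_bonds,
                 criteria = criteria,
                 group_a = group_a$label, group_b = group_b$label),
            class = "hbond_result")
}

#' @export
print.hbond_result <- function(x, ...) {
  cat(sprintf("<hbond_result> %s -- %s: mean %.2f bonds/frame (%.3f per molecule of %s)\n",
              x$group_a, x$group_b, x$mean_count, x$per_molecule_a, x$group_a))
  invisible(x)
}

#' Crystal density and lattice-parameter validation
#'
#' Time-averages density and lattice parameters over the analysis window of
#' an NPT (or zero-length) run of a crystal supercell, divides the box by
#' the replication counts to recover unit-cell parameters, and reports the
#' percent deviation `100 (sim - ref) / ref` against the reference cell.
#' The validation criterion used for force-field checks is that all
#' deviations stay below 3 percent in magnitude.
#'
#' @param run a `run_result` with a recorded box series
#' @param reference a [unit_cell_spec()]
#' @param nrep replication counts `c(nx, ny, nz)` used to build the
#'   supercell
#' @param window optional `c(t_start, t_end)` ps
#' @param total_mass total system molar mass, g/mol (default: reference
#'   `z * molar_mass * prod(nrep)`)
#' @return `crystal_metrics`: mean density (g/cc), mean unit-cell
#'   parameters (Angstrom/degrees), `deviation_percent` per quantity,
#'   `pass` flag (all |dev| < 3)
#' @export
crystal_metrics <- function(run, reference, nrep, window = NULL,
                            total_mass = NULL) {
  traj <- run$trajectory
  if (!is.null(window)) traj <- trajectory_window(traj, window[1], window[2])
  if (is.null(total_mass))
    total_mass <- reference$z * reference$molar_mass * prod(nrep)
  pars <- t(vapply(traj$frames, function(f) {
    p <- box_parameters(f$box)
    c(a = p$a, b = p$b, c = p$c, alpha = p$alpha, beta = p$beta,
      gamma = p$gamma, V = box_volume(f$box))
  }, numeric(7)))
  mean_V <- mean(pars[, "V"])
  density <- total_mass * .amu_per_nm3_to_gcc / mean_V
  cellpar <- c(a = mean(pars[, "a"]) / nrep[1] * 10,
               b = mean(pars[, "b"]) / nrep[2] * 10,
               c = mean(pars[, "c"]) / nrep[3] * 10,
               alpha = mean(pars[, "alpha"]),
               beta = mean(pars[, "beta"]),
               gamma = mean(pars[, "gamma"]))
  ref <- c(a = reference$a, b = reference$b, c = reference$c,
           alpha = reference$alpha, beta = reference$beta,
           gamma = reference$gamma, density = cell_density(reference))
  simv <- c(cellpar, density = density)
  dev <- 100 * (simv - ref[names(simv)]) / ref[names(simv)]
  structure(list(density = density, cell = cellpar,
                 reference = ref, deviation_percent = dev,
                 pass = all(abs(dev) < 3), n_frames = nrow(pars)),
            class = "crystal_metrics")
}

#' @export
print.crystal_metrics <- function(x, ...) {
  cat(sprintf("<crystal_metrics> density %.4f g/cc; %s (max |dev| %.2f%%)\n",
              x$density, if (x$pass) "PASS (<3%)" else "FAIL (>=3%)",
              max(abs(x$deviation_percent))))
  print(round(rbind(simulated = c(x$cell, density = x$density),
                    reference = x$reference[c("a","b","c","alpha","beta","gamma","density")],
                    deviation_pct = x$deviation_percent[c("a","b","c","alpha","beta","gamma","density")]), 4))
  invisible(x)
}
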