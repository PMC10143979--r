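#' Configuration objects for the MD engine
#'
#' Defaults mirror the emulated protocol: leap-frog with dt = 2 fs,
#' stochastic velocity-rescale thermostat with tau = 0.1 ps, steepest
#' descent to a maximum force of 1000 kJ/mol/nm.
#'
#' @param dt time step, ps
#' @param n_steps number of integration steps
#' @param save_interval save a frame every this many steps
#' @param seed RNG seed for thermostat noise and reproducibility
#' @export
integrator_config <- function(dt = 0.002, n_steps = 1000,
                              save_interval = 50, seed = 1) {
  stopifnot(dt > 0, n_steps >= 0, save_interval >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed)),
            class = "integrator_config")
}

#' @rdname integrator_config
#' @param target_T target temperature, K
#' @param tau thermostat relaxation time, ps
#' @param enabled thermostat on/off
#' @param type `"csvr"` (canonical stochastic velocity rescale, default) or
#'   `"berendsen"` (plain weak-coupling rescale, for comparison)
#' @export
thermostat_config <- function(target_T = 300, tau = 0.1, enabled = TRUE,
                              type = c("csvr", "berendsen")) {
  stopifnot(tau > 0, target_T >= 0)
  structure(list(target_T = target_T, tau = tau, enabled = enabled,
                 type = match.arg(type)),
            class = "thermostat_config")
}

#' @rdname integrator_config
#' @param target_P target pressure, bar
#' @param tau_P barostat relaxation time, ps
#' @param compressibility isothermal compressibility, 1/bar
#' @export
barostat_config <- function(target_P = 1, tau_P = 1.0,
                            compressibility = 4.5e-5) {
  stopifnot(tau_P > 0)
  structure(list(target_P = target_P, tau_P = tau_P,
                 compressibility = compressibility),
            class = "barostat_config")
}

#' @rdname integrator_config
#' @param max_force_tol convergence threshold on the largest atomic force,
#'   kJ/mol/nm
#' @param max_steps step budget
#' @param initial_step initial displacement of the most-strained atom, nm
#' @export
minimizer_config <- function(max_force_tol = 1000, max_steps = 2000,
                             initial_step = 0.01) {
  stopifnot(max_force_tol > 0, max_steps >= 1, initial_step > 0)
  structure(list(max_force_tol = max_force_tol,
                 max_steps = as.integer(max_steps),
                 initial_step = initial_step),
            class = "minimizer_config")
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent: the potential energy is non-increasing
#' across accepted steps (the step is halved whenever a trial increases the
#' energy) and iteration stops when the largest atomic force falls below
#' `max_force_tol` or the step budget is exhausted.
#'
#' @param frame starting [md_frame()] (box required)
#' @param sys an [md_system()]
#' @param cfg a [minimizer_config()]
#' @param cutoffs a [cutoff_scheme()]
#' @return an `md_frame` with attributes `energy`, `max_force`, `steps`,
#'   `converged`
#' @export
minimize_steepest_descent <- function(frame, sys, cfg = minimizer_config(),
                                      cutoffs = cutoff_scheme()) {
  r <- cpp_minimize(frame$positions, frame$box$vectors,
                    topology_for_kernel(sys),
                    opts_for_kernel(cutoffs, sys, frame$box),
                    cfg$max_force_tol, cfg$max_steps, cfg$initial_step)
  out <- md_frame(r$positions, box = frame$box, time = frame$time,
                  velocities = frame$velocities)
  attr(out, "energy") <- r$energy
  attr(out, "max_force") <- r$max_force
  attr(out, "steps") <- r$steps
  attr(out, "converged") <- r$converged
  out
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Each velocity component is drawn from Normal(0, kB T / m), centre-of-mass
#' momentum is removed, and velocities are rescaled so the instantaneous
#' kinetic temperature (with 3N - 3 degrees of freedom) equals the target
#' exactly.
#'
#' @param frame an [md_frame()]
#' @param sys an [md_system()]
#' @param temperature target temperature, K (0 gives zero velocities)
#' @param seed RNG seed
#' @return the frame with velocities set
#' @export
init_velocities_mb <- function(frame, sys, temperature, seed = 1) {
  if (temperature < 0) stop("temperature must be >= 0")
  m <- sys$atoms$mass
  if (any(m <= 0)) stop("masses must be > 0")
  n <- length(m)
  if (temperature == 0) {
    frame$velocities <- matrix(0, n, 3)
    return(frame)
  }
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(.kB * temperature / m)
  # remove COM momentum
  p <- colSums(v * m) / sum(m)
  v <- sweep(v, 2, p)
  nf <- max(3 * n - 3, 1)
  Tinst <- sum(m * rowSums(v^2)) / (nf * .kB)
  v <- v * sqrt(temperature / Tinst)
  frame$velocities <- v
  frame
}

run_result <- function(raw, sys, ensemble) {
  frames <- lapply(seq_along(raw$positions), function(i) {
    md_frame(raw$positions[[i]],
             box = simulation_box(vectors = raw$boxes[[i]]),
             time = raw$energies[i, "time"],
             velocities = raw$velocities[[i]])
  })
  structure(list(trajectory = md_trajectory(frames),
                 energies = as.data.frame(raw$energies),
                 ensemble = ensemble,
                 dt = raw$dt, save_every = raw$save_every),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  e <- x$energies
  cat(sprintf("<run_result> %s, %d saved frames, t = %.3f..%.3f ps\n",
              toupper(x$ensemble), nrow(e), min(e$time), max(e$time)))
  cat(sprintf("  <T> = %.1f K, <E_pot> = %.2f kJ/mol, <E_tot> = %.2f kJ/mol\n",
              mean(e$temperature), mean(e$e_pot), mean(e$e_total)))
  invisible(x)
}

run_integrator <- function(frame, sys, icfg, tcfg, pcfg, cutoffs,
                           remove_com, ensemble) {
  if (is.null(frame$velocities))
    stop("frame has no velocities; call init_velocities_mb() first")
  set.seed(icfg$seed)
  raw <- cpp_integrate(frame$positions, frame$velocities, frame$box$vectors,
                       topology_for_kernel(sys),
                       opts_for_kernel(cutoffs, sys, frame$box),
                       icfg$dt, icfg$n_steps, icfg$save_interval,
                       !is.null(tcfg) && tcfg$enabled,
                       if (is.null(tcfg)) 0 else tcfg$target_T,
                       if (is.null(tcfg)) 1 else tcfg$tau,
                       if (!is.null(tcfg) && tcfg$type == "berendsen") 1L else 0L,
                       !is.null(pcfg),
                       if (is.null(pcfg)) 0 else pcfg$target_P,
                       if (is.null(pcfg)) 1 else pcfg$tau_P,
                       if (is.null(pcfg)) 0 else pcfg$compressibility,
                       remove_com, frame$time)
  run_result(raw, sys, ensemble)
}

#' Leap-frog NVT dynamics with a velocity-rescale thermostat
#'
#' Stochastic velocity rescaling (the canonical-sampling variant) with
#' relaxation time `tcfg$tau`; centre-of-mass motion is removed every step
#' in thermostatted runs.  Runs are bit-reproducible for a given seed.
#' Energy-shifted cutoffs (the integration default) keep the potential
#' continuous at the cutoff.
#'
#' @param frame minimized, velocity-initialized [md_frame()]
#' @param sys an [md_system()]
#' @param icfg an [integrator_config()]
#' @param tcfg a [thermostat_config()]
#' @param cutoffs a [cutoff_scheme()]
#' @return a `run_result` (trajectory + per-frame energy table)
#' @export
integrate_nvt <- function(frame, sys, icfg = integrator_config(),
                          tcfg = thermostat_config(),
                          cutoffs = cutoff_scheme(shift_lj = TRUE)) {
  run_integrator(frame, sys, icfg, tcfg, NULL, cutoffs,
                 remove_com = TRUE, ensemble = "nvt")
}

#' @rdname integrate_nvt
#' @export
integrate_nve <- function(frame, sys, icfg = integrator_config(),
                          cutoffs = cutoff_scheme(shift_lj = TRUE)) {
  run_integrator(frame, sys, icfg, NULL, NULL, cutoffs,
                 remove_com = FALSE, ensemble = "nve")
}

#' @rdname integrate_nvt
#' @param pcfg a [barostat_config()]; isotropic weak-coupling scaling of an
#'   orthorhombic box
#' @export
integrate_npt <- function(frame, sys, icfg = integrator_config(),
                          tcfg = thermostat_config(),
                          pcfg = barostat_config(),
                          cutoffs = cutoff_scheme(shift_lj = TRUE)) {
  run_integrator(frame, sys, icfg, tcfg, pcfg, cutoffs,
                 remove_com = TRUE, ensemble = "npt")
}

#' Last frame of a run
#' @param run a `run_result`
#' @export
final_frame <- function(run) {
  fr <- run$trajectory$frames
  fr[[length(fr)]]
}
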