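# minimizer, velocity initialization, integrators

lj_dimer <- function(r, sigma = 0.34, epsilon = 1.0, mass = 39.948) {
  atoms <- data.frame(name = "A", element = "Ar", resname = "M", molid = 1:2,
                      charge = 0, sigma = sigma, epsilon = epsilon,
                      mass = mass)
  sys <- md_system(atoms)
  box <- simulation_box(lengths = c(4, 4, 4))
  list(sys = sys,
       frame = md_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box = box))
}

test_that("steepest descent leaves a minimized dimer unchanged and pulls a strained one to the minimum", {
  rmin <- 2^(1 / 6) * 0.34
  d0 <- lj_dimer(rmin)
  m0 <- minimize_steepest_descent(d0$frame, d0$sys,
                                  minimizer_config(max_force_tol = 1))
  expect_equal(m0$positions, d0$frame$positions, tolerance = 1e-4)
  d1 <- lj_dimer(0.34) # starts at the root, force strongly repulsive
  m1 <- minimize_steepest_descent(d1$frame, d1$sys,
                                  minimizer_config(max_force_tol = 0.1))
  expect_equal(dist(m1$positions)[1], rmin, tolerance = 1e-3)
  expect_true(attr(m1, "converged"))
})

test_that("random 30-atom box minimizes below the stated force tolerance", {
  f <- lj_fluid(30, 2.5, seed = 21)
  mn <- minimize_steepest_descent(f$frame, f$sys,
                                  minimizer_config(max_force_tol = 1000),
                                  cutoffs = cutoff_scheme(rc_lj = 0.9,
                                                          rc_coul = 0.9))
  expect_lte(attr(mn, "max_force"), 1000)
  e <- system_potential(mn, f$sys, cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9),
                        forces = TRUE)
  expect_lte(sqrt(max(rowSums(e$forces^2))), 1000 + 1e-6)
})

test_that("Maxwell-Boltzmann initialization: zero at T=0, exact kinetic T, normal components", {
  f <- lj_fluid(1000, 8, seed = 2)
  fr0 <- init_velocities_mb(f$frame, f$sys, 0)
  expect_true(all(fr0$velocities == 0))
  fr <- init_velocities_mb(f$frame, f$sys, 300, seed = 5)
  kB <- md_constants()$kB
  ke <- 0.5 * sum(f$sys$atoms$mass * rowSums(fr$velocities^2))
  Tkin <- 2 * ke / ((3 * 1000 - 3) * kB)
  expect_equal(Tkin, 300, tolerance = 1e-12)
  # COM momentum removed
  p <- colSums(fr$velocities * f$sys$atoms$mass)
  expect_lt(max(abs(p)), 1e-9)
  # component normality at alpha = 0.01 across seeds
  for (s in c(11, 22, 33)) {
    v <- init_velocities_mb(f$frame, f$sys, 300, seed = s)$velocities
    expect_gt(stats::shapiro.test(as.vector(v[seq_len(1000), ]))$p.value,
              0.01)
  }
  expect_error(init_velocities_mb(f$frame, f$sys, -1), "temperature")
})

test_that("zero integration steps return the input state", {
  d <- lj_dimer(2^(1 / 6) * 0.34)
  fr <- init_velocities_mb(d$frame, d$sys, 50, seed = 1)
  r <- integrate_nve(fr, d$sys, integrator_config(n_steps = 0))
  expect_equal(final_frame(r)$positions, fr$positions)
  expect_equal(final_frame(r)$velocities, fr$velocities)
})

test_that("a free particle moves in a straight line at constant kinetic energy", {
  atoms <- data.frame(name = "A", element = "Ar", resname = "M", molid = 1,
                      charge = 0, sigma = 0.3, epsilon = 0, mass = 40)
  sys <- md_system(atoms)
  box <- simulation_box(lengths = c(5, 5, 5))
  fr <- md_frame(matrix(c(1, 1, 1), 1, 3), box = box,
                 velocities = matrix(c(0.1, 0.05, -0.02), 1, 3))
  r <- integrate_nve(fr, sys, integrator_config(dt = 0.002, n_steps = 500,
                                                save_interval = 100))
  tt <- r$energies$time
  expect_equal(final_frame(r)$positions[1, ],
               c(1, 1, 1) + c(0.1, 0.05, -0.02) * max(tt), tolerance = 1e-10)
  expect_equal(diff(range(r$energies$e_kin)), 0, tolerance = 1e-12)
})

test_that("LJ dimer oscillation period matches the harmonic approximation to 5%", {
  sigma <- 0.34; eps <- 1.0; m <- 39.948
  rmin <- 2^(1 / 6) * sigma
  d <- lj_dimer(1.02 * rmin, sigma, eps, m)
  fr <- d$frame
  fr$velocities <- matrix(0, 2, 3)
  r <- integrate_nve(fr, d$sys, integrator_config(dt = 0.001, n_steps = 4000,
                                                  save_interval = 1))
  sep <- vapply(r$trajectory$frames,
                function(f) sqrt(sum((f$positions[2, ] - f$positions[1, ])^2)),
                numeric(1))
  # period from successive maxima of the separation
  pk <- which(diff(sign(diff(sep))) < 0) + 1
  periods <- diff(r$energies$time[pk])
  omega <- sqrt(57.1464 * eps / sigma^2 / (m / 2)) # sqrt(k_eff / mu)
  expect_equal(mean(periods), 2 * pi / omega, tolerance = 0.05)
})

test_that("NVE conserves momentum when COM motion is removed at start", {
  eq <- equilibrated_lj_fluid(seed = 31)
  r <- integrate_nve(eq$frame, eq$sys,
                     integrator_config(dt = 0.001, n_steps = 2000,
                                       save_interval = 500),
                     cutoffs = eq$cutoffs)
  m <- eq$sys$atoms$mass
  for (f in r$trajectory$frames) {
    vcom <- colSums(f$velocities * m) / sum(m)
    expect_lt(max(abs(vcom)), 1e-8)
  }
})

test_that("NVT runs are bit-reproducible for a fixed seed", {
  eq <- equilibrated_lj_fluid(seed = 7)
  icfg <- integrator_config(dt = 0.002, n_steps = 500, save_interval = 100,
                            seed = 99)
  r1 <- integrate_nvt(eq$frame, eq$sys, icfg, thermostat_config(300),
                      cutoffs = eq$cutoffs)
  r2 <- integrate_nvt(eq$frame, eq$sys, icfg, thermostat_config(300),
                      cutoffs = eq$cutoffs)
  expect_identical(final_frame(r1)$positions, final_frame(r2)$positions)
  expect_identical(r1$energies, r2$energies)
  # Berendsen variant runs and thermostats too
  rb <- integrate_nvt(eq$frame, eq$sys, icfg,
                      thermostat_config(300, type = "berendsen"),
                      cutoffs = eq$cutoffs)
  expect_equal(mean(rb$energies$temperature), 300, tolerance = 0.1)
})

test_that("weak-coupling barostat drives an ideal gas to the target density", {
  n <- 100; Temp <- 300; P <- 200 # bar
  atoms <- data.frame(name = "A", element = "Ar", resname = "M",
                      molid = seq_len(n), charge = 0, sigma = 0.3,
                      epsilon = 0, mass = 39.948)
  sys <- md_system(atoms)
  edge <- 3.0
  set.seed(12)
  fr <- md_frame(matrix(runif(3 * n, 0, edge), n, 3),
                 box = simulation_box(lengths = rep(edge, 3)))
  fr <- init_velocities_mb(fr, sys, Temp, seed = 13)
  cs <- cutoff_scheme(rc_lj = 0.5, rc_coul = 0.5)
  r <- integrate_npt(fr, sys,
                     integrator_config(dt = 0.002, n_steps = 15000,
                                       save_interval = 100, seed = 14),
                     thermostat_config(Temp),
                     barostat_config(target_P = P, tau_P = 0.5,
                                     compressibility = 4.5e-4),
                     cutoffs = cs)
  e <- r$energies
  w <- e$time > max(e$time) / 2
  rho <- mean(n * 39.948 * md_constants()$amu_per_nm3_to_gcc / e$volume[w])
  rho_ideal <- P * 39.948 / (83.14462618 * Temp) # P M / (R T), g/cc
  expect_equal(rho, rho_ideal, tolerance = 0.05)
})

test_that("infinite barostat relaxation reduces NPT to NVT", {
  eq <- equilibrated_lj_fluid(seed = 41)
  icfg <- integrator_config(dt = 0.002, n_steps = 300, save_interval = 100,
                            seed = 5)
  rn <- integrate_nvt(eq$frame, eq$sys, icfg, thermostat_config(300),
                      cutoffs = eq$cutoffs)
  rp <- integrate_npt(eq$frame, eq$sys, icfg, thermostat_config(300),
                      barostat_config(target_P = 1, tau_P = 1e12),
                      cutoffs = eq$cutoffs)
  expect_equal(final_frame(rp)$positions, final_frame(rn)$positions,
               tolerance = 1e-9)
  expect_equal(diff(range(rp$energies$volume)), 0, tolerance = 1e-6)
})

test_that("divergent dynamics abort with a diagnostic", {
  d <- lj_dimer(0.15) # deep overlap
  fr <- d$frame
  fr$velocities <- matrix(0, 2, 3)
  expect_error(integrate_nve(fr, d$sys,
                             integrator_config(dt = 0.05, n_steps = 100,
                                               save_interval = 10)),
               "divergence")
})
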