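# pairwise kernels, combining rules, system potential, forces

test_that("LJ pair energy has its root at sigma and minimum -epsilon", {
  expect_equal(lj_pair_energy(0.34, 0.34, 1.7), 0)
  expect_equal(lj_pair_energy(2^(1 / 6) * 0.34, 0.34, 1.7), -1.7)
  # high-precision direct evaluation oracle (frozen from Rmpfr-style
  # extended arithmetic; the formula is exact in doubles here)
  sr <- 0.34 / 0.5
  expect_equal(lj_pair_energy(0.5, 0.34, 1.0), 4 * (sr^12 - sr^6),
               tolerance = 1e-15)
  expect_error(lj_pair_energy(0, 0.34, 1), "r must be > 0")
})

test_that("Coulomb pair energy follows f q q / r with the MD constant", {
  expect_equal(coulomb_pair_energy(0.7, 0, 1), 0)
  expect_equal(coulomb_pair_energy(0.5, 1, -1), -2 * 138.935458)
  set.seed(1)
  for (k in 1:10) {
    r <- runif(1, 0.1, 2); qi <- rnorm(1); qj <- rnorm(1)
    e <- coulomb_pair_energy(r, qi, qj)
    expect_equal(sign(e), sign(qi * qj))
    expect_equal(e, 138.935458 * qi * qj / r, tolerance = 1e-14)
  }
})

test_that("geometric combining rules", {
  c1 <- combine_params(0.3, 0.5, 0.3, 0.5)
  expect_equal(c1$sigma, 0.3); expect_equal(c1$epsilon, 0.5)
  expect_equal(combine_params(0.2, 1, 0.8, 1)$sigma, 0.4)
  set.seed(2)
  for (k in 1:5) {
    si <- runif(1, 0.1, 0.5); sj <- runif(1, 0.1, 0.5)
    ei <- runif(1, 0, 2); ej <- runif(1, 0, 2)
    cc <- combine_params(si, ei, sj, ej)
    expect_equal(cc$sigma, sqrt(si * sj))
    expect_equal(cc$epsilon, sqrt(ei * ej))
  }
  expect_error(combine_params(NA, 1, 0.3, 1), "missing")
})

test_that("system potential matches O(N^2) brute-force oracle to 1e-9", {
  f <- lj_fluid(50, 2.5, charge = rep(c(0.2, -0.2), 25), seed = 11)
  cs <- cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9,
                      shift_lj = FALSE, shift_coul = FALSE)
  e <- system_potential(f$frame, f$sys, cs)
  or <- brute_nonbonded(f$frame$positions, 2.5, f$sys$atoms$sigma,
                        f$sys$atoms$epsilon, f$sys$atoms$charge, 0.9)
  expect_equal(e$e_lj, or$e_lj, tolerance = 1e-9)
  expect_equal(e$e_coul, or$e_coul, tolerance = 1e-9)
  expect_equal(e$e_total, e$e_lj + e$e_coul + e$e_bonded)
})

test_that("neighbour-search path equals brute-force path", {
  f <- lj_fluid(300, 3.0, charge = rep(c(0.1, -0.1), 150), seed = 3)
  e1 <- system_potential(f$frame, f$sys,
                         cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9,
                                       use_cells = FALSE))
  e2 <- system_potential(f$frame, f$sys,
                         cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9,
                                       use_cells = TRUE))
  expect_equal(e2$e_lj, e1$e_lj, tolerance = 1e-12)
  expect_equal(e2$e_coul, e1$e_coul, tolerance = 1e-12)
})

test_that("two atoms beyond the cutoff contribute nothing; dimer at the LJ minimum gives -epsilon", {
  atoms <- data.frame(name = "A", element = "Ar", resname = "M", molid = 1:2,
                      charge = 0, sigma = 0.34, epsilon = 1.7, mass = 40)
  sys <- md_system(atoms)
  box <- simulation_box(lengths = c(4, 4, 4))
  far <- md_frame(rbind(c(1, 1, 1), c(1, 1, 2.5)), box = box)
  expect_equal(system_potential(far, sys)$e_lj, 0)
  rmin <- 2^(1 / 6) * 0.34
  dim <- md_frame(rbind(c(1, 1, 1), c(1 + rmin, 1, 1)), box = box)
  expect_equal(system_potential(dim, sys)$e_total, -1.7, tolerance = 1e-12)
})

test_that("pairs at exactly r = r_c are included (closed interval)", {
  atoms <- data.frame(name = "A", element = "Ar", resname = "M", molid = 1:2,
                      charge = 0, sigma = 0.34, epsilon = 1, mass = 40)
  sys <- md_system(atoms)
  box <- simulation_box(lengths = c(4.5, 4.5, 4.5))
  cs <- cutoff_scheme(rc_lj = 1.0, rc_coul = 1.0)
  at_rc <- md_frame(rbind(c(1, 1, 1), c(2, 1, 1)), box = box)
  expect_equal(system_potential(at_rc, sys, cs)$e_lj,
               lj_pair_energy(1, 0.34, 1), tolerance = 1e-12)
  beyond <- md_frame(rbind(c(1, 1, 1), c(2 + 1e-9, 1, 1)), box = box)
  expect_equal(system_potential(beyond, sys, cs)$e_lj, 0)
})

test_that("box smaller than twice the cutoff is rejected", {
  f <- lj_fluid(10, 1.5, seed = 5)
  expect_error(system_potential(f$frame, f$sys,
                                cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9)),
               "twice the cutoff")
})

test_that("energy is invariant to translations and whole-box lattice shifts", {
  f <- lj_fluid(40, 2.5, charge = rep(c(0.3, -0.3), 20), seed = 9)
  cs <- cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9)
  e0 <- system_potential(f$frame, f$sys, cs)$e_total
  shift <- md_frame(sweep(f$frame$positions, 2, c(0.31, -1.7, 5.2), `+`),
                    box = f$box)
  expect_equal(system_potential(shift, f$sys, cs)$e_total, e0,
               tolerance = 1e-9)
  p <- f$frame$positions
  p[7, ] <- p[7, ] + c(2.5, -2.5, 2.5) # whole lattice-vector shifts
  expect_equal(system_potential(md_frame(p, box = f$box), f$sys, cs)$e_total,
               e0, tolerance = 1e-9)
})

test_that("forces match central-difference gradients on random bonded systems", {
  for (tname in c("DLO", "OPZ")) {
    tpl <- api_template(tname)
    sys <- tpl$system
    box <- simulation_box(lengths = c(6, 6, 6))
    set.seed(17)
    pos <- tpl$positions + 2 +
      matrix(rnorm(length(tpl$positions), 0, 0.01), nrow(tpl$positions), 3)
    cs <- cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9)
    an <- system_potential(md_frame(pos, box = box), sys, cs, forces = TRUE)
    h <- 1e-6
    # spot-check every coordinate of a third of the atoms
    for (i in seq(1, nrow(pos), by = 3)) for (d in 1:3) {
      p1 <- pos; p1[i, d] <- p1[i, d] + h
      p2 <- pos; p2[i, d] <- p2[i, d] - h
      num <- -(system_potential(md_frame(p1, box = box), sys, cs)$e_total -
               system_potential(md_frame(p2, box = box), sys, cs)$e_total) /
             (2 * h)
      expect_equal(an$forces[i, d], num, tolerance = 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("bonded exclusions remove 1-2/1-3 nonbonded terms and scale 1-4", {
  # linear 4-atom chain: only the 1-4 pair contributes nonbonded energy
  atoms <- data.frame(name = paste0("C", 1:4), element = "C", resname = "M",
                      molid = 1L, charge = c(0.2, -0.2, -0.2, 0.2),
                      sigma = 0.3, epsilon = 0.5, mass = 12)
  r <- 0.25
  bonds <- data.frame(i = 1:3, j = 2:4, r0 = r, k = 1e5)
  sys <- md_system(atoms, bonds = bonds)
  expect_equal(nrow(sys$pairs14), 1)
  pos <- cbind(seq(0, by = r, length.out = 4), 0, 0) + 2
  box <- simulation_box(lengths = c(6, 6, 6))
  e <- system_potential(md_frame(pos, box = box), sys,
                        cutoff_scheme(rc_lj = 1.2, rc_coul = 1.2,
                                      shift_coul = FALSE))
  r14 <- 3 * r
  expect_equal(e$e_lj, 0.5 * lj_pair_energy(r14, 0.3, 0.5), tolerance = 1e-12)
  expect_equal(e$e_coul, 0.5 * coulomb_pair_energy(r14, 0.2, 0.2),
               tolerance = 1e-12)
  expect_equal(e$e_bonded, 0) # all bonds at r0
})

test_that("plain Ewald sum reproduces the NaCl Madelung constant", {
  a <- 0.56
  frac <- rbind(c(0,0,0), c(.5,.5,0), c(.5,0,.5), c(0,.5,.5),
                c(.5,0,0), c(0,.5,0), c(0,0,.5), c(.5,.5,.5))
  q1 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  nrep <- 3
  pos <- NULL; q <- NULL
  for (ix in 0:(nrep-1)) for (iy in 0:(nrep-1)) for (iz in 0:(nrep-1)) {
    pos <- rbind(pos, sweep(frac, 2, c(ix, iy, iz), `+`) * a)
    q <- c(q, q1)
  }
  n <- nrow(pos)
  atoms <- data.frame(name = ifelse(q > 0, "NA", "CL"),
                      element = ifelse(q > 0, "Na", "Cl"), resname = "NAC",
                      molid = seq_len(n), charge = q, sigma = 0.3,
                      epsilon = 0.1, mass = 30)
  sys <- md_system(atoms)
  box <- simulation_box(lengths = rep(nrep * a, 3))
  fr <- md_frame(pos, box = box)
  e <- ewald_energy(fr, sys, kmax = 8)
  r_nn <- a / 2
  madelung <- -e * r_nn / (138.935458 * (n / 2))
  expect_equal(madelung, 1.747565, tolerance = 2e-4)
})
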