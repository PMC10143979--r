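# group interaction energies, energy ratios, excipient ranking

ion_pair_frame <- function(r = 0.5, sigma = 0.3, epsilon = 0.5) {
  atoms <- data.frame(name = c("P", "M"), element = c("Na", "Cl"),
                      resname = c("PLS", "MNS"), molid = 1:2,
                      charge = c(1, -1), sigma = sigma, epsilon = epsilon,
                      mass = 30)
  sys <- suppressWarnings(md_system(atoms))
  box <- simulation_box(lengths = c(4, 4, 4))
  fr <- md_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box = box)
  list(sys = sys, traj = md_trajectory(list(fr)))
}

test_that("fixed +1/-1 ion pair at 0.5 nm gives the closed-form energies", {
  ip <- ion_pair_frame(0.5)
  ga <- select_group(ip$sys, "resname PLS")
  gb <- select_group(ip$sys, "resname MNS")
  r <- group_interaction_energy(ip$traj, ip$sys, ga, gb)
  expect_equal(r$e_coul, -2 * 138.935458, tolerance = 1e-12)
  expect_equal(r$e_lj, lj_pair_energy(0.5, 0.3, 0.5), tolerance = 1e-12)
  expect_equal(r$e_total, r$e_coul + r$e_lj) # exact decomposition
})

test_that("groups beyond the cutoff in all frames interact with zero energy", {
  ip <- ion_pair_frame(1.8)
  ga <- select_group(ip$sys, "resname PLS")
  gb <- select_group(ip$sys, "resname MNS")
  r <- group_interaction_energy(ip$traj, ip$sys, ga, gb,
                                cutoffs = cutoff_scheme(rc_lj = 0.9,
                                                        rc_coul = 0.9,
                                                        shift_coul = FALSE))
  expect_equal(r$e_total, 0)
})

test_that("group energies match the brute-force per-frame oracle to 1e-9", {
  mix <- ana_mix_fixture()
  sys <- mix$sys
  cs <- cutoff_scheme(rc_lj = 0.8, rc_coul = 0.8,
                      shift_lj = FALSE, shift_coul = FALSE)
  ga <- select_group(sys, "resname DLO", "API")
  gb <- select_group(sys, "resname ELM", "polymer")
  r_ab <- group_interaction_energy(mix$traj, sys, ga, gb, cutoffs = cs)
  r_aa <- group_interaction_energy(mix$traj, sys, ga, ga, cutoffs = cs)
  a <- sys$atoms
  o_ab <- o_aa <- numeric(n_frames(mix$traj))
  for (i in seq_len(n_frames(mix$traj))) {
    pos <- mix$traj$frames[[i]]$positions
    o_ab[i] <- brute_group_energy(pos, mix$L, a$sigma, a$epsilon, a$charge,
                                  a$molid, ga$atom_indices, gb$atom_indices,
                                  0.8, skip_same_mol = FALSE)$e_total
    o_aa[i] <- brute_group_energy(pos, mix$L, a$sigma, a$epsilon, a$charge,
                                  a$molid, ga$atom_indices, NULL, 0.8,
                                  skip_same_mol = TRUE,
                                  same_group = TRUE)$e_total
  }
  expect_equal(r_ab$e_total, mean(o_ab), tolerance = 1e-9)
  expect_equal(r_aa$e_total, mean(o_aa), tolerance = 1e-9)
  # label swap symmetry
  r_ba <- group_interaction_energy(mix$traj, sys, gb, ga, cutoffs = cs)
  expect_equal(r_ba$e_total, r_ab$e_total, tolerance = 1e-12)
})

test_that("within- plus between-group energies recover the system potential", {
  f <- lj_fluid(60, 2.5, charge = rep(c(0.15, -0.15), 30), seed = 23)
  cs <- cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9,
                      shift_lj = FALSE, shift_coul = FALSE)
  traj <- md_trajectory(list(f$frame))
  ga <- select_group(f$sys, "molid 1:30", "half1")
  gb <- select_group(f$sys, "molid 31:60", "half2")
  e_aa <- group_interaction_energy(traj, f$sys, ga, ga, cutoffs = cs)
  e_bb <- group_interaction_energy(traj, f$sys, gb, gb, cutoffs = cs)
  e_ab <- group_interaction_energy(traj, f$sys, ga, gb, cutoffs = cs)
  tot <- system_potential(f$frame, f$sys, cs)
  expect_equal(e_aa$e_total + e_bb$e_total + e_ab$e_total,
               tot$e_coul + tot$e_lj, tolerance = 1e-9)
})

test_that("group energies are invariant to atom reordering", {
  f <- lj_fluid(40, 2.5, charge = rep(c(0.2, -0.2), 20), seed = 31)
  cs <- cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9, shift_coul = FALSE)
  traj <- md_trajectory(list(f$frame))
  ga <- select_group(f$sys, "molid 1:20"); gb <- select_group(f$sys, "molid 21:40")
  e1 <- group_interaction_energy(traj, f$sys, ga, gb, cutoffs = cs)$e_total
  perm <- sample(40)
  atoms2 <- f$sys$atoms[perm, ]
  atoms2$molid <- f$sys$atoms$molid[perm]
  sys2 <- md_system(atoms2)
  fr2 <- md_frame(f$frame$positions[perm, ], box = f$box)
  ga2 <- select_group(sys2, "molid 1:20"); gb2 <- select_group(sys2, "molid 21:40")
  e2 <- group_interaction_energy(md_trajectory(list(fr2)), sys2, ga2, gb2,
                                 cutoffs = cs)$e_total
  expect_equal(e2, e1, tolerance = 1e-9)
})

test_that("overlapping distinct groups and empty windows are rejected", {
  ip <- ion_pair_frame(0.5)
  ga <- select_group(ip$sys, "resname PLS")
  gmix <- select_group(ip$sys, "resname PLS or resname MNS")
  expect_error(group_interaction_energy(ip$traj, ip$sys, ga, gmix),
               "share atoms")
  gb <- select_group(ip$sys, "resname MNS")
  expect_error(group_interaction_energy(ip$traj, ip$sys, ga, gb,
                                        window = c(5, 10)), "window")
})

test_that("energy ratio follows the sign conventions and validity rules", {
  mk <- function(et) structure(list(e_total = et), class = "interaction_energy_result")
  r1 <- energy_ratio(mk(-100), mk(-50))
  expect_true(r1$valid); expect_equal(r1$ratio, 2)
  r2 <- energy_ratio(mk(0), mk(-50))
  expect_true(r2$valid); expect_equal(r2$ratio, 0)
  r3 <- energy_ratio(mk(-10), mk(-0.5)) # denominator below threshold
  expect_false(r3$valid); expect_match(r3$reason, "below threshold")
  r4 <- energy_ratio(mk(-10), mk(30))
  expect_false(r4$valid); expect_match(r4$reason, "repulsive")
  r5 <- energy_ratio(mk(25), mk(-30))
  expect_false(r5$valid)
})

test_that("ratio from averaged energies equals ratio from raw frame sums", {
  mix <- ana_mix_fixture()
  sys <- mix$sys
  cs <- cutoff_scheme(rc_lj = 0.8, rc_coul = 0.8,
                      shift_lj = FALSE, shift_coul = FALSE)
  ga <- select_group(sys, "resname DLO"); gb <- select_group(sys, "resname ELM")
  e_ab <- group_interaction_energy(mix$traj, sys, ga, gb, cutoffs = cs)
  e_aa <- group_interaction_energy(mix$traj, sys, ga, ga, cutoffs = cs)
  rr <- energy_ratio(e_ab, e_aa)
  if (rr$valid)
    expect_equal(rr$ratio,
                 mean(e_ab$per_frame$e_total) / mean(e_aa$per_frame$e_total))
})

test_that("excipient ranking orders by E_total with documented tie-breaks", {
  res <- data.frame(excipient = c("E1", "E2", "E3"),
                    e_total = c(-10, -20, -30), ratio = c(1, 1, 1),
                    hbonds = c(0, 0, 0))
  rep <- rank_excipients(res, api = "X")
  expect_equal(rep$best, "E3")
  expect_equal(rep$ranking$excipient, c("E3", "E2", "E1"))
  tie <- data.frame(excipient = c("A", "B"), e_total = c(-30, -30),
                    ratio = c(0.5, 2.0), hbonds = c(9, 0))
  expect_equal(rank_excipients(tie)$best, "B") # tie broken by larger ratio
  planted <- data.frame(excipient = c("X", "Y", "Z"),
                        e_total = c(-120, -340, -95),
                        ratio = c(0.8, 1.9, 0.4), hbonds = c(1, 4, 0))
  expect_equal(rank_excipients(planted)$best, "Y")
  expect_error(rank_excipients(res[1, ]), "at least two")
})
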