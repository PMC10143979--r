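# domain types and file-format round trips

test_that("box vector/parameter conversion is a volume-preserving bijection", {
  cases <- list(
    list(lengths = c(6, 6, 6), angles = c(90, 90, 90)),
    list(lengths = c(1.33, 0.576, 0.787), angles = c(90, 93.9, 90)),
    list(lengths = c(0.387, 0.564, 0.836), angles = c(100.8, 100.3, 105.7)))
  for (cs in cases) {
    b <- simulation_box(lengths = cs$lengths, angles = cs$angles)
    p <- box_parameters(b)
    expect_equal(c(p$a, p$b, p$c), cs$lengths, tolerance = 1e-12)
    expect_equal(c(p$alpha, p$beta, p$gamma), cs$angles, tolerance = 1e-9)
    b2 <- simulation_box(lengths = c(p$a, p$b, p$c),
                         angles = c(p$alpha, p$beta, p$gamma))
    expect_equal(box_volume(b2) / box_volume(b), 1, tolerance = 1e-10)
  }
  expect_true(is_cubic(simulation_box(lengths = c(2, 2, 2))))
  expect_false(is_cubic(simulation_box(lengths = c(2, 2, 3))))
  expect_error(simulation_box(lengths = c(1, 1, 1), angles = c(170, 10, 90)),
               "degenerate")
})

test_that("single-atom XYZ parses to one atom at the origin", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0 0 0"), p)
  st <- read_structure(p)
  expect_equal(nrow(st$atoms), 1)
  expect_equal(unlist(st$atoms[, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_null(st$box) # XYZ carries no box; caller must supply one
})

test_that("GRO box line '6.0 6.0 6.0' gives the 6 nm cubic protocol box", {
  p <- tempfile(fileext = ".gro")
  writeLines(c("toy", "    1",
               "    1MOL     C1    1   3.000   3.000   3.000",
               "   6.00000   6.00000   6.00000"), p)
  st <- read_structure(p)
  expect_true(is_cubic(st$box))
  expect_equal(box_parameters(st$box)$a, 6)
})

test_that("structure round trips reproduce coordinates to format precision", {
  set.seed(7)
  n <- 100
  atoms <- data.frame(name = sprintf("C%d", 1:n), element = "C",
                      resname = "MOL", molid = rep(1:10, each = 10),
                      x = runif(n, 0, 5), y = runif(n, 0, 5),
                      z = runif(n, 0, 5))
  box <- simulation_box(lengths = c(5, 5, 5))
  for (fmt in c("pdb", "gro", "xyz")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_structure(atoms, p, format = fmt, box = box)
    st <- read_structure(p)
    tol <- switch(fmt, pdb = 1e-4, xyz = 1e-8, gro = 1e-3) # file decimals
    expect_equal(st$atoms$x, atoms$x, tolerance = tol)
    expect_equal(st$atoms$y, atoms$y, tolerance = tol)
    expect_equal(st$atoms$z, atoms$z, tolerance = tol)
    if (fmt != "xyz")
      expect_equal(box_parameters(st$box)$a, 5, tolerance = 1e-3)
  }
})

test_that("malformed records raise parse errors naming the line", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c("2", "", "C 0 0 0", "C 1 bad 0"), p)
  expect_error(read_structure(p), "line 4")
  p2 <- tempfile(fileext = ".gro")
  writeLines(c("t", "1", "    1MOL     C1    1   0.000   0.000   0.000",
               "not a box"), p2)
  expect_error(read_structure(p2), "box")
})

test_that("trajectory writers preserve frames and times on re-read", {
  set.seed(1)
  box <- simulation_box(lengths = c(3, 3, 3))
  mk <- function(t) md_frame(matrix(runif(9, 0, 3), 3, 3), box = box, time = t)
  # 5 frames at 2-ps spacing -> times 0,2,4,6,8
  traj <- md_trajectory(lapply(c(0, 2, 4, 6, 8), mk))
  for (fmt in c("bin", "multi_xyz", "multi_pdb")) {
    p <- tempfile()
    write_trajectory(traj, p, format = fmt)
    rt <- read_trajectory(p, format = fmt, box = box)
    expect_equal(n_frames(rt), 5)
    expect_equal(trajectory_times(rt), c(0, 2, 4, 6, 8))
    tol <- if (fmt == "bin") 0 else 1e-4
    expect_equal(rt$frames[[3]]$positions, traj$frames[[3]]$positions,
                 tolerance = tol)
  }
  # single frame identity
  t1 <- md_trajectory(list(mk(0)))
  p <- tempfile()
  write_trajectory(t1, p, format = "bin")
  expect_equal(read_trajectory(p)$frames[[1]]$positions,
               t1$frames[[1]]$positions)
})

test_that("4000-frame binary trajectory round-trips bit-exactly", {
  set.seed(2)
  box <- simulation_box(lengths = c(2, 2, 2))
  frames <- lapply(seq_len(4000), function(i)
    md_frame(matrix(rnorm(9), 3, 3), box = box, time = (i - 1) * 0.5,
             velocities = matrix(rnorm(9), 3, 3)))
  traj <- md_trajectory(frames)
  p <- tempfile(fileext = ".bin")
  write_trajectory(traj, p, format = "bin")
  rt <- read_trajectory(p)
  expect_equal(n_frames(rt), 4000)
  expect_identical(rt$frames[[1234]]$positions, traj$frames[[1234]]$positions)
  expect_identical(rt$frames[[4000]]$velocities, traj$frames[[4000]]$velocities)
  expect_identical(trajectory_times(rt), trajectory_times(traj))
})

test_that("trajectories with inconsistent atom counts or times are rejected", {
  box <- simulation_box(lengths = c(3, 3, 3))
  f1 <- md_frame(matrix(0, 3, 3), box = box, time = 0)
  f2 <- md_frame(matrix(0, 4, 3), box = box, time = 1)
  expect_error(md_trajectory(list(f1, f2)), "atom count")
  f3 <- md_frame(matrix(0, 3, 3), box = box, time = 0)
  expect_error(md_trajectory(list(f1, f3)), "increasing")
})

test_that("selection grammar matches species and supports set algebra", {
  mix <- cached("small_mix", {
    api <- api_template("DMF")
    chain <- build_polymer_chain(excipient_template("HAS"), 10)
    build_mixture_box(api, 10, chain, 33, seed = 4, density = 0.3,
                      minimize = FALSE)
  })
  sys <- mix$system
  g_api <- select_group(sys, "resname DMF")
  expect_s3_class(g_api, "group_selection")
  expect_length(g_api$molecule_ids, 10) # 10 API molecules selected
  g_pol <- select_group(sys, "resname HAS")
  g_not <- select_group(sys, "not resname DMF")
  expect_setequal(g_not$atom_indices, g_pol$atom_indices)
  expect_setequal(union(g_api$atom_indices, g_pol$atom_indices),
                  seq_len(n_atoms(sys)))
  g_el <- select_group(sys, "element O and resname DMF")
  expect_true(all(sys$atoms$element[g_el$atom_indices] == "O"))
  g_mix <- select_group(sys, "molid 1:2 or ( resname DMF and element C )")
  expect_true(all(sys$atoms$molid[g_mix$atom_indices] %in% 1:2 |
                  sys$atoms$resname[g_mix$atom_indices] == "DMF"))
  expect_error(select_group(sys, "resname NOPE"), "matched no atoms")
  expect_error(select_group(sys, "color blue"), "unknown selection keyword")
})

test_that("topology text format round trips", {
  tpl <- api_template("OPZ")
  p <- tempfile(fileext = ".top")
  write_topology(tpl$system, p)
  sys2 <- read_topology(p)
  expect_equal(n_atoms(sys2), n_atoms(tpl$system))
  expect_equal(sys2$atoms$charge, tpl$system$atoms$charge, tolerance = 1e-6)
  expect_equal(sys2$atoms$donor, tpl$system$atoms$donor)
  expect_equal(nrow(sys2$bonds), nrow(tpl$system$bonds))
  expect_equal(sys2$bonds$r0, tpl$system$bonds$r0, tolerance = 1e-5)
  expect_equal(nrow(sys2$angles), nrow(tpl$system$angles))
  expect_equal(sort(paste(sys2$pairs14$i, sys2$pairs14$j)),
               sort(paste(tpl$system$pairs14$i, tpl$system$pairs14$j)))
})

test_that("TOML-subset config parser handles sections, types and arrays", {
  p <- tempfile(fileext = ".toml")
  writeLines(c("# run config", "[system]", 'topology = "sys.top"',
               "[md]", "n_steps = 1000", "dt_ps = 0.002",
               "use_thermostat = true", "temps = [300, 373, 433]"), p)
  cfg <- read_config(p)
  expect_equal(cfg$system$topology, "sys.top")
  expect_equal(cfg$md$n_steps, 1000)
  expect_identical(cfg$md$use_thermostat, TRUE)
  expect_equal(cfg$md$temps, c(300, 373, 433))
  p2 <- tempfile(fileext = ".toml")
  writeLines("what is this", p2)
  expect_error(read_config(p2), "key = value")
})
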