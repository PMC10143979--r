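# shared fixtures and independent R oracles; heavy results are cached so
# acceptance tests and property tests can share the same runs

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# ---- simple systems ---------------------------------------------------------

# monatomic LJ fluid (argon-like unless overridden)
lj_fluid <- function(n, edge, sigma = 0.34, epsilon = 1.0, mass = 39.948,
                     charge = 0, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(name = "AR", element = "Ar", resname = "ARG",
                      molid = seq_len(n), charge = charge, sigma = sigma,
                      epsilon = epsilon, mass = mass)
  sys <- md_system(atoms)
  box <- simulation_box(lengths = rep(edge, 3))
  frame <- md_frame(matrix(stats::runif(3 * n, 0, edge), n, 3), box = box)
  list(sys = sys, frame = frame, box = box)
}

# equilibrated 200-atom LJ fluid used by the engine acceptance suite
equilibrated_lj_fluid <- function(seed = 1, temperature = 300) {
  key <- sprintf("ljfluid_%d_%g", seed, temperature)
  cached(key, {
    f <- lj_fluid(200, 2.0, seed = seed)
    cs <- cutoff_scheme(rc_lj = 0.9, rc_coul = 0.9, shift_lj = TRUE)
    mn <- minimize_steepest_descent(f$frame, f$sys,
                                    minimizer_config(max_steps = 2000),
                                    cutoffs = cs)
    fr <- init_velocities_mb(mn, f$sys, temperature, seed = seed + 1000)
    eq <- integrate_nvt(fr, f$sys,
                        integrator_config(dt = 0.002, n_steps = 2500,
                                          save_interval = 2500, seed = seed),
                        thermostat_config(target_T = temperature),
                        cutoffs = cs)
    list(sys = f$sys, frame = final_frame(eq), cutoffs = cs)
  })
}

# ---- independent oracles ----------------------------------------------------

# O(N^2) nonbonded energy with minimum image (orthorhombic box), plain
# truncation, closed cutoff interval, no exclusions
brute_nonbonded <- function(pos, L, sigma, epsilon, charge, rc) {
  n <- nrow(pos)
  f <- md_constants()$f_coul
  elj <- 0; ecoul <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r <= rc && r > 0) {
        sij <- sqrt(sigma[i] * sigma[j]); eij <- sqrt(epsilon[i] * epsilon[j])
        if (eij > 0) elj <- elj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
        ecoul <- ecoul + f * charge[i] * charge[j] / r
      }
    }
  }
  list(e_lj = elj, e_coul = ecoul)
}

# brute-force group-group energy (i in A, j in B), minimum image,
# skipping same-molecule pairs when requested
brute_group_energy <- function(pos, L, sigma, epsilon, charge, molid,
                               ia, ib, rc, skip_same_mol = TRUE,
                               same_group = FALSE) {
  f <- md_constants()$f_coul
  elj <- 0; ecoul <- 0
  pairs <- if (same_group) {
    utils::combn(ia, 2)
  } else {
    rbind(rep(ia, each = length(ib)), rep(ib, times = length(ia)))
  }
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (i == j) next
    if (skip_same_mol && molid[i] == molid[j]) next
    d <- pos[i, ] - pos[j, ]
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    if (r <= rc && r > 0) {
      sij <- sqrt(sigma[i] * sigma[j]); eij <- sqrt(epsilon[i] * epsilon[j])
      if (eij > 0) elj <- elj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
      ecoul <- ecoul + f * charge[i] * charge[j] / r
    }
  }
  list(e_lj = elj, e_coul = ecoul, e_total = elj + ecoul)
}

# brute-force ordered-pair distance histogram
brute_rdf_counts <- function(pos, L, ia, ib, r_max, dr, molid = NULL,
                             exclude_same_mol = FALSE) {
  nb <- ceiling(r_max / dr)
  h <- numeric(nb)
  for (i in ia) for (j in ib) {
    if (i == j) next
    if (exclude_same_mol && molid[i] == molid[j]) next
    d <- pos[i, ] - pos[j, ]
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    if (r < r_max) {
      b <- floor(r / dr) + 1
      if (b >= 1 && b <= nb) h[b] <- h[b] + 1
    }
  }
  h
}

# exhaustive triple-loop hydrogen-bond count for one frame
brute_hbond_count <- function(pos, L, sys, ia_mask, ib_mask,
                              d_max_nm, alpha_max_deg) {
  a <- sys$atoms
  n <- nrow(a)
  count <- 0
  for (H in seq_len(n)) {
    if (a$element[H] != "H") next
    Ds <- c(sys$bonds$j[sys$bonds$i == H], sys$bonds$i[sys$bonds$j == H])
    Ds <- Ds[a$element[Ds] %in% c("O", "N")]
    for (D in Ds) {
      for (A in seq_len(n)) {
        if (!(a$element[A] %in% c("O", "N"))) next
        if (a$molid[A] == a$molid[D]) next
        ok_dir <- (ia_mask[D] && ib_mask[A]) || (ib_mask[D] && ia_mask[A])
        if (!ok_dir) next
        dv <- pos[A, ] - pos[D, ]
        dv <- dv - L * round(dv / L)
        dist <- sqrt(sum(dv^2))
        if (dist > d_max_nm + 1e-12) next
        hv <- pos[H, ] - pos[D, ]
        hv <- hv - L * round(hv / L)
        cosang <- sum(dv * hv) / (dist * sqrt(sum(hv^2)))
        if (cosang >= cos(alpha_max_deg * pi / 180) - 1e-12) count <- count + 1
      }
    }
  }
  count
}

# short thermostatted run of a small ionic mixture, shared by the
# energy-analysis oracle tests
ana_mix_fixture <- function() {
  cached("ana_mix", {
    api <- api_template("DLO")
    chain <- build_polymer_chain(excipient_template("ELM"), 10)
    m <- build_mixture_box(api, 4, chain, 30, seed = 77, density = 0.4)
    fr <- init_velocities_mb(m$frame, m$system, 300, seed = 1)
    run <- integrate_nvt(fr, m$system,
                         integrator_config(dt = 0.002, n_steps = 500,
                                           save_interval = 50, seed = 2),
                         thermostat_config(300),
                         cutoffs = cutoff_scheme(rc_lj = 0.8, rc_coul = 0.8,
                                                 shift_lj = TRUE))
    list(sys = m$system, traj = run$trajectory, L = m$box_edge)
  })
}

tiny_matrix_fixture <- function() {
  cached("tiny_matrix", {
    plan <- experiment_plan(n_api = 4, t_run_ps = 1.5, save_interval_ps = 0.1,
                            seeds = 1L, apis = "DLO",
                            excipients = c("HPP", "ELM"))
    run_screening_matrix(plan)
  })
}


# two-molecule donor/acceptor geometry with exact boundary placement
hbond_geometry <- function(d_A, alpha_deg) {
  d <- d_A / 10
  a <- alpha_deg * pi / 180
  atoms <- data.frame(name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
                      resname = c("DON", "DON", "ACC"), molid = c(1L, 1L, 2L),
                      charge = 0, sigma = c(0.3, 0.1, 0.3),
                      epsilon = 0.1, mass = c(16, 1, 16),
                      donor = c(FALSE, TRUE, FALSE),
                      acceptor = c(FALSE, FALSE, TRUE))
  sys <- md_system(atoms, bonds = data.frame(i = 1, j = 2, r0 = 0.1, k = 5e4))
  box <- simulation_box(lengths = c(4, 4, 4))
  pos <- rbind(c(1, 1, 1),
               c(1, 1, 1) + 0.1 * c(cos(a), sin(a), 0), # H at angle alpha
               c(1 + d, 1, 1))                          # acceptor on +x axis
  list(sys = sys, traj = md_trajectory(list(md_frame(pos, box = box))))
}

# packed donor-rich mixture frame for hydrogen-bond oracle checks
hb_mix_fixture <- function() {
  cached("hb_mix", {
    api <- api_template("OPZ")
    chain <- build_polymer_chain(excipient_template("HPP"), 10)
    build_mixture_box(api, 8, chain, 30, seed = 5, density = 0.5)
  })
}

# ---- directional study batteries (shared between acceptance + properties) ---

dominance_battery <- function(seeds = 1:3) {
  cached("dominance_battery", {
    plan <- experiment_plan(n_api = 6, t_run_ps = 5, seeds = 1L)
    rows <- list()
    for (nm in c("DLO", "NPX", "DMF", "OPZ")) {
      for (s in seeds) {
        res <- run_mixture_system(nm, "HPP", 5, 300, plan, seed = s)
        rows[[length(rows) + 1L]] <- data.frame(
          api = nm, seed = s,
          e_coul = res$e_api_polymer$e_coul,
          e_lj = res$e_api_polymer$e_lj,
          hb_per_api = res$hbonds$per_molecule_a)
      }
    }
    do.call(rbind, rows)
  })
}

loading_battery <- function(seeds = 1:3) {
  cached("loading_battery", {
    plan <- experiment_plan(wt_percent = c(5, 50), n_api = 7,
                            t_run_ps = 10, seeds = seeds)
    run_loading_study(plan, api = "DMF", excipient = "HAS")
  })
}

temperature_battery <- function(seeds = 1:3) {
  cached("temperature_battery", {
    plan <- experiment_plan(temperatures = c(300, 373, 433), n_api = 12,
                            t_run_ps = 40, seeds = seeds)
    run_temperature_study(plan, api = "DMF", excipient = "HAS", wt = 50)
  })
}
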