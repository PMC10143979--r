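#' Experiment plan for screening / loading / temperature studies
#'
#' Fully specifies a set of desk-scale runs: every run is reproducible from
#' the plan plus its seed.  Defaults are toy-scale (hundreds to a couple of
#' thousand atoms, tens of ps) stand-ins for the emulated protocol's ~6 nm
#' boxes and 10 ns trajectories; the first `equil_fraction` of each run is
#' discarded from analysis, mirroring the "last 80%" analysis convention.
#'
#' @param apis character vector of API archetypes (see [api_template()])
#' @param excipients character vector of excipient archetypes
#'   (see [excipient_template()])
#' @param wt_percent API loadings (weight percent) to simulate
#' @param temperatures simulation temperatures, K
#' @param n_api API molecules per box
#' @param n_monomers monomer units per polymer chain
#' @param t_run_ps production length per run, ps
#' @param dt time step, ps
#' @param save_interval_ps trajectory save interval, ps
#' @param equil_fraction fraction of each run discarded before analysis
#' @param rc nonbonded cutoff used for both engine and analysis, nm
#'   (toy-scale boxes cannot honour the full-scale 1.4 nm everywhere)
#' @param density target melt density for box construction, g/cc
#' @param seeds integer vector of replicate seeds
#' @return `experiment_plan`
#' @export
experiment_plan <- function(apis = c("NPX", "DLO", "DMF", "OPZ"),
                            excipients = c("ELM", "HPP", "HAS"),
                            wt_percent = 5, temperatures = 300,
                            n_api = 6, n_monomers = 10,
                            t_run_ps = 10, dt = 0.002,
                            save_interval_ps = 0.1,
                            equil_fraction = 0.2,
                            rc = 0.9, density = 0.75,
                            seeds = 1L) {
  plan <- structure(list(apis = apis, excipients = excipients,
                         wt_percent = wt_percent,
                         temperatures = temperatures,
                         n_api = as.integer(n_api),
                         n_monomers = as.integer(n_monomers),
                         t_run_ps = t_run_ps, dt = dt,
                         save_interval_ps = save_interval_ps,
                         equil_fraction = equil_fraction,
                         rc = rc, density = density,
                         seeds = as.integer(seeds)),
                    class = "experiment_plan")
  plan$hash <- config_hash(unclass(plan))
  plan
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan %s> %s x %s; wt%% {%s}; T {%s} K; %d APIs, %d-mer chains, %g ps, seeds {%s}\n",
              x$hash, paste(x$apis, collapse = ","),
              paste(x$excipients, collapse = ","),
              paste(x$wt_percent, collapse = ","),
              paste(x$temperatures, collapse = ","),
              x$n_api, x$n_monomers, x$t_run_ps,
              paste(x$seeds, collapse = ",")))
  invisible(x)
}

# derived per-run seed, kept below 2^31
derive_seed <- function(base_seed, run_index) {
  as.integer((as.numeric(base_seed) * 7919 + run_index * 104729) %% 2147483647) + 1L
}

#' Build, equilibrate and analyze one API/excipient mixture system
#'
#' The full single-system pipeline: build templates and chain, pack the
#' mixture box, minimize, draw Maxwell-Boltzmann velocities, run NVT, then
#' compute API-polymer and API-API interaction energies, the energy ratio,
#' hydrogen bonds and the API MSD over the post-equilibration window.
#'
#' @param api,excipient archetype names
#' @param wt API weight percent
#' @param temperature K
#' @param plan an [experiment_plan()]
#' @param seed run seed
#' @param box_edge optional fixed cubic box edge, nm (used by the loading
#'   study to keep the simulation cell identical across loadings, the
#'   constant-volume construction of the emulated protocol); `NULL` sizes
#'   the box from `plan$density`
#' @return list with `energies` (named scalars), `ratio`, `hbonds`,
#'   `msd_profile`, `run`, `system`, provenance fields
#' @export
run_mixture_system <- function(api, excipient, wt, temperature, plan,
                               seed = 1, box_edge = NULL) {
  api_t <- api_template(api)
  mono <- excipient_template(excipient)
  chain <- build_polymer_chain(mono, plan$n_monomers)
  mix <- build_mixture_box(api_t, plan$n_api, chain, wt,
                           box_edge = box_edge,
                           seed = derive_seed(seed, 1),
                           density = plan$density)
  sys <- mix$system
  rc <- min(plan$rc, mix$box_edge / 2 * 0.999)
  cs_run <- cutoff_scheme(rc_lj = rc, rc_coul = rc, shift_lj = TRUE)
  cs_ana <- cutoff_scheme(rc_lj = rc, rc_coul = rc,
                          shift_lj = FALSE, shift_coul = FALSE)
  fr <- init_velocities_mb(mix$frame, sys, temperature,
                           seed = derive_seed(seed, 2))
  n_steps <- round(plan$t_run_ps / plan$dt)
  save_every <- max(1L, round(plan$save_interval_ps / plan$dt))
  run <- integrate_nvt(fr, sys,
                       integrator_config(dt = plan$dt, n_steps = n_steps,
                                         save_interval = save_every,
                                         seed = derive_seed(seed, 3)),
                       thermostat_config(target_T = temperature),
                       cutoffs = cs_run)
  t_all <- trajectory_times(run$trajectory)
  t0 <- min(t_all) + plan$equil_fraction * diff(range(t_all))
  window <- c(t0, max(t_all))
  g_api <- select_group(sys, paste("resname", api_t$resname), "API")
  g_pol <- select_group(sys, paste("resname", mono$resname), "polymer")
  e_ap <- group_interaction_energy(run$trajectory, sys, g_api, g_pol,
                                   cutoffs = cs_ana, window = window)
  e_aa <- group_interaction_energy(run$trajectory, sys, g_api, g_api,
                                   cutoffs = cs_ana, window = window)
  ratio <- energy_ratio(e_ap, e_aa)
  hb <- detect_hbonds(trajectory_window(run$trajectory, window[1], window[2]),
                      sys, g_api, g_pol)
  msd_p <- msd(unwrap_trajectory(run$trajectory), sys, g_api,
               window = window)
  list(api = api, excipient = excipient, wt = wt,
       temperature = temperature, seed = seed,
       n_chains = mix$n_chains,
       achieved_wt_percent = mix$achieved_wt_percent,
       box_edge = mix$box_edge,
       e_api_polymer = e_ap, e_api_api = e_aa, ratio = ratio, hbonds = hb,
       msd_profile = msd_p,
       energies = c(e_coul = e_ap$e_coul, e_lj = e_ap$e_lj,
                    e_total = e_ap$e_total,
                    e_total_per_api = e_ap$e_total_per_mol),
       run = run, system = sys, window = window)
}

#' Run the API x excipient screening matrix
#'
#' Builds, simulates and analyzes every API/excipient combination of the
#' plan (first loading and temperature), then ranks excipients per API by
#' most-negative total interaction energy (ties: energy ratio, hydrogen
#' bonds).  A failing system is marked incomplete and the matrix continues.
#'
#' @param plan an [experiment_plan()]
#' @param out_dir optional output directory for JSON/CSV/Markdown reports
#' @param verbose print progress
#' @return `screening_matrix_report`: `table` (one row per system),
#'   `reports` (per-API [rank_excipients()] output), `failed`, `plan`
#' @export
run_screening_matrix <- function(plan = experiment_plan(), out_dir = NULL,
                                 verbose = FALSE) {
  wt <- plan$wt_percent[1]; temp <- plan$temperatures[1]
  rows <- list(); failed <- character(0); k <- 0L
  for (api in plan$apis) {
    for (exc in plan$excipients) {
      k <- k + 1L
      if (verbose) message(sprintf("[%d] %s-%s ...", k, api, exc))
      res <- tryCatch(
        run_mixture_system(api, exc, wt, temp, plan, seed = plan$seeds[1]),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, sprintf("%s-%s: %s", api, exc, conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        api = api, excipient = exc,
        e_coul = res$e_api_polymer$e_coul,
        e_lj = res$e_api_polymer$e_lj,
        e_total = res$e_api_polymer$e_total,
        ratio = if (res$ratio$valid) res$ratio$ratio else NA_real_,
        hbonds = res$hbonds$per_molecule_a,
        seed = plan$seeds[1])
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stop("all systems failed: ", paste(failed, collapse = "; "))
  reports <- lapply(split(tab, tab$api), function(d)
    rank_excipients(data.frame(excipient = d$excipient, e_total = d$e_total,
                               ratio = d$ratio, hbonds = d$hbonds),
                    api = d$api[1]))
  out <- structure(list(table = tab, reports = reports, failed = failed,
                        plan = plan, seeds = plan$seeds[1],
                        best = vapply(reports, `[[`, character(1), "best")),
                   class = "screening_matrix_report")
  if (!is.null(out_dir)) write_report(out, out_dir, "screening")
  out
}

#' @export
print.screening_matrix_report <- function(x, ...) {
  cat(sprintf("<screening_matrix_report> plan %s\n", x$plan$hash))
  for (r in x$reports)
    cat(sprintf("  %s: best %s (%s)\n", r$api, r$best,
                paste(r$ranking$excipient, collapse = " > ")))
  if (length(x$failed)) cat("  incomplete:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}

# mean MSD value over the top half of the lag range (a scalar mobility proxy)
msd_scalar <- function(profile) {
  t <- profile$t
  mean(profile$msd[t >= max(t) / 2])
}

#' Loading study: effect of API weight percent
#'
#' Runs one API/excipient pair at each loading of the plan (default 5 and
#' 50 wt%) for each seed and reports interaction energies, energy ratios
#' and a scalar MSD mobility proxy, plus deltas between the extreme
#' loadings.
#'
#' @param plan an [experiment_plan()]; `wt_percent` should hold the
#'   loadings to compare
#' @param api,excipient the pair to study (defaults: ionic API, polar
#'   excipient)
#' @param out_dir optional report directory
#' @param verbose print progress
#' @return `loading_report`: `table` (per wt x seed), `deltas`, `plan`
#' @export
run_loading_study <- function(plan = experiment_plan(wt_percent = c(5, 50),
                                                     n_api = 12),
                              api = "DLO", excipient = "HPP",
                              out_dir = NULL, verbose = FALSE) {
  rows <- list()
  # constant simulation cell across loadings: the box is sized for the
  # lowest loading at the plan density; higher loadings then contain less
  # material in the same volume (fewer chains per the wt%% formula)
  api_t <- api_template(api)
  chain_m <- plan$n_monomers * excipient_template(excipient)$molar_mass
  wt_ref <- min(plan$wt_percent)
  mass_ref <- plan$n_api * api_t$molar_mass +
    n_chains_for_wt(plan$n_api, api_t$molar_mass, wt_ref, chain_m) * chain_m
  edge_ref <- (mass_ref * md_constants()$amu_per_nm3_to_gcc /
                 plan$density)^(1 / 3)
  for (wt in plan$wt_percent) {
    for (s in plan$seeds) {
      if (verbose) message(sprintf("loading %g wt%% seed %d ...", wt, s))
      res <- run_mixture_system(api, excipient, wt, plan$temperatures[1],
                                plan, seed = s, box_edge = edge_ref)
      rows[[length(rows) + 1L]] <- data.frame(
        wt = wt, seed = s,
        e_coul = res$e_api_polymer$e_coul,
        e_lj = res$e_api_polymer$e_lj,
        e_total = res$e_api_polymer$e_total,
        ratio = if (res$ratio$valid) res$ratio$ratio else NA_real_,
        msd = msd_scalar(res$msd_profile),
        achieved_wt = res$achieved_wt_percent)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab[c("e_total", "ratio", "msd")],
                          by = list(wt = tab$wt), FUN = mean)
  lo <- agg[which.min(agg$wt), ]; hi <- agg[which.max(agg$wt), ]
  deltas <- c(d_abs_e_total = abs(hi$e_total) - abs(lo$e_total),
              d_ratio = hi$ratio - lo$ratio,
              d_msd = hi$msd - lo$msd)
  out <- structure(list(api = api, excipient = excipient, table = tab,
                        means = agg, deltas = deltas, plan = plan),
                   class = "loading_report")
  if (!is.null(out_dir)) write_report(out, out_dir, "loading")
  out
}

#' @export
print.loading_report <- function(x, ...) {
  cat(sprintf("<loading_report> %s in %s\n", x$api, x$excipient))
  print(x$means, digits = 4)
  cat(sprintf("  high-vs-low loading: d|E_total| = %.2f, d(ratio) = %.3f, d(MSD) = %.4f nm^2\n",
              x$deltas[1], x$deltas[2], x$deltas[3]))
  invisible(x)
}

#' Temperature study: effect of temperature on binding and mobility
#'
#' Runs one API/excipient mixture at each plan temperature for each seed.
#' A degenerate single-temperature plan yields a single-row report.
#'
#' @param plan an [experiment_plan()]; `temperatures` holds the sweep
#' @param api,excipient the pair to study (default: small neutral ester in
#'   the acetate-like excipient at the high-loading composition)
#' @param wt loading used for the sweep, weight percent
#' @param out_dir optional report directory
#' @param verbose print progress
#' @return `temperature_report`: `table`, `means` per temperature, `plan`
#' @export
run_temperature_study <- function(plan = experiment_plan(
                                    temperatures = c(300, 373, 433),
                                    n_api = 12),
                                  api = "DMF", excipient = "HAS", wt = 50,
                                  out_dir = NULL, verbose = FALSE) {
  rows <- list()
  for (temp in plan$temperatures) {
    for (s in plan$seeds) {
      if (verbose) message(sprintf("T = %g K seed %d ...", temp, s))
      res <- run_mixture_system(api, excipient, wt, temp, plan, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = temp, seed = s,
        e_coul = res$e_api_polymer$e_coul,
        e_lj = res$e_api_polymer$e_lj,
        e_total = res$e_api_polymer$e_total,
        ratio = if (res$ratio$valid) res$ratio$ratio else NA_real_,
        msd = msd_scalar(res$msd_profile),
        mean_T = mean(res$run$energies$temperature))
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab[c("e_total", "ratio", "msd")],
                          by = list(temperature = tab$temperature), FUN = mean)
  out <- structure(list(api = api, excipient = excipient, wt = wt,
                        table = tab, means = agg, plan = plan),
                   class = "temperature_report")
  if (!is.null(out_dir)) write_report(out, out_dir, "temperature")
  out
}

#' @export
print.temperature_report <- function(x, ...) {
  cat(sprintf("<temperature_report> %s in %s at %g wt%%\n", x$api,
              x$excipient, x$wt))
  print(x$means, digits = 4)
  invisible(x)
}

# JSON + CSV + Markdown report writer shared by the study functions
write_report <- function(report, out_dir, stem) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$table
  utils::write.csv(tab, file.path(out_dir, paste0(stem, ".csv")),
                   row.names = FALSE)
  meta <- list(kind = stem, plan_hash = report$plan$hash,
               seeds = report$plan$seeds,
               plan = unclass(report$plan), table = tab)
  if (!is.null(report$means)) meta$means <- report$means
  if (!is.null(report$best)) meta$best <- as.list(report$best)
  if (!is.null(report$deltas)) meta$deltas <- as.list(report$deltas)
  jsonlite::write_json(meta, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c(paste0("# ", stem, " report"),
          paste0("plan hash: ", report$plan$hash),
          paste0("seeds: ", paste(report$plan$seeds, collapse = ", ")), "",
          paste(utils::capture.output(print(tab, digits = 4)), collapse = "\n"))
  writeLines(md, file.path(out_dir, paste0(stem, ".md")))
  invisible(out_dir)
}
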