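#' Time-averaged interaction energy between two atom groups
#'
#' Per frame, sums pairwise Lennard-Jones and Coulomb terms over pairs
#' (i in a, j in b) within the cutoff under the minimum-image convention,
#' honouring topology exclusions, then averages over the frames in the
#' analysis window.  Negative values indicate attraction.  Group energies
#' use plain real-space terms within the cutoff (no reciprocal-space or
#' shift contribution) -- the standard practical convention for
#' "interaction energy between groups", which mesh-Ewald totals cannot
#' provide either.
#'
#' With `group_b` identical to `group_a` (self-interaction, e.g. API-API),
#' pairs within the same molecule are excluded at molecule granularity
#' unless `include_intramolecular = TRUE` (which still honours bonded
#' exclusions; useful to inspect the counter-ion/anion contribution of an
#' ionic API).
#'
#' @param traj an [md_trajectory()]
#' @param sys an [md_system()]
#' @param group_a,group_b [select_group()] selections; disjoint unless
#'   identical
#' @param cutoffs a [cutoff_scheme()]; analysis defaults are unshifted
#' @param window `c(t_start, t_end)` in ps (default: whole trajectory)
#' @param include_intramolecular see above (self-interaction mode only)
#' @return `interaction_energy_result`: `e_coul`, `e_lj`, `e_total`
#'   (kJ/mol, time-averaged; `e_total = e_coul + e_lj` exactly), `se`
#'   (block-averaged standard error of `e_total`, 5 blocks), `n_frames`,
#'   `per_frame` (data.frame), `e_total_per_mol` (normalized by the number
#'   of molecules in `group_a`)
#' @export
group_interaction_energy <- function(traj, sys, group_a, group_b,
                                     cutoffs = cutoff_scheme(shift_coul = FALSE),
                                     window = NULL,
                                     include_intramolecular = FALSE) {
  same <- setequal(group_a$atom_indices, group_b$atom_indices)
  if (!same) check_groups_disjoint(group_a, group_b)
  if (!is.null(window)) traj <- trajectory_window(traj, window[1], window[2])
  top <- topology_for_kernel(sys)
  molid <- as.integer(sys$atoms$molid)
  nf <- n_frames(traj)
  ec <- numeric(nf); el <- numeric(nf)
  for (i in seq_len(nf)) {
    f <- traj$frames[[i]]
    r <- cpp_group_energy(f$positions, f$box$vectors, top,
                          opts_for_kernel(cutoffs),
                          group_a$atom_indices - 1L, group_b$atom_indices - 1L,
                          same, molid,
                          same && !include_intramolecular)
    ec[i] <- r[["e_coul"]]; el[i] <- r[["e_lj"]]
  }
  et <- ec + el
  se <- block_standard_error(et, 5)
  structure(list(group_a = group_a$label, group_b = group_b$label,
                 e_coul = mean(ec), e_lj = mean(el), e_total = mean(et),
                 e_total_per_mol = mean(et) / length(group_a$molecule_ids),
                 n_frames = nf, se = se,
                 per_frame = data.frame(time = trajectory_times(traj),
                                        e_coul = ec, e_lj = el, e_total = et)),
            class = "interaction_energy_result")
}

block_standard_error <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks) return(NA_real_)
  blk <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  sd(bm) / sqrt(length(bm))
}

#' @export
print.interaction_energy_result <- function(x, ...) {
  cat(sprintf("<interaction_energy> %s -- %s over %d frames\n",
              x$group_a, x$group_b, x$n_frames))
  cat(sprintf("  E_coul = %.2f, E_LJ = %.2f, E_total = %.2f (+/- %.2f) kJ/mol; per molecule %.2f\n",
              x$e_coul, x$e_lj, x$e_total, x$se, x$e_total_per_mol))
  invisible(x)
}

#' API-polymer / API-API energy ratio
#'
#' `ratio = E_total(API-polymer) / E_total(API-API)` when both energies are
#' attractive (negative), yielding a positive ratio; a zero API-polymer
#' energy gives ratio 0.  Otherwise the result is flagged invalid with a
#' reason (never an exception): a near-zero API-API denominator
#' (|E| < `eps0`) or a repulsive term.
#'
#' @param e_ab API-polymer `interaction_energy_result`
#' @param e_aa API-API `interaction_energy_result` for the same API and run
#' @param eps0 denominator validity threshold, kJ/mol
#' @return `energy_ratio_result`: `ratio`, `valid`, `reason`,
#'   `numerator`, `denominator`
#' @export
energy_ratio <- function(e_ab, e_aa, eps0 = 1) {
  num <- e_ab$e_total; den <- e_aa$e_total
  out <- list(ratio = NA_real_, valid = FALSE, reason = "",
              numerator = num, denominator = den)
  if (abs(den) < eps0) {
    out$reason <- sprintf("|E_total(API-API)| = %.3g kJ/mol below threshold %g", abs(den), eps0)
  } else if (den > 0) {
    out$reason <- "API-API interaction is repulsive (positive E_total)"
  } else if (num > 0) {
    out$reason <- "API-polymer interaction is repulsive (positive E_total)"
  } else {
    out$ratio <- num / den
    out$valid <- TRUE
  }
  structure(out, class = "energy_ratio_result")
}

#' @export
print.energy_ratio_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<energy_ratio> %.3f (= %.2f / %.2f kJ/mol)\n",
                x$ratio, x$numerator, x$denominator))
  else
    cat(sprintf("<energy_ratio> invalid: %s\n", x$reason))
  invisible(x)
}

#' Rank excipients for one API
#'
#' Primary key: most negative API-polymer `e_total` first; exact ties are
#' broken by the larger energy ratio, then by the larger hydrogen-bond
#' count.  The full ordering and the selected best excipient are reported.
#'
#' @param results data.frame with columns `excipient`, `e_total`, `ratio`,
#'   `hbonds` (one row per excipient; >= 2 rows)
#' @param api label of the API being screened
#' @return `screening_report` row set with `ranking` (data.frame in rank
#'   order) and `best`
#' @export
rank_excipients <- function(results, api = "API") {
  results <- as.data.frame(results)
  if (nrow(results) < 2) stop("need at least two excipients to rank")
  ord <- order(results$e_total, -results$ratio, -results$hbonds)
  ranking <- results[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(api = api, ranking = ranking,
                 best = ranking$excipient[1]),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> API %s: best excipient = %s\n", x$api, x$best))
  cat(sprintf("  order (strongest first): %s\n",
              paste(x$ranking$excipient, collapse = " > ")))
  print(x$ranking, digits = 4)
  invisible(x)
}
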