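#' Unwrap / wrap a trajectory across periodic boundaries
#'
#' `unwrap_trajectory` makes coordinates continuous in time by removing
#' box jumps: each frame-to-frame displacement is minimum-imaged and
#' accumulated from the first frame.  This requires that no atom moves more
#' than half a box edge between saved frames; displacements at (numerically
#' at) that limit raise an error advising denser saving.
#' `wrap_trajectory` maps all coordinates back into the primary cell;
#' `wrap(unwrap(x))` reproduces a wrapped input exactly up to floating
#' point.
#'
#' @param traj an [md_trajectory()] (boxes required)
#' @return an [md_trajectory()]
#' @export
unwrap_trajectory <- function(traj) {
  nf <- n_frames(traj)
  out <- traj$frames
  prev_wrapped <- traj$frames[[1]]$positions
  cur <- prev_wrapped
  for (i in seq_len(nf)[-1]) {
    f <- traj$frames[[i]]
    d <- f$positions - prev_wrapped
    dmic <- minimum_image(d, f$box)
    L <- vapply(1:3, function(k) sqrt(sum(f$box$vectors[k, ]^2)), numeric(1))
    lim <- matrix(L / 2 * 0.999, nrow(d), 3, byrow = TRUE)
    if (any(abs(dmic) >= lim))
      stop(sprintf("frame %d: displacement at the half-box limit; save frames more densely before unwrapping", i))
    cur <- cur + dmic
    prev_wrapped <- f$positions
    out[[i]] <- md_frame(cur, box = f$box, time = f$time,
                         velocities = f$velocities)
  }
  md_trajectory(out)
}

#' @rdname unwrap_trajectory
#' @export
wrap_trajectory <- function(traj) {
  md_trajectory(lapply(traj$frames, function(f)
    md_frame(wrap_positions(f$positions, f$box), box = f$box,
             time = f$time, velocities = f$velocities)))
}

#' Mean-squared displacement of molecular centres of mass
#'
#' \deqn{MSD(t) = \frac{1}{N}\sum_{i=1}^N \langle |r_i(t) - r_i(0)|^2 \rangle}
#' where \eqn{r_i} is the centre of mass of molecule i of the group and N
#' the number of molecules.  The angle bracket is read as a sliding
#' time-origin average in `"multi"` mode (default); `"single"` uses the
#' window start as the only origin (the literal reading).  The trajectory
#' must be unwrapped first.
#'
#' @param traj an unwrapped [md_trajectory()]
#' @param sys an [md_system()] (for masses and molecule ids)
#' @param group a [select_group()] selection
#' @param window optional `c(t_start, t_end)` ps
#' @param origin_mode `"multi"` or `"single"`
#' @return `msd_profile`: `t` (lag times, ps), `msd` (nm^2),
#'   `n_molecules`, `origin_mode`
#' @export
msd <- function(traj, sys, group, window = NULL,
                origin_mode = c("multi", "single")) {
  origin_mode <- match.arg(origin_mode)
  if (!is.null(window)) traj <- trajectory_window(traj, window[1], window[2])
  nf <- n_frames(traj)
  mols <- group$molecule_ids
  ng <- length(mols)
  masses <- sys$atoms$mass
  molid <- sys$atoms$molid
  idx_by_mol <- lapply(mols, function(m)
    intersect(group$atom_indices, which(molid == m)))
  if (any(lengths(idx_by_mol) == 0)) stop("group has empty molecules")
  # COM array: frames x molecules x 3
  com <- array(0, c(nf, ng, 3))
  for (fi in seq_len(nf)) {
    p <- traj$frames[[fi]]$positions
    for (g in seq_len(ng)) {
      id <- idx_by_mol[[g]]
      w <- masses[id] / sum(masses[id])
      com[fi, g, ] <- colSums(p[id, , drop = FALSE] * w)
    }
  }
  tt <- trajectory_times(traj)
  lags <- seq_len(nf - 1)
  val <- numeric(length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    if (origin_mode == "single") {
      d <- com[1 + l, , , drop = FALSE] - com[1, , , drop = FALSE]
      val[li] <- mean(apply(d, 2, function(m) sum(m^2)))
    } else {
      orig <- seq_len(nf - l)
      d <- com[orig + l, , , drop = FALSE] - com[orig, , , drop = FALSE]
      val[li] <- mean(rowSums(matrix(d, ncol = 3)^2))
    }
  }
  structure(list(t = c(0, tt[1 + lags] - tt[1]), msd = c(0, val),
                 n_molecules = ng, origin_mode = origin_mode,
                 window = range(tt)),
            class = "msd_profile")
}

#' @export
print.msd_profile <- function(x, ...) {
  cat(sprintf("<msd_profile> %d molecules, %d lags to %.2f ps (%s origins); MSD(max) = %.4f nm^2\n",
              x$n_molecules, length(x$t) - 1, max(x$t), x$origin_mode,
              x$msd[length(x$msd)]))
  invisible(x)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of MSD(t) over `fit_range` divided by 6.  A poor
#' linear fit (R^2 below `r2_threshold`, e.g. a ballistic regime) is
#' flagged via `linear_ok` rather than raising.
#'
#' @param profile an `msd_profile`
#' @param fit_range `c(t_min, t_max)` ps; default the upper half of the
#'   profile
#' @param r2_threshold flag threshold for fit quality
#' @return list: `D` (nm^2/ps), `slope`, `r_squared`, `linear_ok`,
#'   `n_points`
#' @export
diffusion_coefficient <- function(profile, fit_range = NULL,
                                  r2_threshold = 0.9) {
  t <- profile$t; y <- profile$msd
  if (is.null(fit_range)) fit_range <- c(max(t) / 2, max(t))
  keep <- t >= fit_range[1] & t <= fit_range[2]
  if (sum(keep) < 5) stop("fit range must contain at least 5 points")
  if (stats::var(t[keep]) == 0) stop("degenerate fit: constant time values")
  fit <- lm(y[keep] ~ t[keep])
  slope <- unname(coef(fit)[2])
  # an exactly linear profile is legitimate input; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(D = slope / 6, slope = slope, r_squared = r2,
       linear_ok = is.finite(r2) && r2 >= r2_threshold,
       n_points = sum(keep))
}
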