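#' Deepest well escape frame (DWEF)
#'
#' The first frame index at which a trajectory has durably left the basin it
#' was seeded in: the earliest f such that every frame in
#' [f, f + persistence) is assigned to a basin other than the seed basin
#' (unassigned frames count as outside). The persistence window suppresses
#' instantaneous barrier recrossings. Frame indices are global (0-based,
#' honoring the trajectory's frame offset).
#'
#' @param traj a \code{gn_trajectory} (or n x 2 matrix).
#' @param surface the \code{gn_surface} the trajectory ran on.
#' @param wells \code{gn_wellset} of that surface.
#' @param persistence frames required outside the seed basin to count as
#'   escaped.
#' @return An object of class \code{gn_escape}: \code{escaped} (logical),
#'   \code{dwef} (frame index, or NA when not escaped), \code{seed_basin},
#'   \code{persistence}, \code{n_frames}.
#' @export
dwef <- function(traj, surface, wells, persistence = 50) {
  if (!inherits(traj, "gn_trajectory")) traj <- trajectory(traj)
  basins <- assign_basins(surface, traj, wells)
  if (is.na(basins[1]))
    stop("invalid seed: frame 0 is not assigned to any basin")
  seed_basin <- basins[1]
  outside <- is.na(basins) | basins != seed_basin
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  escaped <- length(hit) > 0
  structure(list(
    escaped = escaped,
    dwef = if (escaped) traj$frame_offset + starts[hit[1]] - 1L else NA_integer_,
    seed_basin = seed_basin,
    persistence = persistence,
    n_frames = length(basins)), class = "gn_escape")
}

#' @export
print.gn_escape <- function(x, ...) {
  if (x$escaped) {
    cat("<gn_escape: escaped seed basin ", x$seed_basin, " at frame ", x$dwef,
        " (persistence ", x$persistence, ")>\n", sep = "")
  } else {
    cat("<gn_escape: not escaped from basin", x$seed_basin, "within",
        x$n_frames, "frames>\n")
  }
  invisible(x)
}

#' Count the wells a trajectory identified
#'
#' A well counts as identified when at least \code{min_frames} frames of the
#' trajectory are assigned to its basin — a dwell criterion (default one
#' inner-segment's worth of frames) rather than a mere visit.
#'
#' @inheritParams dwef
#' @param min_frames dwell threshold per basin.
#' @return Integer count in [0, number of wells].
#' @export
wells_identified <- function(traj, surface, wells, min_frames = 50) {
  stopifnot(nrow(wells$minima) >= 1)
  if (!inherits(traj, "gn_trajectory")) traj <- trajectory(traj)
  basins <- assign_basins(surface, traj, wells)
  counts <- tabulate(basins[!is.na(basins)], nbins = nrow(wells$minima))
  sum(counts >= min_frames)
}

#' Search success initialization ratio (SSIR)
#'
#' The ratio of the total number of successful well identifications across
#' initializations to the product of the number of wells and the number of
#' initializations: \eqn{\sum_i N^i_{success} / (N_{wells} N_{init})}.
#' 1 means every initialization found every well.
#'
#' @param x a \code{gn_ssir} experiment (from
#'   \code{\link{run_ssir_experiment}}) or a vector of per-initialization
#'   success counts.
#' @param n_wells number of wells (required when \code{x} is a vector).
#' @param n_init number of initializations; defaults to \code{length(x)}.
#' @return Ratio in [0, 1].
#' @export
ssir <- function(x, n_wells = NULL, n_init = NULL) {
  if (inherits(x, "gn_ssir")) {
    counts <- x$counts; n_wells <- x$n_wells; n_init <- x$n_init
  } else {
    counts <- x
    if (is.null(n_wells)) stop("n_wells is required")
    if (is.null(n_init)) n_init <- length(counts)
  }
  stopifnot(n_wells >= 1, n_init >= 1)
  if (any(counts > n_wells))
    stop("inconsistent experiment: a success count exceeds n_wells")
  sum(counts) / (n_wells * n_init)
}

#' Initialization grid for an SSIR experiment
#'
#' Regular grid over the surface's region of interest; nodes whose potential
#' energy exceeds the divergence cap (450 above the global minimum) are
#' dropped, reducing the number of initializations accordingly.
#'
#' @param surface a \code{gn_surface}.
#' @param wells its \code{gn_wellset}.
#' @param spacing grid spacing.
#' @param xlim,ylim grid extent; default \code{\link{default_region}}.
#' @return m x 2 matrix of start points.
#' @export
ssir_grid <- function(surface, wells, spacing = 0.8, xlim = NULL, ylim = NULL) {
  if (is.null(xlim) || is.null(ylim)) {
    reg <- default_region(surface)
    if (is.null(reg)) stop("no default region for this surface; supply xlim/ylim")
    xlim <- reg$xlim; ylim <- reg$ylim
  }
  g <- as.matrix(expand.grid(x = seq(xlim[1], xlim[2], by = spacing),
                             y = seq(ylim[1], ylim[2], by = spacing)))
  keep <- pes_evaluate(surface, g) <= energy_cap(wells)
  g[keep, , drop = FALSE]
}

#' Run an initialization-sensitivity (SSIR) experiment
#'
#' For every grid start, runs either plain Langevin dynamics or GradNav for
#' \code{frames_per_init} frames and counts the wells identified
#' (\code{\link{wells_identified}}). Deterministic given \code{seed}: start i
#' uses seed \code{seed * 100 + i}.
#'
#' @param surface a \code{gn_surface}.
#' @param wells its \code{gn_wellset}.
#' @param method "ld" or "gradnav".
#' @param spacing grid spacing.
#' @param frames_per_init frame budget per initialization.
#' @param seed experiment seed.
#' @param params \code{gn_ld_params} for the dynamics.
#' @param config \code{gn_config} for method "gradnav"; defaults to the
#'   preset named after the surface when one exists.
#' @param min_frames dwell threshold for identification.
#' @param xlim,ylim grid extent; default \code{\link{default_region}}.
#' @return An object of class \code{gn_ssir}: \code{starts}, per-init
#'   \code{counts}, \code{n_wells}, \code{n_init}, \code{ssir},
#'   \code{method}.
#' @export
run_ssir_experiment <- function(surface, wells, method = c("ld", "gradnav"),
                                spacing = 0.8, frames_per_init = 10000,
                                seed = 1, params = ld_params(), config = NULL,
                                min_frames = 50, xlim = NULL, ylim = NULL) {
  method <- match.arg(method)
  grid <- ssir_grid(surface, wells, spacing, xlim, ylim)
  if (nrow(grid) == 0) stop("empty initialization grid")
  if (method == "gradnav" && is.null(config)) {
    config <- if (surface$name %in% c("muller", "modified_muller")) {
      gradnav_config(preset = surface$name, total_frames = frames_per_init)
    } else {
      gradnav_config(total_frames = frames_per_init)
    }
  }
  counts <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    si <- as.numeric(seed) * 100 + i
    traj <- tryCatch({
      if (method == "ld") {
        ld_simulate(surface, params, grid[i, ], frames_per_init, seed = si)
      } else {
        gradnav_run(langevin_engine(surface, params), config, grid[i, ],
                    seed = si)$trajectory
      }
    }, error = function(e)
      stop("engine failure at start (", grid[i, 1], ", ", grid[i, 2], "): ",
           conditionMessage(e)))
    counts[i] <- wells_identified(traj, surface, wells, min_frames)
  }
  res <- structure(list(starts = grid, counts = counts,
                        n_wells = nrow(wells$minima), n_init = nrow(grid),
                        method = method, frames_per_init = frames_per_init,
                        seed = seed),
                   class = "gn_ssir")
  res$ssir <- ssir(res)
  res
}

#' @export
print.gn_ssir <- function(x, ...) {
  cat(sprintf("<gn_ssir: %s, %d starts x %d frames, %d wells -> SSIR = %.3f>\n",
              x$method, x$n_init, x$frames_per_init, x$n_wells, x$ssir))
  invisible(x)
}
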