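#' GradNav configuration
#'
#' Hyperparameters of the gradient-of-observation-density navigation loop.
#' The named presets carry the published settings per system:
#' \tabular{lccc}{
#'   \tab beta \tab k \tab outer/inner frames \cr
#'   muller \tab 0.75 \tab 100 \tab 500 / 50 \cr
#'   modified_muller \tab 1 \tab 20 \tab 500 / 50 \cr
#'   fs_peptide \tab 0.1 \tab 100 \tab 300 / 40 \cr
#' }
#' with a total frame budget of 10,000 in all presets.
#'
#' @param preset optional preset name ("muller", "modified_muller",
#'   "fs_peptide"); explicit arguments override preset values.
#' @param beta update-rate intercept (CV-space length units).
#' @param k update-rate slope divisor; the rate grows by 1/k per failed probe.
#' @param outer_frames frames per outer (density-building) segment.
#' @param inner_frames frames per inner (probe) segment.
#' @param total_frames overall frame budget per run.
#' @param bandwidth kernel density bandwidth: positive number or "auto"
#'   (Scott's rule).
#' @param boundary_mode "bbox" (axis-aligned bounding box) or "hull"
#'   (convex hull).
#' @param obs_scope observation set for the density and boundary: "run"
#'   (default) accumulates every frame since the start of the run, so the
#'   boundary covers all explored regions and an escape means reaching a
#'   genuinely new region; "well" resets the accumulation after every escape,
#'   so only the current well's observations count. With "well", the tight
#'   boundary of a single outer segment misclassifies probes whose centroid
#'   is dragged slightly off-center by their initial transit, so the stride
#'   never escalates on surfaces whose neighboring wells are far away; "run"
#'   self-corrects because the boundary absorbs past probe paths.
#' @param max_stride abort when the update stride exceeds this.
#' @return An object of class \code{gn_config}.
#' @export
gradnav_config <- function(preset = NULL, beta = NULL, k = NULL,
                           outer_frames = NULL, inner_frames = NULL,
                           total_frames = NULL, bandwidth = "auto",
                           boundary_mode = c("bbox", "hull"),
                           obs_scope = c("run", "well"),
                           max_stride = 10000) {
  presets <- list(
    muller = list(beta = 0.75, k = 100, outer_frames = 500, inner_frames = 50),
    modified_muller = list(beta = 1, k = 20, outer_frames = 500, inner_frames = 50),
    fs_peptide = list(beta = 0.1, k = 100, outer_frames = 300, inner_frames = 40))
  base <- list(beta = 0.75, k = 100, outer_frames = 500, inner_frames = 50,
               total_frames = 10000)
  if (!is.null(preset)) {
    if (!preset %in% names(presets)) stop("unknown preset '", preset, "'")
    base[names(presets[[preset]])] <- presets[[preset]]
  }
  pick <- function(user, def) if (is.null(user)) def else user
  cfg <- list(beta = pick(beta, base$beta), k = pick(k, base$k),
              outer_frames = pick(outer_frames, base$outer_frames),
              inner_frames = pick(inner_frames, base$inner_frames),
              total_frames = pick(total_frames, base$total_frames),
              bandwidth = bandwidth,
              boundary_mode = match.arg(boundary_mode),
              obs_scope = match.arg(obs_scope),
              max_stride = max_stride,
              preset = if (is.null(preset)) NA_character_ else preset)
  with(cfg, stopifnot(beta > 0, k > 0, inner_frames < outer_frames,
                      total_frames >= outer_frames, max_stride > 0))
  structure(cfg, class = "gn_config")
}

#' @export
print.gn_config <- function(x, ...) {
  cat(sprintf(
    "<gn_config%s: beta=%g k=%g outer=%d inner=%d budget=%d boundary=%s scope=%s>\n",
    if (is.na(x$preset)) "" else paste0(" (", x$preset, ")"),
    x$beta, x$k, x$outer_frames, x$inner_frames, x$total_frames,
    x$boundary_mode, x$obs_scope))
  invisible(x)
}

# ---- observation density -----------------------------------------------------

#' Gaussian kernel density of observed points
#'
#' Product-Gaussian KDE over 2-D observations with per-dimension bandwidths.
#' "auto" uses Scott's rule, h_d = sd_d * n^(-1/6). The model exposes the
#' density rho and its analytic gradient at arbitrary points.
#'
#' @param points n x 2 matrix (n >= 2) or a \code{gn_trajectory}.
#' @param bandwidth positive scalar (same width both dimensions), length-2
#'   vector, or "auto".
#' @return An object of class \code{gn_density}.
#' @export
estimate_density <- function(points, bandwidth = "auto") {
  if (inherits(points, "gn_trajectory")) points <- points$points
  p <- as_points_matrix(points)
  if (nrow(p) < 2) stop("density estimation needs at least 2 points")
  if (identical(bandwidth, "auto")) {
    h <- apply(p, 2, stats::sd) * nrow(p)^(-1 / 6)
    h[!is.finite(h) | h <= 0] <- 1e-3
  } else {
    h <- rep(as.numeric(bandwidth), length.out = 2)
    if (any(!is.finite(h) | h <= 0)) stop("bandwidth must be positive")
  }
  structure(list(points = p, h = h), class = "gn_density")
}

#' Evaluate an observation density
#' @param density a \code{gn_density}.
#' @param x length-2 point.
#' @return rho(x), a non-negative scalar; integrates to 1 over the plane.
#' @export
density_value <- function(density, x) {
  z1 <- (x[1] - density$points[, 1]) / density$h[1]
  z2 <- (x[2] - density$points[, 2]) / density$h[2]
  mean(exp(-0.5 * (z1^2 + z2^2))) / (2 * pi * density$h[1] * density$h[2])
}

#' Analytic gradient of an observation density
#' @inheritParams density_value
#' @return Length-2 gradient of rho at x.
#' @export
density_gradient <- function(density, x) {
  d1 <- x[1] - density$points[, 1]
  d2 <- x[2] - density$points[, 2]
  w <- exp(-0.5 * ((d1 / density$h[1])^2 + (d2 / density$h[2])^2))
  norm <- 2 * pi * density$h[1] * density$h[2] * nrow(density$points)
  c(-sum(w * d1) / density$h[1]^2, -sum(w * d2) / density$h[2]^2) / norm
}

# ---- observation boundary ----------------------------------------------------

#' Spatial boundary of observed points
#'
#' Either the axis-aligned bounding box of the points or their convex hull.
#' Boundary points count as inside.
#'
#' @param points n x 2 matrix or \code{gn_trajectory}.
#' @param mode "bbox" or "hull".
#' @return An object of class \code{gn_boundary}.
#' @export
observation_boundary <- function(points, mode = c("bbox", "hull")) {
  mode <- match.arg(mode)
  if (inherits(points, "gn_trajectory")) points <- points$points
  p <- as_points_matrix(points)
  if (mode == "hull" && nrow(p) >= 3) {
    idx <- grDevices::chull(p[, 1], p[, 2])
    if (length(idx) >= 3)
      return(structure(list(mode = "hull", vertices = p[idx, , drop = FALSE]),
                       class = "gn_boundary"))
    # degenerate (collinear) hull: fall through to bbox geometry
  }
  structure(list(mode = "bbox",
                 xlim = range(p[, 1]), ylim = range(p[, 2])),
            class = "gn_boundary")
}

#' Test whether a point lies inside a boundary
#' @param boundary a \code{gn_boundary}.
#' @param point length-2 point.
#' @param eps tolerance; boundary points count as inside.
#' @return Logical.
#' @export
boundary_contains <- function(boundary, point, eps = 1e-9) {
  if (boundary$mode == "bbox") {
    return(point[1] >= boundary$xlim[1] - eps &&
           point[1] <= boundary$xlim[2] + eps &&
           point[2] >= boundary$ylim[1] - eps &&
           point[2] <= boundary$ylim[2] + eps)
  }
  v <- boundary$vertices
  n <- nrow(v)
  # chull() returns vertices in clockwise order; inside = all cross <= 0
  s <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (point[2] - a[2]) - (b[2] - a[2]) * (point[1] - a[1])
    if (cr > eps && s < 0) return(FALSE)
    if (cr < -eps && s > 0) return(FALSE)
    if (abs(cr) > eps) s <- sign(cr)
  }
  TRUE
}

#' Centroid (mean position) of a trajectory or point set
#' @param points n x 2 matrix or \code{gn_trajectory}.
#' @return Length-2 vector.
#' @export
traj_centroid <- function(points) {
  if (inherits(points, "gn_trajectory")) points <- points$points
  colMeans(as_points_matrix(points))
}

# ---- the update rule ---------------------------------------------------------

#' Restart update rate
#'
#' The displacement magnitude applied to the next restart point,
#' \eqn{rate = \gamma (\beta + v / k)}: a linear escalation in the update
#' stride v with intercept beta and slope 1/k, gated by the centroid
#' indicator gamma (gamma = 0, i.e. centroid escaped the boundary, resets the
#' rate to zero).
#'
#' @param stride update stride v (consecutive non-escaped segments), >= 0.
#' @param cfg a \code{gn_config} supplying beta and k.
#' @param gamma 0 or 1 centroid-in-boundary indicator.
#' @return Non-negative rate (CV-space length).
#' @export
update_rate <- function(stride, cfg, gamma) {
  stopifnot(stride >= 0, gamma %in% c(0, 1))
  gamma * (cfg$beta + stride / cfg$k)
}

#' Propose the next restart point
#'
#' Displaces the last observed point by \code{rate} along the negative,
#' unit-normalized observation density gradient — away from explored regions.
#' When the gradient is numerically zero the direction falls back to a random
#' unit vector drawn from R's RNG (seed it for reproducibility).
#'
#' @param x_last length-2 last point of the preceding segment.
#' @param density a \code{gn_density} built from prior observations.
#' @param rate displacement magnitude (>= 0), see \code{\link{update_rate}}.
#' @return Length-2 new start point; equals \code{x_last} when rate is 0.
#' @export
next_start <- function(x_last, density, rate) {
  stopifnot(rate >= 0)
  if (rate == 0) return(x_last)
  g <- density_gradient(density, x_last)
  ng <- sqrt(sum(g^2))
  dir <- if (ng < 1e-12) {
    ang <- stats::runif(1, 0, 2 * pi)
    c(cos(ang), sin(ang))
  } else {
    -g / ng
  }
  x_last + rate * dir
}

#' Temper a restart proposal to accessible energies
#'
#' A proposed restart point whose potential energy exceeds the accessible-
#' energy cap lies inside a repulsive wall where no physical system can be
#' initialized (and where the discretized dynamics overflow). The proposal is
#' backtracked along the straight line toward the launch point to the
#' farthest point whose energy is within the cap (bisection). If the launch
#' point itself exceeds the cap the launch point is returned.
#'
#' @param surface a \code{gn_surface}.
#' @param x_from length-2 launch point (assumed accessible).
#' @param x_to length-2 proposed restart point.
#' @param cap accessible-energy cap (absolute energy).
#' @return Length-2 point on the segment [x_from, x_to] with energy <= cap
#'   (or \code{x_from}).
#' @export
temper_start <- function(surface, x_from, x_to, cap) {
  if (pes_evaluate(surface, x_to) <= cap) return(x_to)
  if (pes_evaluate(surface, x_from) > cap) return(x_from)
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (pes_evaluate(surface, x_from + mid * (x_to - x_from)) <= cap)
      lo <- mid else hi <- mid
  }
  x_from + lo * (x_to - x_from)
}

# ---- engines -----------------------------------------------------------------

#' Langevin dynamics engine for GradNav
#'
#' Wraps a surface and integrator parameters as the dynamics backend of
#' \code{\link{gradnav_run}}.
#'
#' @param surface a \code{gn_surface}.
#' @param params a \code{gn_ld_params}.
#' @return An object of class \code{gn_engine}.
#' @export
langevin_engine <- function(surface, params = ld_params()) {
  structure(list(kind = "langevin", surface = surface, params = params),
            class = "gn_engine")
}

#' Run one dynamics segment through an engine
#'
#' @param engine a \code{gn_engine}.
#' @param start length-2 start (query point for replay engines).
#' @param n number of frames.
#' @param seed segment seed (counter-based stream key).
#' @return A \code{gn_trajectory}; replay engines attach the resolved cursors
#'   as attribute \code{cursors}.
#' @export
simulate_segment <- function(engine, start, n, seed) {
  stopifnot(inherits(engine, "gn_engine"))
  if (engine$kind == "langevin") {
    ld_simulate(engine$surface, engine$params, start, n, seed)
  } else {
    bank_segment(engine$bank, start, n)
  }
}

# ---- the GradNav loop --------------------------------------------------------

segment_seed <- function(seed, idx) as.numeric(seed) * 2^20 + idx

#' Run the GradNav algorithm
#'
#' Alternates long outer segments (which establish the observation density
#' and boundary) with short inner probe segments restarted at points pushed
#' along the negative density gradient. Each probe's centroid is tested
#' against the boundary of the accumulated observations plus the probe's own
#' launch point (the restart displacement is deliberate navigation, not
#' discovery; without the launch point the launch transit drags the centroid
#' outside and fabricates escapes). Observations accumulate over every frame
#' since the start of the run under \code{obs_scope = "run"} (default), or
#' since the last escape under \code{obs_scope = "well"}. A centroid inside
#' (gamma = 1) increments the update stride and escalates the next restart
#' displacement linearly; a centroid outside (gamma = 0) marks an escape,
#' resets the stride, and starts a fresh outer segment from the escaped
#' segment's last frame. For Langevin engines, restart proposals are
#' tempered to accessible energies (see \code{\link{temper_start}}) so that
#' escalating strides cannot initialize the dynamics inside a repulsive wall;
#' replay engines are inherently safe because restarts snap to existing bank
#' frames. The dynamics
#' themselves are never modified — only restart points — so every segment is
#' an unbiased run of the engine, reproducible from its recorded
#' (start, seed, length).
#'
#' @param engine a \code{gn_engine}, or a \code{gn_surface} (wrapped in a
#'   Langevin engine with default \code{\link{ld_params}}).
#' @param cfg a \code{gn_config}.
#' @param start length-2 initial point.
#' @param seed run seed; all segment noise streams and R-level fallbacks
#'   derive from it.
#' @return An object of class \code{gn_result}: \code{trajectory}
#'   (concatenated \code{gn_trajectory}), \code{segment_id} per frame,
#'   \code{segments} (one row per segment: kind, start, end, stride at
#'   launch, gamma, centroid, escaped flag, frame span, segment seed),
#'   \code{config}, \code{seed}.
#' @export
gradnav_run <- function(engine, cfg, start, seed) {
  if (inherits(engine, "gn_surface")) engine <- langevin_engine(engine)
  stopifnot(inherits(engine, "gn_engine"), inherits(cfg, "gn_config"),
            length(start) == 2, all(is.finite(start)))
  set.seed(seed %% .Machine$integer.max)

  pts_all <- vector("list", 64)
  seg_rows <- vector("list", 64)
  seg_ids <- vector("list", 64)
  obs <- NULL
  v <- 0L
  mode <- "outer"
  cur_start <- as.numeric(start)
  offset <- 0L
  remaining <- cfg$total_frames
  idx <- 0L
  vmin <- Inf   # lowest observed energy; anchors the accessible-energy cap

  while (remaining > 0) {
    idx <- idx + 1L
    n <- min(if (mode == "outer") cfg$outer_frames else cfg$inner_frames,
             remaining)
    sseed <- segment_seed(seed, idx)
    seg <- simulate_segment(engine, cur_start, n, sseed)
    pts <- seg$points
    cen <- colMeans(pts)
    if (engine$kind == "langevin")
      vmin <- min(vmin, min(pes_evaluate(engine$surface, pts)))

    if (mode == "outer") {
      gamma <- 1L  # outer segments establish the boundary, never test it
      escaped <- FALSE
    } else {
      # the launch point joins the boundary for this probe's test: the
      # restart displacement is deliberate navigation, so a probe escapes
      # only when its dynamics settle beyond both the observations and the
      # point it was launched from (otherwise the launch transit drags the
      # centroid outside and fabricates an escape)
      test_boundary <- observation_boundary(rbind(obs, cur_start),
                                            cfg$boundary_mode)
      gamma <- as.integer(boundary_contains(test_boundary, cen))
      escaped <- gamma == 0L
    }
    # under "run" scope escaped frames are observations of the new region
    # and enter the accumulation; under "well" scope they are discarded
    # along with the rest of the accumulation when the new outer starts
    if (cfg$obs_scope == "run" || !escaped) {
      obs <- if (mode == "outer" && cfg$obs_scope == "well") pts
             else rbind(obs, pts)
    }

    x_last <- pts[nrow(pts), ]
    pts_all[[idx]] <- pts
    seg_ids[[idx]] <- rep(idx, n)
    seg_rows[[idx]] <- data.frame(
      segment = idx, kind = mode,
      start_x = cur_start[1], start_y = cur_start[2],
      end_x = x_last[1], end_y = x_last[2],
      stride_at_launch = v, gamma = gamma,
      centroid_x = cen[1], centroid_y = cen[2],
      escaped = escaped,
      frame_first = offset, frame_last = offset + n - 1L,
      n_frames = n, seed = sseed)

    offset <- offset + n
    remaining <- remaining - n
    if (remaining <= 0) break

    rate <- update_rate(v, cfg, gamma)
    if (escaped) {
      v <- 0L
      mode <- "outer"
      cur_start <- x_last          # rate is 0: restart where the escape ended
      if (cfg$obs_scope == "well") obs <- NULL
    } else {
      density <- estimate_density(obs, cfg$bandwidth)
      cur_start <- next_start(x_last, density, rate)
      if (engine$kind == "langevin") {
        # same +450 margin as the basin-descent accessible-energy cap
        cur_start <- temper_start(engine$surface, x_last, cur_start,
                                  vmin + 450)
      }
      v <- v + 1L
      if (v > cfg$max_stride)
        stop("update stride exceeded max_stride (", cfg$max_stride,
             ") at segment ", idx, "; configuration is pathological")
      mode <- "inner"
    }
  }

  traj <- trajectory(do.call(rbind, pts_all[seq_len(idx)]), frame_offset = 0)
  structure(list(trajectory = traj,
                 segment_id = unlist(seg_ids[seq_len(idx)]),
                 segments = do.call(rbind, seg_rows[seq_len(idx)]),
                 config = cfg, seed = seed,
                 engine_kind = engine$kind),
            class = "gn_result")
}

#' @export
print.gn_result <- function(x, ...) {
  cat(sprintf(
    "<gn_result: %d frames in %d segments (%d escapes), engine=%s, seed=%s>\n",
    n_frames(x$trajectory), nrow(x$segments), sum(x$segments$escaped),
    x$engine_kind, format(x$seed)))
  invisible(x)
}

#' Replay a recorded GradNav segment through the plain engine
#'
#' Re-runs the dynamics engine from a segment's recorded start point, seed
#' and length. For Langevin engines the result is bit-identical to the frames
#' stored in the run — the no-bias guarantee that GradNav alters only restart
#' points, never the dynamics.
#'
#' @param engine the \code{gn_engine} used in the run (or the surface).
#' @param result a \code{gn_result}.
#' @param segment segment number (row of \code{result$segments}).
#' @return A \code{gn_trajectory}.
#' @export
replay_gradnav_segment <- function(engine, result, segment) {
  if (inherits(engine, "gn_surface")) engine <- langevin_engine(engine)
  rec <- result$segments[result$segments$segment == segment, ]
  if (nrow(rec) != 1) stop("no such segment: ", segment)
  simulate_segment(engine, c(rec$start_x, rec$start_y), rec$n_frames, rec$seed)
}

#' Frames of a run belonging to one segment
#' @param result a \code{gn_result}.
#' @param segment segment number.
#' @return n x 2 matrix of that segment's frames.
#' @export
segment_frames <- function(result, segment) {
  result$trajectory$points[result$segment_id == segment, , drop = FALSE]
}
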