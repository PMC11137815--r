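#' Bank of pre-computed collective-variable trajectories
#'
#' Internal constructor: builds the flat point table and the uniform-grid
#' spatial index (cell size = cutoff) used by \code{\link{propose_restart}}.
#' @noRd
new_bank <- function(trajectories, cutoff) {
  stopifnot(length(trajectories) >= 1, cutoff > 0)
  lens <- vapply(trajectories, nrow, integer(1))
  if (any(lens < 1)) stop("every bank trajectory must be non-empty")
  flat <- do.call(rbind, trajectories)
  traj_id <- rep(seq_along(trajectories), lens)
  frame_id <- unlist(lapply(lens, seq_len))
  index <- new.env(parent = emptyenv())
  keys <- paste(floor(flat[, 1] / cutoff), floor(flat[, 2] / cutoff))
  sp <- split(seq_len(nrow(flat)), keys)
  for (k in names(sp)) assign(k, sp[[k]], envir = index)
  structure(list(trajectories = trajectories, cutoff = cutoff,
                 total_frames = sum(lens), flat = flat, traj_id = traj_id,
                 frame_id = frame_id, index = index),
            class = "gn_bank")
}

#' @export
print.gn_bank <- function(x, ...) {
  cat(sprintf("<gn_bank: %d trajectories, %d frames, cutoff %g>\n",
              length(x$trajectories), x$total_frames, x$cutoff))
  invisible(x)
}

#' Load a trajectory bank from CSV files
#'
#' Each file holds one 2-D collective-variable trajectory with columns
#' \code{frame,x,y}.
#'
#' @param paths character vector of CSV files.
#' @param cutoff restart search radius in CV units.
#' @return An object of class \code{gn_bank}.
#' @export
load_bank <- function(paths, cutoff = 0.02) {
  trajs <- lapply(paths, function(p) read_trajectory_csv(p)$points)
  new_bank(trajs, cutoff)
}

#' Build a bank from in-memory trajectories
#'
#' @param trajectories list of n x 2 matrices or \code{gn_trajectory} objects.
#' @param cutoff restart search radius.
#' @return A \code{gn_bank}.
#' @export
bank_from_trajectories <- function(trajectories, cutoff = 0.02) {
  trajs <- lapply(trajectories, function(t)
    if (inherits(t, "gn_trajectory")) t$points else as_points_matrix(t))
  new_bank(trajs, cutoff)
}

#' Write a bank to per-trajectory CSV files
#'
#' @param bank a \code{gn_bank}.
#' @param dir output directory (created if missing).
#' @return Character vector of the files written.
#' @export
write_bank <- function(bank, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("traj_%03d.csv", seq_along(bank$trajectories)))
  for (i in seq_along(paths))
    write_trajectory_csv(trajectory(bank$trajectories[[i]]), paths[i])
  invisible(paths)
}

#' Candidate bank points within the cutoff of a query (spatial index)
#' @noRd
bank_candidates <- function(bank, query) {
  cu <- bank$cutoff
  cx <- floor(query[1] / cu); cy <- floor(query[2] / cu)
  idx <- integer(0)
  for (i in (cx - 1):(cx + 1)) {
    for (j in (cy - 1):(cy + 1)) {
      k <- paste(i, j)
      if (exists(k, envir = bank$index, inherits = FALSE))
        idx <- c(idx, get(k, envir = bank$index, inherits = FALSE))
    }
  }
  if (length(idx) == 0) return(integer(0))
  d2 <- (bank$flat[idx, 1] - query[1])^2 + (bank$flat[idx, 2] - query[2])^2
  sort(idx[d2 <= cu^2])
}

#' Propose a restart point from a trajectory bank
#'
#' All bank points within the cutoff radius of the query are candidates; one
#' is chosen uniformly at random (R's RNG — seed it for reproducibility). If
#' no point lies within the cutoff, the single nearest point is selected
#' deterministically, ties broken by lowest (trajectory, frame).
#'
#' @param bank a \code{gn_bank}.
#' @param query length-2 proposed CV point.
#' @return A replay cursor: list with \code{traj_id} and \code{frame}
#'   (1-based index within that trajectory), class \code{gn_cursor}.
#' @export
propose_restart <- function(bank, query) {
  stopifnot(length(query) == 2, all(is.finite(query)))
  cand <- bank_candidates(bank, query)
  if (length(cand) >= 1) {
    pick <- cand[sample.int(length(cand), 1)]
  } else {
    d2 <- (bank$flat[, 1] - query[1])^2 + (bank$flat[, 2] - query[2])^2
    best <- which(d2 == min(d2))
    ord <- order(bank$traj_id[best], bank$frame_id[best])
    pick <- best[ord[1]]
  }
  structure(list(traj_id = bank$traj_id[pick], frame = bank$frame_id[pick]),
            class = "gn_cursor")
}

#' Replay frames from a bank trajectory
#'
#' Returns the next \code{n} frames of the cursor's trajectory starting at
#' the cursor (inclusive), truncated at the trajectory end with attribute
#' \code{truncated} set.
#'
#' @param bank a \code{gn_bank}.
#' @param cursor a \code{gn_cursor}.
#' @param n number of frames requested.
#' @return A \code{gn_trajectory} with attribute \code{truncated}.
#' @export
replay_segment <- function(bank, cursor, n) {
  tr <- bank$trajectories[[cursor$traj_id]]
  if (cursor$frame < 1 || cursor$frame > nrow(tr)) stop("invalid cursor")
  last <- min(nrow(tr), cursor$frame + n - 1)
  out <- trajectory(tr[cursor$frame:last, , drop = FALSE])
  attr(out, "truncated") <- (last - cursor$frame + 1) < n
  out
}

#' Pseudo-dynamics segment over a bank
#'
#' Emulates a simulation segment of \code{n} frames: a restart is proposed
#' near the query point and subsequent frames are collected from the bank;
#' when a source trajectory ends mid-segment a new restart is proposed from
#' the last collected frame and collection continues until \code{n} frames
#' are gathered.
#'
#' @param bank a \code{gn_bank}.
#' @param query length-2 CV point to restart near.
#' @param n frames to collect.
#' @return A \code{gn_trajectory} with attribute \code{cursors} (list of the
#'   replay cursors used).
#' @export
bank_segment <- function(bank, query, n) {
  pts <- matrix(numeric(0), ncol = 2)
  cursors <- list()
  q <- query
  while (nrow(pts) < n) {
    cur <- propose_restart(bank, q)
    cursors[[length(cursors) + 1]] <- cur
    seg <- replay_segment(bank, cur, n - nrow(pts))
    pts <- rbind(pts, seg$points)
    q <- pts[nrow(pts), ]
  }
  out <- trajectory(pts)
  attr(out, "cursors") <- cursors
  out
}

#' Trajectory-bank replay engine for GradNav
#'
#' Treats a bank of pre-computed CV trajectories as the restartable dynamics
#' backend of \code{\link{gradnav_run}} (pseudo-dynamics). The bank is never
#' modified.
#'
#' @param bank a \code{gn_bank}.
#' @return A \code{gn_engine}.
#' @export
bank_engine <- function(bank) {
  stopifnot(inherits(bank, "gn_bank"))
  structure(list(kind = "bank", bank = bank), class = "gn_engine")
}

#' Angle at the vertex of three points
#'
#' The angle p1-p2-p3 at vertex p2, in radians within [0, pi]. Works in any
#' dimension; useful for building angle collective variables from structural
#' coordinates.
#'
#' @param p1,p2,p3 numeric coordinate vectors of equal length.
#' @return Angle in radians.
#' @export
three_point_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("invalid geometry: zero-length arm at vertex")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Generate a synthetic trajectory bank
#'
#' Discrete-time dwell/jump processes over a set of well centers: each frame
#' the walker stays in its current well with Gaussian jitter and jumps to a
#' different (uniformly chosen) well with a per-frame probability. Per-
#' trajectory jump probabilities allow mixing transitioning and
#' non-transitioning trajectories, emulating CV trajectory banks in which
#' only some source simulations cross between metastable states.
#'
#' @param wells k x 2 matrix of well centers (k >= 2).
#' @param jump_prob per-frame transition probability; scalar or one value per
#'   trajectory (recycled).
#' @param jitter Gaussian jitter s.d. around the well center.
#' @param n_traj number of trajectories.
#' @param frames frames per trajectory.
#' @param seed RNG seed.
#' @param cutoff restart search radius of the resulting bank.
#' @return A \code{gn_bank}; each trajectory carries its per-frame well label
#'   in the attribute \code{labels} (list, one vector per trajectory).
#' @export
synthesize_bank <- function(wells, jump_prob = 0.001, jitter = 0.05,
                            n_traj = 10, frames = 1000, seed = 1,
                            cutoff = 0.02) {
  wells <- as_points_matrix(wells)
  if (nrow(wells) < 2) stop("need at least 2 wells")
  jp <- rep(jump_prob, length.out = n_traj)
  if (any(jp < 0 | jp >= 1)) stop("jump probabilities must be in [0, 1)")
  if (jitter < 0) stop("jitter must be non-negative")
  set.seed(seed)
  k <- nrow(wells)
  trajs <- vector("list", n_traj)
  labels <- vector("list", n_traj)
  for (t in seq_len(n_traj)) {
    w <- sample.int(k, 1)
    lab <- integer(frames)
    pts <- matrix(0, frames, 2)
    for (f in seq_len(frames)) {
      if (f > 1 && stats::runif(1) < jp[t]) {
        others <- setdiff(seq_len(k), w)
        w <- others[sample.int(length(others), 1)]
      }
      lab[f] <- w
      pts[f, ] <- wells[w, ] + stats::rnorm(2, 0, jitter)
    }
    trajs[[t]] <- pts
    labels[[t]] <- lab
  }
  bank <- new_bank(trajs, cutoff)
  attr(bank, "labels") <- labels
  bank
}
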