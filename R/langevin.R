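#' Langevin dynamics parameters
#'
#' Settings for the single-particle Langevin integrator
#' \deqn{m \ddot X = -\nabla V(X) - m\gamma \dot X + R(t),}
#' with Gaussian white noise \eqn{R(t)} obeying fluctuation-dissipation.
#' Units follow the MD convention: energies in kJ/mol-like units with
#' lengths in nm, masses in Da and times in ps (1 energy unit = 1 Da nm^2 /
#' ps^2); \code{dt} is given in femtoseconds for convenience.
#'
#' The default time step is 10 fs. The built-in surfaces have maximum
#' curvature about 4000 energy/nm^2 at the deepest well, so stability of any
#' explicit Langevin scheme requires roughly \eqn{\Delta t < 2/\omega_{max}
#' \approx 30} fs; 10 fs leaves a comfortable margin and matches the standard
#' Mueller-surface Langevin setup used with these temperature and friction
#' values.
#'
#' @param dt time step in fs.
#' @param friction friction coefficient gamma in 1/ps.
#' @param mass particle mass in Da.
#' @param temperature temperature in K.
#' @param kB Boltzmann constant in energy units per K (default kJ/mol/K).
#' @return An object of class \code{gn_ld_params}.
#' @export
ld_params <- function(dt = 10, friction = 100, mass = 1, temperature = 750,
                      kB = 0.008314462618) {
  vals <- c(dt = dt, friction = friction, mass = mass,
            temperature = temperature, kB = kB)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all Langevin parameters must be strictly positive")
  structure(as.list(vals), class = "gn_ld_params")
}

#' Trajectory container
#'
#' Ordered frames of 2-D points, with the global index of the first frame and
#' a provenance label.
#'
#' @param points n x 2 numeric matrix (or length-2 vector for one frame).
#' @param frame_offset global index of the first frame (0-based).
#' @param segment_id provenance label (optionally one per frame).
#' @return An object of class \code{gn_trajectory}.
#' @export
trajectory <- function(points, frame_offset = 0, segment_id = NA) {
  p <- as_points_matrix(points)
  if (nrow(p) < 1) stop("a trajectory needs at least one frame")
  colnames(p) <- c("x", "y")
  structure(list(points = p, frame_offset = frame_offset,
                 segment_id = segment_id),
            class = "gn_trajectory")
}

#' @export
print.gn_trajectory <- function(x, ...) {
  cat("<gn_trajectory: ", nrow(x$points), " frames, offset ", x$frame_offset,
      ">\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gn_trajectory <- function(x, ...) {
  data.frame(frame = x$frame_offset + seq_len(nrow(x$points)) - 1L,
             x = x$points[, 1], y = x$points[, 2])
}

#' Number of frames in a trajectory
#' @param traj a \code{gn_trajectory}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$points)

#' Simulate Langevin dynamics on a surface
#'
#' BAOAB splitting (half-kick, drift, friction + noise, drift, half-kick).
#' All noise comes from a counter-based stream keyed by \code{seed}, so
#' identical arguments give a bit-identical trajectory regardless of R's RNG
#' state. Unless \code{v0} is supplied, the initial velocity is
#' Maxwell-Boltzmann at the run temperature, drawn from the same stream.
#'
#' @param surface a \code{gn_surface}.
#' @param params a \code{gn_ld_params}.
#' @param start length-2 starting position; becomes frame 0.
#' @param n_frames number of frames (>= 1).
#' @param seed non-negative integer-valued seed (exact below 2^53).
#' @param v0 optional length-2 initial velocity.
#' @param frame_offset global index of the first frame.
#' @param segment_id provenance label.
#' @return A \code{gn_trajectory} with attribute \code{v_final}.
#' @export
ld_simulate <- function(surface, params, start, n_frames, seed, v0 = NULL,
                        frame_offset = 0, segment_id = NA) {
  stopifnot(inherits(surface, "gn_surface"), inherits(params, "gn_ld_params"),
            n_frames >= 1, length(start) == 2, all(is.finite(start)))
  res <- .ld_simulate_cpp(surface$terms, as.numeric(start), as.integer(n_frames),
                          params$dt * 1e-3, params$friction, params$mass,
                          params$temperature, params$kB, as.numeric(seed),
                          v0, sanity_box = 100)
  tr <- trajectory(res$points, frame_offset = frame_offset,
                   segment_id = segment_id)
  attr(tr, "v_final") <- res$v_final
  tr
}

#' One integrator step
#'
#' A single BAOAB update with explicitly supplied noise (two standard
#' normals). \code{\link{ld_simulate}} is the n-fold composition of this step
#' with stream-drawn noise.
#'
#' @param state list with \code{position} and \code{velocity} (length-2 each).
#' @param surface a \code{gn_surface}.
#' @param params a \code{gn_ld_params}.
#' @param noise length-2 standard-normal draw.
#' @return Updated state list.
#' @export
ld_step <- function(state, surface, params, noise) {
  stopifnot(all(is.finite(state$position)), all(is.finite(state$velocity)))
  .ld_step_cpp(surface$terms, as.numeric(state$position),
               as.numeric(state$velocity), as.numeric(noise),
               params$dt * 1e-3, params$friction, params$mass,
               params$temperature, params$kB)
}

#' The noise stream used by the integrator
#'
#' Standard-normal draws of the counter-based stream for a given seed. Frame
#' i (i >= 1) of \code{\link{ld_simulate}} consumes draws 2i and 2i+1; draws
#' 0 and 1 initialize the velocity.
#'
#' @param seed stream seed.
#' @param from index of the first draw.
#' @param n number of draws.
#' @return Numeric vector of standard normals.
#' @export
noise_stream <- function(seed, from, n) {
  .noise_normal_cpp(as.numeric(seed), as.numeric(from), as.integer(n))
}

#' Write a trajectory to CSV (columns frame, x, y)
#'
#' Floats are written with full round-trip precision (17 significant digits)
#' so re-reading reproduces the values exactly.
#'
#' @param traj a \code{gn_trajectory}.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  lines <- c("frame,x,y",
             sprintf("%d,%.17g,%.17g", df$frame, df$x, df$y))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory from CSV (columns frame, x, y)
#'
#' @param path input file.
#' @return A \code{gn_trajectory}.
#' @export
read_trajectory_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("failed to parse '", path, "': ", conditionMessage(e)))
  if (nrow(df) == 0) stop("failed to parse '", path, "': no data rows")
  if (!all(c("frame", "x", "y") %in% names(df)))
    stop("failed to parse '", path, "': need columns frame,x,y")
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  fr <- suppressWarnings(as.numeric(df$frame))
  bad <- is.na(x) | is.na(y) | is.na(fr)
  if (any(bad))
    stop("failed to parse '", path, "': malformed row ", which(bad)[1] + 1L)
  trajectory(cbind(x, y), frame_offset = fr[1])
}
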