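#' Gaussian term of a potential energy surface
#'
#' One term of a Gaussian-sum potential,
#' \deqn{A \exp\{a (x-x_0)^2 + b (x-x_0)(y-y_0) + c (y-y_0)^2\}.}
#' Wells have negative \code{A} with negative-definite quadratic form
#' (\code{a}, \code{c} < 0); positive \code{A} terms are hills or confining
#' walls.
#'
#' @param A amplitude (energy units); the term's value at its own center.
#' @param a,b,c quadratic-form coefficients (1/length^2).
#' @param x0,y0 center coordinates.
#' @return An object of class \code{gn_term}.
#' @export
gaussian_term <- function(A, a, b, c, x0, y0) {
  vals <- c(A = A, a = a, b = b, c = c, x0 = x0, y0 = y0)
  if (!all(is.finite(vals))) stop("all Gaussian term parameters must be finite")
  structure(as.list(vals), class = "gn_term")
}

#' Gaussian-sum potential energy surface
#'
#' @param terms list of \code{\link{gaussian_term}} objects (may be empty).
#' @param name label for the surface.
#' @return An object of class \code{gn_surface} holding the term matrix
#'   (columns \code{A, a, b, c, x0, y0}) and the name.
#' @export
potential_surface <- function(terms, name = "custom") {
  if (length(terms) == 0) {
    tm <- matrix(numeric(0), ncol = 6)
  } else {
    stopifnot(all(vapply(terms, inherits, logical(1), "gn_term")))
    tm <- do.call(rbind, lapply(terms, function(t) unlist(t)))
  }
  colnames(tm) <- c("A", "a", "b", "c", "x0", "y0")
  structure(list(terms = tm, name = name), class = "gn_surface")
}

#' @export
print.gn_surface <- function(x, ...) {
  cat("<gn_surface '", x$name, "': ", nrow(x$terms), " Gaussian terms>\n",
      sep = "")
  invisible(x)
}

#' The Mueller potential surface
#'
#' Four-Gaussian model surface with two deep wells and one shallow
#' intermediate well, widely used to benchmark path-finding and enhanced
#' sampling methods. Parameters: A = (-200, -100, -170, 15),
#' a = (-1, -1, -6.5, 0.7), b = (0, 0, 11, 0.5), c = (-10, -10, -6.5, 0.7),
#' centers (1,0), (0,0.5), (-0.5,1.5), (-1,1).
#'
#' @return A \code{gn_surface}.
#' @export
muller_surface <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.5)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  terms <- lapply(1:4, function(j) gaussian_term(A[j], a[j], b[j], cc[j], x0[j], y0[j]))
  potential_surface(terms, name = "muller")
}

#' The modified Mueller surface
#'
#' The Mueller surface plus a broad positive Gaussian hill
#' (A5 = 500, a5 = c5 = -0.1, b5 = 0, center (-0.56, 1.44)) placed over the
#' original deepest well. The hill removes the shallow intermediate well,
#' lifts the whole landscape, and leaves the lower-right well as the deepest
#' basin with two shallower metastable states (the residual upper-left well
#' and a rim well near (-1.73, 0.28)), so escaping the deep valley requires
#' navigating in more than one direction.
#'
#' @return A \code{gn_surface}.
#' @export
modified_muller_surface <- function() {
  base <- muller_surface()
  add <- gaussian_term(500, -0.1, 0, -0.1, -0.56, 1.44)
  tm <- rbind(base$terms, unlist(add))
  rownames(tm) <- NULL
  structure(list(terms = tm, name = "modified_muller"), class = "gn_surface")
}

as_points_matrix <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 2)
    p <- point
  } else {
    stopifnot(length(point) == 2)
    p <- matrix(point, ncol = 2)
  }
  if (!all(is.finite(p))) stop("points must be finite")
  p
}

#' Evaluate a potential surface
#'
#' @param surface a \code{gn_surface}.
#' @param point length-2 vector, or an n x 2 matrix of points.
#' @return Energy value(s); 0 for an empty term list.
#' @export
pes_evaluate <- function(surface, point) {
  stopifnot(inherits(surface, "gn_surface"))
  p <- as_points_matrix(point)
  if (nrow(surface$terms) == 0) return(rep(0, nrow(p)))
  .pes_eval_cpp(surface$terms, p)
}

#' Analytic gradient of a potential surface
#'
#' @inheritParams pes_evaluate
#' @return Length-2 gradient for a single point, or an n x 2 matrix.
#' @export
pes_gradient <- function(surface, point) {
  stopifnot(inherits(surface, "gn_surface"))
  p <- as_points_matrix(point)
  if (nrow(surface$terms) == 0) {
    g <- matrix(0, nrow(p), 2)
  } else {
    g <- .pes_grad_cpp(surface$terms, p)
  }
  if (!is.matrix(point) && length(point) == 2) g[1, ] else g
}

#' Analytic Hessian of a potential surface at a point
#'
#' @inheritParams pes_evaluate
#' @return 2 x 2 Hessian matrix.
#' @export
pes_hessian <- function(surface, point) {
  stopifnot(inherits(surface, "gn_surface"), length(point) == 2)
  tm <- surface$terms
  H <- matrix(0, 2, 2)
  for (j in seq_len(nrow(tm))) {
    dx <- point[1] - tm[j, "x0"]; dy <- point[2] - tm[j, "y0"]
    q <- tm[j, "a"] * dx^2 + tm[j, "b"] * dx * dy + tm[j, "c"] * dy^2
    e <- tm[j, "A"] * exp(q)
    qx <- 2 * tm[j, "a"] * dx + tm[j, "b"] * dy
    qy <- tm[j, "b"] * dx + 2 * tm[j, "c"] * dy
    H[1, 1] <- H[1, 1] + e * (2 * tm[j, "a"] + qx * qx)
    H[2, 2] <- H[2, 2] + e * (2 * tm[j, "c"] + qy * qy)
    H[1, 2] <- H[1, 2] + e * (tm[j, "b"] + qx * qy)
  }
  H[2, 1] <- H[1, 2]
  H
}

#' Default region of interest for the built-in surfaces
#'
#' The rectangle that contains a surface's three metastable minima, used as
#' the default search window for \code{\link{find_minima}} and the default
#' initialization-grid extent for SSIR experiments. The modified surface's
#' window extends further left than the base surface's because its third
#' (rim) well sits near (-1.73, 0.28).
#'
#' @param surface a \code{gn_surface}.
#' @return list with \code{xlim} and \code{ylim}, or NULL for custom surfaces.
#' @export
default_region <- function(surface) {
  switch(surface$name,
    muller = list(xlim = c(-1.6, 1.2), ylim = c(-0.4, 2.0)),
    modified_muller = list(xlim = c(-1.8, 1.2), ylim = c(-0.4, 2.0)),
    NULL)
}

#' Locate the minima of a surface by multi-start local minimization
#'
#' L-BFGS-B with the analytic gradient is started from every node of a
#' regular grid; converged points are kept when the gradient norm is below
#' \code{descent_tolerance}, the analytic Hessian is positive definite, and
#' the point lies inside the search window (with a small margin). Duplicates
#' closer than \code{merge_radius} are merged; minima are sorted by energy.
#'
#' @param surface a \code{gn_surface}.
#' @param xlim,ylim search window; default \code{\link{default_region}}.
#' @param spacing grid spacing between minimization starts.
#' @param merge_radius minima closer than this are considered identical.
#' @param descent_tolerance gradient-norm threshold for convergence.
#' @return An object of class \code{gn_wellset}: \code{minima} (k x 2 matrix),
#'   \code{energies} (ascending), the surface, and the tolerances used.
#' @export
find_minima <- function(surface, xlim = NULL, ylim = NULL, spacing = 0.2,
                        merge_radius = 0.05, descent_tolerance = 1e-5) {
  stopifnot(inherits(surface, "gn_surface"))
  if (is.null(xlim) || is.null(ylim)) {
    reg <- default_region(surface)
    if (is.null(reg)) {
      if (nrow(surface$terms) == 0) stop("empty surface has no minima")
      # fall back to the bounding box of the term centers, padded
      xlim <- range(surface$terms[, "x0"]) + c(-1, 1)
      ylim <- range(surface$terms[, "y0"]) + c(-1, 1)
    } else {
      xlim <- reg$xlim; ylim <- reg$ylim
    }
  }
  fn <- function(p) pes_evaluate(surface, p)
  gr <- function(p) pes_gradient(surface, p)
  starts <- expand.grid(x = seq(xlim[1], xlim[2], by = spacing),
                        y = seq(ylim[1], ylim[2], by = spacing))
  margin <- 0.3
  found <- list()
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), fn, gr, method = "L-BFGS-B",
                   control = list(factr = 10, pgtol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    p <- res$par
    if (p[1] < xlim[1] - margin || p[1] > xlim[2] + margin ||
        p[2] < ylim[1] - margin || p[2] > ylim[2] + margin) next
    if (sqrt(sum(pes_gradient(surface, p)^2)) >= descent_tolerance) next
    ev <- eigen(pes_hessian(surface, p), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) next
    found[[length(found) + 1]] <- c(p, res$value)
  }
  if (length(found) == 0) stop("no minimum converged from any grid start")
  cand <- do.call(rbind, found)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      for (j in (i + 1):nrow(cand)) {
        if (keep[j] &&
            sqrt(sum((cand[i, 1:2] - cand[j, 1:2])^2)) <= merge_radius)
          keep[j] <- FALSE
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  minima <- cand[, 1:2, drop = FALSE]
  colnames(minima) <- c("x", "y")
  structure(list(minima = minima, energies = cand[, 3], surface = surface,
                 descent_tolerance = descent_tolerance,
                 merge_radius = merge_radius),
            class = "gn_wellset")
}

#' @export
print.gn_wellset <- function(x, ...) {
  cat("<gn_wellset: ", nrow(x$minima), " minima of '", x$surface$name, "'>\n",
      sep = "")
  df <- data.frame(x = round(x$minima[, 1], 4), y = round(x$minima[, 2], 4),
                   energy = round(x$energies, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Divergence energy cap for a well set
#'
#' Points with energy more than \code{margin} above the surface's global
#' minimum are treated as lying in the divergent outer region: basin
#' assignment marks them unassigned and SSIR grids drop them. The margin is
#' relative to the global minimum so that the same criterion applies to
#' surfaces whose whole landscape is shifted (e.g. by an added hill).
#'
#' @param wells a \code{gn_wellset}.
#' @param margin energy above the global minimum.
#' @return Energy cap (scalar).
#' @export
energy_cap <- function(wells, margin = 450) {
  stopifnot(inherits(wells, "gn_wellset"))
  min(wells$energies) + margin
}

#' Assign a point to a basin of attraction
#'
#' Damped gradient descent from the point (displacement capped at
#' \code{step}) until the gradient norm falls below the well set's
#' \code{descent_tolerance} or the path comes within \code{snap_radius} of a
#' known minimum. The index (into \code{wells}, energy-ascending order) of
#' the reached minimum is returned; ties and ambiguity are resolved by
#' nearest minimum, lowest index first. Returns \code{NA} ("unassigned") if
#' the start lies above the divergence cap or descent ends far from every
#' known minimum.
#'
#' @param surface a \code{gn_surface}.
#' @param point length-2 numeric.
#' @param wells a \code{gn_wellset} for the same surface.
#' @param step maximum displacement per descent iteration.
#' @param max_iter iteration cap.
#' @param snap_radius early-assignment distance to a minimum.
#' @param assign_radius maximum distance from a minimum for assignment after
#'   convergence.
#' @param cap divergence energy cap; default \code{\link{energy_cap}(wells)}.
#' @return Integer basin index or \code{NA}.
#' @export
basin_of <- function(surface, point, wells, step = 1e-3, max_iter = 50000,
                     snap_radius = 0.02, assign_radius = 0.15, cap = NULL) {
  stopifnot(inherits(wells, "gn_wellset"), nrow(wells$minima) >= 1)
  if (is.null(cap)) cap <- energy_cap(wells)
  as.integer(.assign_basins_cpp(surface$terms, as_points_matrix(point),
                                wells$minima, step, 2e-4,
                                wells$descent_tolerance, max_iter,
                                snap_radius, assign_radius, cap,
                                memoize = FALSE)[1])
}

#' Assign every frame of a trajectory (or point set) to a basin
#'
#' Batch version of \code{\link{basin_of}}. Descent starts are quantized to a
#' 1e-3 grid and memoized, which is below the descent displacement scale and
#' makes repeated assignment of long trajectories cheap.
#'
#' @param surface a \code{gn_surface}.
#' @param points n x 2 matrix or a \code{gn_trajectory}.
#' @inheritParams basin_of
#' @return Integer vector of basin indices (NA = unassigned).
#' @export
assign_basins <- function(surface, points, wells, step = 1e-3,
                          max_iter = 50000, snap_radius = 0.02,
                          assign_radius = 0.15, cap = NULL) {
  stopifnot(inherits(wells, "gn_wellset"), nrow(wells$minima) >= 1)
  if (inherits(points, "gn_trajectory")) points <- points$points
  if (is.null(cap)) cap <- energy_cap(wells)
  .assign_basins_cpp(surface$terms, as_points_matrix(points), wells$minima,
                     step, 2e-4, wells$descent_tolerance, max_iter,
                     snap_radius, assign_radius, cap, memoize = TRUE)
}

#' Load a custom surface from a YAML config file
#'
#' The file holds a list under key \code{terms}, each entry with keys
#' \code{A, a, b, c, x0, y0}, and an optional \code{name}.
#'
#' @param path file path.
#' @return A \code{gn_surface}.
#' @export
surface_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$terms)) stop("config must contain a 'terms' list")
  terms <- lapply(cfg$terms, function(t)
    gaussian_term(t$A, t$a, t$b, t$c, t$x0, t$y0))
  potential_surface(terms, name = if (is.null(cfg$name)) "custom" else cfg$name)
}

#' Resolve a surface by name or config path
#'
#' @param spec "muller", "modified_muller", or a path to a YAML config.
#' @return A \code{gn_surface}.
#' @export
resolve_surface <- function(spec) {
  if (inherits(spec, "gn_surface")) return(spec)
  switch(spec,
    muller = muller_surface(),
    modified_muller = modified_muller_surface(),
    surface_from_config(spec))
}

#' Export a well set as JSON
#'
#' @param wells a \code{gn_wellset}.
#' @param path optional output file; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
wellset_json <- function(wells, path = NULL) {
  df <- data.frame(x = wells$minima[, 1], y = wells$minima[, 2],
                   energy = wells$energies)
  js <- jsonlite::toJSON(df, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
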