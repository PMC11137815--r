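#' Cross-section through a 2-D surface
#'
#' A line with an anchor and unit direction; trajectory points within
#' \code{half_width} of the line are projected onto it and binned over
#' \code{range}.
#'
#' @param anchor length-2 point on the line.
#' @param direction length-2 direction (normalized internally).
#' @param half_width capture distance from the line.
#' @param bins number of histogram bins (>= 2).
#' @param range c(lo, hi) signed positions along the line.
#' @return An object of class \code{gn_section}.
#' @export
cross_section <- function(anchor, direction, half_width = 0.1, bins = 50,
                          range = c(0, 1)) {
  stopifnot(length(anchor) == 2, length(direction) == 2, bins >= 2,
            range[1] < range[2], half_width > 0)
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  structure(list(anchor = as.numeric(anchor), direction = direction / nd,
                 half_width = half_width, bins = as.integer(bins),
                 range = as.numeric(range)),
            class = "gn_section")
}

#' Section through the two deepest wells of a surface
#'
#' Convenience constructor: the line from the deepest minimum through the
#' second-deepest, with the range padded beyond both wells.
#'
#' @param wells a \code{gn_wellset} with at least 2 minima.
#' @param pad extension beyond each well along the line.
#' @param half_width,bins see \code{\link{cross_section}}.
#' @return A \code{gn_section}.
#' @export
deep_wells_section <- function(wells, pad = 0.3, half_width = 0.1, bins = 50) {
  stopifnot(nrow(wells$minima) >= 2)
  a <- wells$minima[1, ]
  b <- wells$minima[2, ]
  d <- b - a
  cross_section(a, d, half_width = half_width, bins = bins,
                range = c(-pad, sqrt(sum(d^2)) + pad))
}

#' Project trajectory points onto a cross-section
#'
#' Signed distance along the section direction from the anchor, for every
#' frame within \code{half_width} of the (infinite) line; frame order is
#' preserved. May be empty.
#'
#' @param traj a \code{gn_trajectory} or n x 2 matrix.
#' @param cs a \code{gn_section}.
#' @return Numeric vector of positions along the line.
#' @export
project_section <- function(traj, cs) {
  if (inherits(traj, "gn_trajectory")) traj <- traj$points
  p <- as_points_matrix(traj)
  dx <- p[, 1] - cs$anchor[1]
  dy <- p[, 2] - cs$anchor[2]
  t_along <- dx * cs$direction[1] + dy * cs$direction[2]
  t_perp <- dx * (-cs$direction[2]) + dy * cs$direction[1]
  t_along[abs(t_perp) <= cs$half_width]
}

#' Histogram probabilities along a section
#'
#' Counts per bin over the section range, normalized to sum to 1; samples
#' outside the range are dropped.
#'
#' @param samples scalar positions along the line (from
#'   \code{\link{project_section}}).
#' @param cs a \code{gn_section}.
#' @return List with \code{bin_centers} and \code{probabilities}.
#' @export
histogram_probabilities <- function(samples, cs) {
  edges <- seq(cs$range[1], cs$range[2], length.out = cs$bins + 1)
  inr <- samples >= cs$range[1] & samples <= cs$range[2]
  if (!any(inr)) stop("no samples fall inside the section range")
  h <- graphics::hist(samples[inr], breaks = edges, plot = FALSE)
  list(bin_centers = h$mids, probabilities = h$counts / sum(h$counts))
}

#' Boltzmann inversion of occupancy probabilities
#'
#' Converts bin probabilities into energies via
#' \eqn{\epsilon_i = -k_B T \ln p_i}, then shifts so the lowest occupied-bin
#' energy equals the reference \code{E0}. Zero-probability bins are undefined
#' (NA). Multiplying all probabilities by a common factor leaves the result
#' unchanged.
#'
#' @param probabilities per-bin probabilities (at least one positive).
#' @param temperature temperature in K.
#' @param kB Boltzmann constant in energy units per K.
#' @param E0 reference energy assigned to the lowest occupied bin.
#' @return Numeric vector of energies (NA for empty bins).
#' @export
boltzmann_invert <- function(probabilities, temperature = 750,
                             kB = 0.008314462618, E0 = 0) {
  if (all(probabilities <= 0) || any(probabilities < 0) ||
      any(!is.finite(probabilities)))
    stop("probabilities must be non-negative with at least one positive entry")
  e <- ifelse(probabilities > 0, -kB * temperature * log(probabilities), NA)
  e - min(e, na.rm = TRUE) + E0
}

#' Reconstruct an energy profile from a trajectory
#'
#' Projects the trajectory onto a cross-section, histograms the positions and
#' Boltzmann-inverts the occupancies into an energy profile.
#'
#' @param traj a \code{gn_trajectory} or n x 2 matrix.
#' @param cs a \code{gn_section}.
#' @param temperature,kB see \code{\link{boltzmann_invert}}.
#' @param E0 reference energy for the lowest occupied bin; defaults to 0.
#' @return An object of class \code{gn_profile}: data.frame-like list with
#'   \code{bin_centers}, \code{probabilities}, \code{energies}, plus the
#'   temperature and \code{E0} used.
#' @export
reconstruct_profile <- function(traj, cs, temperature = 750,
                                kB = 0.008314462618, E0 = 0) {
  s <- project_section(traj, cs)
  h <- histogram_probabilities(s, cs)
  structure(list(bin_centers = h$bin_centers,
                 probabilities = h$probabilities,
                 energies = boltzmann_invert(h$probabilities, temperature, kB, E0),
                 temperature = temperature, E0 = E0,
                 section = cs),
            class = "gn_profile")
}

#' @export
print.gn_profile <- function(x, ...) {
  occ <- sum(x$probabilities > 0)
  cat(sprintf("<gn_profile: %d bins (%d occupied), T = %g K>\n",
              length(x$bin_centers), occ, x$temperature))
  invisible(x)
}

#' @export
as.data.frame.gn_profile <- function(x, ...) {
  data.frame(bin_center = x$bin_centers, probability = x$probabilities,
             energy = x$energies)
}

#' Write an energy profile as CSV (bin_center, probability, energy)
#'
#' Undefined (empty-bin) energies are written as empty fields.
#'
#' @param profile a \code{gn_profile}.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
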