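#' Potential of mean force from a height histogram (inverse Boltzmann)
#'
#' Converts an equilibrium probability density p(z) over the particle
#' height into an energy profile E(z) = -ln p(z) (in kT), shifted so the
#' minimum is zero, together with the force F(z) = -dE/dz from centered
#' finite differences (one-sided at the endpoints). Bins with zero
#' observed probability are assigned a finite capped energy of
#' `max(E observed) + zero_bin_penalty` so the force field stays finite.
#'
#' @param histogram Tibble with columns `z_nm` (uniform bin centers,
#'   ascending) and `density` (non-negative, integrating to 1), as
#'   produced by [summarize_z()] or [trajectory_to_distribution()].
#' @param temperature Temperature in K (stored for unit conversion only;
#'   energies are in kT).
#' @param zero_bin_penalty Energy (kT) added above the largest observed
#'   energy for empty bins.
#' @return An `energy_profile`: tibble with columns `z_nm`, `energy_kT`,
#'   `force_kT_per_nm`; attributes `temperature`, `bin_width`.
#' @export
invert_boltzmann <- function(histogram, temperature = 298,
                             zero_bin_penalty = 5) {
  stopifnot(is.data.frame(histogram),
            all(c("z_nm", "density") %in% names(histogram)))
  z <- histogram$z_nm
  p <- histogram$density
  if (length(z) < 2) stop("histogram must have more than one bin", call. = FALSE)
  if (any(p < 0)) stop("histogram density must be non-negative", call. = FALSE)
  if (all(p == 0)) stop("all-zero histogram", call. = FALSE)
  dz <- diff(z)
  if (any(abs(dz - dz[1]) > 1e-8 * dz[1])) {
    stop("histogram bins must be uniform", call. = FALSE)
  }
  dz <- dz[1]
  if (sum(p > 0) < 10) {
    stop("need at least 10 non-empty bins for a usable profile", call. = FALSE)
  }
  total <- sum(p) * dz
  if (abs(total - 1) > 0.01) {
    stop(sprintf("histogram integrates to %.4f, not 1", total), call. = FALSE)
  }

  e <- rep(NA_real_, length(p))
  e[p > 0] <- -log(p[p > 0])
  e <- e - min(e, na.rm = TRUE)
  e[is.na(e)] <- max(e, na.rm = TRUE) + zero_bin_penalty

  # F = -dE/dz, centered differences; one-sided at the endpoints
  n <- length(e)
  f <- numeric(n)
  f[1] <- -(e[2] - e[1]) / dz
  f[n] <- -(e[n] - e[n - 1]) / dz
  if (n > 2) {
    f[2:(n - 1)] <- -(e[3:n] - e[1:(n - 2)]) / (2 * dz)
  }

  out <- tibble::tibble(z_nm = z, energy_kT = e, force_kT_per_nm = f)
  attr(out, "temperature") <- temperature
  attr(out, "bin_width") <- dz
  class(out) <- c("energy_profile", class(out))
  out
}

#' Interpolated force from an energy profile
#'
#' Linear interpolation of the per-bin force. Below the first bin center
#' the profile is treated as a hard reflecting wall: the first bin's force
#' is returned and the dynamics integrator additionally reflects at z = 0.
#' Above the last bin the force is continued linearly from the last two
#' bins.
#'
#' @param profile An [invert_boltzmann()] profile.
#' @param z Height(s) in nm.
#' @return Force in kT/nm, same length as `z`.
#' @export
force_at <- function(profile, z) {
  stopifnot(inherits(profile, "energy_profile"))
  if (any(is.na(z))) stop("NaN/NA z", call. = FALSE)
  zb <- profile$z_nm
  fb <- profile$force_kT_per_nm
  n <- length(zb)
  out <- stats::approx(zb, fb, xout = z, rule = 1)$y
  below <- z < zb[1]
  out[below] <- fb[1]
  above <- z > zb[n]
  if (any(above)) {
    slope <- (fb[n] - fb[n - 1]) / (zb[n] - zb[n - 1])
    out[above] <- fb[n] + slope * (z[above] - zb[n])
  }
  out
}

#' Equilibrium density implied by an energy profile
#'
#' Boltzmann re-weighting: normalize(exp(-E)) on the profile's bins.
#' Inverse of [invert_boltzmann()] up to the empty-bin energy cap.
#'
#' @param profile An `energy_profile`.
#' @return Tibble with `z_nm`, `density` (integrates to 1).
#' @export
profile_density <- function(profile) {
  stopifnot(inherits(profile, "energy_profile"))
  dz <- attr(profile, "bin_width")
  p <- exp(-profile$energy_kT)
  p <- p / (sum(p) * dz)
  tibble::tibble(z_nm = profile$z_nm, density = p)
}
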