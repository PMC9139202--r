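#' Microfluidic chip channel specification
#'
#' Geometry and working fluid of the parallel-plate culture channel. Defaults
#' follow a 56 x 1.2 x 0.1 mm PDMS channel perfused with culture medium,
#' whose viscosity is taken as that of water at 37 degrees C (about
#' 7e-4 Pa s). The wide-shallow assumption h <= w underlies the
#' parallel-plate shear formula; the density enters only the laminarity
#' check.
#'
#' @param length channel length, m.
#' @param width channel width w, m.
#' @param height channel height h, m.
#' @param viscosity dynamic viscosity mu, Pa s.
#' @param density fluid density, kg/m^3 (water at 37 C).
#' @return a list of class `chip_spec`.
#' @export
chip_spec <- function(length = 56e-3, width = 1.2e-3, height = 0.1e-3,
                      viscosity = 7e-4, density = 993) {
  vals <- c(length, width, height, viscosity, density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort_aneuflow("all chip_spec fields must be positive", "aneuflow_domain_error")
  if (height > width)
    abort_aneuflow("chip_spec requires h <= w (wide shallow channel)",
                   "aneuflow_domain_error")
  structure(list(length = length, width = width, height = height,
                 viscosity = viscosity, density = density),
            class = "chip_spec")
}

#' @export
print.chip_spec <- function(x, ...) {
  cat(sprintf("<chip_spec> %.3g x %.3g x %.3g mm, mu = %.3g Pa s\n",
              x$length * 1e3, x$width * 1e3, x$height * 1e3, x$viscosity))
  invisible(x)
}

#' Wall shear rate from volumetric flow rate
#'
#' Parallel-plate approximation \eqn{\gamma = 6 Q / (h^2 w)} for a wide
#' shallow rectangular channel.
#'
#' @param Q volumetric flow rate, m^3/s (>= 0).
#' @param chip a [chip_spec()].
#' @return shear rate in 1/s.
#' @export
shear_rate_from_flow <- function(Q, chip = chip_spec()) {
  if (any(Q < 0)) abort_aneuflow("Q must be >= 0", "aneuflow_domain_error")
  6 * Q / (chip$height^2 * chip$width)
}

#' Wall shear stress from volumetric flow rate
#'
#' \eqn{\tau = \mu \gamma = 6 \mu Q / (h^2 w)}. With the default chip,
#' Q = 4.33e-9 m^3/s gives 1.5 Pa (2 s.f.).
#'
#' @inheritParams shear_rate_from_flow
#' @return shear stress in Pa.
#' @export
shear_stress_from_flow <- function(Q, chip = chip_spec()) {
  chip$viscosity * shear_rate_from_flow(Q, chip)
}

#' Volumetric flow rate for a target wall shear stress
#'
#' Algebraic inverse \eqn{Q = \tau h^2 w / (6 \mu)}; exact round trip with
#' [shear_stress_from_flow()].
#'
#' @param tau target shear stress, Pa (>= 0).
#' @param chip a [chip_spec()].
#' @return flow rate in m^3/s.
#' @export
flow_for_target_shear <- function(tau, chip = chip_spec()) {
  if (any(tau < 0)) abort_aneuflow("tau must be >= 0", "aneuflow_domain_error")
  tau * chip$height^2 * chip$width / (6 * chip$viscosity)
}

#' Channel Reynolds number at a given flow rate
#'
#' Bulk velocity Q/(h w) with the hydraulic diameter 2hw/(h+w).
#'
#' @inheritParams shear_rate_from_flow
#' @return dimensionless Reynolds number of the chip channel.
#' @export
chip_reynolds <- function(Q, chip = chip_spec()) {
  U <- Q / (chip$height * chip$width)
  Dh <- 2 * chip$height * chip$width / (chip$height + chip$width)
  chip$density * U * Dh / chip$viscosity
}

#' Build a chip operating point for a target shear stress
#'
#' The (tau, gamma, Q) triple for one culture condition, with laminarity and
#' aspect-ratio warnings attached.
#'
#' @param tau target wall shear stress, Pa.
#' @param chip a [chip_spec()].
#' @return an object of class `operating_point` with fields `tau`, `gamma`,
#'   `Q`, `Q_uL_min` (1 m^3/s = 6e10 uL/min exactly), `reynolds_chip`,
#'   `chip` and `warnings`.
#' @export
operating_point <- function(tau, chip = chip_spec()) {
  gamma <- tau / chip$viscosity          # tau = gamma mu by construction
  Q <- gamma * chip$height^2 * chip$width / 6
  re <- chip_reynolds(Q, chip)
  warn <- character(0)
  if (re >= 2000)
    warn <- c(warn, sprintf("chip Reynolds number %.3g >= 2000: flow may not be laminar", re))
  if (chip$height / chip$width > 0.25)
    warn <- c(warn, sprintf(
      "aspect ratio h/w = %.3g > 0.25: parallel-plate formula error grows beyond ~10%%",
      chip$height / chip$width))
  structure(list(tau = tau, gamma = gamma, Q = Q, Q_uL_min = Q * 6e10,
                 reynolds_chip = re, chip = chip, warnings = warn),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> tau = %.4g Pa, gamma = %.4g 1/s, Q = %.4g m^3/s (%.4g uL/min), Re_chip = %.3g\n",
              x$tau, x$gamma, x$Q, x$Q_uL_min, x$reynolds_chip))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Check a (tau, Q) pair for internal consistency
#'
#' Evaluates the parallel-plate formula at Q and warns when the implied
#' stress disagrees with the stated tau by more than `tol` (relative).
#' Published operating pairs are occasionally inconsistent with the very
#' formula printed beside them (e.g. a stated 0.03 Pa at 8.67e-10 m^3/s in a
#' 56 x 1.2 x 0.1 mm channel, where the formula yields 0.30 Pa - a factor of
#' exactly 10); such pairs are surfaced, never silently corrected.
#'
#' @param tau stated shear stress, Pa.
#' @param Q stated flow rate, m^3/s.
#' @param chip a [chip_spec()].
#' @param tol relative disagreement triggering the warning (default 0.05).
#' @return the implied stress (invisibly); warns on disagreement.
#' @export
check_operating_pair <- function(tau, Q, chip = chip_spec(), tol = 0.05) {
  implied <- shear_stress_from_flow(Q, chip)
  if (abs(implied - tau) > tol * max(tau, implied))
    warning(sprintf(
      "stated tau = %.3g Pa disagrees with the parallel-plate value %.3g Pa at Q = %.3g m^3/s (factor %.3g)",
      tau, implied, Q, implied / tau))
  invisible(implied)
}

#' Map shear sites to chip operating points
#'
#' One operating point per site, using the site's representative (median)
#' dimensional stress. Sites must carry Pa values, i.e. the WSS field must
#' have been computed with a dimensional scaling.
#'
#' @param sites a [find_extreme_sites()] object whose fields carry `tau_Pa`.
#' @param chip a [chip_spec()].
#' @return a list of records `list(site_kind, site_rank, tau_Pa, point)`.
#' @export
map_sites <- function(sites, chip = chip_spec()) {
  all_sites <- c(lapply(sites$low_sites, function(s) c(s, kind = "low")),
                 lapply(sites$high_sites, function(s) c(s, kind = "high")))
  if (length(all_sites) == 0L)
    abort_aneuflow("no sites to map", "aneuflow_usage_error")
  if (is.null(all_sites[[1]]$tau_median_Pa))
    abort_aneuflow(
      "sites lack dimensional stresses; recompute the WSS field with a `scaling` (rho, nu, U, D)",
      "aneuflow_usage_error")
  rank_counter <- c(low = 0L, high = 0L)
  lapply(all_sites, function(s) {
    rank_counter[s$kind] <<- rank_counter[s$kind] + 1L
    list(site_kind = s$kind, site_rank = unname(rank_counter[s$kind]),
         tau_Pa = s$tau_median_Pa, centroid = s$centroid,
         n_faces = s$n_faces, point = operating_point(s$tau_median_Pa, chip))
  })
}

#' Tabulate mapped operating points
#' @param mapped result of [map_sites()].
#' @return a data frame (site, tau_Pa, gamma_per_s, Q_m3_per_s, Q_uL_per_min,
#'   Re_chip, warnings).
#' @export
operating_table <- function(mapped) {
  do.call(rbind, lapply(mapped, function(r) {
    data.frame(site = sprintf("%s_%d", r$site_kind, r$site_rank),
               tau_Pa = r$point$tau, gamma_per_s = r$point$gamma,
               Q_m3_per_s = r$point$Q, Q_uL_per_min = r$point$Q_uL_min,
               Re_chip = r$point$reynolds_chip,
               warnings = paste(r$point$warnings, collapse = "; "))
  }))
}
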