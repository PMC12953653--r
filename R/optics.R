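#' Electrowetting liquid-lens parameters
#'
#' Bundles the physical constants of an electrowetting liquid lens that enter
#' the Young-Lippmann focal-length relation: the focal length is set by the
#' curvature of the liquid-liquid interface, which the applied voltage
#' controls through the contact angle.
#'
#' @param aperture_D effective aperture of the lens (m)
#' @param n_conductive,n_nonconductive refractive indices of the conductive
#'   and non-conductive liquids (both > 1 and distinct)
#' @param theta0 contact angle at zero applied voltage (rad)
#' @param eps_rel relative dielectric constant of the insulating layer
#' @param eps0 vacuum permittivity (F/m)
#' @param thickness_H dielectric-layer thickness (m)
#' @param tension_gamma liquid-liquid interfacial tension (N/m)
#' @return an object of class `liquid_lens`
#' @examples
#' lens <- liquid_lens(aperture_D = 5.8e-3, n_conductive = 1.38,
#'                     n_nonconductive = 1.58, theta0 = 2 * pi / 3)
#' focal_length(lens, voltage = 30)
#' @export
liquid_lens <- function(aperture_D = 5.8e-3,
                        n_conductive = 1.38,
                        n_nonconductive = 1.58,
                        theta0 = 2 * pi / 3,
                        eps_rel = 70,
                        eps0 = 8.8541878128e-12,
                        thickness_H = 3e-6,
                        tension_gamma = 0.04) {
  stopifnot(aperture_D > 0, thickness_H > 0, tension_gamma > 0,
            n_conductive > 1, n_nonconductive > 1, eps_rel > 0, eps0 > 0)
  if (n_conductive == n_nonconductive)
    stop("the two liquids must have distinct refractive indices")
  structure(list(aperture_D = aperture_D, n_conductive = n_conductive,
                 n_nonconductive = n_nonconductive, theta0 = theta0,
                 eps_rel = eps_rel, eps0 = eps0, thickness_H = thickness_H,
                 tension_gamma = tension_gamma),
            class = "liquid_lens")
}

#' Focal length of an electrowetting liquid lens at a given voltage
#'
#' Young-Lippmann relation: `f = -D (n_c - n_n) / [cos(theta0) +
#' eps eps0 U^2 / (2 H gamma)]`. The optical power 1/f is affine in the
#' squared voltage, which is what makes voltage-driven continuous zooming
#' possible.
#'
#' @param lens a [liquid_lens()]
#' @param voltage applied voltage U (V), non-negative
#' @return focal length in metres (signed)
#' @seealso [optical_power()]
#' @export
focal_length <- function(lens, voltage) {
  stopifnot(inherits(lens, "liquid_lens"), all(voltage >= 0))
  denom <- cos(lens$theta0) +
    lens$eps_rel * lens$eps0 * voltage^2 / (2 * lens$thickness_H * lens$tension_gamma)
  if (any(abs(denom) < 1e-15)) {
    u0 <- voltage[which.min(abs(denom))]
    stop(sprintf("singular focus: optical power is zero at U = %.6g V", u0))
  }
  -lens$aperture_D * (lens$n_conductive - lens$n_nonconductive) / denom
}

#' Optical power (1/f) of the liquid lens, in diopters
#' @inheritParams focal_length
#' @return optical power in D (m^-1)
#' @export
optical_power <- function(lens, voltage) 1 / focal_length(lens, voltage)

#' Two-group zoom configuration
#'
#' Holds the optical powers of the front and rear zoom groups together with
#' the fixed working distance and group separation of the relay-based zoom
#' model. The relay-plane offset is carried as metadata only: it modulates
#' the aberration schedule of the PSF simulator, not the paraxial
#' magnification (working distance and group separation stay constant while
#' zooming).
#'
#' @param power_front,power_rear optical powers of the front and rear zoom
#'   groups (D, i.e. m^-1)
#' @param working_distance_u working distance of the system (m), > 0
#' @param separation_d distance between the group centers (m), > 0
#' @param relay_offset signed shift of the relay image plane (m); metadata
#' @return an object of class `zoom_config`
#' @examples
#' cfg <- zoom_config(power_front = 10, power_rear = 20,
#'                    working_distance_u = 0.05, separation_d = 0.1)
#' system_magnification(cfg)  # 3
#' @export
zoom_config <- function(power_front, power_rear,
                        working_distance_u = 0.05, separation_d = 0.174,
                        relay_offset = 0) {
  stopifnot(working_distance_u > 0, separation_d > 0)
  structure(list(power_front = power_front, power_rear = power_rear,
                 working_distance_u = working_distance_u,
                 separation_d = separation_d, relay_offset = relay_offset),
            class = "zoom_config")
}

#' Overall magnification of the two-group zoom system
#'
#' `beta = (1 - Phi_f u)^-1 * [1 + Phi_c (Phi_f + 1/u)^-1 - Phi_f d]^-1`
#' with `Phi_f`, `Phi_c` the front/rear group powers, `u` the working
#' distance and `d` the group separation.
#'
#' @param config a [zoom_config()]
#' @return the dimensionless system magnification
#' @export
system_magnification <- function(config) {
  stopifnot(inherits(config, "zoom_config"))
  u <- config$working_distance_u; d <- config$separation_d
  pf <- config$power_front; pc <- config$power_rear
  t1 <- 1 - pf * u
  if (abs(t1) < 1e-12)
    stop("singular configuration: front factor 1 - Phi_f*u is zero")
  t2 <- pf + 1 / u
  if (abs(t2) < 1e-12)
    stop("singular configuration: Phi_f + 1/u is zero")
  t3 <- 1 + pc / t2 - pf * d
  if (abs(t3) < 1e-12)
    stop("singular configuration: rear bracket factor is zero")
  (1 / t1) * (1 / t3)
}

# Front-power split schedule: the two-group model under-determines the pair
# (Phi_f, Phi_c) for a target magnification, so the front power ramps
# linearly in log(beta) across its share of the feasible band while the rear
# power is solved for.
front_power_schedule <- function(beta, beta_range = c(1, 120),
                                 front_range = c(5, 6.5)) {
  lb <- log(pmin(pmax(beta, beta_range[1]), beta_range[2]) / beta_range[1])
  frac <- lb / log(beta_range[2] / beta_range[1])
  front_range[1] + frac * (front_range[2] - front_range[1])
}

#' Solve the rear-group power for a target magnification
#'
#' Inverts the two-group magnification equation for the rear power
#' `Phi_c` by bracketed scalar root finding, with the front power fixed by
#' a split schedule that ramps linearly in `log(beta)`. Deterministic given
#' the template.
#'
#' @param target_beta desired system magnification
#' @param config_template a [zoom_config()] supplying `u`, `d`,
#'   `relay_offset`, and (if `fix_front = TRUE`) the front power
#' @param power_bounds feasible optical-power interval for the rear group
#'   (D); default -5 to 10 per the tunable range of the liquid lenses
#' @param fix_front keep the template's front power instead of the schedule
#' @return a [zoom_config()] whose [system_magnification()] equals
#'   `target_beta` to within 1e-6 relative
#' @export
solve_powers <- function(target_beta, config_template = zoom_config(0, 0),
                         power_bounds = c(-5, 10), fix_front = FALSE) {
  stopifnot(inherits(config_template, "zoom_config"), target_beta > 0)
  pf <- if (fix_front) config_template$power_front
        else front_power_schedule(target_beta)
  f <- function(pc) {
    cfg <- zoom_config(pf, pc, config_template$working_distance_u,
                       config_template$separation_d,
                       config_template$relay_offset)
    tryCatch(system_magnification(cfg) - target_beta,
             error = function(e) NA_real_)
  }
  lo <- power_bounds[1]; hi <- power_bounds[2]
  # The rear bracket factor has a pole in Phi_c, so sign changes on a scan
  # can be either roots or poles; try each bracketing interval and keep the
  # first root that reproduces the target magnification.
  grid <- seq(lo, hi, length.out = 401)
  vals <- vapply(grid, f, numeric(1))
  ok <- which(is.finite(vals))
  flips <- ok[which(diff(sign(vals[ok])) != 0 &
                    diff(ok) == 1L)]
  for (i in flips) {
    root <- tryCatch(
      stats::uniroot(function(p) {
        v <- f(p); if (!is.finite(v)) .Machine$double.xmax else v
      }, c(grid[i], grid[i + 1L]), tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (is.finite(root)) {
      v <- f(root)
      if (is.finite(v) && abs(v) <= 1e-6 * max(1, target_beta))
        return(zoom_config(pf, root, config_template$working_distance_u,
                           config_template$separation_d,
                           config_template$relay_offset))
    }
  }
  achievable <- range(vals[ok] + target_beta)
  stop(sprintf(paste0("infeasible magnification: target %.4g not reachable; ",
                      "achievable magnifications span [%.4g, %.4g] for rear ",
                      "power in [%g, %g] D"),
               target_beta, achievable[1], achievable[2], lo, hi))
}

#' Geometric ladder of zoom configurations across a magnification range
#'
#' Discretizes `[beta_min, beta_max]` into `n_levels` geometrically spaced
#' magnifications (endpoints exact) and solves each level's group powers.
#'
#' @param beta_min,beta_max magnification endpoints, `beta_min < beta_max`
#' @param n_levels number of zoom levels (>= 2)
#' @param config_template template passed to [solve_powers()]
#' @param power_bounds rear-power bounds passed to [solve_powers()]
#' @return list of [zoom_config()], one per level, with attribute `betas`
#' @export
magnification_grid <- function(beta_min, beta_max, n_levels,
                               config_template = zoom_config(0, 0),
                               power_bounds = c(-5, 10)) {
  if (!(beta_min < beta_max)) stop("beta_min must be less than beta_max")
  stopifnot(n_levels >= 2)
  betas <- exp(seq(log(beta_min), log(beta_max), length.out = n_levels))
  betas[1] <- beta_min; betas[n_levels] <- beta_max
  cfgs <- lapply(betas, solve_powers, config_template = config_template,
                 power_bounds = power_bounds)
  attr(cfgs, "betas") <- betas
  cfgs
}

#' Zoom table of magnifications and group powers
#'
#' @inheritParams magnification_grid
#' @return a tibble with columns `beta`, `power_front`, `power_rear`
#' @export
zoom_table <- function(beta_min, beta_max, n_levels,
                       config_template = zoom_config(0, 0),
                       power_bounds = c(-5, 10)) {
  cfgs <- magnification_grid(beta_min, beta_max, n_levels,
                             config_template, power_bounds)
  tibble::tibble(
    beta = attr(cfgs, "betas"),
    power_front = vapply(cfgs, `[[`, numeric(1), "power_front"),
    power_rear = vapply(cfgs, `[[`, numeric(1), "power_rear"))
}
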