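#' Flat-plate reactor light configuration
#'
#' Geometry and optics used to convert incident photon flux into the average
#' light intensity the kinetics consume. `mode = "incident"` bypasses the
#' attenuation model and feeds the incident flux straight through as I_av,
#' which is how single-factor experiments quoting I_av directly are
#' represented.
#'
#' @param light_path Flat-plate depth, m.
#' @param k_a Biomass-specific attenuation coefficient in (g/L)-1 m-1, i.e.
#'   the optical depth is `k_a * X * light_path` with X in g/L.
#' @param mode `"beer_lambert"` (depth-averaged attenuation) or
#'   `"incident"` (I_av equals the incident flux).
#' @return An object of class `reactor_config`.
#' @export
reactor_config <- function(light_path = 0.05, k_a = 0.2,
                           mode = c("beer_lambert", "incident")) {
  mode <- match.arg(mode)
  if (light_path <= 0) stop("reactor_config: light_path must be > 0")
  if (k_a < 0) stop("reactor_config: k_a must be >= 0")
  structure(list(light_path = light_path, k_a = k_a, mode = mode),
            class = "reactor_config")
}

#' Depth-averaged light intensity in a flat plate
#'
#' Beer-Lambert average over the light path:
#' `I_av = I_0 (1 - exp(-k_a X L)) / (k_a X L)`, with the continuous limit
#' `I_av -> I_0` as the optical depth goes to zero. In `"incident"` mode the
#' incident flux is returned unchanged.
#'
#' @param I_0 Incident photon flux density, umol photons m-2 s-1 (>= 0).
#' @param X Biomass dry weight, g/L (>= 0). Vectorized.
#' @param reactor A [reactor_config()].
#' @return I_av, umol photons m-2 s-1.
#' @export
average_light_intensity <- function(I_0, X, reactor = reactor_config()) {
  if (any(I_0 < 0)) stop("average_light_intensity: I_0 must be >= 0")
  if (any(X < 0)) stop("average_light_intensity: X must be >= 0")
  if (reactor$mode == "incident") return(I_0 + 0 * X)
  tau <- reactor$k_a * X * reactor$light_path
  ifelse(tau < 1e-12, I_0, I_0 * (1 - exp(-tau)) / ifelse(tau > 0, tau, 1))
}

#' Incident irradiance under a square-wave photoperiod
#'
#' Dawn is t = 0: each 24 h cycle starts with the light phase. A 24:0
#' photoperiod gives constant light.
#'
#' @param t Time since inoculation, h (>= 0). Vectorized.
#' @param photoperiod Length-2 numeric, light and dark hours summing to 24.
#' @param I_0 Incident flux during the light phase.
#' @return I_0(t): `I_0` in the light phase, 0 in the dark.
#' @export
irradiance_at_time <- function(t, photoperiod, I_0) {
  check_photoperiod(photoperiod)
  if (any(t < 0)) stop("irradiance_at_time: t must be >= 0")
  ifelse(t %% 24 < photoperiod[1], I_0, 0)
}

#' Attenuation coefficient from a transmission measurement
#'
#' Inverts Beer-Lambert for the attenuation coefficient given incident and
#' transmitted photon flux across a known light path at a known biomass:
#' `k_a = ln(I_0 / I_t) / (X L)`.
#'
#' @param I_0 Incident flux (> 0).
#' @param I_transmitted Transmitted flux, in (0, I_0].
#' @param X Biomass dry weight, g/L (> 0).
#' @param light_path Light path, m (> 0).
#' @return k_a in (g/L)-1 m-1.
#' @export
attenuation_from_transmission <- function(I_0, I_transmitted, X, light_path) {
  if (I_0 <= 0 || I_transmitted <= 0 || X <= 0 || light_path <= 0)
    stop("attenuation_from_transmission: all inputs must be strictly positive")
  if (I_transmitted > I_0)
    stop("attenuation_from_transmission: transmitted flux exceeds incident flux")
  log(I_0 / I_transmitted) / (X * light_path)
}

check_photoperiod <- function(photoperiod) {
  if (length(photoperiod) != 2L || any(photoperiod < 0) ||
      abs(sum(photoperiod) - 24) > 1e-9)
    stop("photoperiod must be two non-negative hour counts summing to 24, got [",
         paste(photoperiod, collapse = ", "), "]")
  invisible(TRUE)
}
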