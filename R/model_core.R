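#' Instantaneous culture conditions
#'
#' Environment vector consumed by the kinetic rate laws. Temperature is given
#' in degrees Celsius and converted to Kelvin inside the Arrhenius
#' exponentials.
#'
#' @param temperature Culture temperature, degrees C. Guard band [-20, 60].
#' @param I_av Average light intensity, umol photons m-2 s-1 (>= 0).
#' @param nitrogen Nitrate concentration, mg/L.
#' @param carbon Inorganic carbon concentration, mM.
#' @return An object of class `culture_env`.
#' @export
culture_env <- function(temperature = 25, I_av = 600, nitrogen = 500,
                        carbon = 50) {
  if (temperature < -20 || temperature > 60)
    stop("culture_env: temperature ", temperature,
         " C is outside the [-20, 60] C guard band")
  if (I_av < 0) stop("culture_env: I_av must be >= 0")
  if (nitrogen < 0) stop("culture_env: nitrogen must be >= 0")
  if (carbon < 0) stop("culture_env: carbon must be >= 0")
  structure(list(temperature = temperature, I_av = I_av,
                 nitrogen = nitrogen, carbon = carbon),
            class = "culture_env")
}

#' Culture state vector
#'
#' @param X Biomass dry weight, g/L (>= 0).
#' @param W Beta-carotene content as a mass fraction of dry weight.
#' @return An object of class `culture_state`.
#' @export
culture_state <- function(X, W) {
  if (X < 0) stop("culture_state: X must be >= 0")
  if (W < 0) stop("culture_state: W must be >= 0")
  structure(list(X = X, W = W), class = "culture_state")
}

#' Double-Arrhenius temperature factor
#'
#' `f(T) = A exp(-E_a / (R T)) - B exp(-E_b / (R T))`: an activation term
#' minus a thermal-inactivation term. The difference may be negative at
#' extreme temperatures; the raw value is returned and the caller (the
#' simulator) decides the clipping policy.
#'
#' @param T_K Absolute temperature, K. Vectorized.
#' @param A,B Pre-exponential coefficients.
#' @param E_a,E_b Activation/inactivation energies, kJ/mol.
#' @param R Gas constant, kJ mol-1 K-1.
#' @return Dimensionless factor, same length as `T_K`.
#' @export
temperature_factor <- function(T_K, A, B, E_a, E_b, R = R_GAS) {
  if (any(T_K <= 0)) stop("temperature_factor: absolute temperature must be > 0 K")
  stopifnot(all(is.finite(c(A, B, E_a, E_b, R))))
  A * exp(-E_a / (R * T_K)) - B * exp(-E_b / (R * T_K))
}

#' Aiba light-response factor
#'
#' `I / (I + K_s + I^2 / K_i)`: saturating at low light, inhibited at high
#' light. Unimodal in `I` with its maximum at `sqrt(K_s * K_i)`, where it
#' equals `1 / (1 + 2 sqrt(K_s / K_i))`.
#'
#' @param I_av Average light intensity, umol photons m-2 s-1 (>= 0).
#'   Vectorized.
#' @param K_s Saturation constant.
#' @param K_i Photoinhibition constant.
#' @return Dimensionless factor in [0, 1).
#' @export
light_factor <- function(I_av, K_s, K_i) {
  if (any(I_av < 0)) stop("light_factor: I_av must be >= 0")
  stopifnot(K_s > 0, K_i > 0)
  I_av / (I_av + K_s + I_av^2 / K_i)
}

#' Monod substrate-limitation factor
#'
#' `S / (K + S)`; 0.5 at `S = K`, approaching 1 as `S` grows.
#'
#' @param S Substrate concentration (>= 0). Vectorized.
#' @param K Half-velocity constant (> 0).
#' @return Dimensionless factor in [0, 1).
#' @export
substrate_factor <- function(S, K) {
  if (any(S < 0)) stop("substrate_factor: S must be >= 0")
  stopifnot(K > 0)
  S / (K + S)
}

#' Specific growth rate under co-limitation
#'
#' Product of the maximum specific growth rate, the double-Arrhenius
#' temperature factor, the Aiba light factor and Monod factors for carbon and
#' nitrate. `mu_max` is a constant scalar; the co-limiting conditions enter
#' only through the factors.
#'
#' @param env A [culture_env()].
#' @param p A [parameter_set()].
#' @return mu_0 in 1/h (may be negative if the temperature factor is).
#' @export
specific_growth_rate <- function(env, p) {
  stopifnot(inherits(env, "culture_env"), inherits(p, "parameter_set"))
  g <- p$growth
  T_K <- env$temperature + 273.15
  g$mu_max *
    temperature_factor(T_K, g$A, g$B, g$E_a, g$E_b, p$R) *
    light_factor(env$I_av, g$K_s, g$K_i) *
    substrate_factor(env$carbon, g$K_C) *
    substrate_factor(env$nitrogen, g$K_N)
}

#' Biomass net rate of change
#'
#' `dX/dt = mu_0 X - mu_d X^2`: exponential growth minus a quadratic
#' respiration/decay term. Roots at `X = 0` and `X = mu_0 / mu_d`.
#'
#' @param X Biomass dry weight, g/L (>= 0). Vectorized.
#' @param mu0 Specific growth rate, 1/h.
#' @param mu_d Decay coefficient.
#' @return dX/dt in g L-1 h-1.
#' @export
biomass_rate <- function(X, mu0, mu_d) {
  if (any(X < 0)) stop("biomass_rate: X must be >= 0")
  mu0 * X - mu_d * X^2
}

#' Beta-carotene content rate of change
#'
#' Evaluates the accumulation rate law exactly as a single product:
#' a nitrogen prefactor `[b + (1 - K_NW/N)] * (K_NW/N)`, a carbon prefactor
#' `(1 - K_CW/C) * (K_CW/C)`, the logistic ceiling `(1 - W/w_max)`, an Aiba
#' light factor with the carotene constants, and a double-Arrhenius
#' temperature factor. The result can be negative (net consumption), e.g.
#' when carbon is below `K_CW`.
#'
#' @param state A [culture_state()] (only `W` enters the rate).
#' @param env A [culture_env()]; requires strictly positive nitrogen and
#'   carbon (both appear in denominators).
#' @param p A [parameter_set()].
#' @return dW/dt in fraction-of-DW per hour.
#' @export
carotene_rate <- function(state, env, p) {
  stopifnot(inherits(state, "culture_state"), inherits(env, "culture_env"),
            inherits(p, "parameter_set"))
  w <- p$carotene
  if (env$nitrogen <= 0 || env$carbon <= 0)
    stop("carotene_rate: nitrogen and carbon must be > 0 (they divide the rate law)")
  if (state$W > w$w_max)
    stop("carotene_rate: W exceeds w_max")
  T_K <- env$temperature + 273.15
  (w$b + (1 - w$K_NW / env$nitrogen)) * (w$K_NW / env$nitrogen) *
    (1 - w$K_CW / env$carbon) * (w$K_CW / env$carbon) *
    (1 - state$W / w$w_max) *
    light_factor(env$I_av, w$K_sw, w$K_iw) *
    temperature_factor(T_K, w$A_w, w$B_w, w$E_aw, w$E_bw, p$R)
}

#' Light intensity maximizing the Aiba factor
#'
#' Closed form: the factor peaks at `I = sqrt(K_s K_i)` with value
#' `1 / (1 + 2 sqrt(K_s / K_i))`.
#'
#' @param K_s,K_i Aiba constants.
#' @return List with `I_opt` and `f_max`.
#' @export
optimal_light <- function(K_s, K_i) {
  stopifnot(K_s > 0, K_i > 0)
  list(I_opt = sqrt(K_s * K_i), f_max = 1 / (1 + 2 * sqrt(K_s / K_i)))
}
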