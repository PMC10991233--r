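#' Gas constant used in the Arrhenius exponentials
#'
#' Fixed at 8.3145e-3 kJ mol-1 K-1 so that activation energies tabulated in
#' kJ mol-1 can be used directly with temperatures in Kelvin. Never estimated.
#'
#' @format A length-one numeric.
#' @export
R_GAS <- 8.3145e-3

growth_symbols <- c("mu_max", "mu_d", "K_s", "K_i", "K_N", "K_C",
                    "A", "B", "E_a", "E_b")
carotene_symbols <- c("w_max", "b", "K_NW", "K_CW", "K_sw", "K_iw",
                      "A_w", "B_w", "E_aw", "E_bw")

#' Kinetic constants of the biomass growth rate law
#'
#' Bundles the coefficients of the specific-growth-rate model: a maximum
#' specific growth rate scaled by a double-Arrhenius temperature factor, an
#' Aiba light factor (saturation plus photoinhibition) and Monod factors for
#' nitrate and inorganic carbon, plus a quadratic decay term on biomass.
#'
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param mu_d Decay coefficient multiplying X^2. Its effective unit is
#'   L g-1 h-1 because it multiplies the square of a g/L concentration; the
#'   value is stored exactly as tabulated.
#' @param K_s Light saturation constant, umol photons m-2 s-1.
#' @param K_i Photoinhibition constant, umol photons m-2 s-1. Must exceed
#'   `K_s`.
#' @param K_N Nitrate half-velocity constant, mg/L.
#' @param K_C Inorganic-carbon half-velocity constant, mM.
#' @param A,B Pre-exponential coefficients of the temperature factor
#'   (dimensionless).
#' @param E_a,E_b Activation and inactivation energies, kJ/mol.
#' @return An object of class `growth_parameters` (named list).
#' @seealso [carotene_parameters()], [parameter_set()], [carokin_preset()]
#' @export
growth_parameters <- function(mu_max, mu_d, K_s, K_i, K_N, K_C, A, B, E_a, E_b) {
  p <- list(mu_max = mu_max, mu_d = mu_d, K_s = K_s, K_i = K_i,
            K_N = K_N, K_C = K_C, A = A, B = B, E_a = E_a, E_b = E_b)
  check_positive_scalars(p, "growth_parameters")
  if (p$K_i <= p$K_s)
    stop("growth_parameters: K_i must exceed K_s (photoinhibition above saturation)")
  structure(p, class = "growth_parameters")
}

#' Kinetic constants of the beta-carotene accumulation rate law
#'
#' @param w_max Maximum beta-carotene content as a mass fraction of dry
#'   weight (0.039 means 3.9 % of DW). Must lie in (0, 1).
#' @param b Growth-uncoupled offset coefficient (dimensionless).
#' @param K_NW Nitrate constant for carotene synthesis, mg/L.
#' @param K_CW Carbon constant for carotene synthesis, mM.
#' @param K_sw Light saturation constant for accumulation, umol photons m-2 s-1.
#' @param K_iw Photoinhibition constant for accumulation, umol photons m-2 s-1.
#'   Must exceed `K_sw`.
#' @param A_w,B_w Pre-exponential coefficients.
#' @param E_aw,E_bw Activation and inactivation energies, kJ/mol.
#' @return An object of class `carotene_parameters`.
#' @export
carotene_parameters <- function(w_max, b, K_NW, K_CW, K_sw, K_iw,
                                A_w, B_w, E_aw, E_bw) {
  p <- list(w_max = w_max, b = b, K_NW = K_NW, K_CW = K_CW, K_sw = K_sw,
            K_iw = K_iw, A_w = A_w, B_w = B_w, E_aw = E_aw, E_bw = E_bw)
  check_positive_scalars(p, "carotene_parameters")
  if (p$w_max >= 1)
    stop("carotene_parameters: w_max is a mass fraction and must be < 1")
  if (p$K_iw <= p$K_sw)
    stop("carotene_parameters: K_iw must exceed K_sw")
  structure(p, class = "carotene_parameters")
}

#' Full kinetic parameter set
#'
#' Single source of model coefficients: the growth block, the carotene block
#' and the (fixed) gas constant.
#'
#' @param growth A [growth_parameters()] object.
#' @param carotene A [carotene_parameters()] object.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(growth, carotene) {
  stopifnot(inherits(growth, "growth_parameters"),
            inherits(carotene, "carotene_parameters"))
  structure(list(growth = growth, carotene = carotene, R = R_GAS),
            class = "parameter_set")
}

#' Packaged parameter presets
#'
#' `"table1_prior"` holds the constants obtained from the single-factor
#' experiments and used as the starting point for joint estimation;
#' `"table2_optimized"` holds the jointly optimized values. Both reproduce
#' the tabulated numbers exactly.
#'
#' @param name `"table1_prior"` or `"table2_optimized"`.
#' @return A [parameter_set()].
#' @export
carokin_preset <- function(name = c("table1_prior", "table2_optimized")) {
  name <- match.arg(name)
  if (name == "table1_prior") {
    parameter_set(
      growth_parameters(mu_max = 0.1608, mu_d = 0.3, K_s = 379.6, K_i = 1705,
                        K_N = 9.88, K_C = 0.22, A = 15.09, B = 14.9,
                        E_a = 0.6684, E_b = 0.6449),
      carotene_parameters(w_max = 0.039, b = 0.03, K_NW = 43.37, K_CW = 10.38,
                          K_sw = 580, K_iw = 936.5, A_w = 0.4355, B_w = 0.35,
                          E_aw = 5.286, E_bw = 6.069))
  } else {
    parameter_set(
      growth_parameters(mu_max = 0.20278, mu_d = 0.15, K_s = 384.9, K_i = 1707,
                        K_N = 10.23, K_C = 0.26, A = 22.6350, B = 17.4630,
                        E_a = 1.0026, E_b = 0.5572),
      carotene_parameters(w_max = 0.0405, b = 0.0150, K_NW = 45.98, K_CW = 10.5,
                          K_sw = 581.6, K_iw = 937.1, A_w = 0.6533, B_w = 0.1750,
                          E_aw = 7.9290, E_bw = 3.0345))
  }
}

#' Flatten a parameter set to a named numeric vector
#'
#' The flat representation is keyed by the conventional symbol names
#' (`mu_max`, `K_s`, ..., `E_bw`) and is the exchange format for JSON
#' serialization and for the estimation layer.
#'
#' @param p A [parameter_set()].
#' @return Named numeric vector of the 20 kinetic constants.
#' @export
flatten_parameters <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  c(unlist(unclass(p$growth)), unlist(unclass(p$carotene)))
}

#' Rebuild a parameter set from a flat named vector
#'
#' @param x Named numeric vector containing all 20 symbols (extra names are
#'   rejected).
#' @return A [parameter_set()].
#' @export
unflatten_parameters <- function(x) {
  wanted <- c(growth_symbols, carotene_symbols)
  missing <- setdiff(wanted, names(x))
  if (length(missing))
    stop("parameter vector is missing: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(x), wanted)
  if (length(extra))
    stop("unknown parameter symbol(s): ", paste(extra, collapse = ", "))
  g <- as.list(x[growth_symbols])
  w <- as.list(x[carotene_symbols])
  parameter_set(do.call(growth_parameters, g), do.call(carotene_parameters, w))
}

#' Replace selected constants in a parameter set
#'
#' @param p A [parameter_set()].
#' @param values Named numeric vector of symbols to replace.
#' @return The modified [parameter_set()].
#' @export
update_parameters <- function(p, values) {
  flat <- flatten_parameters(p)
  bad <- setdiff(names(values), names(flat))
  if (length(bad))
    stop("unknown parameter symbol(s): ", paste(bad, collapse = ", "))
  flat[names(values)] <- values
  unflatten_parameters(flat)
}

#' Write a parameter set to JSON
#'
#' Flat JSON object keyed by symbol name, written at full double precision so
#' that a read/write round trip is bit-exact.
#'
#' @param p A [parameter_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  flat <- as.list(flatten_parameters(p))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path Path to a flat parameter JSON file as written by
#'   [write_parameters()].
#' @return A [parameter_set()].
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unflatten_parameters(unlist(x))
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  flat <- flatten_parameters(x)
  cat("  growth:  ", paste(sprintf("%s=%.6g", growth_symbols,
                                   flat[growth_symbols]), collapse = " "), "\n")
  cat("  carotene:", paste(sprintf("%s=%.6g", carotene_symbols,
                                   flat[carotene_symbols]), collapse = " "), "\n")
  cat("  R =", x$R, "kJ mol-1 K-1 (fixed)\n")
  invisible(x)
}

# all fields length-1, finite, strictly positive
check_positive_scalars <- function(p, where) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(where, ": ", nm, " must be a finite numeric scalar")
    if (v <= 0)
      stop(where, ": ", nm, " must be strictly positive")
  }
  invisible(TRUE)
}
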