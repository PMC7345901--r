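#' Thermodynamic context for energy/affinity conversions
#'
#' Bundles the temperature and unit conventions used by every conversion
#' between binding free energy and equilibrium constants. Binding free
#' energies are stored under the *magnitude convention*: `dg` is the
#' magnitude of the free-energy decrease on binding, so `dg >= 0` and a
#' larger `dg` means a better binder, with `K_D = exp(-dg/RT)` and
#' `K_A = exp(+dg/RT)`.
#'
#' @param temperature Thermodynamic temperature in kelvin. The default 310 K
#'   (body temperature) makes a 27.67 kJ/mol binding energy correspond to a
#'   dissociation constant of about 2e-5.
#' @param energy_unit Either `"kJ/mol"` (energies are molar, `RT = R * T`)
#'   or `"kBT"` (energies are dimensionless multiples of thermal energy,
#'   `RT = 1`).
#' @param gas_constant Molar gas constant in kJ/(mol K); only used for the
#'   `"kJ/mol"` unit system.
#'
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `gas_constant`, `energy_unit` and the derived thermal energy `rt`.
#' @examples
#' ctx <- thermo_context()
#' ctx$rt # about 2.577 kJ/mol
#' @export
thermo_context <- function(temperature = 310,
                           energy_unit = c("kJ/mol", "kBT"),
                           gas_constant = 8.314e-3) {
  energy_unit <- match.arg(energy_unit)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single finite value > 0 (kelvin)")
  }
  if (!is.finite(gas_constant) || gas_constant <= 0) {
    stop("`gas_constant` must be > 0")
  }
  rt <- if (energy_unit == "kBT") 1 else gas_constant * temperature
  structure(
    list(temperature = temperature, gas_constant = gas_constant,
         energy_unit = energy_unit, rt = rt),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat("thermo_context: T =", x$temperature, "K, energies in", x$energy_unit,
      "(RT =", format(x$rt), x$energy_unit, ")\n")
  invisible(x)
}

as_thermo_context <- function(ctx) {
  if (!inherits(ctx, "thermo_context")) {
    stop("`ctx` must be a thermo_context (see thermo_context())")
  }
  ctx
}

check_dg <- function(dg) {
  if (!is.numeric(dg) || any(!is.finite(dg))) {
    stop("binding energy `dg` must be finite")
  }
  if (any(dg < 0)) {
    stop("`dg` must be >= 0 under the magnitude convention ",
         "(magnitude of free-energy decrease on binding)")
  }
  dg
}

#' Equilibrium constant from binding free energy
#'
#' Converts a binding free energy (magnitude of the free-energy decrease on
#' binding) into a dimensionless equilibrium constant: the dissociation
#' constant `K_D = exp(-dg/RT)` or the association constant
#' `K_A = exp(+dg/RT)`.
#'
#' @param dg Binding free energy (>= 0), in the unit system of `ctx`.
#' @param ctx A [thermo_context].
#' @param kind `"dissociation"` or `"association"`.
#' @return Dimensionless equilibrium constant(s), same length as `dg`.
#' @examples
#' ctx <- thermo_context(310)
#' k_from_dg(27.67, ctx, "dissociation") # ~2.2e-5
#' @seealso [dg_from_k] for the inverse map.
#' @export
k_from_dg <- function(dg, ctx = thermo_context(),
                      kind = c("dissociation", "association")) {
  ctx <- as_thermo_context(ctx)
  kind <- match.arg(kind)
  dg <- check_dg(dg)
  sign <- if (kind == "dissociation") -1 else 1
  exp(sign * dg / ctx$rt)
}

#' Binding free energy from an equilibrium constant
#'
#' Exact inverse of [k_from_dg]: `dg = -RT log(K_D) = +RT log(K_A)`.
#'
#' @param k Dimensionless equilibrium constant(s), > 0.
#' @inheritParams k_from_dg
#' @return Binding free energy (magnitude convention) in the `ctx` units.
#' @examples
#' ctx <- thermo_context(310)
#' dg_from_k(2.17e-5, ctx, "dissociation") # ~27.67 kJ/mol
#' @export
dg_from_k <- function(k, ctx = thermo_context(),
                      kind = c("dissociation", "association")) {
  ctx <- as_thermo_context(ctx)
  kind <- match.arg(kind)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be finite and > 0")
  }
  sign <- if (kind == "dissociation") -1 else 1
  sign * ctx$rt * log(k)
}

#' Regulated free-antigen concentration implied by a binding energy
#'
#' The model's regulatory principle is that the steady-state concentration
#' of free antigen is tuned to the dissociation constant of the controlling
#' antibody, `[Ag] ~ K_D`. This function therefore returns
#' `exp(-dg/RT)` - the same map as `k_from_dg(dg, ctx, "dissociation")`,
#' read as a concentration in units of K_D. It is monotone decreasing in
#' `dg`: stronger antibodies hold their target at lower free levels.
#'
#' @inheritParams k_from_dg
#' @return Steady-state free-antigen level(s), dimensionless.
#' @export
regulated_antigen_concentration <- function(dg, ctx = thermo_context()) {
  k_from_dg(dg, ctx, kind = "dissociation")
}

#' System equilibrium constant of a binder
#'
#' `K_sys = K_A / <K_A> = exp((dg - mean_dg)/RT)` measures a molecule's
#' binding propensity relative to the system: the ratio of its association
#' constant to the system median. `K_sys > 1` marks a stronger-than-average
#' binder; `K_sys == 1` when `dg == mean_dg`.
#'
#' @param dg Binding free energy (magnitude convention).
#' @param mean_dg Mean binding free energy of the system, same units.
#' @param ctx A [thermo_context].
#' @return Dimensionless K_sys value(s).
#' @examples
#' ctx <- thermo_context(310)
#' ksys_from_dg(30, 27.67, ctx) # > 1: above-average binder
#' @export
ksys_from_dg <- function(dg, mean_dg, ctx = thermo_context()) {
  ctx <- as_thermo_context(ctx)
  dg <- check_dg(dg)
  if (!is.numeric(mean_dg) || any(!is.finite(mean_dg))) {
    stop("`mean_dg` must be finite")
  }
  exp((dg - mean_dg) / ctx$rt)
}

#' Mean of a lognormal distribution on the energy scale
#'
#' When log-binding-affinities are Gaussian with log-scale mean `mu` and
#' standard deviation `sigma`, the affinity itself is lognormal with mean
#' `exp(mu + sigma^2/2)`. With `mu = 0` and `sigma` equal to the numeric
#' value of RT at 310 K in kJ/mol (about 2.577), this gives the
#' characteristic system mean binding energy of about 27.7 kJ/mol.
#'
#' @param mu Log-scale mean.
#' @param sigma Log-scale standard deviation, >= 0.
#' @return The lognormal mean `exp(mu + sigma^2/2)`.
#' @examples
#' lognormal_mean_energy(0, thermo_context(310)$rt) # ~27.7
#' @export
lognormal_mean_energy <- function(mu, sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("`sigma` must be finite and >= 0")
  }
  if (!is.numeric(mu) || any(!is.finite(mu))) stop("`mu` must be finite")
  exp(mu + sigma^2 / 2)
}
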