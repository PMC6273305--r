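## Effect-compartment link and pharmacodynamic response models.

#' Sigmoid Emax (Hill) effect model
#'
#' `E = Emax * Ce^gamma / (EC50^gamma + Ce^gamma)`; the effect is 0 at
#' `Ce = 0`, `Emax/2` at `Ce = EC50` and saturates at `Emax`.
#'
#' @param ce effect-site concentration(s), `>= 0` (ng/mL).
#' @param emax maximal effect (degrees C), `> 0`.
#' @param ec50 concentration at half-maximal effect (ng/mL), `> 0`.
#' @param gamma Hill shape coefficient, `> 0`.
#' @return Effect values, same length as `ce`.
#' @examples
#' sigmoid_emax(10944.43, emax = 1.31, ec50 = 10944.43, gamma = 2.03)  # 0.655
#' @export
sigmoid_emax <- function(ce, emax, ec50, gamma) {
  if (any(ce < 0)) stop_input("ce must be >= 0")
  if (emax <= 0 || ec50 <= 0 || gamma <= 0) stop_input("emax, ec50 and gamma must be > 0")
  # emax / (1 + (ec50/ce)^gamma): stable at saturation, exact 0 at the origin
  out <- emax / (1 + (ec50 / ce)^gamma)
  out[ce == 0] <- 0
  out
}

#' Hyperbolic Emax model
#'
#' [sigmoid_emax] with `gamma = 1`.
#' @inheritParams sigmoid_emax
#' @return Effect values.
#' @export
emax_hyperbolic <- function(ce, emax, ec50) sigmoid_emax(ce, emax, ec50, 1)

#' Linear effect model
#'
#' `E = slope * Ce`, the no-saturation alternative used in PD model
#' comparison.
#' @inheritParams sigmoid_emax
#' @param slope effect per unit concentration (degrees C per ng/mL).
#' @return Effect values.
#' @export
pd_linear <- function(ce, slope) slope * ce

ce_from_terms <- function(terms, ke0, times, eps = 1e-8) {
  ## Ce solves dCe/dt = ke0 (Cp - Ce), Ce(0) = 0, for Cp a sum of
  ## exponentials in tau = t - tlag; the convolution is itself a sum of
  ## exponentials. ke0 equal to a plasma exponent is a removable singularity.
  if (min(abs(ke0 - terms$lam)) <= eps * ke0) {
    warning("ke0 coincides with a plasma exponent; perturbing ke0")
    ke0 <- ke0 * (1 + 1e-8)
  }
  tau <- times - terms$tlag
  B <- ke0 * terms$A / (ke0 - terms$lam)
  pos <- pmax(tau, 0)
  out <- colSums(B * exp(-outer(terms$lam, pos))) - sum(B) * exp(-ke0 * pos)
  out[tau <= 0] <- 0
  out
}

#' Effect-site concentration from a fitted pharmacokinetic model
#'
#' Solves the effect-compartment equation `dCe/dt = ke0 * (Cp(t) - Ce)`,
#' `Ce(0) = 0`, for plasma concentration `Cp` given by a compartment-model
#' fit. The effect compartment is concentration-equilibrating (standard link
#' convention), so `Ce` is in plasma units and tends to `Cp` as
#' `ke0 -> Inf`. The analytic route expands the convolution of the
#' exponential sum; `method = "ode"` integrates the augmented ODE system
#' numerically instead (useful as a cross-check).
#'
#' @param pk a `pk_fit` (converged) or a [pk_params] object.
#' @param ke0 plasma/effect-site equilibration rate constant (1/h), `> 0`.
#' @param times evaluation times (h).
#' @param dose dose in mg/kg; taken from the fit when `pk` is a `pk_fit`.
#' @param method `"analytic"` (default) or `"ode"`.
#' @return Effect-site concentrations (ng/mL).
#' @examples
#' p <- pk_params(ka = 24, v_c = 290, k10 = 2.4, k12 = 2.1, k21 = 0.36)
#' effect_site_conc(p, ke0 = 1.59, times = c(0.5, 1, 2), dose = 23.04)
#' @export
effect_site_conc <- function(pk, ke0, times, dose = NULL,
                             method = c("analytic", "ode")) {
  method <- match.arg(method)
  if (!is_number(ke0) || ke0 <= 0) stop_input("ke0 must be a positive number")
  if (inherits(pk, "pk_fit")) {
    if (!isTRUE(pk$converged)) stop_input("pk fit has not converged")
    params <- pk$params; dose <- dose %||% pk$dose
  } else if (inherits(pk, "pk_params")) {
    params <- pk
    if (is.null(dose)) stop_input("dose is required when pk is a pk_params")
  } else stop_input("pk must be a pk_fit or pk_params")
  if (method == "analytic") {
    return(ce_from_terms(exp_terms(params, dose), ke0, times))
  }
  ode_effect_site(params, dose, ke0, times)
}

## Numeric route: integrate absorption depot / central / peripheral / effect
## states with lsoda on a grid containing the requested times.
ode_effect_site <- function(params, dose, ke0, times) {
  two <- !is.null(params$k12)
  rhs <- function(t, y, p) {
    inflow <- if (t > params$tlag) params$ka * y[1] else 0
    dA <- if (t > params$tlag) -params$ka * y[1] else 0
    dC <- inflow / params$v_c - params$k10 * y[2] +
      if (two) params$k21 * y[3] - params$k12 * y[2] else 0
    dP <- if (two) params$k12 * y[2] - params$k21 * y[3] else 0
    dE <- ke0 * (y[2] - y[4])
    list(c(dA, dC, dP, dE))
  }
  y0 <- c(dose * 1e6, 0, 0, 0)
  grid <- sort(unique(c(0, params$tlag, times)))
  sol <- deSolve::lsoda(y0, grid, rhs, parms = NULL, rtol = 1e-10, atol = 1e-8)
  sol[match(times, grid), 5]
}
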