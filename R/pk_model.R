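## Closed-form one- and two-compartment extravascular models with first-order
## absorption and optional lag time. Concentrations are expressed as sums of
## exponentials; the exponential-term representation is shared with the
## effect-compartment link.

#' Candidate compartmental model specification
#'
#' Enumerates the four candidate disposition models: one or two compartments,
#' with or without an absorption lag time.
#'
#' @param n_compartments 1 or 2.
#' @param lag logical; include a lag time before first-order absorption.
#' @return An object of class `pk_model_spec`.
#' @examples
#' pk_model_spec(2, lag = TRUE)
#' @export
pk_model_spec <- function(n_compartments = 2, lag = TRUE) {
  if (!n_compartments %in% c(1, 2)) stop_input("n_compartments must be 1 or 2")
  structure(list(n_compartments = n_compartments, lag = isTRUE(lag)),
            class = "pk_model_spec")
}

#' @export
print.pk_model_spec <- function(x, ...) {
  cat(sprintf("<pk_model_spec> %d-compartment%s\n", x$n_compartments,
              if (x$lag) " with lag time" else ""))
  invisible(x)
}

n_free_params <- function(spec) {
  3L + (spec$n_compartments == 2) * 2L + spec$lag
}

param_names <- function(spec) {
  nm <- c("ka", "v_c", "k10")
  if (spec$n_compartments == 2) nm <- c(nm, "k12", "k21")
  if (spec$lag) nm <- c(nm, "tlag")
  nm
}

#' Micro-constant parameter set for an extravascular compartment model
#'
#' @param ka first-order absorption rate constant (1/h), `> 0`.
#' @param v_c apparent central volume of distribution (mL/kg), `> 0`.
#' @param k10 elimination rate constant from the central compartment (1/h).
#' @param k12,k21 central-peripheral distribution rate constants (1/h); both
#'   `NULL` for a one-compartment model.
#' @param tlag absorption lag time (h), `>= 0`.
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(ka = 24, v_c = 290, k10 = 2.4, k12 = 2.1, k21 = 0.36, tlag = 0.02)
#' @export
pk_params <- function(ka, v_c, k10, k12 = NULL, k21 = NULL, tlag = 0) {
  for (nm in c("ka", "v_c", "k10"))
    if (!is_number(get(nm)) || get(nm) <= 0) stop_input("%s must be a positive number", nm)
  if (is.null(k12) != is.null(k21)) stop_input("k12 and k21 must be supplied together")
  if (!is.null(k12)) {
    if (!is_number(k12) || k12 <= 0 || !is_number(k21) || k21 <= 0)
      stop_input("k12 and k21 must be positive numbers")
  }
  if (!is_number(tlag) || tlag < 0) stop_input("tlag must be >= 0")
  structure(list(ka = ka, v_c = v_c, k10 = k10, k12 = k12, k21 = k21, tlag = tlag),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  v <- unlist(x[!vapply(x, is.null, logical(1))])
  cat("<pk_params>\n"); print(signif(v, 5))
  if (!is.null(x$k12)) {
    hy <- hybrid_constants(x)
    cat(sprintf("  hybrid: alpha %.5g, beta %.5g (1/h)\n", hy[["alpha"]], hy[["beta"]]))
  }
  invisible(x)
}

#' Hybrid disposition constants of a two-compartment model
#'
#' Returns `alpha` and `beta` (1/h), the fast and slow disposition exponents,
#' satisfying `alpha + beta = k10 + k12 + k21` and `alpha * beta = k10 * k21`.
#'
#' @param params a [pk_params] with `k12`/`k21`.
#' @return Named numeric vector `c(alpha, beta)` with `alpha > beta > 0`.
#' @export
hybrid_constants <- function(params) {
  stopifnot(!is.null(params$k12))
  s <- params$k10 + params$k12 + params$k21
  disc <- sqrt(s^2 - 4 * params$k10 * params$k21)
  c(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

## Exponential-term representation: C(t) = sum_i A_i * exp(-lam_i * (t - tlag))
## for t > tlag, else 0. A is in ng/mL (the mg -> ng dose conversion is folded
## into the coefficients); lam in 1/h. ka coincident with a disposition
## exponent is a removable singularity, handled by a relative eps-perturbation.
exp_terms <- function(params, dose, eps = 1e-8) {
  stopifnot(inherits(params, "pk_params"))
  if (!is_number(dose) || dose <= 0) stop_input("dose must be positive (mg/kg)")
  amt <- dose * 1e6  # mg/kg -> ng/kg so that with v_c in mL/kg, C is ng/mL
  ka <- params$ka
  if (is.null(params$k12)) {
    if (abs(ka - params$k10) <= eps * params$k10) {
      warning("ka coincides with k10; perturbing ka to avoid the singularity")
      ka <- ka * (1 + 1e-8)
    }
    K <- ka * amt / (params$v_c * (ka - params$k10))
    A <- c(K, -K); lam <- c(params$k10, ka)
  } else {
    hy <- hybrid_constants(params)
    al <- hy[["alpha"]]; be <- hy[["beta"]]
    if (min(abs(ka - al), abs(ka - be)) <= eps * ka) {
      warning("ka coincides with a disposition exponent; perturbing ka")
      ka <- ka * (1 + 1e-8)
    }
    K <- ka * amt / params$v_c
    A <- K * c((params$k21 - al) / ((ka - al) * (be - al)),
               (params$k21 - be) / ((ka - be) * (al - be)),
               (params$k21 - ka) / ((al - ka) * (be - ka)))
    lam <- c(al, be, ka)
  }
  list(A = A, lam = lam, tlag = params$tlag)
}

eval_exp_terms <- function(terms, times) {
  tau <- times - terms$tlag
  out <- colSums(terms$A * exp(-outer(terms$lam, pmax(tau, 0))))
  out[tau <= 0] <- 0
  out
}

#' Predict plasma concentrations from a compartment model
#'
#' Evaluates the closed-form concentration of the one- or two-compartment
#' extravascular model (first-order absorption, optional lag) at the given
#' times. For the two-compartment model,
#' `C(tau) = (ka D / v_c) [c1 e^(-alpha tau) + c2 e^(-beta tau) + c3 e^(-ka tau)]`
#' with `tau = t - tlag` and the usual hybrid-constant coefficients;
#' concentrations are 0 at `t <= tlag`. Dose is converted mg -> ng internally
#' so that with `v_c` in mL/kg the result is in ng/mL.
#'
#' @param params a [pk_params]; one- vs two-compartment is inferred from the
#'   presence of `k12`/`k21`.
#' @param dose dose in mg/kg.
#' @param times evaluation times (h).
#' @return Numeric vector of concentrations (ng/mL).
#' @examples
#' p <- pk_params(ka = 24, v_c = 290, k10 = 2.4, k12 = 2.1, k21 = 0.36, tlag = 0.02)
#' predict_conc(p, dose = 23.04, times = c(0, 0.17, 1, 2.5))
#' @export
predict_conc <- function(params, dose, times) {
  eval_exp_terms(exp_terms(params, dose), times)
}

## Resolve absorption/disposition exchange ("flip-flop"): report the solution
## with ka > alpha when an equivalent relabelling exists. The observable curve
## is invariant; only the micro-constant labels change.
canonicalize_flipflop <- function(params, dose) {
  if (is.null(params$k12)) {
    if (params$ka < params$k10) {
      v <- params$v_c * params$k10 / params$ka
      return(pk_params(ka = params$k10, v_c = v, k10 = params$ka, tlag = params$tlag))
    }
    return(params)
  }
  hy <- hybrid_constants(params)
  if (params$ka >= hy[["alpha"]]) return(params)
  tm <- exp_terms(params, dose)
  ## exponents sorted; new absorption rate = old alpha, disposition = {ka, beta}
  ka_new <- hy[["alpha"]]
  al_new <- max(params$ka, hy[["beta"]]); be_new <- min(params$ka, hy[["beta"]])
  A_at <- function(l) tm$A[which.min(abs(tm$lam - l))]
  A2 <- A_at(be_new); A3 <- A_at(al_new)
  M <- (A2 * (ka_new - be_new) * (al_new - be_new) -
        A3 * (ka_new - al_new) * (be_new - al_new)) / (al_new - be_new)
  if (!is.finite(M) || M <= 0) return(params)
  k21_new <- be_new + A2 * (ka_new - be_new) * (al_new - be_new) / M
  if (!(k21_new > be_new && k21_new < al_new)) return(params)  # no valid relabelling
  v_new <- ka_new * dose * 1e6 / M
  k10_new <- al_new * be_new / k21_new
  k12_new <- al_new + be_new - k10_new - k21_new
  if (!all(is.finite(c(k10_new, k12_new, v_new))) ||
      k10_new <= 0 || k12_new <= 0 || v_new <= 0) return(params)
  tryCatch(pk_params(ka = ka_new, v_c = v_new, k10 = k10_new, k12 = k12_new,
                     k21 = k21_new, tlag = params$tlag),
           error = function(e) params)
}
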