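## Sequential (two-stage) PD estimation: the PK fit is fixed, then the link
## and response parameters are estimated jointly against the temperature
## change series.

pd_param_names <- function(model) {
  switch(model,
    sigmoid_emax = c("ke0", "emax", "ec50", "gamma"),
    emax         = c("ke0", "emax", "ec50"),
    linear       = c("ke0", "slope"))
}

pd_predict <- function(terms, model, p, times) {
  ce <- ce_from_terms(terms, p[["ke0"]], times)
  switch(model,
    sigmoid_emax = sigmoid_emax(ce, p[["emax"]], p[["ec50"]], p[["gamma"]]),
    emax         = emax_hyperbolic(ce, p[["emax"]], p[["ec50"]]),
    linear       = pd_linear(ce, p[["slope"]]))
}

#' Fit an effect-compartment PD model against temperature change
#'
#' Jointly estimates the equilibration rate `ke0` and the response-model
#' parameters by unweighted least squares on the temperature-change series,
#' with the pharmacokinetic stage held fixed (sequential strategy). Effects
#' are evaluated at the temperature sampling times through model-predicted
#' effect-site concentrations, so concentration and temperature grids never
#' need to match. Optimisation is Levenberg-Marquardt over log-parameters
#' from a Latin-hypercube multistart.
#'
#' `emax_upper` optionally bounds Emax from above (bounded
#' log-odds parameterisation). The natural choice is the maximal fever
#' increment of the untreated control arm: suppression of a fever cannot
#' exceed the fever itself. The bound regularises the weakly identified
#' saturation of sparse mean profiles; leave `NULL` for an unbounded fit.
#'
#' @param pk converged `pk_fit` from [fit_pk].
#' @param response [temp_profile] in `delta_t` form; the positive
#'   suppression-magnitude convention is assumed.
#' @param model `"sigmoid_emax"` (default), `"emax"` (gamma fixed at 1) or
#'   `"linear"`.
#' @param emax_upper optional upper bound for Emax (degrees C).
#' @param n_starts multistart size (default 64 for the 4-parameter problem).
#' @param seed RNG seed for the multistart.
#' @return An object of class `pd_fit`: `model`, `params` (named numeric),
#'   `ssr`, `aic`, `n_obs`, `n_params`, `converged`, `seed`, `emax_upper`,
#'   the data (`times`, `effect`) and `fitted` values, plus the `pk` fit
#'   used. Derived effect metrics are added by [derived_metrics].
#' @examples
#' fx <- qkl_fixture()
#' pk <- fit_pk(fx$conc_baicalin, pk_model_spec(2, TRUE))
#' pd <- fit_pd(pk, fx$delta_t, emax_upper = fx$references$max_increment)
#' pd$params
#' @export
fit_pd <- function(pk, response, model = c("sigmoid_emax", "emax", "linear"),
                   emax_upper = NULL, n_starts = 64, seed = 23) {
  model <- match.arg(model)
  stopifnot(inherits(pk, "pk_fit"), inherits(response, "temp_profile"))
  if (!isTRUE(pk$converged)) stop_input("pk fit has not converged")
  if (is.null(response$delta_t)) stop_input("response must carry delta_t values")
  t <- response$times; e <- response$delta_t
  nm <- pd_param_names(model)
  if (length(e) < length(nm) + 2)
    stop_input("need at least %d temperature observations", length(nm) + 2)
  terms <- exp_terms(pk$params, pk$dose)
  cmax_obs <- max(pk$conc)
  e_pos <- max(e)
  bounded <- !is.null(emax_upper) && is.finite(emax_upper)
  if (bounded && emax_upper <= 0) stop_input("emax_upper must be positive")
  to_par <- function(lp) {
    p <- pmin(pmax(exp(lp), 1e-12), 1e12); names(p) <- nm
    if (bounded && "emax" %in% nm)
      p[["emax"]] <- emax_upper * stats::plogis(lp[[which(nm == "emax")]])
    p
  }
  resid_fn <- function(lp) {
    p <- to_par(lp)
    e - suppressWarnings(pd_predict(terms, model, p, t))
  }
  ce_ref <- max(ce_from_terms(terms, 1, t))
  lo <- c(ke0 = log(0.05), emax = log(e_pos * 0.2), ec50 = log(cmax_obs / 200),
          gamma = log(0.3), slope = log(e_pos / cmax_obs / 50))[nm]
  hi <- c(ke0 = log(30), emax = log(e_pos * 5), ec50 = log(cmax_obs * 2),
          gamma = log(10), slope = log(e_pos / max(ce_ref, 1) * 50))[nm]
  if (bounded && "emax" %in% nm) {  # bounded scale: logit of emax/emax_upper
    lo[["emax"]] <- stats::qlogis(0.05)
    hi[["emax"]] <- stats::qlogis(0.99)
  }
  starts <- with_local_seed(seed, lhs_box(n_starts, lo, hi))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(starts[i, ], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(err) NULL)
    if (is.null(f) || !all(is.finite(f$par))) next
    ssr <- sum(resid_fn(f$par)^2)
    ok <- f$info %in% 1:4
    if (is.null(best) || (ssr < best$ssr && ok) || (ssr < best$ssr && !best$converged)) {
      best <- list(par = f$par, ssr = ssr, converged = ok)
    }
  }
  if (is.null(best)) {
    fit <- list(model = model, params = NULL, ssr = NA_real_, aic = NA_real_,
                n_obs = length(e), n_params = length(nm), converged = FALSE,
                seed = seed, emax_upper = emax_upper, times = t, effect = e,
                fitted = NULL, pk = pk)
    class(fit) <- "pd_fit"
    return(fit)
  }
  p <- to_par(best$par)
  fit <- list(model = model, params = p, ssr = best$ssr,
              aic = aic_from_ssr(best$ssr, length(e), length(nm)),
              n_obs = length(e), n_params = length(nm),
              converged = best$converged, seed = seed, emax_upper = emax_upper,
              times = t, effect = e,
              fitted = pd_predict(terms, model, p, t), pk = pk)
  class(fit) <- "pd_fit"
  fit
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(sprintf("<pd_fit> %s | n=%d%s\n", x$model, x$n_obs,
              if (!is.null(x$emax_upper)) sprintf(", Emax bounded at %.3g", x$emax_upper) else ""))
  if (!isTRUE(x$converged)) cat("  ** not converged **\n")
  print(signif(x$params, 5))
  cat(sprintf("  SSR %.6g, AIC %.4g\n", x$ssr, x$aic))
  if (!is.null(x$derived)) {
    cat(sprintf("  Emax fraction %.1f%%, EC50/Cmax %.1f%%\n",
                x$derived$emax_fraction * 100, x$derived$ec50_over_cmax * 100))
  }
  invisible(x)
}

#' @export
plot.pd_fit <- function(x, n_grid = 200, ...) {
  grid <- seq(min(x$times), max(x$times), length.out = n_grid)
  terms <- exp_terms(x$pk$params, x$pk$dose)
  pred <- pd_predict(terms, x$model, x$params, grid)
  plot(x$times, x$effect, xlab = "time (h)", ylab = "deltaT (degrees C)", ...)
  lines(grid, pred, col = "firebrick")
  invisible(x)
}

#' Signed area of a concentration-effect hysteresis loop
#'
#' Shoelace (polygon) area of the `(C, E)` loop traversed in time order and
#' closed back to the first point. Positive area means anticlockwise
#' traversal, the signature of an effect lagging behind plasma concentration
#' (an effect compartment); effect proportional to concentration gives a
#' degenerate loop of zero area.
#'
#' @param conc concentration series (ng/mL).
#' @param effect paired effect series (degrees C), same time grid.
#' @return Signed area (ng/mL x degrees C).
#' @examples
#' hysteresis_area(c(0, 1, 1, 0), c(0, 0, 1, 1))  # +1: anticlockwise unit square
#' @export
hysteresis_area <- function(conc, effect) {
  if (length(conc) != length(effect)) stop_input("conc and effect must have equal length")
  if (length(conc) < 3) stop_input("need at least 3 points to form a loop")
  j <- c(2:length(conc), 1L)
  sum(conc * effect[j] - conc[j] * effect) / 2
}

#' Derived effect metrics
#'
#' Scales the fitted PD parameters against external references: the Emax
#' fraction `emax / max_increment` (how much of the maximal fever increment
#' the drug can suppress) and the relative potency `ec50 / cmax`.
#'
#' @param pd a `pd_fit` with an `emax`/`ec50` parameterisation.
#' @param max_increment reference maximal temperature increment (degrees C),
#'   `> 0`.
#' @param cmax reference observed maximal plasma concentration (ng/mL), `> 0`.
#' @return The `pd_fit` with a `derived` element (list `emax_fraction`,
#'   `ec50_over_cmax`, both unitless ratios).
#' @examples
#' # ratios as percentages: 1.31/1.38 = 94.9%, 10944.43/59063.86 = 18.5%
#' @export
derived_metrics <- function(pd, max_increment, cmax) {
  stopifnot(inherits(pd, "pd_fit"))
  if (!is_number(max_increment) || max_increment <= 0) stop_input("max_increment must be > 0")
  if (!is_number(cmax) || cmax <= 0) stop_input("cmax must be > 0")
  if (!all(c("emax", "ec50") %in% names(pd$params)))
    stop_input("derived metrics need an emax/ec50 parameterisation")
  pd$derived <- list(emax_fraction = unname(pd$params[["emax"]] / max_increment),
                     ec50_over_cmax = unname(pd$params[["ec50"]] / cmax))
  pd
}
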