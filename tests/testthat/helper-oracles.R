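## Independent numeric oracles used to cross-check the closed-form
## implementations. The ODE route integrates the compartment system in
## amounts (depot, central, peripheral) plus the effect-site state, in the
## shifted time tau = t - tlag so the absorption switch is not a
## discontinuity for the solver.

ode_oracle <- function(params, dose, times, ke0 = 1) {
  k12 <- params$k12
  k21 <- params$k21
  two <- !is.null(k12)
  rhs <- function(tau, y, p) {
    dA <- -params$ka * y[1]
    dXc <- params$ka * y[1] - params$k10 * y[2] +
      (if (two) k21 * y[3] - k12 * y[2] else 0)
    dXp <- if (two) k12 * y[2] - k21 * y[3] else 0
    dCe <- ke0 * (y[2] / params$v_c - y[4])
    list(c(dA, dXc, dXp, dCe))
  }
  tau <- pmax(times - params$tlag, 0)
  grid <- sort(unique(c(0, tau)))
  sol <- deSolve::lsoda(c(dose * 1e6, 0, 0, 0), grid, rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-13)
  i <- match(tau, grid)
  list(cp = sol[i, 3] / params$v_c, ce = sol[i, 5])
}

## random valid two-compartment parameter draw, kept away from the
## removable ka ~ alpha/beta singularities
rand_pk_params <- function() {
  repeat {
    p <- pk_params(ka = exp(runif(1, log(2), log(60))),
                   v_c = exp(runif(1, log(50), log(1000))),
                   k10 = exp(runif(1, log(0.3), log(8))),
                   k12 = exp(runif(1, log(0.05), log(8))),
                   k21 = exp(runif(1, log(0.05), log(8))),
                   tlag = runif(1, 0, 0.1))
    hy <- hybrid_constants(p)
    if (min(abs(p$ka - hy)) > 1e-3 * p$ka) return(p)
  }
}

rand_ke0 <- function(params) {
  hy <- hybrid_constants(params)
  repeat {
    ke0 <- exp(runif(1, log(0.2), log(10)))
    if (min(abs(ke0 - c(hy, params$ka))) > 1e-3 * ke0) return(ke0)
  }
}

rel_err <- function(a, b, scale = max(abs(b))) abs(a - b) / pmax(abs(b), 1e-9 * scale)

## plain term-by-term linear trapezoid, written out longhand
trapz_linear_oracle <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) s <- s + (y[i] + y[i + 1]) / 2 * (t[i + 1] - t[i])
  s
}

table2_times <- function() c(0, 0.033, 0.067, 0.1, 0.17, 0.25, 0.33, 0.5,
                             0.75, 1, 1.5, 2, 2.5)
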