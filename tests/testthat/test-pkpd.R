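test_that("sigmoid Emax identities: origin, half-max, saturation", {
  expect_equal(sigmoid_emax(0, 1.31, 10944.43, 2.03), 0)
  expect_equal(sigmoid_emax(10944.43, 1.31, 10944.43, 2.03), 0.655)
  expect_equal(sigmoid_emax(1e12, 1.31, 10944.43, 2.03), 1.31, tolerance = 1e-6)
  # gamma = 1 reproduces the hyperbolic model
  ce <- c(0, 50, 500, 5000)
  expect_equal(sigmoid_emax(ce, 2, 300, 1), emax_hyperbolic(ce, 2, 300))
})

test_that("sigmoid Emax is monotone in ce and in emax", {
  set.seed(3)
  for (i in 1:20) {
    ec50 <- exp(runif(1, log(10), log(1e4)))
    g <- exp(runif(1, log(0.4), log(6)))
    emax <- runif(1, 0.5, 3)
    ce <- sort(exp(runif(30, log(1e-2), log(1e6))))
    e <- sigmoid_emax(ce, emax, ec50, g)
    expect_true(all(diff(e) >= -1e-15 * emax))          # nondecreasing up to ulp noise
    mid <- sort(runif(20, ec50 / 10, ec50 * 10))        # strict away from saturation
    expect_true(all(diff(sigmoid_emax(mid, emax, ec50, g)) > 0))
    expect_true(all(sigmoid_emax(ce, emax * 2, ec50, g) >= e))
  }
})

test_that("effect-site concentration: equilibration limits and step response", {
  p <- pk_params(ka = 24, v_c = 290, k10 = 2.4, k12 = 2.1, k21 = 0.36, tlag = 0.02)
  times <- c(0.1, 0.25, 0.5, 1, 2)
  cp <- predict_conc(p, 23.04, times)
  # ke0 -> Inf: the effect site tracks plasma
  ce_fast <- effect_site_conc(p, ke0 = 1e6, times = times, dose = 23.04)
  expect_lt(max(rel_err(ce_fast, cp)), 1e-3)
  # constant plasma concentration: textbook first-order step response
  const_terms <- list(A = 100, lam = 1e-12, tlag = 0)
  t <- c(0.2, 0.7, 1.9)
  ce <- pkpdlink:::ce_from_terms(const_terms, 1.3, t)
  expect_equal(ce, 100 * (1 - exp(-1.3 * t)), tolerance = 1e-8)
})

test_that("analytic effect-site concentrations match the ODE oracle to 1e-6", {
  set.seed(7)
  times <- seq(0.05, 12, length.out = 50)
  for (i in 1:100) {
    p <- rand_pk_params()
    ke0 <- rand_ke0(p)
    ce <- effect_site_conc(p, ke0, times, dose = 23.04)
    ode <- ode_oracle(p, 23.04, times, ke0)$ce
    expect_lt(max(rel_err(ce, ode)), 1e-6)
  }
  # the published equilibration rate on a fixture-like PK
  p <- pk_params(ka = 24, v_c = 290, k10 = 2.4, k12 = 2.1, k21 = 0.36, tlag = 0.02)
  ce <- effect_site_conc(p, 1.59, times, dose = 23.04)
  expect_lt(max(rel_err(ce, ode_oracle(p, 23.04, times, 1.59)$ce)), 1e-6)
  # in-package ODE route agrees with the analytic one
  ce_ode <- effect_site_conc(p, 1.59, times, dose = 23.04, method = "ode")
  expect_lt(max(rel_err(ce_ode, ce)), 1e-5)
})

test_that("the effect site lags plasma: later peak, anticlockwise loop", {
  set.seed(19)
  grid <- seq(0, 8, by = 0.01)
  for (i in 1:25) {
    p <- rand_pk_params()
    ke0 <- rand_ke0(p)
    cp <- predict_conc(p, 23.04, grid)
    ce <- effect_site_conc(p, ke0, grid, dose = 23.04)
    expect_gte(grid[which.max(ce)], grid[which.max(cp)])
    e <- sigmoid_emax(ce, 1.3, max(ce) / 2, 2)
    idx <- seq(1, length(grid), by = 10)
    expect_gt(hysteresis_area(cp[idx], e[idx]), 0)
  }
})

test_that("shoelace area: unit square, degenerate loop, fixture loop", {
  expect_equal(hysteresis_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)   # anticlockwise
  expect_equal(hysteresis_area(c(0, 1, 1, 0), rev(c(0, 0, 1, 1))), -1)
  conc <- c(0, 2, 5, 9, 4, 1)
  expect_equal(hysteresis_area(conc, 0.3 * conc), 0)               # E proportional to C
  expect_error(hysteresis_area(c(1, 2), c(1, 2)), "3 points")
  fx <- qkl_fixture()
  expect_gt(hysteresis_area(fx$conc_baicalin$conc, fx$delta_t$delta_t), 0)
  expect_gt(hysteresis_area(fx$conc_geniposide$conc, fx$delta_t$delta_t), 0)
})

test_that("PD fit recovers known parameters from noise-free link-model output", {
  p <- pk_params(ka = 24, v_c = 290, k10 = 2.4, k12 = 2.1, k21 = 0.36, tlag = 0.02)
  t <- table2_times()
  prof <- conc_profile("s", "x", 23.04, t, predict_conc(p, 23.04, t))
  pk <- fit_pk(prof, pk_model_spec(2, TRUE), n_starts = 24, seed = 3)
  truth <- c(ke0 = 1.59, emax = 1.31, ec50 = 10944.43, gamma = 2.03)
  ce <- effect_site_conc(pk, truth[["ke0"]], t)
  resp <- temp_profile("s", "MTG", t,
                       delta_t = sigmoid_emax(ce, truth[["emax"]], truth[["ec50"]],
                                              truth[["gamma"]]))
  pd <- fit_pd(pk, resp, "sigmoid_emax", n_starts = 48, seed = 4)
  expect_true(pd$converged)
  for (nm in names(truth))
    expect_equal(pd$params[[nm]], truth[[nm]], tolerance = 1e-3)
})

test_that("free gamma never loses to fixed gamma by more than its AIC penalty", {
  fx <- qkl_fixture()
  pk <- fit_pk(fx$conc_baicalin, pk_model_spec(2, TRUE), seed = 17)
  sig <- fit_pd(pk, fx$delta_t, "sigmoid_emax", n_starts = 48, seed = 9)
  hyp <- fit_pd(pk, fx$delta_t, "emax", n_starts = 48, seed = 9)
  expect_lte(sig$ssr, hyp$ssr + 1e-8)       # nested models
  expect_lte(sig$aic, hyp$aic + 2)
})

test_that("derived metrics scale the fit against its references", {
  pd <- structure(list(params = c(emax = 1.31, ec50 = 10944.43)), class = "pd_fit")
  d <- derived_metrics(pd, max_increment = 1.38, cmax = 59063.86)$derived
  expect_equal(round(100 * d$emax_fraction, 1), 94.9)
  expect_equal(round(100 * d$ec50_over_cmax, 1), 18.5)
  same <- derived_metrics(structure(list(params = c(emax = 1.38, ec50 = 1)),
                                    class = "pd_fit"), 1.38, 10)$derived
  expect_equal(same$emax_fraction, 1)
  expect_error(derived_metrics(pd, -1, 10), "max_increment")
})
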