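test_that("reproductive output reads the season-end cumulative states", {
  p <- colony_params(T_W = 50)
  sim <- run_scenario(p, settings = simulation_settings(dt_out = 1))
  tr <- sim$trajectory
  expect_equal(reproductive_output(sim), tr$M[nrow(tr)] + tr$G[nrow(tr)])
  # a colony that lays nothing produces nothing
  p0 <- colony_params(b_W = 0, b_M = 0, b_G = 0, T_W = 50)
  expect_equal(reproductive_output(run_scenario(p0,
    settings = simulation_settings(dt_out = 1))), 0, tolerance = 1e-8)
  # truncated trajectories are rejected
  simt <- sim
  simt$trajectory <- tr[tr$time <= 45, ]
  expect_error(reproductive_output(simt), "truncated")
})

test_that("cumulative reproductives equal the integrated emergence fluxes", {
  p <- colony_params(T_W = 90)
  sim <- run_scenario(p, settings = simulation_settings(dt_out = 0.25))
  tr <- sim$trajectory
  ic <- initial_conditions(p)
  # trapezoid-integrate the emergence expressions evaluated from the stored
  # trajectory itself (independent of the solver's internal accumulation)
  interp <- lapply(names(tr)[-1], function(col)
    stats::approxfun(tr$time, tr[[col]], rule = 2))
  names(interp) <- names(tr)[-1]
  bst <- function(s) {
    if (s <= 22) return(ic$history(s))
    y <- colony_state()
    for (k in names(y)) y[[k]] <- interp[[k]](s)
    list(bstar = effective_laying_rates(s, y, p),
         Phi = c(w = y[["PhiW"]], m = y[["PhiM"]], g = y[["PhiG"]]))
  }
  ts <- seq(22, 90, by = 0.25)
  fm <- vapply(ts, emergence_flux, numeric(1), history = bst, caste = "male")
  fg <- vapply(ts, emergence_flux, numeric(1), history = bst, caste = "gyne")
  trap <- function(f) sum(diff(ts) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  expect_equal(trap(fm) + trap(fg), reproductive_output(sim),
               tolerance = 0.01)
})

test_that("peak day is the argmax of the dense output, earliest tie wins", {
  df <- data.frame(time = 1:10, W = c(1:5, 5, 4:1))
  expect_equal(peak_day(df, "W"), 5)
  mono <- data.frame(time = 1:10, W = 1:10)
  expect_equal(peak_day(mono, "W"), 10)
  sym <- data.frame(time = seq(0, 10, 0.5), W = -(seq(0, 10, 0.5) - 5)^2)
  expect_equal(peak_day(sym, "W"), 5)
  expect_error(peak_day(df, "Q"), "component")
})

test_that("percent change against control", {
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(25, 50), -50)
  expect_equal(percent_change(0, 50), -100)
  expect_error(percent_change(10, 0), "positive")
})

test_that("colony metrics collect endpoints and landmarks", {
  p <- colony_params(T_W = 90)  # long enough that reproductives emerge
  st <- simulation_settings(dt_out = 1)
  ctrl <- run_scenario(p, settings = st)
  sim <- run_scenario(p, exposure_scenario(forage_reduction_P = 0.5), st)
  m <- colony_metrics(sim, control = ctrl)
  expect_s3_class(m, "bombus_metrics")
  expect_equal(m$reproductive_output, reproductive_output(sim))
  expect_true(m$peak_worker_day >= 22 && m$peak_worker_day <= 90)
  expect_lt(m$pct_change_reproductives, 0)
})
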