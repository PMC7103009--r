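p0 <- colony_params()
sch <- stage_schedule()

# analytic history with constant effective laying and linear Phi(t) = m * t
const_history <- function(bw = 8.5, bm = 2, bg = 2.6, m = 0) {
  function(s) list(bstar = c(W = bw, M = bm, G = bg),
                   Phi = c(w = m * s, m = m * s, g = m * s))
}

test_that("emergence flux evaluates the delayed-birth expression", {
  # no larval mortality: flux equals the lagged laying rate
  expect_equal(emergence_flux(50, const_history(), "worker", sch), 8.5)
  expect_equal(emergence_flux(50, const_history(), "male", sch), 2)
  expect_equal(emergence_flux(50, const_history(), "gyne", sch), 2.6)
  # constant mu over the larval window: exp(-m * duration)
  for (m in c(0.05, 0.1)) {
    expect_equal(emergence_flux(60, const_history(m = m), "worker", sch),
                 8.5 * exp(-9 * m))
    expect_equal(emergence_flux(60, const_history(m = m), "male", sch),
                 2 * exp(-11 * m))
    expect_equal(emergence_flux(60, const_history(m = m), "gyne", sch),
                 2.6 * exp(-13 * m))
  }
  # direct evaluation of the printed worker expression
  h <- function(s) list(bstar = c(W = 8.5, M = 0, G = 0),
                        Phi = c(w = if (s <= 42) 0.5 else 1.2, m = 0, g = 0))
  expect_equal(emergence_flux(60, h, "worker", sch), 8.5 * exp(0.5 - 1.2))
})

test_that("stage transfer fluxes reproduce the lagged substage expressions", {
  f <- stage_transfer_fluxes(60, const_history(), "worker", sch, Phi_now = 0)
  expect_equal(f, c(8.5, 8.5, 8.5))  # steady state: all transfers equal
  # linear Phi: survival from each substage's larval start to now
  m <- 0.1
  f2 <- stage_transfer_fluxes(60, const_history(m = m), "worker", sch,
                              Phi_now = m * 60)
  expect_equal(f2, c(8.5, 8.5 * exp(-6 * m), 8.5 * exp(-9 * m)))
  fg <- stage_transfer_fluxes(60, const_history(m = m), "gyne", sch,
                              Phi_now = m * 60)
  expect_equal(fg, 2.6 * exp(-m * c(0, 5, 9, 13)))
  # silent history: all fluxes vanish
  f0 <- stage_transfer_fluxes(60, const_history(0, 0, 0), "male", sch, 0)
  expect_equal(f0, c(0, 0, 0))
})

test_that("initial conditions pre-fill worker larvae from the laying history", {
  ic <- initial_conditions(p0, sch)
  expect_equal(ic$t0, 22)
  expect_equal(ic$state[["L1w"]], 8.5 * 6, tolerance = 1e-6)   # 51
  expect_equal(ic$state[["L2w"]], 8.5 * 3, tolerance = 1e-6)   # 25.5
  expect_equal(unname(ic$state[c("L1m", "L2m", "L1g", "L2g", "L3g")]),
               rep(0, 5))
  expect_equal(ic$state[["N"]], p0$N0)
  expect_equal(ic$state[["P"]], p0$P0)
  expect_equal(unname(ic$state[c("W", "M", "G", "PhiW", "Ew")]), rep(0, 5))
  # pre-start history: worker laying at the scheduled rate, Phi = 0
  h <- ic$history(10)
  expect_equal(unname(h$bstar), c(8.5, 0, 0))
  expect_equal(unname(h$Phi), c(0, 0, 0))
  # first emergence draws on eggs laid at t = 0
  expect_equal(emergence_flux(23, ic$history, "worker", sch), 8.5)
  # brood reductions thin the pre-filled compartments
  sc <- exposure_scenario(brood1_reduction = 0.4, brood2_reduction = 0.2)
  ic2 <- initial_conditions(p0, sch, sc)
  # L2w window: eggs laid on days (9, 12], all brood 1
  expect_equal(ic2$state[["L2w"]], 25.5 * 0.6, tolerance = 1e-6)
  # L1w window: eggs laid (12, 18]: one day brood 1, five days brood 2
  expect_equal(ic2$state[["L1w"]], 8.5 * (1 * 0.6 + 5 * 0.8),
               tolerance = 1e-3)
})

test_that("the assembled derivative matches hand-computed balances", {
  ic <- initial_conditions(p0, sch)
  # empty colony: nothing moves
  d0 <- colony_rhs(50, colony_state(), p0, NULL, sch, const_history(0, 0, 0))
  expect_equal(unname(d0), rep(0, 16))
  # workers only, ample stores: resource balances from the printed rates
  y <- colony_state(N = 1e5, P = 1e5, W = 100)
  d <- colony_rhs(50, y, p0, NULL, sch, const_history(0, 0, 0))
  expect_equal(d[["N"]], 0.6 * 100 - 0.35 * 100, tolerance = 1e-5)  # 25
  expect_equal(d[["P"]], 0.4 * 100 - 0.25 * 100, tolerance = 1e-5)  # 15
  expect_equal(d[["W"]], -0.05 * 100)
  # adult reproductives draw on both stores
  y2 <- colony_state(N = 1e5, P = 1e5, W = 100, M = 10, G = 10)
  d2 <- colony_rhs(50, y2, p0, NULL, sch, const_history(0, 0, 0))
  expect_equal(d2[["N"]] - d[["N"]], -20 * p0$mu_NR, tolerance = 1e-5)
  expect_equal(d2[["P"]] - d[["P"]], -20 * p0$mu_PR, tolerance = 1e-5)
  # emergence feeds W, M, G and the worker emergence counter
  d3 <- colony_rhs(50, y, p0, NULL, sch, const_history())
  expect_equal(d3[["W"]], 8.5 - 5)
  expect_equal(d3[["M"]], 2)
  expect_equal(d3[["G"]], 2.6)
  expect_equal(d3[["Ew"]], 8.5)
})

test_that("fast integration path agrees with the reference assembly", {
  p <- colony_params(T_W = 70)
  st <- simulation_settings(dt_out = 1)
  sc <- exposure_scenario(acute_day = 30, forage_reduction_P = 0.2,
                          brood2_reduction = 0.1)
  a <- run_scenario(p, sc, st)$trajectory
  b <- run_scenario(p, sc, st, reference_rhs = TRUE)$trajectory
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), 1e-6)
})
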