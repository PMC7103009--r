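p0 <- colony_params()

test_that("projected pollen demand follows the printed linear form", {
  expect_equal(pollen_demand(colony_state(), p0), 0)
  s <- colony_state(L1w = 10)
  expect_equal(pollen_demand(s, p0), 10 * p0$c1)
  # hand evaluation with explicit rates
  p <- colony_params(c2 = 0.13, c5 = 0.25)
  s2 <- colony_state(L2w = 4, L3g = 2)
  expect_equal(pollen_demand(s2, p), 4 * 0.13 + 2 * 0.25)  # 1.02
  expect_equal(nectar_demand(s2, p), 2.04)
  expect_error(pollen_demand(colony_state(L1w = -5), p0), "negative")
})

test_that("pollen demand is linear in every larval class", {
  set.seed(41)
  for (i in 1:20) {
    L <- stats::runif(7, 0, 200)
    s <- colony_state(L1w = L[1], L2w = L[2], L1m = L[3], L2m = L[4],
                      L1g = L[5], L2g = L[6], L3g = L[7])
    s2 <- s; s2[4:10] <- 2 * s2[4:10]
    expect_equal(pollen_demand(s2, p0), 2 * pollen_demand(s, p0))
    expect_equal(nectar_demand(s, p0), 2 * pollen_demand(s, p0))
  }
})

test_that("deficit factors stay in [0, 1] for arbitrary non-negative states", {
  set.seed(42)
  for (i in 1:200) {
    s <- colony_state(N = stats::rexp(1, 1e-2), P = stats::rexp(1, 1e-2),
                      W = stats::rexp(1, 1e-2))
    s[4:10] <- stats::rexp(7, 1e-2)
    sig <- regulation_signal(s, p0)
    expect_true(sig$D_neglect >= 0 && sig$D_neglect <= 1)
    expect_true(sig$D_malnut >= 0 && sig$D_malnut <= 1)
    expect_true(sig$D_oophagy >= 0 && sig$D_oophagy <= 1)
    expect_true(larval_mortality_rate(s, p0) >= 0)
  }
})

test_that("larval mortality vanishes without shortfall and matches the capped
          form's hand-computed value", {
  # no shortfall: plenty of workers and stores
  s <- colony_state(N = 1e3, P = 1e3, W = 50, L1w = 50, L2w = 50)
  expect_equal(larval_mortality_rate(s, p0), 0)
  # worker-capped form, care shortfall only: W=10, L=80 > ZW=40
  pc <- colony_params(ejection = "worker_capped")
  s2 <- colony_state(N = 1e3, P = 1e3, W = 10, L1w = 80)
  expect_equal(larval_mortality_rate(s2, pc),
               0.75 * 10 * ((80 - 40) / (80 + 0.001)) / (80 + 0.001),
               tolerance = 1e-10)  # ~0.0469/day
  # capped form: no workers, no ejection
  s3 <- colony_state(P = 1e3, N = 1e3, W = 0, L1w = 80)
  expect_equal(larval_mortality_rate(s3, pc), 0)
  # deficit form: unattended larvae die at alpha per unit deficit
  expect_equal(larval_mortality_rate(s2, p0),
               0.75 * (80 - 40) / (80 + 0.001), tolerance = 1e-10)
  # forced override wins
  pf <- colony_params(mu_L_override = 0.2)
  expect_equal(larval_mortality_rate(s2, pf), 0.2)
})

test_that("oophagy factor follows the clamped shortfall of either resource", {
  s <- colony_state(N = 100, P = 100, L1w = 100)  # demand 1, ample stores
  expect_equal(oophagy_factor(s, p0), 0)
  s2 <- colony_state(N = 100, P = 0, L1w = 100)   # total pollen shortfall
  expect_equal(oophagy_factor(s2, p0), 1 / (1 + p0$eps), tolerance = 1e-9)
  # half the pollen demand covered, nectar ample: factor ~ 0.5
  C <- pollen_demand(colony_state(L1w = 100), p0)
  s3 <- colony_state(N = 100, P = C / 2, L1w = 100)
  expect_equal(oophagy_factor(s3, p0), (C / 2) / (C + p0$eps),
               tolerance = 1e-9)
  # disabled oophagy reports 0 under total shortfall
  poff <- colony_params(oophagy = FALSE)
  expect_equal(oophagy_factor(s2, poff), 0)
})

test_that("laying schedule opens and closes the printed windows", {
  r10 <- laying_schedule(10, p0)
  expect_equal(c(r10$W, r10$M, r10$G), c(8.5, 0, 0))
  r42 <- laying_schedule(42, p0)  # overlap window between T* and T**
  expect_equal(c(r42$W, r42$M, r42$G), c(8.5, 2, 2.6))
  r50 <- laying_schedule(50, p0)  # worker laying ended at day 44
  expect_equal(c(r50$W, r50$M, r50$G), c(0, 2, 2.6))
  out <- laying_schedule(125, p0) # past season end
  expect_equal(c(out$W, out$M, out$G), c(0, 0, 0))
  # edge ramps are centred: integral of the window is preserved
  tt <- seq(43.9, 44.1, by = 1e-4)
  wk <- laying_schedule(tt, p0)$W
  expect_equal(mean(wk) * 0.2, 8.5 * 0.1, tolerance = 1e-3)
})

test_that("effective laying rates combine oophagy and brood factors", {
  s <- colony_state(N = 1e3, P = 1e3)
  expect_equal(unname(effective_laying_rates(42, s, p0)["W"]), 8.5)
  # total shortfall silences laying
  s0 <- colony_state(N = 0, P = 0, L1w = 100)
  expect_lt(effective_laying_rates(42, s0, p0)[["W"]], 1e-2)
  # multiplicative composition: b_W * (1 - D) * brood factor
  sc <- exposure_scenario(brood2_reduction = 0.1)
  C <- pollen_demand(colony_state(L1w = 100), p0)
  sh <- colony_state(N = 1e3, P = 0.8 * C, L1w = 100)
  D <- oophagy_factor(sh, p0)
  expect_equal(unname(effective_laying_rates(15, sh, p0, sc)["W"]),
               8.5 * (1 - D) * 0.9, tolerance = 1e-9)
  expect_equal(brood_factor(c(5, 15, 30), sc), c(1, 0.9, 1))
})
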