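# Independent oracles used by the property and acceptance tests. Both are
# deliberately self-contained re-derivations of the model's bookkeeping and do
# not call the package's flux or rhs functions.

# --- discrete-day cohort bookkeeping -----------------------------------------
# With larval mortality and resource feedback disabled, every egg laid on day
# d emerges as an adult during [d + A, d + A + 1). Laying rates are piecewise
# constant on integer days (evaluated at day midpoints, away from the narrow
# window ramps), so cumulative emergence by time T is an exact sum with a
# fractional last day.
cohort_emerged_by <- function(Tend, caste = c("worker", "male", "gyne"),
                              params = colony_params(), scenario = NULL) {
  caste <- match.arg(caste)
  A <- switch(caste, worker = 22, male = 26, gyne = 30)
  lay_rate <- function(d) {
    mid <- d + 0.5
    if (caste == "worker") {
      r <- if (mid >= params$T_s && mid < params$T_dstar) params$b_W else 0
      if (!is.null(scenario)) {
        w <- scenario$brood_windows
        if (mid >= w[1] && mid < w[2]) r <- r * (1 - scenario$brood1_reduction)
        if (mid >= w[2] && mid < w[3]) r <- r * (1 - scenario$brood2_reduction)
      }
      r
    } else {
      b <- if (caste == "male") params$b_M else params$b_G
      if (mid >= params$T_star && mid < params$T_W) b else 0
    }
  }
  days <- seq(floor(params$T_s), ceiling(Tend))
  total <- 0
  for (d in days) {
    frac <- min(1, max(0, Tend - (d + A)))
    total <- total + lay_rate(d) * frac
  }
  total
}

# --- fixed-step Euler method of steps ----------------------------------------
# Full re-implementation of the colony equations on a uniform mesh (step h
# dividing 1 day). Delayed quantities are read from stored per-step arrays;
# times before t0 use the analytic pre-start history. Supports the default
# parameterisation (deficit ejection form) plus forced mortality, disabled
# oophagy and the exposure channels.
euler_colony <- function(params = colony_params(), scenario = NULL,
                         h = 0.01, out_by = 1) {
  stopifnot(abs(1 / h - round(1 / h)) < 1e-9)
  p <- params
  sc <- if (is.null(scenario)) exposure_scenario() else scenario
  t0 <- p$T_s + 22
  nstep <- round((p$T_W - t0) / h)
  times <- t0 + h * (0:nstep)

  win <- function(s, a, b, r) {
    if (r <= 0) return(as.numeric(s >= a & s < b))
    u <- min(max((s - a) / r + 0.5, 0), 1)
    v <- min(max((b - s) / r + 0.5, 0), 1)
    u * v
  }
  brood <- function(s) {
    w <- sc$brood_windows
    if (s >= w[1] && s < w[2]) 1 - sc$brood1_reduction
    else if (s >= w[2] && s < w[3]) 1 - sc$brood2_reduction else 1
  }
  # pre-start laying history (no oophagy, Phi = 0)
  pre_b <- function(s)
    c(p$b_W * win(s, p$T_s, p$T_dstar, p$switch_ramp) * brood(s),
      p$b_M * win(s, p$T_star, p$T_W, p$switch_ramp),
      p$b_G * win(s, p$T_star, p$T_W, p$switch_ramp))

  # states: N P W L1w L2w L1m L2m L1g L2g L3g M G Phiw Phim Phig Ew
  X <- matrix(0, nstep + 1, 16)
  Bh <- matrix(0, nstep + 1, 3)  # effective laying rates along the mesh
  # initial larvae: integrate pre-start laying over the age windows
  intb <- function(a, b, comp) {
    if (b <= a) return(0)
    ss <- seq(a, b, by = h)
    sum(vapply(utils::head(ss, -1) + h / 2, function(s) pre_b(s)[comp],
               numeric(1))) * h
  }
  X[1, ] <- c(p$N0, p$P0, 0,
              intb(t0 - 10, t0 - 4, 1), intb(t0 - 13, t0 - 10, 1),
              intb(t0 - 12, t0 - 4, 2), intb(t0 - 15, t0 - 12, 2),
              intb(t0 - 9, t0 - 4, 3), intb(t0 - 13, t0 - 9, 3),
              intb(t0 - 17, t0 - 13, 3),
              0, 0, 0, 0, 0, 0)

  lagB <- function(i, lag, comp) {
    j <- i - round(lag / h)
    if (j >= 1) Bh[j, comp] else pre_b(times[1] + h * (j - 1))[comp]
  }
  lagPhi <- function(i, lag, comp) {
    j <- i - round(lag / h)
    if (j >= 1) X[j, 12 + comp] else 0
  }
  phiN <- 1 - sc$forage_reduction_N
  phiP <- 1 - sc$forage_reduction_P
  cullstep <- if (!is.null(sc$acute_day)) round((sc$acute_day - t0) / h) + 1
    else -1

  for (i in seq_len(nstep + 1)) {
    t <- times[i]
    if (i == cullstep) X[i, 3] <- X[i, 3] * (1 - sc$acute_kill_fraction)
    y <- X[i, ]
    L <- pmax(y[4:10], 0)
    C <- p$c1 * (L[1] + L[3] + L[5]) + p$c2 * L[2] + p$c3 * L[4] +
      p$c4 * L[6] + p$c5 * L[7]
    Ltot <- sum(L)
    W <- max(y[3], 0)
    Dn <- min(max((Ltot - p$Z * W) / (Ltot + p$eps), 0), 1)
    Dm <- min(max(max((C - max(y[2], 0)) / (C + p$eps),
                      (2 * C - max(y[1], 0)) / (2 * C + p$eps)), 0), 1)
    Do <- if (isTRUE(p$oophagy)) Dm else 0
    mu <- if (!is.null(p$mu_L_override)) p$mu_L_override else
      if (identical(p$ejection, "worker_capped"))
        (p$alpha * Dn + p$beta * Dm) * W / (Ltot + p$eps)
      else p$alpha * Dn + p$beta * Dm
    Bh[i, ] <- c(p$b_W * win(t, p$T_s, p$T_dstar, p$switch_ramp) * brood(t),
                 p$b_M * win(t, p$T_star, p$T_W, p$switch_ramp),
                 p$b_G * win(t, p$T_star, p$T_W, p$switch_ramp)) * (1 - Do)
    if (i > nstep) break

    gN <- max(y[1], 0) / (max(y[1], 0) + p$K_store)
    gP <- max(y[2], 0) / (max(y[2], 0) + p$K_store)
    R <- max(y[11], 0) + max(y[12], 0)
    # caste bookkeeping: (entry ages, total age, pupa) per caste
    em <- numeric(3); fl <- list()
    spec <- list(list(a = c(4, 10, 13), A = 22, pu = 9),
                 list(a = c(4, 12, 15), A = 26, pu = 11),
                 list(a = c(4, 9, 13, 17), A = 30, pu = 13))
    for (r in 1:3) {
      s <- spec[[r]]
      nj <- length(s$a)
      f <- numeric(nj)
      f[1] <- lagB(i, s$a[1], r)
      for (j in 2:nj)
        f[j] <- lagB(i, s$a[j], r) * exp(lagPhi(i, s$a[j] - 4, r) -
                                           y[12 + r])
      fl[[r]] <- f
      em[r] <- lagB(i, s$A, r) * exp(lagPhi(i, s$A - 4, r) -
                                       lagPhi(i, s$pu, r))
    }
    fw <- fl[[1]]; fm <- fl[[2]]; fg <- fl[[3]]
    dy <- c(phiN * p$b_NW * W - (p$mu_NW * W + p$mu_NR * R + 2 * C) * gN,
            phiP * p$b_PW * W - (p$mu_PW * W + p$mu_PR * R + C) * gP,
            em[1] - p$mu_W * W,
            fw[1] - fw[2] - mu * y[4], fw[2] - fw[3] - mu * y[5],
            fm[1] - fm[2] - mu * y[6], fm[2] - fm[3] - mu * y[7],
            fg[1] - fg[2] - mu * y[8], fg[2] - fg[3] - mu * y[9],
            fg[3] - fg[4] - mu * y[10],
            em[2], em[3], mu, mu, mu, em[1])
    X[i + 1, ] <- y + h * dy
  }
  keep <- which(round((times - t0) / h) %% round(out_by / h) == 0 |
                  seq_along(times) == nstep + 1)
  out <- data.frame(time = times[keep], X[keep, , drop = FALSE])
  names(out) <- c("time", "N", "P", "W", "L1w", "L2w", "L1m", "L2m",
                  "L1g", "L2g", "L3g", "M", "G", "PhiW", "PhiM", "PhiG", "Ew")
  out
}
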