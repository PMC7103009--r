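# History contract used by the delayed terms: a function(s) returning
#   list(bstar = c(W=, M=, G=),  # effective laying rates at time s (eggs/day)
#        Phi   = c(w=, m=, g=))  # cumulative per-larva mortality integrals
# For s before the simulation start this is the analytic pre-start history;
# afterwards it is reconstructed from the stored solution.

#' Pre-start colony history
#'
#' The assumed history before the first workers emerge: the founding queen
#' lays worker eggs at the scheduled rate from the first day of spring
#' (reduced only by any brood-window factor of the scenario), no male or gyne
#' eggs exist before the switch time, and no larvae are lost, so the
#' cumulative mortality integrals are 0.
#'
#' @param s time (days since first day of spring), `s < t0`.
#' @param params a [colony_params()] object.
#' @param scenario an [exposure_scenario()] or `NULL`.
#' @return A history record: `list(bstar = c(W, M, G), Phi = c(w, m, g))`.
#' @export
prestart_history <- function(s, params, scenario = NULL) {
  bw <- params$b_W * win1(s, params$T_s, params$T_dstar, params$switch_ramp)
  rg <- win1(s, params$T_star, params$T_W, params$switch_ramp)
  bf <- 1
  if (!is.null(scenario)) {
    w <- scenario$brood_windows
    if (s >= w[1] && s < w[2]) bf <- 1 - scenario$brood1_reduction
    else if (s >= w[2] && s < w[3]) bf <- 1 - scenario$brood2_reduction
  }
  list(bstar = c(W = bw * bf, M = params$b_M * rg, G = params$b_G * rg),
       Phi = c(w = 0, m = 0, g = 0))
}

# Exact integral of the pre-start worker laying rate over [a, b]: the rate is
# piecewise constant with knots at the season anchors and brood-window edges.
integrate_prestart_laying <- function(a, b, params, scenario, caste = "W") {
  if (b <= a) return(0)
  knots <- sort(unique(c(a, b, params$T_s, params$T_star, params$T_dstar,
                         params$T_W,
                         if (!is.null(scenario)) scenario$brood_windows)))
  knots <- knots[knots >= a & knots <= b]
  if (knots[1] > a) knots <- c(a, knots)
  if (knots[length(knots)] < b) knots <- c(knots, b)
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    mid <- (knots[i] + knots[i + 1L]) / 2
    rate <- prestart_history(mid, params, scenario)$bstar[[caste]]
    total <- total + rate * (knots[i + 1L] - knots[i])
  }
  total
}

#' Initial conditions of the colony simulation
#'
#' The simulation starts when the first workers emerge, `t0 = T_s + 22` (the
#' worker emergence age). At that moment there are no adult workers, males or
#' gynes yet, stores equal `N0`/`P0`, the mortality integrals are 0, and the
#' larval compartments are pre-filled from the pre-start laying history: each
#' substage holds the eggs laid during the corresponding age window. With the
#' default schedule and laying rate this gives 51 first-stage and 25.5
#' second-stage worker larvae.
#'
#' @param params a [colony_params()] object.
#' @param schedule a [stage_schedule()] object.
#' @param scenario an [exposure_scenario()] or `NULL` (brood reductions act on
#'   the pre-start laying history and therefore on the initial larvae).
#' @return `list(t0, state, history)` where `history(s)` is the analytic
#'   pre-start history function.
#' @examples
#' ic <- initial_conditions(colony_params(), stage_schedule())
#' ic$state[c("L1w", "L2w")]  # 51, 25.5
#' @export
initial_conditions <- function(params, schedule = stage_schedule(),
                               scenario = NULL) {
  t0 <- params$T_s + schedule$worker$total_age
  y <- colony_state(N = params$N0, P = params$P0)
  castes <- c(worker = "W", male = "M", gyne = "G")
  slots <- list(worker = c("L1w", "L2w"), male = c("L1m", "L2m"),
                gyne = c("L1g", "L2g", "L3g"))
  for (k in names(castes)) {
    cs <- schedule[[k]]
    for (j in seq_len(cs$n_sub)) {
      y[[slots[[k]][j]]] <- integrate_prestart_laying(
        t0 - cs$entry_ages[j + 1L], t0 - cs$entry_ages[j],
        params, scenario, caste = castes[[k]])
    }
  }
  list(t0 = t0, state = y,
       history = function(s) prestart_history(s, params, scenario))
}

#' Adult emergence flux
#'
#' Rate at which adults of a caste emerge at time `t`: the effective laying
#' rate one emergence age earlier, discounted by larval mortality accumulated
#' between the cohort's larval-phase start and its pupation,
#' `b*_k(t - A) exp[Phi_k(t - (A - egg)) - Phi_k(t - pupa)]`
#' (worker: `b*_W(t-22) exp[Phi_w(t-18) - Phi_w(t-9)]`). All lags derive from
#' the stage schedule.
#'
#' @param t current time (days).
#' @param history history function (see [prestart_history()] for the record
#'   contract); must cover `[t - total_age, t)`.
#' @param caste `"worker"`, `"male"` or `"gyne"`.
#' @param schedule a [stage_schedule()] object.
#' @return Emergence rate (adults/day).
#' @export
emergence_flux <- function(t, history, caste = c("worker", "male", "gyne"),
                           schedule = stage_schedule()) {
  caste <- match.arg(caste)
  cs <- schedule[[caste]]
  key <- substr(caste, 1, 1)
  laid <- history(t - cs$total_age)
  phi_start <- history(t - (cs$total_age - cs$egg))$Phi[[key]]
  phi_pupation <- history(t - cs$pupa)$Phi[[key]]
  laid$bstar[[toupper(key)]] * exp(phi_start - phi_pupation)
}

#' Larval substage transfer fluxes
#'
#' The delayed inflow into each larval substage of a caste, plus the pupation
#' outflow as the last element. The inflow to substage `j` at time `t` is the
#' cohort laid `a_j` days earlier (where `a_j` is the substage entry age),
#' discounted by mortality accumulated since its larval phase began:
#' `b*_k(t - a_j) exp[Phi_k(t - a_j + egg) - Phi_k(t)]`. For workers this
#' gives inflow `b*_W(t-4)`, stage-1 to stage-2 transfer
#' `b*_W(t-10) exp[Phi_w(t-6) - Phi_w(t)]` and pupation flux
#' `b*_W(t-13) exp[Phi_w(t-9) - Phi_w(t)]`.
#'
#' @inheritParams emergence_flux
#' @param Phi_now current value of the caste's cumulative mortality integral.
#' @return Numeric vector of length `n_sub + 1`: inflow into each substage,
#'   then the pupation outflow (larvae/day).
#' @export
stage_transfer_fluxes <- function(t, history,
                                  caste = c("worker", "male", "gyne"),
                                  schedule = stage_schedule(), Phi_now = 0) {
  caste <- match.arg(caste)
  cs <- schedule[[caste]]
  key <- substr(caste, 1, 1)
  ckey <- toupper(key)
  out <- numeric(length(cs$entry_ages))
  for (j in seq_along(cs$entry_ages)) {
    a <- cs$entry_ages[j]
    rec <- history(t - a)
    phi_start <- if (a == cs$egg) Phi_now else
      history(t - a + cs$egg)$Phi[[key]]
    out[j] <- rec$bstar[[ckey]] * exp(phi_start - Phi_now)
  }
  out
}

# Smooth store-limiting factor: consumption is throttled as a store empties
# so stocks cannot run negative.
g_store <- function(S, K) {
  S <- max(S, 0)
  S / (S + K)
}

#' Right-hand side of the colony DDE system
#'
#' Assembles the time derivative of the full state: resource balances
#' (collection minus worker, adult-reproductive and larval consumption, all
#' throttled by the store-limiting factor), delayed larval substage transfers
#' and adult emergences, worker death, per-larva ejection losses, and the
#' cumulative mortality and emergence accountants.
#'
#' @param t current time (days since first day of spring).
#' @param y named state vector (see [colony_state()]).
#' @param params a [colony_params()] object.
#' @param scenario an [exposure_scenario()] or `NULL` for control.
#' @param schedule a [stage_schedule()] object.
#' @param history history function covering `[t - 30, t)` (see
#'   [prestart_history()]).
#' @return Named derivative vector, same layout as `y`.
#' @export
colony_rhs <- function(t, y, params, scenario = NULL,
                       schedule = stage_schedule(), history) {
  # memoise history lookups: the three castes share several lag offsets
  memo <- new.env(hash = TRUE, parent = emptyenv())
  h <- function(s) {
    k <- as.character(s)
    v <- memo[[k]]
    if (is.null(v)) {
      v <- history(s)
      memo[[k]] <- v
    }
    v
  }

  sig <- regulation_signal(y, params)
  W <- max(y[["W"]], 0)
  mu_L <- larval_mortality_rate(y, params)

  phi_N <- if (is.null(scenario)) 1 else 1 - scenario$forage_reduction_N
  phi_P <- if (is.null(scenario)) 1 else 1 - scenario$forage_reduction_P
  gN <- g_store(y[["N"]], params$K_store)
  gP <- g_store(y[["P"]], params$K_store)

  emw <- emergence_flux(t, h, "worker", schedule)
  emm <- emergence_flux(t, h, "male", schedule)
  emg <- emergence_flux(t, h, "gyne", schedule)
  fw <- stage_transfer_fluxes(t, h, "worker", schedule, y[["PhiW"]])
  fm <- stage_transfer_fluxes(t, h, "male", schedule, y[["PhiM"]])
  fg <- stage_transfer_fluxes(t, h, "gyne", schedule, y[["PhiG"]])

  R <- max(y[["M"]], 0) + max(y[["G"]], 0)
  dy <- c(
    phi_N * params$b_NW * W - (params$mu_NW * W + params$mu_NR * R +
                                 sig$C_N) * gN,
    phi_P * params$b_PW * W - (params$mu_PW * W + params$mu_PR * R +
                                 sig$C) * gP,
    emw - params$mu_W * W,
    fw[1] - fw[2] - mu_L * y[["L1w"]],
    fw[2] - fw[3] - mu_L * y[["L2w"]],
    fm[1] - fm[2] - mu_L * y[["L1m"]],
    fm[2] - fm[3] - mu_L * y[["L2m"]],
    fg[1] - fg[2] - mu_L * y[["L1g"]],
    fg[2] - fg[3] - mu_L * y[["L2g"]],
    fg[3] - fg[4] - mu_L * y[["L3g"]],
    emm,
    emg,
    mu_L, mu_L, mu_L,
    emw
  )
  if (any(!is.finite(dy)))
    stop("non-finite derivative at t = ", t, "; state: ",
         paste(sprintf("%s=%.4g", names(y), y), collapse = ", "),
         call. = FALSE)
  names(dy) <- state_names()
  dy
}

# Specialised derivative closure for the integration hot path: identical
# algebra to colony_rhs() (asserted by tests), with parameters hoisted to
# locals, precomputed lag-offset index maps, and one history lookup per unique
# offset. `lagged(s)` must return the full state vector for s > t0.
make_colony_rhs <- function(params, scenario, schedule, t0, lagged) {
  p <- params
  sc <- if (is.null(scenario)) control_scenario() else scenario
  c1 <- p$c1; c2 <- p$c2; c3 <- p$c3; c4 <- p$c4; c5 <- p$c5
  eps <- p$eps; Z <- p$Z; alpha <- p$alpha; beta <- p$beta
  b_NW <- p$b_NW; b_PW <- p$b_PW; mu_NW <- p$mu_NW; mu_PW <- p$mu_PW
  mu_NR <- p$mu_NR; mu_PR <- p$mu_PR
  bW <- p$b_W; bM <- p$b_M; bG <- p$b_G; mu_W <- p$mu_W
  Ts <- p$T_s; Tst <- p$T_star; Tds <- p$T_dstar; TW <- p$T_W
  ramp <- p$switch_ramp; Ks <- p$K_store
  oo <- isTRUE(p$oophagy); muov <- p$mu_L_override
  capped <- identical(p$ejection, "worker_capped")
  phiN <- 1 - sc$forage_reduction_N; phiP <- 1 - sc$forage_reduction_P
  w1 <- sc$brood_windows[1]; w2 <- sc$brood_windows[2]
  w3 <- sc$brood_windows[3]
  br1 <- 1 - sc$brood1_reduction; br2 <- 1 - sc$brood2_reduction

  castes <- c("worker", "male", "gyne")
  ages <- lapply(castes, function(k) schedule[[k]]$entry_ages)
  eggs <- vapply(castes, function(k) schedule[[k]]$egg, numeric(1))
  tots <- vapply(castes, function(k) schedule[[k]]$total_age, numeric(1))
  pups <- vapply(castes, function(k) schedule[[k]]$pupa, numeric(1))
  nsub <- lengths(ages) - 1L
  # unique lag offsets; per caste: positions of the laying-rate lookups
  # (entry ages + emergence age) and of the Phi lookups (larval-phase starts,
  # emergence-cohort larval start, pupation)
  boffs <- lapply(1:3, function(r) c(ages[[r]], tots[r]))
  poffs <- lapply(1:3, function(r) c(ages[[r]][-1] - eggs[r],
                                     tots[r] - eggs[r], pups[r]))
  uoffs <- sort(unique(c(unlist(boffs), unlist(poffs))))
  K <- length(uoffs)
  bpos <- lapply(1:3, function(r) match(boffs[[r]], uoffs))
  ppos <- lapply(1:3, function(r) match(poffs[[r]], uoffs))

  # effective laying rates (W, M, G) from an unnamed lagged state
  bstar_loc <- function(s, ys) {
    keep <- 1
    if (oo) {
      C <- c1 * (max(ys[4L], 0) + max(ys[6L], 0) + max(ys[8L], 0)) +
        c2 * max(ys[5L], 0) + c3 * max(ys[7L], 0) + c4 * max(ys[9L], 0) +
        c5 * max(ys[10L], 0)
      d <- max((C - max(ys[2L], 0)) / (C + eps),
               (2 * C - max(ys[1L], 0)) / (2 * C + eps))
      if (d > 1) d <- 1 else if (d < 0) d <- 0
      keep <- 1 - d
    }
    bf <- if (s >= w1 && s < w2) br1 else if (s >= w2 && s < w3) br2 else 1
    c(bW * win1(s, Ts, Tds, ramp) * keep * bf,
      bM * win1(s, Tst, TW, ramp) * keep,
      bG * win1(s, Tst, TW, ramp) * keep)
  }

  function(t, y) {
    B <- matrix(0, 3L, K)
    PH <- matrix(0, 3L, K)
    for (q in seq_len(K)) {
      s <- t - uoffs[q]
      if (s <= t0 + 1e-12) {
        bf <- if (s >= w1 && s < w2) br1
          else if (s >= w2 && s < w3) br2 else 1
        B[1L, q] <- bW * win1(s, Ts, Tds, ramp) * bf
        B[2L, q] <- bM * win1(s, Tst, TW, ramp)
        B[3L, q] <- bG * win1(s, Tst, TW, ramp)
      } else {
        ys <- lagged(s)
        B[, q] <- bstar_loc(s, ys)
        PH[1L, q] <- ys[13L]
        PH[2L, q] <- ys[14L]
        PH[3L, q] <- ys[15L]
      }
    }

    L4 <- max(y[4L], 0); L5 <- max(y[5L], 0); L6 <- max(y[6L], 0)
    L7 <- max(y[7L], 0); L8 <- max(y[8L], 0); L9 <- max(y[9L], 0)
    L10 <- max(y[10L], 0)
    C <- c1 * (L4 + L6 + L8) + c2 * L5 + c3 * L7 + c4 * L9 + c5 * L10
    Ltot <- L4 + L5 + L6 + L7 + L8 + L9 + L10
    W <- max(y[3L], 0)
    if (is.null(muov)) {
      Dn <- (Ltot - Z * W) / (Ltot + eps)
      if (Dn > 1) Dn <- 1 else if (Dn < 0) Dn <- 0
      Dm <- max((C - max(y[2L], 0)) / (C + eps),
                (2 * C - max(y[1L], 0)) / (2 * C + eps))
      if (Dm > 1) Dm <- 1 else if (Dm < 0) Dm <- 0
      mu <- alpha * Dn + beta * Dm
      if (capped) mu <- mu * W / (Ltot + eps)
    } else mu <- muov
    SN <- max(y[1L], 0); SP <- max(y[2L], 0)
    gN <- SN / (SN + Ks)
    gP <- SP / (SP + Ks)

    phin <- c(y[13L], y[14L], y[15L])
    em <- numeric(3L)
    fl <- vector("list", 3L)
    for (r in 1:3) {
      bp <- bpos[[r]]; pp <- ppos[[r]]
      nj <- nsub[r] + 1L  # substage inflows + pupation outflow
      f <- numeric(nj)
      f[1L] <- B[r, bp[1L]]
      if (nj > 1L)
        for (j in 2:nj)
          f[j] <- B[r, bp[j]] * exp(PH[r, pp[j - 1L]] - phin[r])
      fl[[r]] <- f
      em[r] <- B[r, bp[nj + 1L]] *
        exp(PH[r, pp[nj]] - PH[r, pp[nj + 1L]])
    }
    fw <- fl[[1L]]; fm <- fl[[2L]]; fg <- fl[[3L]]

    R <- max(y[11L], 0) + max(y[12L], 0)
    dy <- c(
      phiN * b_NW * W - (mu_NW * W + mu_NR * R + 2 * C) * gN,
      phiP * b_PW * W - (mu_PW * W + mu_PR * R + C) * gP,
      em[1L] - mu_W * W,
      fw[1L] - fw[2L] - mu * y[4L],
      fw[2L] - fw[3L] - mu * y[5L],
      fm[1L] - fm[2L] - mu * y[6L],
      fm[2L] - fm[3L] - mu * y[7L],
      fg[1L] - fg[2L] - mu * y[8L],
      fg[2L] - fg[3L] - mu * y[9L],
      fg[3L] - fg[4L] - mu * y[10L],
      em[2L], em[3L],
      mu, mu, mu,
      em[1L]
    )
    if (any(!is.finite(dy)))
      stop("non-finite derivative at t = ", t, "; state: ",
           paste(sprintf("%s=%.4g", state_names(), y), collapse = ", "),
           call. = FALSE)
    dy
  }
}
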