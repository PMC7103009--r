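# State vector layout used throughout the model. The first twelve entries are
# the colony state variables; PhiW/PhiM/PhiG are the cumulative per-larva
# mortality integrals and Ew the cumulative count of emerged adult workers
# (M and G are already cumulative).
state_names <- function() {
  c("N", "P", "W",
    "L1w", "L2w", "L1m", "L2m", "L1g", "L2g", "L3g",
    "M", "G", "PhiW", "PhiM", "PhiG", "Ew")
}

larvae_names <- function() c("L1w", "L2w", "L1m", "L2m", "L1g", "L2g", "L3g")

#' Colony state vector
#'
#' Builds a named state vector in the layout the model uses: nectar `N` (ml),
#' pollen `P` (g), workers `W`, the seven larval substage counts, cumulative
#' adult males `M` and gynes `G`, the cumulative per-larva mortality integrals
#' `PhiW`, `PhiM`, `PhiG`, and the cumulative worker emergence counter `Ew`.
#'
#' @param ... named components; anything not supplied is 0.
#' @return Named numeric vector of length 16.
#' @examples
#' colony_state(N = 10, P = 5, L1w = 51, L2w = 25.5)
#' @export
colony_state <- function(...) {
  y <- stats::setNames(numeric(length(state_names())), state_names())
  args <- list(...)
  if (length(args)) {
    bad <- setdiff(names(args), state_names())
    if (length(bad) || is.null(names(args)) || any(names(args) == ""))
      stop("unknown state component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    y[names(args)] <- unlist(args)
  }
  y
}

#' Projected larval pollen demand
#'
#' The colony-wide pollen demand rate of the current larval population:
#' `C = c1 (L1w + L1m + L1g) + c2 L2w + c3 L2m + c4 L2g + c5 L3g` (g/day).
#'
#' Larval counts are clamped at 0, so solver trial states with tiny negative
#' excursions are tolerated; genuinely negative counts (beyond integration
#' roundoff) are a contract violation.
#'
#' @param state named state vector (see [colony_state()]).
#' @param params a [colony_params()] object.
#' @return Demand rate in g/day.
#' @export
pollen_demand <- function(state, params) {
  L <- pmax(state[larvae_names()], 0)
  neg <- state[larvae_names()] < -0.05
  if (any(neg))
    stop("negative larval counts in state: ",
         paste(sprintf("%s=%.6g", larvae_names()[neg],
                       state[larvae_names()][neg]), collapse = ", "),
         call. = FALSE)
  unname(params$c1 * (L[["L1w"]] + L[["L1m"]] + L[["L1g"]]) +
           params$c2 * L[["L2w"]] + params$c3 * L[["L2m"]] +
           params$c4 * L[["L2g"]] + params$c5 * L[["L3g"]])
}

#' Projected larval nectar demand
#'
#' Larvae consume nectar at twice the pollen rate, so the nectar demand is
#' `C_N = 2 C` (ml/day against the g/day pollen figure, in native units).
#'
#' @inheritParams pollen_demand
#' @return Demand rate in ml/day.
#' @export
nectar_demand <- function(state, params) 2 * pollen_demand(state, params)

# Relative shortfall of supply against demand, clamped to [0, 1].
# eps guards the denominator when demand is ~0.
deficit_factor <- function(demand, supply, eps) {
  min(max((demand - supply) / (demand + eps), 0), 1)
}

#' Regulation signal of the colony
#'
#' Evaluates the quantities that drive larval ejection and oophagy: projected
#' pollen and nectar demand, the total larval count against the care capacity
#' `Z W`, and the three deficit factors in `[0, 1]`:
#' * `D_neglect` -- relative excess of larvae over the care capacity;
#' * `D_malnut` -- relative shortfall of stores against demand (pollen and
#'   nectar channels combined by their maximum);
#' * `D_oophagy` -- the same resource-shortfall comparison, driving egg
#'   cannibalism (0 when [colony_params()] disables oophagy).
#'
#' @inheritParams pollen_demand
#' @return A list with components `C`, `C_N`, `L_tot`, `capacity`,
#'   `D_neglect`, `D_malnut`, `D_oophagy`.
#' @export
regulation_signal <- function(state, params) {
  C <- pollen_demand(state, params)
  C_N <- 2 * C
  L_tot <- sum(pmax(state[larvae_names()], 0))
  capacity <- params$Z * max(state[["W"]], 0)
  D_neglect <- deficit_factor(L_tot, capacity, params$eps)
  D_malnut <- max(deficit_factor(C, max(state[["P"]], 0), params$eps),
                  deficit_factor(C_N, max(state[["N"]], 0), params$eps))
  list(C = C, C_N = C_N, L_tot = L_tot, capacity = capacity,
       D_neglect = D_neglect, D_malnut = D_malnut,
       D_oophagy = if (isTRUE(params$oophagy)) D_malnut else 0)
}

#' Per-larva ejection (mortality) rate
#'
#' Larvae are lost when there are too many for the workforce to care for
#' (negligence) or when stores fall short of projected consumption
#' (malnutrition). Under the default `"deficit"` form the per-larva rate is
#' `mu_L = alpha D_neglect + beta D_malnut` -- a total care or food deficit
#' kills larvae at the maximum rate however few workers remain. Under the
#' `"worker_capped"` form losses are active ejections whose colony-wide fluxes
#' are capped at `alpha W` and `beta W` larvae/day, giving
#' `mu_L = (alpha D_neglect + beta D_malnut) W / (L_tot + eps)`.
#' If `mu_L_override` is set in the parameters it is returned unconditionally.
#'
#' @inheritParams pollen_demand
#' @return Per-larva rate (1/day).
#' @export
larval_mortality_rate <- function(state, params) {
  if (!is.null(params$mu_L_override)) return(params$mu_L_override)
  sig <- regulation_signal(state, params)
  base <- params$alpha * sig$D_neglect + params$beta * sig$D_malnut
  if (identical(params$ejection, "worker_capped")) {
    W <- max(state[["W"]], 0)
    base * W / (sig$L_tot + params$eps)
  } else base
}

#' Oophagy factor
#'
#' Fraction of laid eggs consumed under resource shortfall, computed from the
#' same clamped demand-versus-supply comparison as malnutrition ejection.
#'
#' @inheritParams pollen_demand
#' @return A fraction in `[0, 1]`.
#' @export
oophagy_factor <- function(state, params) {
  regulation_signal(state, params)$D_oophagy
}

#' Scheduled (raw) egg-laying rates
#'
#' The queen lays worker eggs at `b_W` from the first day of spring until the
#' end of worker laying (`[T_s, T_dstar)`), and male and gyne eggs at `b_M`
#' and `b_G` from the switch time until winter (`[T_star, T_W)`). Outside the
#' windows the rates are 0; the window edges carry a narrow centered linear
#' ramp of width `switch_ramp` (default 0.01 day) so the rates are continuous
#' in time (see [colony_params()]).
#'
#' @param t day since the first day of spring (may be a vector).
#' @param params a [colony_params()] object.
#' @return A list with numeric components `W`, `M`, `G` (eggs/day), each the
#'   length of `t`.
#' @examples
#' laying_schedule(42, colony_params())  # overlap window: all three castes
#' @export
laying_schedule <- function(t, params) {
  wk <- smooth_window(t, params$T_s, params$T_dstar, params$switch_ramp)
  rg <- smooth_window(t, params$T_star, params$T_W, params$switch_ramp)
  list(W = params$b_W * wk, M = params$b_M * rg, G = params$b_G * rg)
}

# Window indicator with centered linear edge ramps of width r: 0.5 exactly at
# each edge, 0/1 at r/2 beyond/inside. r = 0 gives the sharp half-open window.
smooth_window <- function(t, a, b, r) {
  if (r <= 0) return(as.numeric(t >= a & t < b))
  up <- function(x) pmin(pmax(x / r + 0.5, 0), 1)
  up(t - a) * up(b - t)
}

# scalar version of smooth_window for the integration hot path
win1 <- function(t, a, b, r) {
  if (r <= 0) return(if (t >= a && t < b) 1 else 0)
  u <- (t - a) / r + 0.5
  if (u < 0) u <- 0 else if (u > 1) u <- 1
  v <- (b - t) / r + 0.5
  if (v < 0) v <- 0 else if (v > 1) v <- 1
  u * v
}

# Fixed positions of state components in the (unnamed) integration vector;
# must agree with state_names().
.i <- list(N = 1L, P = 2L, W = 3L, L = 4:10, L1w = 4L, L2w = 5L, L1m = 6L,
           L2m = 7L, L1g = 8L, L2g = 9L, L3g = 10L, M = 11L, G = 12L,
           PhiW = 13L, PhiM = 14L, PhiG = 15L, Ew = 16L)

# Effective laying rates from an unnamed state vector at time s -- the
# integration hot path equivalent of effective_laying_rates(); kept in exact
# algebraic agreement with the documented functions (asserted in tests).
bstar_fast <- function(s, ys, params, scenario) {
  C <- params$c1 * (max(ys[4L], 0) + max(ys[6L], 0) + max(ys[8L], 0)) +
    params$c2 * max(ys[5L], 0) + params$c3 * max(ys[7L], 0) +
    params$c4 * max(ys[9L], 0) + params$c5 * max(ys[10L], 0)
  keep <- 1
  if (isTRUE(params$oophagy)) {
    dP <- (C - max(ys[2L], 0)) / (C + params$eps)
    dN <- (2 * C - max(ys[1L], 0)) / (2 * C + params$eps)
    d <- max(dP, dN)
    if (d > 1) d <- 1 else if (d < 0) d <- 0
    keep <- 1 - d
  }
  bw <- params$b_W * win1(s, params$T_s, params$T_dstar, params$switch_ramp)
  rg <- win1(s, params$T_star, params$T_W, params$switch_ramp)
  bf <- 1
  if (!is.null(scenario)) {
    w <- scenario$brood_windows
    if (s >= w[1] && s < w[2]) bf <- 1 - scenario$brood1_reduction
    else if (s >= w[2] && s < w[3]) bf <- 1 - scenario$brood2_reduction
  }
  c(W = bw * keep * bf, M = params$b_M * rg * keep, G = params$b_G * rg * keep)
}

#' Brood-window reduction factor on worker laying
#'
#' Sublethal exposure of the queen reduces worker egg laying within the two
#' brood windows: eggs laid on days `[0, 13)` form brood 1 (emerging from day
#' 22) and eggs laid on days `[13, 22)` form brood 2 (emerging from day 35).
#'
#' @param t laying day (vector allowed).
#' @param scenario an [exposure_scenario()] object (or `NULL` for control).
#' @return Multiplier in `[0, 1]`, same length as `t`.
#' @export
brood_factor <- function(t, scenario = NULL) {
  if (is.null(scenario)) return(rep(1, length(t)))
  f <- rep(1, length(t))
  w <- scenario$brood_windows
  f[t >= w[1] & t < w[2]] <- 1 - scenario$brood1_reduction
  f[t >= w[2] & t < w[3]] <- 1 - scenario$brood2_reduction
  f
}

#' Effective egg-laying rates
#'
#' The laying rates that actually produce larvae: the scheduled rates reduced
#' by oophagy and, for worker eggs, by any brood-window reduction:
#' `b*_k(t) = b_k(t) (1 - D_oophagy(t)) brood_factor_k(t)`.
#'
#' @param t day since the first day of spring (scalar).
#' @param state named state vector at time `t`.
#' @param params a [colony_params()] object.
#' @param scenario an [exposure_scenario()] object or `NULL`.
#' @return Numeric vector `c(W =, M =, G =)` in eggs/day.
#' @export
effective_laying_rates <- function(t, state, params, scenario = NULL) {
  raw <- laying_schedule(t, params)
  keep <- 1 - oophagy_factor(state, params)
  c(W = raw$W * keep * brood_factor(t, scenario),
    M = raw$M * keep, G = raw$G * keep)
}
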