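#' Colony model parameters
#'
#' Constructs the full parameter set of the colony model. Defaults are the
#' published estimates for *Bombus terrestris*: collection and consumption
#' rates per worker, caste-specific egg-laying rates, the worker death rate,
#' the care capacity `Z` (larvae one worker can tend), the maximum larval
#' ejection rates for negligence (`alpha`) and malnutrition (`beta`), and the
#' season schedule anchors.
#'
#' @param b_NW nectar collection rate (ml/day per worker).
#' @param b_PW pollen collection rate (g/day per worker).
#' @param mu_NW worker nectar consumption rate (ml/day per worker).
#' @param mu_PW worker pollen consumption rate (g/day per worker).
#' @param mu_NR,mu_PR nectar and pollen consumption rates of adult
#'   reproductives (ml/day and g/day per male or gyne). Males remain in the
#'   nest and feed, and gynes feed heavily -- especially on pollen -- to
#'   build overwintering reserves, so the default pollen rate is elevated
#'   above the worker rate. Set both to 0 to make adult reproductives
#'   resource-neutral.
#' @param c1,c2,c3,c4,c5 larval pollen consumption rates (g/day per larva) for,
#'   respectively: all first-instar classes, second worker instar, second male
#'   instar, second gyne instar, third gyne instar. The published range is
#'   0.01--0.25 g/day; the defaults place the final feeding instar of each
#'   caste at the top of that range and first instars at the bottom (see the
#'   methods vignette for the calibration against the control-season
#'   landmarks).
#' @param b_W,b_M,b_G raw egg-laying rates (eggs/day) for workers, males and
#'   gynes while the corresponding laying window is open.
#' @param mu_W adult worker death rate (1/day).
#' @param Z number of larvae a single worker can care for (dimensionless).
#' @param alpha maximum ejection rate from negligence (larvae/day per worker).
#' @param beta maximum ejection rate from malnutrition (larvae/day per worker).
#' @param eps roundoff correction factor used in the shortfall denominators.
#' @param T_s first day of spring (day 0 of the season clock).
#' @param T_star switch time: first day male/gyne eggs are laid.
#' @param T_dstar last day worker eggs are laid (laying window is
#'   `[T_s, T_dstar)`).
#' @param T_W beginning of winter; hive functions (and the simulation) cease.
#' @param N0,P0 in-nest nectar (ml) and pollen (g) stores when the first
#'   workers emerge and the simulation starts.
#' @param K_store half-saturation constant (g or ml) of the smooth
#'   store-limiting factor `g(S) = S / (S + K_store)` that throttles
#'   consumption as a store empties, keeping stocks non-negative.
#' @param switch_ramp width (days) of the centered linear on/off ramp applied
#'   to the laying-window edges. A zero-width switch makes the delayed inflow
#'   of an empty larval compartment jump discontinuously, which an adaptive
#'   integrator cannot traverse at absolute-tolerance level; a 0.01-day
#'   (~15 minute) ramp is biologically indistinguishable and preserves the
#'   laying integral exactly. Set to 0 for sharp half-open windows.
#' @param ejection functional form of the larval-loss channel:
#'   * `"deficit"` (default) -- each larva is lost at per-larva rate
#'     `alpha * D_neglect + beta * D_malnut`: when the care or food deficit is
#'     total every larva dies at the maximum rate, regardless of how few
#'     workers remain (unattended larvae starve). Losing workers *increases*
#'     brood mortality.
#'   * `"worker_capped"` -- active ejection by workers, with total fluxes
#'     capped at `alpha * W` and `beta * W` larvae/day:
#'     `mu_L = (alpha * D_neglect + beta * D_malnut) * W / (L_tot + eps)`.
#'     With no workers nothing is ejected, so losing workers *decreases*
#'     brood mortality.
#' @param oophagy logical; if `FALSE`, egg cannibalism under resource
#'   shortfall is disabled and effective laying rates equal the scheduled
#'   rates (used for no-regulation cross-checks).
#' @param mu_L_override optional non-negative number: force the per-larva
#'   ejection rate to this constant from the simulation start, bypassing the
#'   regulation terms (used for closed-form survival cross-checks). `NULL`
#'   (default) uses the regulated rate.
#'
#' @return An object of class `bombus_params` (a named list).
#' @examples
#' p <- colony_params()
#' p$b_W
#' @export
colony_params <- function(b_NW = 0.6, b_PW = 0.4,
                          mu_NW = 0.35, mu_PW = 0.25,
                          mu_NR = 0.35, mu_PR = 0.35,
                          c1 = 0.01, c2 = 0.13, c3 = 0.13, c4 = 0.13,
                          c5 = 0.25,
                          b_W = 8.5, b_M = 2, b_G = 2.6,
                          mu_W = 0.05, Z = 4,
                          alpha = 0.75, beta = 0.75, eps = 0.001,
                          T_s = 0, T_star = 40, T_dstar = 44, T_W = 120,
                          N0 = 20, P0 = 10,
                          K_store = 0.5, switch_ramp = 0.01,
                          ejection = c("deficit", "worker_capped"),
                          oophagy = TRUE,
                          mu_L_override = NULL) {
  p <- list(
    b_NW = b_NW, b_PW = b_PW, mu_NW = mu_NW, mu_PW = mu_PW,
    mu_NR = mu_NR, mu_PR = mu_PR,
    c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
    b_W = b_W, b_M = b_M, b_G = b_G,
    mu_W = mu_W, Z = Z, alpha = alpha, beta = beta, eps = eps,
    T_s = T_s, T_star = T_star, T_dstar = T_dstar, T_W = T_W,
    N0 = N0, P0 = P0, K_store = K_store, switch_ramp = switch_ramp,
    ejection = match.arg(ejection), oophagy = oophagy,
    mu_L_override = mu_L_override
  )
  class(p) <- "bombus_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- c("b_NW", "b_PW", "mu_NW", "mu_PW", "mu_NR", "mu_PR",
           "c1", "c2", "c3", "c4", "c5",
           "b_W", "b_M", "b_G", "mu_W", "alpha", "beta")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$eps <= 0) stop("'eps' must be > 0", call. = FALSE)
  if (p$K_store <= 0) stop("'K_store' must be > 0", call. = FALSE)
  if (p$switch_ramp < 0) stop("'switch_ramp' must be >= 0", call. = FALSE)
  if (p$Z < 1) stop("'Z' must be >= 1", call. = FALSE)
  if (p$N0 < 0 || p$P0 < 0)
    stop("initial stores 'N0' and 'P0' must be non-negative", call. = FALSE)
  if (!(p$T_s < p$T_star && p$T_star < p$T_dstar))
    stop("schedule anchors must satisfy T_s < T_star < T_dstar",
         call. = FALSE)
  if (p$T_W <= p$T_s + 22)
    stop("'T_W' must exceed T_s + 22 (the season must outlast first worker ",
         "emergence)", call. = FALSE)
  if (!is.null(p$mu_L_override) &&
      (!is.numeric(p$mu_L_override) || p$mu_L_override < 0))
    stop("'mu_L_override' must be NULL or a non-negative number",
         call. = FALSE)
  invisible(p)
}

#' @export
print.bombus_params <- function(x, ...) {
  cat("<bombus_params> colony model parameters\n")
  cat(sprintf("  foraging : b_NW=%.3g ml/d/W, b_PW=%.3g g/d/W\n",
              x$b_NW, x$b_PW))
  cat(sprintf("  adult use: mu_NW=%.3g ml/d/W, mu_PW=%.3g g/d/W, mu_W=%.3g /d\n",
              x$mu_NW, x$mu_PW, x$mu_W))
  cat(sprintf("  reprod.  : mu_NR=%.3g ml/d, mu_PR=%.3g g/d per adult M/G\n",
              x$mu_NR, x$mu_PR))
  cat(sprintf("  larval c : %.3g %.3g %.3g %.3g %.3g g/d/L\n",
              x$c1, x$c2, x$c3, x$c4, x$c5))
  cat(sprintf("  laying   : b_W=%.3g, b_M=%.3g, b_G=%.3g eggs/d\n",
              x$b_W, x$b_M, x$b_G))
  cat(sprintf("  care     : Z=%.3g, alpha=%.3g, beta=%.3g, eps=%.3g\n",
              x$Z, x$alpha, x$beta, x$eps))
  cat(sprintf("  season   : T_s=%g < T*=%g < T**=%g < T_W=%g days\n",
              x$T_s, x$T_star, x$T_dstar, x$T_W))
  cat(sprintf("  stores   : N0=%.3g ml, P0=%.3g g (K_store=%.3g)\n",
              x$N0, x$P0, x$K_store))
  if (!x$oophagy) cat("  oophagy disabled\n")
  if (!is.null(x$mu_L_override))
    cat(sprintf("  larval mortality forced to %.3g /d\n", x$mu_L_override))
  invisible(x)
}

#' Fixed life-stage durations and derived delay structure
#'
#' Builds the per-caste stage schedule: egg duration, larval substage
#' durations (two for workers and males, three for gynes) and pupal duration,
#' all in days. Every delay used by the model is derived from these durations:
#' substage entry ages, the pupation age, the emergence (total) age, and the
#' offsets at which the cumulative mortality integrals are read.
#'
#' @param worker,male,gyne named lists with components `egg` (scalar), `larva`
#'   (vector of substage durations) and `pupa` (scalar), in days.
#' @return An object of class `bombus_schedule`: per caste, the durations plus
#'   `entry_ages` (age at entry into each larval substage, followed by the
#'   pupation age), `total_age` (age at adult emergence) and `larval_duration`.
#' @examples
#' s <- stage_schedule()
#' s$worker$total_age   # 22
#' caste_lags(s, "gyne")
#' @export
stage_schedule <- function(worker = list(egg = 4, larva = c(6, 3), pupa = 9),
                           male = list(egg = 4, larva = c(8, 3), pupa = 11),
                           gyne = list(egg = 4, larva = c(5, 4, 4), pupa = 13)) {
  build <- function(st, caste) {
    if (!all(c("egg", "larva", "pupa") %in% names(st)))
      stop("stage list for ", caste, " needs 'egg', 'larva', 'pupa'",
           call. = FALSE)
    if (any(c(st$egg, st$larva, st$pupa) <= 0))
      stop("all stage durations must be positive (", caste, ")", call. = FALSE)
    entry <- st$egg + cumsum(c(0, st$larva))  # last entry = pupation age
    list(egg = st$egg, larva = st$larva, pupa = st$pupa,
         n_sub = length(st$larva),
         entry_ages = entry,
         pupation_age = entry[length(entry)],
         total_age = st$egg + sum(st$larva) + st$pupa,
         larval_duration = sum(st$larva))
  }
  s <- list(worker = build(worker, "worker"),
            male = build(male, "male"),
            gyne = build(gyne, "gyne"))
  class(s) <- "bombus_schedule"
  s
}

#' Delay set of a caste
#'
#' All constant lags (days) appearing in the delayed terms for one caste:
#' substage entry ages, their larval-phase-start offsets, the pupal duration,
#' and the emergence age with its larval-start offset. No lag is free; all are
#' derived from the stage durations.
#'
#' @param schedule a [stage_schedule()] object.
#' @param caste one of `"worker"`, `"male"`, `"gyne"`.
#' @return Sorted numeric vector of positive lags.
#' @export
caste_lags <- function(schedule, caste = c("worker", "male", "gyne")) {
  caste <- match.arg(caste)
  cs <- schedule[[caste]]
  lags <- c(cs$entry_ages,                 # laying-rate lookups
            cs$entry_ages - cs$egg,        # larval-phase start offsets (Phi)
            cs$total_age, cs$total_age - cs$egg, cs$pupa)
  sort(unique(lags[lags > 0]))
}

#' @export
print.bombus_schedule <- function(x, ...) {
  cat("<bombus_schedule> fixed life-stage durations (days)\n")
  for (k in c("worker", "male", "gyne")) {
    cs <- x[[k]]
    cat(sprintf("  %-6s egg %g | larva %s | pupa %g | emergence age %g\n",
                k, cs$egg, paste(cs$larva, collapse = "+"), cs$pupa,
                cs$total_age))
  }
  invisible(x)
}
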