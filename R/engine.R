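#' Integration settings
#'
#' Numerical settings for the delay integrator. Defaults: relative tolerance
#' `1e-8`, absolute tolerance `1e-10`, dense output every 0.1 day, maximum
#' internal step no larger than the smallest lag (4 days), and second-order
#' propagation of derivative discontinuities.
#'
#' @param rtol,atol relative and absolute error tolerances.
#' @param dt_out spacing (days) of the dense output mesh.
#' @param hmax maximum internal step size (days); must not exceed the
#'   smallest model lag.
#' @param method solver passed to [deSolve::dede()].
#' @param maxsteps maximum number of internal steps.
#' @param mxhist size of the solver's lag-interpolation history buffer.
#' @param disc_order order up to which derivative discontinuities are
#'   propagated into the output mesh (see [propagate_discontinuities()]).
#' @return An object of class `bombus_settings`.
#' @export
simulation_settings <- function(rtol = 1e-8, atol = 1e-10, dt_out = 0.1,
                                hmax = 4, method = "lsoda",
                                maxsteps = 100000, mxhist = 1e5,
                                disc_order = 2) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (dt_out <= 0) stop("'dt_out' must be > 0", call. = FALSE)
  if (hmax <= 0) stop("'hmax' must be > 0", call. = FALSE)
  s <- list(rtol = rtol, atol = atol, dt_out = dt_out, hmax = hmax,
            method = method, maxsteps = maxsteps, mxhist = mxhist,
            disc_order = disc_order)
  class(s) <- "bombus_settings"
  s
}

#' Propagate derivative discontinuities
#'
#' In a constant-lag DDE, any derivative discontinuity at a time `s` (the
#' initial time, a schedule switch, or a state-jump event) re-appears at
#' `s + lag` for every lag, and so on recursively. This returns the sorted
#' breakpoints up to the requested order so the output mesh can resolve them.
#'
#' @param t0 initial time; discontinuity source of order 0.
#' @param lags numeric vector of constant positive lags.
#' @param t_end end of integration; breakpoints beyond it are dropped.
#' @param event_times additional known discontinuity times (state-jump events,
#'   schedule switches); they are themselves included in the result.
#' @param order propagation order (default 2).
#' @return Sorted numeric vector of breakpoints in `(t0, t_end]`.
#' @examples
#' propagate_discontinuities(22, c(4, 22), 120, order = 1)  # 26, 44
#' @export
propagate_discontinuities <- function(t0, lags, t_end,
                                      event_times = numeric(), order = 2) {
  lags <- unique(lags[lags > 0])
  pts <- c(t0, event_times)
  out <- event_times
  for (k in seq_len(order)) {
    if (!length(lags) || !length(pts)) break
    pts <- as.vector(outer(pts, lags, `+`))
    pts <- unique(pts[pts <= t_end])
    out <- c(out, pts)
  }
  out <- sort(unique(round(out, 9)))
  out[out > t0 & out <= t_end]
}

#' Integrate a constant-lag delay differential equation
#'
#' Thin wrapper around [deSolve::dede()] that supplies the pieces the colony
#' model (and any constant-lag DDE) needs: an analytic history for lagged
#' lookups before the initial time, an output mesh refined at propagated
#' discontinuities, and instantaneous state-transform events.
#'
#' @param func derivative function `function(t, y, lag_state)` returning the
#'   derivative vector; `lag_state(s)` gives the (interpolated or analytic)
#'   state at any earlier time `s`.
#' @param y0 named initial state.
#' @param t0,t_end integration span.
#' @param history function of `s` returning the state for `s <= t0`; defaults
#'   to constant `y0`.
#' @param lags constant positive lags used by `func` (for discontinuity
#'   propagation only; `func` performs its own lagged lookups).
#' @param events list of `list(time =, func =)` entries; each `func` maps the
#'   state to the transformed state at `time`, applied as an instantaneous
#'   jump.
#' @param settings a [simulation_settings()] object.
#' @param extra_breaks additional known discontinuity times to propagate
#'   (e.g. laying-schedule switches).
#' @return A `deSolve` matrix: time column plus one column per state.
#' @examples
#' # dy/dt = -y(t - 1), y == 1 for t <= 0: y(t) = 1 - t on [0, 1]
#' f <- function(t, y, lag_state) -lag_state(t - 1)
#' sol <- integrate_dde(f, c(y = 1), 0, 1, lags = 1)
#' sol[nrow(sol), "y"]  # 0
#' @export
integrate_dde <- function(func, y0, t0, t_end,
                          history = function(s) y0,
                          lags = numeric(), events = list(),
                          settings = simulation_settings(),
                          extra_breaks = numeric()) {
  if (t_end <= t0) stop("'t_end' must exceed 't0'", call. = FALSE)
  ev_times <- vapply(events, function(e) e$time, numeric(1))
  if (length(ev_times) && any(ev_times < t0 | ev_times > t_end))
    stop("event time outside integration span", call. = FALSE)
  breaks <- propagate_discontinuities(t0, lags, t_end,
                                      event_times = c(ev_times, extra_breaks),
                                      order = settings$disc_order)
  times <- sort(unique(round(c(seq(t0, t_end, by = settings$dt_out),
                               breaks, t_end), 9)))
  times <- times[c(TRUE, diff(times) > 1e-9)]

  lag_state <- function(s) {
    if (s <= t0 + 1e-12) history(s) else deSolve::lagvalue(s)
  }
  wrapped <- function(t, y, parms) list(unname(func(t, y, lag_state)))

  ev_arg <- NULL
  if (length(events)) {
    ev_fun <- function(t, y, parms) {
      for (e in events)
        if (abs(t - e$time) < 1e-8) y <- e$func(y)
      y
    }
    ev_arg <- list(func = ev_fun, time = round(ev_times, 9))
  }
  sol <- deSolve::dede(y = y0, times = times, func = wrapped, parms = NULL,
                       method = settings$method,
                       rtol = settings$rtol, atol = settings$atol,
                       hmax = settings$hmax, maxsteps = settings$maxsteps,
                       control = list(mxhist = settings$mxhist),
                       events = ev_arg)
  if (attr(sol, "istate")[1] < 0)
    stop("DDE integration failed (solver istate ", attr(sol, "istate")[1],
         ")", call. = FALSE)
  sol
}
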