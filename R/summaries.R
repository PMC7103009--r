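#' Cumulative reproductive output of a season
#'
#' The colony's fitness endpoint: cumulative adult males plus gynes at the
#' beginning of winter, `M(T_W) + G(T_W)`.
#'
#' @param sim a `bombus_sim` object from [run_scenario()].
#' @return A single count.
#' @export
reproductive_output <- function(sim) {
  tr <- sim$trajectory
  if (max(tr$time) < sim$params$T_W - 1e-6)
    stop("trajectory is truncated before T_W; cannot read the season ",
         "endpoint", call. = FALSE)
  last <- tr[nrow(tr), ]
  unname(last$M + last$G)
}

#' Day of the maximum of a state component
#'
#' Argmax over the dense output mesh; ties are broken to the earliest day.
#'
#' @param sim a `bombus_sim` object, or a data.frame with a `time` column.
#' @param component state column name (e.g. `"W"`, `"P"`).
#' @return The day of the maximum.
#' @export
peak_day <- function(sim, component = "W") {
  tr <- if (inherits(sim, "bombus_sim")) sim$trajectory else sim
  if (!component %in% names(tr))
    stop("no component '", component, "' in trajectory", call. = FALSE)
  tr$time[which.max(tr[[component]])]
}

#' Percent change relative to a control value
#'
#' @param metric scenario value(s).
#' @param control_metric control value; must be positive.
#' @return `100 * (metric - control_metric) / control_metric`.
#' @export
percent_change <- function(metric, control_metric) {
  if (!is.numeric(control_metric) || control_metric <= 0)
    stop("'control_metric' must be positive", call. = FALSE)
  100 * (metric - control_metric) / control_metric
}

#' Season summary metrics
#'
#' Endpoints and timeline landmarks of one simulated season: cumulative
#' reproductive output, day and height of the worker population peak, and the
#' day each resource store peaks (the onset of its terminal decline). If a
#' control simulation is supplied, percent changes against it are included.
#'
#' @param sim a `bombus_sim` object.
#' @param control optional control `bombus_sim` for relative metrics.
#' @return A one-row data.frame of class `bombus_metrics`.
#' @export
colony_metrics <- function(sim, control = NULL) {
  tr <- sim$trajectory
  m <- data.frame(
    reproductive_output = reproductive_output(sim),
    males = tr$M[nrow(tr)],
    gynes = tr$G[nrow(tr)],
    peak_worker_day = peak_day(sim, "W"),
    peak_worker_count = max(tr$W),
    pollen_peak_day = peak_day(sim, "P"),
    nectar_peak_day = peak_day(sim, "N")
  )
  if (!is.null(control)) {
    m$pct_change_reproductives <-
      percent_change(m$reproductive_output, reproductive_output(control))
  }
  class(m) <- c("bombus_metrics", class(m))
  m
}
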