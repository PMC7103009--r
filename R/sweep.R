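#' Canned scenario sweep grids
#'
#' The four standard experiment grids:
#' * `"acute-timing"` -- LD50 worker cull, exposure day 22 to 118 in steps of
#'   4 days;
#' * `"foraging"` -- persistent nectar-only and pollen-only foraging
#'   reductions, 0 to 100% in steps of 10%;
#' * `"brood"` -- factorial brood-1 x brood-2 laying reductions, 0 to 50% in
#'   steps of 10%;
#' * `"combined"` -- factorial acute kill fraction x pollen foraging
#'   reduction, each 0 to 60% in steps of 10%, cull on day 30.
#'
#' @param name grid name.
#' @param acute_day exposure day used by the `"combined"` grid.
#' @return A data.frame, one row per scenario, whose columns are
#'   [exposure_scenario()] arguments.
#' @export
sweep_grid <- function(name = c("acute-timing", "foraging", "brood",
                                "combined"),
                       acute_day = 30) {
  name <- match.arg(name)
  switch(name,
    "acute-timing" = data.frame(acute_day = seq(22, 118, by = 4),
                                acute_kill_fraction = 0.5),
    "foraging" = {
      r <- round(seq(0, 1, by = 0.1), 10)
      rbind(data.frame(forage_reduction_N = r, forage_reduction_P = 0),
            data.frame(forage_reduction_N = 0, forage_reduction_P = r))
    },
    "brood" = expand.grid(brood1_reduction = round(seq(0, 0.5, by = 0.1), 10),
                          brood2_reduction = round(seq(0, 0.5, by = 0.1), 10)),
    "combined" = {
      g <- expand.grid(
        acute_kill_fraction = round(seq(0, 0.6, by = 0.1), 10),
        forage_reduction_P = round(seq(0, 0.6, by = 0.1), 10))
      g$acute_day <- ifelse(g$acute_kill_fraction > 0, acute_day, NA)
      g
    })
}

grid_row_scenario <- function(row) {
  args <- as.list(row)
  args <- args[!vapply(args, function(v) is.na(v) || is.null(v), logical(1))]
  do.call(exposure_scenario, args)
}

#' Run a grid of exposure scenarios
#'
#' Simulates every scenario in the grid plus the control, and tabulates the
#' season endpoints. Scenario columns of the grid are passed to
#' [exposure_scenario()]; `NA` entries are dropped (so an `acute_day` of `NA`
#' means no cull).
#'
#' @param params a [colony_params()] object.
#' @param grid a data.frame of scenario arguments, e.g. from [sweep_grid()],
#'   or a grid name accepted by [sweep_grid()].
#' @param settings a [simulation_settings()] object.
#' @param schedule a [stage_schedule()] object.
#' @return An object of class `bombus_sweep`: the grid columns plus
#'   `males`, `gynes`, `reproductive_output` and `pct_change_vs_control`, with
#'   the control output in attribute `"control_output"`.
#' @export
run_sweep <- function(params = colony_params(), grid,
                      settings = simulation_settings(),
                      schedule = stage_schedule()) {
  if (is.character(grid)) grid <- sweep_grid(grid)
  if (!is.data.frame(grid) || nrow(grid) == 0)
    stop("'grid' must be a non-empty data.frame of scenario arguments",
         call. = FALSE)
  control <- run_scenario(params, control_scenario(), settings, schedule)
  ctrl_out <- reproductive_output(control)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- run_scenario(params, grid_row_scenario(grid[i, , drop = FALSE]),
                        settings, schedule)
    tr <- sim$trajectory
    data.frame(males = tr$M[nrow(tr)], gynes = tr$G[nrow(tr)],
               reproductive_output = reproductive_output(sim))
  })
  out <- cbind(grid, do.call(rbind, res))
  out$pct_change_vs_control <- percent_change(out$reproductive_output,
                                              ctrl_out)
  rownames(out) <- NULL
  attr(out, "control_output") <- ctrl_out
  class(out) <- c("bombus_sweep", class(out))
  out
}

#' @export
print.bombus_sweep <- function(x, ...) {
  cat(sprintf("<bombus_sweep> %d scenarios (control output %.1f)\n",
              nrow(x), attr(x, "control_output")))
  NextMethod()
}
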