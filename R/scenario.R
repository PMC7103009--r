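#' Pesticide exposure scenario
#'
#' Describes one exposure experiment as a combination of three channels:
#' * **lethal**: an acute cull of a fraction of adult workers on one day
#'   (`acute_day`, `acute_kill_fraction`; an LD50 dose corresponds to 0.5),
#'   applied as an instantaneous state jump;
#' * **sublethal foraging**: persistent fractional reductions of the nectar
#'   and pollen collection rates (`forage_reduction_N`, `forage_reduction_P`,
#'   applied as multipliers `1 - r`);
#' * **sublethal brood**: fractional reductions of the worker egg-laying rate
#'   within the first and second brood laying windows (`brood1_reduction`,
#'   `brood2_reduction`). Eggs laid on days `[0, 13)` are brood 1 (emerging
#'   from day 22); days `[13, 22)` are brood 2 (emerging from day 35).
#'
#' An empty scenario (all defaults) is the control.
#'
#' @param acute_day day of acute exposure, in `[22, T_W]`, or `NULL` for none.
#' @param acute_kill_fraction fraction of workers killed on `acute_day`.
#' @param forage_reduction_N,forage_reduction_P fractions in `[0, 1]`.
#' @param brood1_reduction,brood2_reduction fractions in `[0, 1]`.
#' @param brood_windows numeric length-3 vector of laying-day breakpoints
#'   `(start, split, end)` of the two brood windows.
#' @return An object of class `bombus_scenario`.
#' @examples
#' exposure_scenario(acute_day = 30)          # LD50 cull on day 30
#' exposure_scenario(forage_reduction_P = 0.2)
#' @export
exposure_scenario <- function(acute_day = NULL, acute_kill_fraction = 0.5,
                              forage_reduction_N = 0, forage_reduction_P = 0,
                              brood1_reduction = 0, brood2_reduction = 0,
                              brood_windows = c(0, 13, 22)) {
  sc <- list(acute_day = acute_day,
             acute_kill_fraction = acute_kill_fraction,
             forage_reduction_N = forage_reduction_N,
             forage_reduction_P = forage_reduction_P,
             brood1_reduction = brood1_reduction,
             brood2_reduction = brood2_reduction,
             brood_windows = brood_windows)
  class(sc) <- "bombus_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  frac <- c("acute_kill_fraction", "forage_reduction_N", "forage_reduction_P",
            "brood1_reduction", "brood2_reduction")
  for (f in frac) {
    v <- sc[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("scenario field '", f, "' must be a fraction in [0, 1]",
           call. = FALSE)
  }
  if (!is.null(sc$acute_day) &&
      (!is.numeric(sc$acute_day) || length(sc$acute_day) != 1L ||
         sc$acute_day < 0))
    stop("'acute_day' must be NULL or a single non-negative day",
         call. = FALSE)
  if (length(sc$brood_windows) != 3L || is.unsorted(sc$brood_windows))
    stop("'brood_windows' must be three increasing laying-day breakpoints",
         call. = FALSE)
  invisible(sc)
}

#' Control (no exposure) scenario
#' @return An empty [exposure_scenario()].
#' @export
control_scenario <- function() exposure_scenario()

is_control <- function(sc) {
  is.null(sc$acute_day) && sc$forage_reduction_N == 0 &&
    sc$forage_reduction_P == 0 && sc$brood1_reduction == 0 &&
    sc$brood2_reduction == 0
}

#' Apply an acute worker cull to a state
#'
#' Instantaneous lethal exposure: the worker count is multiplied by
#' `1 - fraction`; every other state component is unchanged. Used as the
#' integrator event for the acute-exposure channel.
#'
#' @param state named state vector.
#' @param fraction fraction of workers killed, in `[0, 1]`.
#' @return The transformed state vector.
#' @examples
#' s <- colony_state(W = 100)
#' apply_acute_cull(s, 0.5)[["W"]]  # 50
#' @export
apply_acute_cull <- function(state, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]", call. = FALSE)
  state[["W"]] <- (1 - fraction) * state[["W"]]
  state
}

#' @export
print.bombus_scenario <- function(x, ...) {
  cat("<bombus_scenario>")
  if (is_control(x)) {
    cat(" control (no exposure)\n")
    return(invisible(x))
  }
  cat("\n")
  if (!is.null(x$acute_day))
    cat(sprintf("  acute cull: %.0f%% of workers on day %g\n",
                100 * x$acute_kill_fraction, x$acute_day))
  if (x$forage_reduction_N > 0 || x$forage_reduction_P > 0)
    cat(sprintf("  foraging reduced: nectar %.0f%%, pollen %.0f%%\n",
                100 * x$forage_reduction_N, 100 * x$forage_reduction_P))
  if (x$brood1_reduction > 0 || x$brood2_reduction > 0)
    cat(sprintf("  brood laying reduced: brood 1 %.0f%%, brood 2 %.0f%%\n",
                100 * x$brood1_reduction, 100 * x$brood2_reduction))
  invisible(x)
}
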