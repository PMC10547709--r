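#' Filter fixes on GPS dilution of precision
#'
#' Removes fixes whose DOP strictly exceeds `max_dop` (default 7): a fix with
#' DOP exactly 7 is retained. Row order is preserved. Missing DOP values are
#' an error — a fix of unknown quality is never silently kept.
#'
#' @param fixes Fix table with a `dop` column.
#' @param max_dop Retention threshold (default 7).
#' @return Filtered fix table.
#' @export
filter_dop <- function(fixes, max_dop = 7) {
  assert_cols(fixes, "dop", "fixes")
  if (anyNA(fixes$dop)) abort("fixes contain missing dop values; cannot apply the quality filter")
  if (any(fixes$dop <= 0)) abort("dop values must be positive")
  dplyr::filter(fixes, .data$dop <= max_dop)
}

#' Drop roost fixes
#'
#' Removes fixes recorded at the roost times: the nightly 23:58:58 fix and the
#' 05:00 and 06:00 fixes (broods rarely revisit roost sites, and the analysis
#' targets foraging/loafing/travelling behavior). Matching is on UTC
#' time-of-day.
#'
#' @param fixes Fix table with a POSIXct `timestamp` column.
#' @return Fix table without roost-time fixes.
#' @export
drop_roost_fixes <- function(fixes) {
  assert_cols(fixes, "timestamp", "fixes")
  tod <- format(fixes$timestamp, "%H:%M:%S", tz = "UTC")
  dplyr::filter(fixes, !tod %in% c("23:58:58", "05:00:00", "06:00:00"))
}

#' Split fixes into roosting periods
#'
#' Partitions the fix table into the ground-roosting period (days 1-13 since
#' hatch) and the tree-roosting period (days 14-28).
#'
#' @param fixes Fix table with a `day` column in 1-28.
#' @return Named list of two fix tables, `ground` and `tree`.
#' @export
split_periods <- function(fixes) {
  assert_cols(fixes, "day", "fixes")
  if (any(fixes$day < 1 | fixes$day > 28)) {
    abort("day since hatch outside 1-28; cannot assign a roosting period")
  }
  list(ground = dplyr::filter(fixes, .data$day <= 13),
       tree = dplyr::filter(fixes, .data$day >= 14))
}

#' Label a day with its roosting period
#' @param day Integer day since hatch (1-28).
#' @return `"ground"` for days 1-13, `"tree"` for 14-28.
#' @export
period_of_day <- function(day) {
  if (any(day < 1 | day > 28)) abort("day since hatch outside 1-28")
  ifelse(day <= 13, "ground", "tree")
}

#' Build the step/turn observation stream
#'
#' Converts cleaned fixes into steps: Euclidean displacement between
#' consecutive fixes of the same burst, and the signed change in heading
#' between consecutive steps, wrapped to (-pi, pi] (a tie at +/-pi reads +pi).
#' Bursts break at calendar-day boundaries and at gaps longer than
#' `max_gap_h` hours, so no step spans the overnight hole left by roost-fix
#' removal. The first step of a burst, and any step adjacent to a zero-length
#' step (heading undefined), has a missing turning angle.
#'
#' @param fixes Cleaned fix table, time-sorted within brood.
#' @param max_gap_h Maximum within-burst gap, hours (default 1; gaps strictly
#'   longer start a new burst).
#' @return Step series (tibble): `brood_id`, `burst_id`, `step_m`, `turn_rad`,
#'   `t_end`, `day`, plus start/end coordinates (`x0`, `y0`, `x1`, `y1`) and
#'   the row index of the end fix within its brood (`fix_end`).
#' @export
#' @examples
#' fx <- tibble::tibble(
#'   brood_id = "b", day = 1,
#'   timestamp = as.POSIXct("2021-05-01 07:00", tz = "UTC") + 3600 * (0:2),
#'   x = c(0, 3, 3), y = c(0, 4, 9))
#' build_steps(fx)[, c("step_m", "turn_rad")]
build_steps <- function(fixes, max_gap_h = 1) {
  assert_cols(fixes, c("brood_id", "timestamp", "day", "x", "y"), "fixes")
  fixes |>
    dplyr::group_by(.data$brood_id) |>
    dplyr::group_modify(~ build_steps_one(.x, .y$brood_id, max_gap_h)) |>
    dplyr::ungroup()
}

build_steps_one <- function(fx, brood_id, max_gap_h) {
  if (is.unsorted(fx$timestamp)) abort("fixes must be time-sorted within brood")
  if (anyDuplicated(fx$timestamp) > 0) abort("duplicate timestamps within brood")
  n <- nrow(fx)
  if (n < 2) {
    return(tibble::tibble(burst_id = character(), step_m = numeric(),
                          turn_rad = numeric(), t_end = fx$timestamp[0],
                          day = integer(), x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric(), fix_end = integer()))
  }
  gap_h <- as.numeric(difftime(fx$timestamp[-1], fx$timestamp[-n], units = "hours"))
  new_burst <- c(TRUE, fx$day[-1] != fx$day[-n] | gap_h > max_gap_h + 1e-9)
  burst <- cumsum(new_burst)
  dx <- fx$x[-1] - fx$x[-n]
  dy <- fx$y[-1] - fx$y[-n]
  step <- sqrt(dx^2 + dy^2)
  heading <- ifelse(step > 0, atan2(dy, dx), NA_real_)
  same_burst <- burst[-1] == burst[-n]      # step i spans fixes i -> i+1
  steps <- tibble::tibble(
    burst_id = sprintf("%s_%03d", brood_id, burst[-1]),
    step_m = step, t_end = fx$timestamp[-1], day = as.integer(fx$day[-1]),
    x0 = fx$x[-n], y0 = fx$y[-n], x1 = fx$x[-1], y1 = fx$y[-1],
    fix_end = seq_len(n)[-1], keep = same_burst,
    heading = heading)
  steps <- steps[steps$keep, , drop = FALSE]
  # turning angle: difference of headings of consecutive steps within a burst
  m <- nrow(steps)
  turn <- rep(NA_real_, m)
  if (m >= 2) {
    sb <- steps$burst_id[-1] == steps$burst_id[-m]
    tu <- wrap_angle(steps$heading[-1] - steps$heading[-m])
    turn[-1][sb] <- tu[sb]
  }
  steps$turn_rad <- turn
  steps[, c("burst_id", "step_m", "turn_rad", "t_end", "day",
            "x0", "y0", "x1", "y1", "fix_end")]
}
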