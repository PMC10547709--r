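#' State-specific buffer radii
#'
#' Circular buffer radii used for recursion statistics, one per merged
#' behavioral state. Defaults are the mean fitted step lengths of the two
#' merged states rounded to the scales used throughout: 90 m for restricted
#' movements and 250 m for mobile movements.
#'
#' @param restricted,mobile Radii in meters, `> 0`.
#' @return Named numeric vector `c(restricted = , mobile = )`.
#' @export
buffer_spec <- function(restricted = 90, mobile = 250) {
  if (restricted <= 0 || mobile <= 0) abort("buffer radii must be positive")
  c(restricted = restricted, mobile = mobile)
}

# burst membership of fixes, same rule as build_steps (day boundary or gap > 1 h)
fix_bursts <- function(fx, max_gap_h = 1) {
  n <- nrow(fx)
  if (n == 0) return(integer())
  gap_h <- as.numeric(difftime(fx$timestamp[-1], fx$timestamp[-n], units = "hours"))
  cumsum(c(TRUE, fx$day[-1] != fx$day[-n] | gap_h > max_gap_h + 1e-9))
}

# convex-interval crossing of |a + s(b - a) - c| = r; returns both roots
circle_crossings <- function(ax, ay, bx, by, cx, cy, r) {
  dx <- bx - ax; dy <- by - ay
  fx <- ax - cx; fy <- ay - cy
  A <- dx^2 + dy^2
  B <- 2 * (fx * dx + fy * dy)
  C <- fx^2 + fy^2 - r^2
  disc <- B^2 - 4 * A * C
  if (A == 0 || disc < 0) return(c(NA_real_, NA_real_))
  sq <- sqrt(disc)
  c((-B - sq) / (2 * A), (-B + sq) / (2 * A))
}

#' Visit segments of a trajectory through a circular buffer
#'
#' Finds the maximal time intervals during which the trajectory lies inside
#' the closed disc of radius `radius` about `center` (a fix at distance
#' exactly `radius` counts as inside). Crossing times between an inside fix
#' and an outside neighbor are interpolated linearly in space and time along
#' the inter-fix segment (exact line-circle intersection). Interpolation never
#' crosses a burst boundary: a visit in progress at the end of a burst ends at
#' the burst's last fix.
#'
#' @param track Time-sorted fix table of one animal (`timestamp`, `day`, `x`,
#'   `y`).
#' @param center Length-2 numeric, the buffer center (m).
#' @param radius Buffer radius (m), `> 0`.
#' @param max_gap_h Burst gap rule, hours (default 1).
#' @return Tibble of visit segments: `entry_time`, `exit_time`, `entry_day`,
#'   `duration_h`.
#' @export
visit_segments <- function(track, center, radius, max_gap_h = 1) {
  stopifnot(radius > 0, length(center) == 2)
  assert_cols(track, c("timestamp", "day", "x", "y"), "track")
  if (is.unsorted(track$timestamp)) abort("track must be time-sorted")
  burst <- fix_bursts(track, max_gap_h)
  d <- sqrt((track$x - center[1])^2 + (track$y - center[2])^2)
  inside <- d <= radius
  n <- nrow(track)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!inside[i]) { i <- i + 1L; next }
    # start of a run of inside fixes within one burst
    j <- i
    while (j < n && inside[j + 1L] && burst[j + 1L] == burst[j]) j <- j + 1L
    t_i <- as.numeric(track$timestamp[i])
    t_j <- as.numeric(track$timestamp[j])
    entry <- t_i
    if (i > 1L && burst[i - 1L] == burst[i] && !inside[i - 1L]) {
      s <- circle_crossings(track$x[i - 1L], track$y[i - 1L], track$x[i], track$y[i],
                            center[1], center[2], radius)[1]
      t_prev <- as.numeric(track$timestamp[i - 1L])
      if (is.finite(s)) entry <- t_prev + s * (t_i - t_prev)
    }
    exit <- t_j
    if (j < n && burst[j + 1L] == burst[j] && !inside[j + 1L]) {
      s <- circle_crossings(track$x[j], track$y[j], track$x[j + 1L], track$y[j + 1L],
                            center[1], center[2], radius)[2]
      t_next <- as.numeric(track$timestamp[j + 1L])
      if (is.finite(s)) exit <- t_j + s * (t_next - t_j)
    }
    segs[[length(segs) + 1L]] <- c(entry, exit, track$day[i])
    i <- j + 1L
  }
  if (length(segs) == 0) {
    return(tibble::tibble(entry_time = as.POSIXct(character(), tz = "UTC"),
                          exit_time = as.POSIXct(character(), tz = "UTC"),
                          entry_day = integer(), duration_h = numeric()))
  }
  m <- do.call(rbind, segs)
  tibble::tibble(
    entry_time = as.POSIXct(m[, 1], tz = "UTC", origin = "1970-01-01"),
    exit_time = as.POSIXct(m[, 2], tz = "UTC", origin = "1970-01-01"),
    entry_day = as.integer(m[, 3]),
    duration_h = (m[, 2] - m[, 1]) / 3600)
}

#' Assign a behavioral state to every fix
#'
#' Each fix takes the decoded state of its incoming step; a fix with no
#' incoming step (the first fix of a burst) inherits the state of the first
#' step of its burst (backward fill, then forward fill for trailing fixes).
#'
#' @param fixes Cleaned fix table.
#' @param decoded Step series with a `merged` column (from [viterbi()]).
#' @return `fixes` with a `state` column (`restricted`/`mobile`) appended.
#' @export
fix_states <- function(fixes, decoded) {
  assert_cols(decoded, c("fix_end", "merged"), "decoded")
  fixes |>
    dplyr::group_by(.data$brood_id) |>
    dplyr::group_modify(function(fx, key) {
      st <- rep(NA_character_, nrow(fx))
      dd <- decoded[decoded$brood_id == key$brood_id, ]
      st[dd$fix_end] <- dd$merged
      # backward fill then forward fill
      for (i in rev(seq_len(nrow(fx) - 1L))) if (is.na(st[i])) st[i] <- st[i + 1L]
      for (i in seq_len(nrow(fx))[-1]) if (is.na(st[i])) st[i] <- st[i - 1L]
      fx$state <- st
      fx
    }) |>
    dplyr::ungroup()
}

#' Per-fix recursion statistics
#'
#' For every fix, computes revisitation, residence time and return times of
#' the circular buffer centered on that fix, with the buffer radius set by the
#' fix's behavioral state. A revisit is a distinct visit segment whose entry
#' day differs from the focal fix's day; residence time is the total duration
#' of all visit segments over the whole monitoring window; return times are
#' the day-valued gaps between consecutive visit segments. Broods are
#' evaluated independently of one another.
#'
#' @param fixes Cleaned fix table with a `state` column (see [fix_states()]).
#' @param buffers A [buffer_spec()].
#' @param count_mode `"segments"` (default) counts distinct visit segments on
#'   other days; `"fixes"` counts individual fixes inside the buffer on other
#'   days.
#' @param max_gap_h Burst gap rule, hours.
#' @return Tibble, one row per fix: `brood_id`, `fix` (row index within
#'   brood), `day`, `state`, `radius_m`, `revisits`, `residence_h`,
#'   `n_returns`, `mean_return_d`.
#' @export
recursion_stats <- function(fixes, buffers = buffer_spec(),
                            count_mode = c("segments", "fixes"),
                            max_gap_h = 1) {
  count_mode <- match.arg(count_mode)
  assert_cols(fixes, c("brood_id", "timestamp", "day", "x", "y", "state"), "fixes")
  if (anyNA(fixes$state)) abort("every fix needs a behavioral state; see fix_states()")
  if (!all(fixes$state %in% names(buffers))) {
    abort("fix states must match the buffer_spec names (restricted/mobile)")
  }
  fixes |>
    dplyr::group_by(.data$brood_id) |>
    dplyr::group_modify(function(fx, key) {
      n <- nrow(fx)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        r <- buffers[[fx$state[i]]]
        segs <- visit_segments(fx, c(fx$x[i], fx$y[i]), r, max_gap_h)
        revisits <- if (count_mode == "segments") {
          sum(segs$entry_day != fx$day[i])
        } else {
          dd <- sqrt((fx$x - fx$x[i])^2 + (fx$y - fx$y[i])^2)
          sum(dd <= r & fx$day != fx$day[i])
        }
        gaps_d <- if (nrow(segs) >= 2) {
          (as.numeric(segs$entry_time[-1]) -
             as.numeric(segs$exit_time[-nrow(segs)])) / 86400
        } else numeric()
        out[[i]] <- tibble::tibble(
          fix = i, day = fx$day[i], state = fx$state[i], radius_m = r,
          revisits = revisits, residence_h = sum(segs$duration_h),
          n_returns = length(gaps_d),
          mean_return_d = if (length(gaps_d)) mean(gaps_d) else NA_real_)
      }
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
}
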