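#' Simulation configuration
#'
#' Bundles every knob of the synthetic trajectory generator. Defaults encode
#' the study conditions the package is built around: hourly fixes 0500-2000
#' plus one nightly roost fix at 23:58:58, 28 days of monitoring, a 3-state
#' switching walk whose emission parameters are the canonical 3-state
#' initialization (gamma step-length mean/sd of 27/27, 150/150 and 400/1000 m;
#' von Mises turning-angle mean/concentration of pi/0.1, 2.5/0.5 and
#' 0.001/0.99), persistent states (self-transition 0.9), attraction to focal
#' patches that induces revisits, occasional DOP above the 7.0 quality cutoff,
#' and a small daily brood-loss probability.
#'
#' @param n_broods Number of broods to simulate.
#' @param n_days Days of monitoring per brood (default 28).
#' @param day_hours Integer hours of the diurnal fix schedule (default 5:20).
#' @param roost_time Nightly roost fix time, "HH:MM:SS" (default "23:58:58").
#' @param transition_matrix 3x3 row-stochastic state transition matrix.
#' @param gamma_params 3x2 matrix, per-state step-length mean and sd (m).
#' @param vm_params 3x2 matrix, per-state turning-angle mean (rad) and
#'   concentration.
#' @param n_focal_patches Number of attractive focal patches per brood.
#' @param p_return Probability, per non-travelling fix, of steering toward the
#'   nearest previously used focal patch instead of continuing the correlated
#'   walk. This is what generates recursion.
#' @param dop_high_prob Probability a fix draws its DOP from the poor-quality
#'   component (above 7).
#' @param censor_prob Per-day probability the brood is lost (series truncated).
#' @param seed Integer seed.
#' @return A validated `recursel_sim_config` list.
#' @export
sim_config <- function(n_broods = 3,
                       n_days = 28,
                       day_hours = 5:20,
                       roost_time = "23:58:58",
                       transition_matrix = matrix(c(0.9, 0.05, 0.05,
                                                    0.05, 0.9, 0.05,
                                                    0.05, 0.05, 0.9),
                                                  3, 3, byrow = TRUE),
                       gamma_params = cbind(mean = c(27, 150, 400),
                                            sd = c(27, 150, 1000)),
                       vm_params = cbind(mean = c(pi, 2.5, 0.001),
                                         kappa = c(0.1, 0.5, 0.99)),
                       n_focal_patches = 5,
                       p_return = 0.3,
                       dop_high_prob = 0.08,
                       censor_prob = 0.02,
                       seed = 1L) {
  cfg <- list(n_broods = as.integer(n_broods), n_days = as.integer(n_days),
              day_hours = as.integer(day_hours), roost_time = roost_time,
              transition_matrix = transition_matrix,
              gamma_params = gamma_params, vm_params = vm_params,
              n_focal_patches = as.integer(n_focal_patches),
              p_return = p_return, dop_high_prob = dop_high_prob,
              censor_prob = censor_prob, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "recursel_sim_config")
}

validate_sim_config <- function(cfg) {
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || any(dim(tm) != c(3, 3)) ||
      any(abs(rowSums(tm) - 1) > 1e-12) || any(tm < 0)) {
    abort("transition_matrix must be 3x3 row-stochastic (rows sum to 1 within 1e-12)")
  }
  if (any(cfg$gamma_params <= 0)) abort("gamma means and sds must be positive")
  if (any(cfg$vm_params[, 2] < 0)) abort("von Mises concentrations must be >= 0")
  for (p in c("p_return", "dop_high_prob", "censor_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(sprintf("%s must lie in [0, 1]", p))
  }
  if (cfg$n_days < 1 || cfg$n_broods < 1) abort("n_days and n_broods must be >= 1")
  invisible(cfg)
}

# reflect a coordinate into [lo, hi] (repeatedly, for long overshoots)
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  stopifnot(w > 0)
  v <- (v - lo) %% (2 * w)
  v <- ifelse(v > w, 2 * w - v, v)
  v + lo
}

fix_schedule <- function(cfg, day, hatch) {
  day_ts <- hatch + (day - 1) * 86400 + cfg$day_hours * 3600
  hms <- as.numeric(strsplit(cfg$roost_time, ":")[[1]])
  roost_ts <- hatch + (day - 1) * 86400 + hms[1] * 3600 + hms[2] * 60 + hms[3]
  tibble::tibble(
    timestamp = c(day_ts, roost_ts),
    day = day,
    is_roost = c(rep(FALSE, length(day_ts)), TRUE))
}

#' Simulate one brood trajectory
#'
#' A 3-state switching correlated random walk on the landscape. The hidden
#' state evolves fix-to-fix by the configured transition matrix; each move
#' draws a gamma step length and a von Mises turning angle for the current
#' state. While in a non-travelling state (1 or 2), the heading is redirected
#' toward the nearest previously used focal patch with probability `p_return`,
#' which induces revisitation of profitable patches. The hatch site is the
#' first focal patch and counts as used from the start; the others become
#' attractive once the brood first passes within 100 m. Trajectories that would
#' exit the landscape are reflected at the boundary (preserving the
#' step-length distribution). DOP is a two-component mixture with occasional
#' values above 7; the nightly fix is flagged as a roost fix; a small per-day
#' loss probability truncates the series (censoring).
#'
#' @param config A [sim_config()].
#' @param landscape A [generate_landscape()] bundle covering the extent.
#' @param brood_id Identifier for the simulated brood.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A fix table (tibble): `brood_id`, `timestamp` (POSIXct UTC), `day`
#'   (days since hatch, 1-based), `x`, `y` (m), `dop`, `is_roost`,
#'   `true_state` (1 = stationary, 2 = restricted, 3 = travelling).
#' @export
#' @examples
#' ls <- generate_landscape(n_rows = 40, n_cols = 40, seed = 1)
#' fx <- simulate_brood(sim_config(n_days = 3), ls, "b1")
#' head(fx)
simulate_brood <- function(config, landscape, brood_id, seed = config$seed) {
  stopifnot(inherits(config, "recursel_sim_config"),
            inherits(landscape, "recursel_landscape"))
  set.seed(seed)
  ext <- landscape_extent(landscape)
  hatch <- as.POSIXct("2021-05-01 00:00:00", tz = "UTC")

  sched <- purrr::map_dfr(seq_len(config$n_days), fix_schedule,
                          cfg = config, hatch = hatch)
  # censoring: first day (if any) on which the brood is lost
  lost <- which(runif(config$n_days) < config$censor_prob)
  if (length(lost) > 0 && lost[1] > 1) {
    sched <- dplyr::filter(sched, .data$day < lost[1])
  }
  n <- nrow(sched)

  patches <- cbind(
    x = runif(config$n_focal_patches, ext["xmin"] + 0.1 * (ext["xmax"] - ext["xmin"]),
              ext["xmax"] - 0.1 * (ext["xmax"] - ext["xmin"])),
    y = runif(config$n_focal_patches, ext["ymin"] + 0.1 * (ext["ymax"] - ext["ymin"]),
              ext["ymax"] - 0.1 * (ext["ymax"] - ext["ymin"])))
  patch_used <- rep(FALSE, config$n_focal_patches)

  state <- integer(n)
  x <- numeric(n); y <- numeric(n)
  state[1] <- sample.int(3, 1)
  x[1] <- runif(1, ext["xmin"] + 0.3 * (ext["xmax"] - ext["xmin"]),
                ext["xmax"] - 0.3 * (ext["xmax"] - ext["xmin"]))
  y[1] <- runif(1, ext["ymin"] + 0.3 * (ext["ymax"] - ext["ymin"]),
                ext["ymax"] - 0.3 * (ext["ymax"] - ext["ymin"]))
  # the hatch site is itself a focal patch, and is "used" from the start, so
  # patch attraction can act from day 1
  patches[1, ] <- c(x[1], y[1])
  patch_used[1] <- TRUE
  heading <- runif(1, -pi, pi)
  shape <- gamma_shape(config$gamma_params[, 1], config$gamma_params[, 2])
  scale <- gamma_scale(config$gamma_params[, 1], config$gamma_params[, 2])

  for (t in 2:n) {
    s <- sample.int(3, 1, prob = config$transition_matrix[state[t - 1], ])
    state[t] <- s
    step <- rgamma(1, shape = shape[s], scale = scale[s])
    d2 <- (patches[, 1] - x[t - 1])^2 + (patches[, 2] - y[t - 1])^2
    if (s != 3 && any(patch_used) && runif(1) < config$p_return) {
      j <- which(patch_used)[which.min(d2[patch_used])]
      heading <- atan2(patches[j, 2] - y[t - 1], patches[j, 1] - x[t - 1]) +
        rnorm(1, 0, 0.3)
      # do not overshoot a nearby target patch
      step <- min(step, sqrt(d2[j]) + 30)
    } else {
      heading <- heading + rvonmises(1, config$vm_params[s, 1], config$vm_params[s, 2])
    }
    x[t] <- reflect_into(x[t - 1] + step * cos(heading), ext["xmin"], ext["xmax"])
    y[t] <- reflect_into(y[t - 1] + step * sin(heading), ext["ymin"], ext["ymax"])
    patch_used <- patch_used |
      ((patches[, 1] - x[t])^2 + (patches[, 2] - y[t])^2 < 100^2)
  }

  dop_hi <- runif(n) < config$dop_high_prob
  dop <- ifelse(dop_hi, runif(n, 7.5, 15), runif(n, 1, 6.5))

  tibble::tibble(
    brood_id = as.character(brood_id),
    timestamp = sched$timestamp,
    day = as.integer(sched$day),
    x = x, y = y, dop = dop,
    is_roost = sched$is_roost,
    true_state = as.integer(state))
}

#' Simulate a cohort of broods
#'
#' Runs [simulate_brood()] once per brood with per-brood seeds derived from
#' `config$seed`, and row-binds the fix tables.
#'
#' @param config A [sim_config()].
#' @param landscape A [generate_landscape()] bundle.
#' @return Combined fix table with brood ids `"brood_01"`, `"brood_02"`, ...
#' @export
simulate_broods <- function(config, landscape) {
  purrr::map_dfr(seq_len(config$n_broods), function(i) {
    simulate_brood(config, landscape,
                   brood_id = sprintf("brood_%02d", i),
                   seed = (config$seed * 1000L + i) %% .Machine$integer.max)
  })
}

#' Read and write fix tables as CSV
#'
#' Fix tables round-trip through CSV with ISO-8601 UTC timestamps; the
#' `true_state` column (simulation ground truth) is optional.
#'
#' @param fixes A fix table.
#' @param path CSV file path.
#' @return `write_fixes()` returns `path` invisibly; `read_fixes()` a tibble.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out$timestamp <- as.POSIXct(out$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$brood_id <- as.character(out$brood_id)
  out
}
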