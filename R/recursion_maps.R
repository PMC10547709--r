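#' Movement-kernel recursion intensity surface
#'
#' Converts per-fix recursion measures into a continuous intensity grid on the
#' landscape's 30-m raster. Every fix in the requested behavioral state
#' deposits an isotropic bivariate Gaussian kernel weighted by its metric
#' value (revisit count or residence hours), with bandwidth equal to the
#' state's buffer radius. The deposit is additionally smeared along the fix's
#' incoming step (`n_interp` equally spaced points, each carrying
#' `weight / n_interp`), which spreads intensity along the movement path in
#' the spirit of a movement-based (biased random bridge) kernel rather than a
#' point kernel. A fix with no incoming step deposits all its weight at the
#' fix. The grid integrates to approximately the total deposited weight.
#'
#' @param fixes Fix table of one brood with a `state` column ([fix_states()]).
#' @param stats Matching [recursion_stats()] rows for the same brood (same fix
#'   order).
#' @param state Merged state to map, `"restricted"` or `"mobile"`.
#' @param metric `"revisit"` (weights = revisit counts) or `"residence"`
#'   (weights = residence hours).
#' @param landscape A `recursel_landscape` supplying the grid.
#' @param buffers A [buffer_spec()]; the state's radius is the kernel
#'   bandwidth unless `bandwidth` is given.
#' @param bandwidth Optional kernel bandwidth override (m).
#' @param n_interp Interpolation points per step (default 5).
#' @param max_gap_h Burst gap rule, hours.
#' @return Raw intensity matrix (`n_rows` x `n_cols`, values `>= 0`).
#' @export
recursion_intensity <- function(fixes, stats, state, metric, landscape,
                                buffers = buffer_spec(), bandwidth = NULL,
                                n_interp = 5, max_gap_h = 1) {
  stopifnot(inherits(landscape, "recursel_landscape"))
  state <- match.arg(state, c("restricted", "mobile"))
  metric <- match.arg(metric, c("revisit", "residence"))
  assert_cols(fixes, c("timestamp", "day", "x", "y", "state"), "fixes")
  if (nrow(stats) != nrow(fixes)) abort("stats must have one row per fix, in fix order")
  h <- bandwidth %||% unname(buffers[[state]])
  w_all <- if (metric == "revisit") stats$revisits else stats$residence_h

  keep <- fixes$state == state
  grid0 <- matrix(0, landscape$n_rows, landscape$n_cols)
  if (!any(keep)) {
    warn(sprintf("no fixes in state '%s'; returning an all-zero intensity grid", state))
    return(grid0)
  }

  burst <- fix_bursts(fixes, max_gap_h)
  n <- nrow(fixes)
  has_prev <- c(FALSE, burst[-1] == burst[-n])
  px <- c(); py <- c(); pw <- c()
  for (i in which(keep)) {
    w <- w_all[i]
    if (w == 0) next
    if (has_prev[i]) {
      s <- seq_len(n_interp) / n_interp
      px <- c(px, fixes$x[i - 1L] + s * (fixes$x[i] - fixes$x[i - 1L]))
      py <- c(py, fixes$y[i - 1L] + s * (fixes$y[i] - fixes$y[i - 1L]))
      pw <- c(pw, rep(w / n_interp, n_interp))
    } else {
      px <- c(px, fixes$x[i]); py <- c(py, fixes$y[i]); pw <- c(pw, w)
    }
  }
  if (length(px) == 0) return(grid0)

  cen <- cell_centers(landscape)
  gx <- rep(cen$x, each = landscape$n_rows)
  gy <- rep(cen$y, times = landscape$n_cols)
  vals <- numeric(length(gx))
  chunk <- max(1L, floor(4e6 / length(gx)))
  norm <- 1 / (2 * pi * h^2)
  for (i0 in seq(1L, length(px), by = chunk)) {
    idx <- i0:min(length(px), i0 + chunk - 1L)
    d2 <- outer(gx, px[idx], "-")^2 + outer(gy, py[idx], "-")^2
    vals <- vals + as.vector(exp(-d2 / (2 * h^2)) %*% pw[idx]) * norm
  }
  matrix(vals, landscape$n_rows, landscape$n_cols)
}

#' Rescale a raw intensity grid to the 0-100 recursion scale
#'
#' Linearly inverts a non-negative intensity grid onto \[0, 100\], where 0
#' marks the cells most strongly associated with the recursive behavior and
#' values near 100 mark cells with no recursion: `v -> 100 * (1 - v / v_max)`.
#' A constant-zero grid (no recursion anywhere) maps to all-100. The
#' `"rank"` method replaces the linear map by a monotone rank transform with
#' the same endpoints.
#'
#' @param raw Non-negative numeric matrix.
#' @param method `"linear"` (default) or `"rank"`.
#' @return Matrix of the same shape with values in \[0, 100\].
#' @export
#' @examples
#' rescale_0_100(matrix(c(0, 5, 10), 1))
rescale_0_100 <- function(raw, method = c("linear", "rank")) {
  method <- match.arg(method)
  if (any(raw < 0)) abort("raw intensity values must be non-negative")
  vmax <- max(raw)
  if (vmax == 0) return(array(100, dim(raw)))
  if (method == "linear") {
    100 * (1 - raw / vmax)
  } else {
    r <- rank(raw, ties.method = "average")
    out <- 100 * (1 - (r - min(r)) / (max(r) - min(r)))
    array(out, dim(raw))
  }
}

#' Behavioral-state-specific recursion rasters for every brood
#'
#' Builds the four recursion maps (revisit and residence, restricted and
#' mobile) for each brood: raw movement-kernel intensity via
#' [recursion_intensity()], then [rescale_0_100()]. All rasters share the
#' landscape's grid registration.
#'
#' @param fixes Cleaned fix table with `state` (all broods).
#' @param stats [recursion_stats()] for the same fixes.
#' @param landscape A `recursel_landscape`.
#' @param buffers A [buffer_spec()].
#' @param n_interp Interpolation points per step.
#' @param method Rescale method, see [rescale_0_100()].
#' @return Nested list `rasters[[brood_id]][[state]][[metric]]`, each element
#'   a `recursel_raster`: list with `values` (matrix in \[0, 100\]), `origin`,
#'   `cell_size`, `brood_id`, `state`, `metric`.
#' @export
build_recursion_rasters <- function(fixes, stats, landscape,
                                    buffers = buffer_spec(), n_interp = 5,
                                    method = "linear") {
  broods <- unique(fixes$brood_id)
  out <- lapply(broods, function(b) {
    fx <- dplyr::filter(fixes, .data$brood_id == b)
    st <- dplyr::filter(stats, .data$brood_id == b)
    per_state <- lapply(c(restricted = "restricted", mobile = "mobile"), function(s) {
      lapply(c(revisit = "revisit", residence = "residence"), function(m) {
        raw <- suppressWarnings(
          recursion_intensity(fx, st, s, m, landscape, buffers, n_interp = n_interp))
        structure(list(values = rescale_0_100(raw, method),
                       origin = landscape$origin, cell_size = landscape$cell_size,
                       brood_id = b, state = s, metric = m),
                  class = "recursel_raster")
      })
    })
    per_state
  })
  names(out) <- broods
  out
}

#' @export
print.recursel_raster <- function(x, ...) {
  cat(sprintf("<recursel_raster> %s / %s / %s: %d x %d cells of %g m, range [%.1f, %.1f]\n",
              x$brood_id, x$state, x$metric, nrow(x$values), ncol(x$values),
              x$cell_size, min(x$values), max(x$values)))
  invisible(x)
}
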