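#' Landcover class codes
#'
#' Integer codes for the seven landcover classes used throughout the package:
#' water (1), pine forest (2), hardwood forest (3), mixed pine-hardwood forest
#' (4), open treeless (5), shrub/scrub (6), infrastructure (7).
#'
#' @return Named integer vector of length 7.
#' @export
landcover_classes <- function() {
  c(water = 1L, pine = 2L, hardwood = 3L, mixed = 4L,
    open = 5L, shrub = 6L, infrastructure = 7L)
}

# Separable Gaussian blur with edge-replicated padding.
blur_matrix <- function(m, sigma) {
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-k:k)^2) / (2 * sigma^2))
  w <- w / sum(w)
  pad <- function(mm) {
    top <- mm[rep(1L, k), , drop = FALSE]
    bot <- mm[rep(nrow(mm), k), , drop = FALSE]
    mm <- rbind(top, mm, bot)
    left <- mm[, rep(1L, k), drop = FALSE]
    right <- mm[, rep(ncol(mm), k), drop = FALSE]
    cbind(left, mm, right)
  }
  p <- pad(m)
  # convolve rows then columns
  p <- apply(p, 2, function(col) stats::filter(col, w, sides = 2))
  p <- t(apply(p, 1, function(row) stats::filter(row, w, sides = 2)))
  p[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))]
}

#' Generate a synthetic landscape
#'
#' Builds a spatially contiguous categorical landcover grid (7 classes), a
#' continuous NDVI grid in \[-1, 1\], and a set of road polylines, all on a
#' shared 30-m grid. Landcover is produced by smoothing independent Gaussian
#' noise fields (one per class) and taking the per-cell argmax, which yields
#' contiguous patches; NDVI is smoothed noise shifted upward in forested
#' classes and squashed through tanh.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param cell_size Cell edge length in meters (default 30).
#' @param origin Coordinate pair of the grid's lower-left corner (m).
#' @param n_roads Number of road polylines to lay across the extent.
#' @param smooth_sigma Blur bandwidth for the class noise fields, in cells.
#' @param seed Integer seed; the same seed reproduces the bundle bit for bit.
#' @return A `recursel_landscape` list: `origin`, `cell_size`, `n_rows`,
#'   `n_cols`, `landcover` (integer matrix, codes 1-7, row 1 = southern edge),
#'   `ndvi` (numeric matrix), `roads` (tibble of polyline vertices:
#'   `road_id`, `x`, `y`), `road_mask` (logical matrix of cells crossed by a
#'   road).
#' @export
#' @examples
#' ls <- generate_landscape(n_rows = 40, n_cols = 40, seed = 1)
#' table(ls$landcover)
generate_landscape <- function(n_rows = 100, n_cols = 100, cell_size = 30,
                               origin = c(0, 0), n_roads = 2,
                               smooth_sigma = 3, seed = 1) {
  stopifnot(n_rows >= 8, n_cols >= 8, cell_size > 0)
  set.seed(seed)
  k <- landcover_classes()
  fields <- lapply(seq_along(k), function(i) {
    blur_matrix(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), smooth_sigma)
  })
  arr <- simplify2array(fields)
  landcover <- apply(arr, c(1, 2), which.max)
  storage.mode(landcover) <- "integer"
  missing_cls <- setdiff(unname(k), sort(unique(as.vector(landcover))))
  if (length(missing_cls) > 0) {
    abort(sprintf(
      "grid too small to place all 7 landcover classes; missing code(s): %s",
      paste(missing_cls, collapse = ", ")))
  }

  # NDVI: smooth noise + vegetation-density offsets by class (forest > open > water)
  veg_offset <- c(-1.2, 0.7, 0.8, 0.75, 0.1, 0.4, -0.8)[landcover]
  z <- blur_matrix(matrix(rnorm(n_rows * n_cols, sd = 1), n_rows, n_cols), smooth_sigma)
  ndvi <- tanh(0.8 * matrix(veg_offset, n_rows, n_cols) + 1.5 * z)

  width <- n_cols * cell_size
  height <- n_rows * cell_size
  roads <- purrr::map_dfr(seq_len(n_roads), function(i) {
    if (i %% 2 == 1) { # roughly west-east
      y0 <- origin[2] + runif(1, 0.2, 0.8) * height
      tibble::tibble(
        road_id = i,
        x = origin[1] + c(0, 0.5, 1) * width,
        y = c(y0, y0 + runif(1, -0.15, 0.15) * height,
              y0 + runif(1, -0.25, 0.25) * height))
    } else {           # roughly south-north
      x0 <- origin[1] + runif(1, 0.2, 0.8) * width
      tibble::tibble(
        road_id = i,
        x = c(x0, x0 + runif(1, -0.15, 0.15) * width,
              x0 + runif(1, -0.25, 0.25) * width),
        y = origin[2] + c(0, 0.5, 1) * height)
    }
  })

  out <- structure(
    list(origin = as.numeric(origin), cell_size = cell_size,
         n_rows = n_rows, n_cols = n_cols,
         landcover = landcover, ndvi = ndvi, roads = roads,
         road_mask = NULL),
    class = "recursel_landscape")
  out$road_mask <- rasterize_roads(out)
  out
}

#' @export
print.recursel_landscape <- function(x, ...) {
  cat(sprintf("<recursel_landscape> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  landcover classes present: %s\n",
              paste(sort(unique(as.vector(x$landcover))), collapse = " ")))
  cat(sprintf("  ndvi range: [%.3f, %.3f]; %d road polyline(s)\n",
              min(x$ndvi), max(x$ndvi), length(unique(x$roads$road_id))))
  invisible(x)
}

# Cell index helpers. Row 1 is the southern edge; cell centers at
# origin + (index - 0.5) * cell_size.
point_to_cell <- function(landscape, x, y) {
  cs <- landscape$cell_size
  col <- floor((x - landscape$origin[1]) / cs) + 1
  row <- floor((y - landscape$origin[2]) / cs) + 1
  # points exactly on the max edge belong to the last cell
  col[x == landscape$origin[1] + landscape$n_cols * cs] <- landscape$n_cols
  row[y == landscape$origin[2] + landscape$n_rows * cs] <- landscape$n_rows
  bad <- col < 1 | col > landscape$n_cols | row < 1 | row > landscape$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

cell_centers <- function(landscape) {
  cs <- landscape$cell_size
  list(x = landscape$origin[1] + (seq_len(landscape$n_cols) - 0.5) * cs,
       y = landscape$origin[2] + (seq_len(landscape$n_rows) - 0.5) * cs)
}

landscape_extent <- function(landscape) {
  c(xmin = landscape$origin[1], ymin = landscape$origin[2],
    xmax = landscape$origin[1] + landscape$n_cols * landscape$cell_size,
    ymax = landscape$origin[2] + landscape$n_rows * landscape$cell_size)
}

# Mark cells crossed by a road polyline by sampling each segment at
# half-cell spacing.
rasterize_roads <- function(landscape) {
  mask <- matrix(FALSE, landscape$n_rows, landscape$n_cols)
  if (nrow(landscape$roads) == 0) return(mask)
  step <- landscape$cell_size / 2
  segs <- landscape$roads |>
    dplyr::group_by(.data$road_id) |>
    dplyr::reframe(x0 = head(.data$x, -1), y0 = head(.data$y, -1),
                   x1 = tail(.data$x, -1), y1 = tail(.data$y, -1))
  for (i in seq_len(nrow(segs))) {
    len <- sqrt((segs$x1[i] - segs$x0[i])^2 + (segs$y1[i] - segs$y0[i])^2)
    s <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    px <- segs$x0[i] + s * (segs$x1[i] - segs$x0[i])
    py <- segs$y0[i] + s * (segs$y1[i] - segs$y0[i])
    cc <- point_to_cell(landscape, px, py)
    ok <- !is.na(cc$row)
    mask[cbind(cc$row[ok], cc$col[ok])] <- TRUE
  }
  mask
}

# Exact Euclidean distance (m) from every cell center to the nearest TRUE
# cell center. Brute force over source cells, chunked to bound memory;
# exact for the small grids used here.
distance_to_mask <- function(mask, landscape, what = "feature") {
  src <- which(mask, arr.ind = TRUE)
  if (nrow(src) == 0) {
    abort(sprintf("cannot build a distance raster: no cells of class '%s' in the landscape", what))
  }
  cen <- cell_centers(landscape)
  sx <- cen$x[src[, 2]]
  sy <- cen$y[src[, 1]]
  gx <- rep(cen$x, each = landscape$n_rows)
  gy <- rep(cen$y, times = landscape$n_cols)
  n <- length(gx)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(1L, length(sx))))
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    d2 <- outer(gx[idx], sx, "-")^2 + outer(gy[idx], sy, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  matrix(out, landscape$n_rows, landscape$n_cols)
}

#' Distance-to-feature rasters
#'
#' Computes Euclidean distance rasters (m, cell-center to nearest feature
#' cell center) for each of the 7 landcover classes and for the road network,
#' on the landscape's own 30-m grid. Cells of the class itself get distance 0.
#'
#' @param landscape A `recursel_landscape`.
#' @return Named list of matrices: `dist_water`, `dist_pine`, `dist_hardwood`,
#'   `dist_mixed`, `dist_open`, `dist_shrub`, `dist_infrastructure`,
#'   `dist_roads`.
#' @export
distance_rasters <- function(landscape) {
  stopifnot(inherits(landscape, "recursel_landscape"))
  k <- landcover_classes()
  out <- lapply(names(k), function(nm) {
    distance_to_mask(landscape$landcover == k[[nm]], landscape, what = nm)
  })
  names(out) <- paste0("dist_", names(k))
  out$dist_roads <- distance_to_mask(landscape$road_mask, landscape, what = "roads")
  out
}

# Nearest-cell raster lookup; errors on out-of-extent points.
grid_lookup <- function(mat, landscape, x, y) {
  cc <- point_to_cell(landscape, x, y)
  if (anyNA(cc$row)) {
    i <- which(is.na(cc$row))[1]
    abort(sprintf("point (%.1f, %.1f) lies outside the landscape extent", x[i], y[i]))
  }
  mat[cbind(cc$row, cc$col)]
}

#' Write a grid to a TSV file
#'
#' Plain-text serialization of one landscape or recursion grid: a header of
#' `#` comment lines carrying the georeferencing (origin, cell size), then the
#' matrix rows from the northern edge down, tab-separated.
#'
#' @param mat Numeric or integer matrix (row 1 = southern edge).
#' @param origin,cell_size Grid registration.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(mat, origin, cell_size, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin_x %.10g", origin[1]), con)
  writeLines(sprintf("# origin_y %.10g", origin[2]), con)
  writeLines(sprintf("# cell_size %.10g", cell_size), con)
  write.table(mat[rev(seq_len(nrow(mat))), , drop = FALSE], con,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
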