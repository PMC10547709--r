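#' Sample available points for one used step
#'
#' Draws `n` available endpoints conditional on the previous fix: step length
#' from the fitted gamma distribution of the step's decoded state, and
#' absolute direction equal to the previous heading plus a draw from the
#' fitted von Mises distribution of that state. When the previous heading is
#' undefined (a burst-start step), the direction is drawn uniformly on
#' (-pi, pi].
#'
#' @param prev_x,prev_y Coordinates of the previous fix (m).
#' @param prev_heading Previous heading (rad) or `NA`.
#' @param params Fitted [hmm_params()] (or a `recursel_hmm_fit`).
#' @param state Decoded raw state index (1-3) of the used step.
#' @param n Number of available points (default 100).
#' @return Tibble with `x`, `y`, `sl` (drawn step length, m) and `ta` (drawn
#'   turning angle, rad; relative to `prev_heading` when defined).
#' @export
sample_available <- function(prev_x, prev_y, prev_heading, params, state, n = 100) {
  if (inherits(params, "recursel_hmm_fit")) params <- params$params
  sl <- rgamma(n, shape = gamma_shape(params$gamma_mean[state], params$gamma_sd[state]),
               scale = gamma_scale(params$gamma_mean[state], params$gamma_sd[state]))
  ta <- rvonmises(n, params$vm_mean[state], params$vm_kappa[state])
  ang <- if (is.na(prev_heading)) runif(n, -pi, pi) else prev_heading + ta
  tibble::tibble(x = prev_x + sl * cos(ang), y = prev_y + sl * sin(ang),
                 sl = sl, ta = ta)
}

#' Extract covariates at point locations
#'
#' Nearest-cell lookup (30-m raster semantics, no interpolation) of each
#' distance raster, NDVI, and the brood's own state-specific recursion
#' rasters. Points outside the landscape extent are an error.
#'
#' @param points Tibble with `x`, `y` (m).
#' @param landscape A `recursel_landscape`.
#' @param dist Distance raster list from [distance_rasters()].
#' @param brood_rasters One brood's raster set from
#'   [build_recursion_rasters()] (`rasters[[brood_id]]`), or `NULL` to skip
#'   recursion covariates.
#' @param state Merged state whose recursion rasters to read
#'   (`"restricted"`/`"mobile"`), required with `brood_rasters`.
#' @return `points` with `dist_*`, `ndvi`, and (if requested) `revisit` and
#'   `residence` columns appended.
#' @export
extract_covariates <- function(points, landscape, dist, brood_rasters = NULL,
                               state = NULL) {
  stopifnot(inherits(landscape, "recursel_landscape"))
  out <- points
  for (nm in names(dist)) {
    out[[nm]] <- grid_lookup(dist[[nm]], landscape, points$x, points$y)
  }
  out$ndvi <- grid_lookup(landscape$ndvi, landscape, points$x, points$y)
  if (!is.null(brood_rasters)) {
    if (is.null(state)) abort("state is required to pick the recursion rasters")
    out$revisit <- grid_lookup(brood_rasters[[state]]$revisit$values,
                               landscape, points$x, points$y)
    out$residence <- grid_lookup(brood_rasters[[state]]$residence$values,
                                 landscape, points$x, points$y)
  }
  out
}

#' Build used/available strata for step selection
#'
#' For every decoded step whose turning angle is defined (i.e. a previous
#' heading exists), emits one stratum: the observed endpoint (case 1) plus
#' `n_available` endpoints (case 0) sampled with [sample_available()] from
#' the fitted movement distributions of the step's decoded state. Covariates
#' are extracted for all points; the recursion covariates are read from the
#' brood's own rasters for the step's merged state. Movement covariates are
#' `log_sl = log(max(sl, 0.1))` and `cos_ta = cos(ta)`.
#'
#' Available points that fall outside the mapped extent are redrawn (the
#' availability distribution is truncated to the landscape); a point that
#' cannot be placed after `max_resample` rounds is an error.
#'
#' @param decoded Decoded step series ([viterbi()] output) for all broods.
#' @param hmm_fit The `recursel_hmm_fit` supplying movement distributions.
#' @param landscape,dist,rasters Landscape bundle, [distance_rasters()], and
#'   [build_recursion_rasters()] output.
#' @param n_available Available points per stratum (default 100).
#' @param seed Integer seed.
#' @param max_resample Redraw rounds for out-of-extent available points.
#' @return Long tibble, one row per point: `stratum_id`, `brood_id`, `period`,
#'   `state`, `case`, `x`, `y`, `sl`, `log_sl`, `cos_ta`, `dist_*`, `ndvi`,
#'   `revisit`, `residence`.
#' @export
build_strata <- function(decoded, hmm_fit, landscape, dist, rasters,
                         n_available = 100, seed = 1, max_resample = 50) {
  assert_cols(decoded, c("brood_id", "burst_id", "step_m", "turn_rad", "day",
                         "x0", "y0", "x1", "y1", "state_idx", "merged"), "decoded")
  set.seed(seed)
  params <- hmm_fit$params
  ext <- landscape_extent(landscape)
  inside <- function(x, y) {
    x >= ext["xmin"] & x <= ext["xmax"] & y >= ext["ymin"] & y <= ext["ymax"]
  }

  # previous heading: heading of the preceding step within the same burst
  decoded <- decoded |>
    dplyr::group_by(.data$brood_id, .data$burst_id) |>
    dplyr::mutate(
      heading = ifelse(.data$step_m > 0,
                       atan2(.data$y1 - .data$y0, .data$x1 - .data$x0), NA_real_),
      prev_heading = dplyr::lag(.data$heading)) |>
    dplyr::ungroup()

  use <- decoded[!is.na(decoded$turn_rad) & !is.na(decoded$prev_heading), ]
  if (nrow(use) == 0) abort("no steps with a defined turning angle; cannot build strata")

  strata <- purrr::map_dfr(seq_len(nrow(use)), function(i) {
    st <- use[i, ]
    av <- sample_available(st$x0, st$y0, st$prev_heading, params,
                           st$state_idx, n = n_available)
    tries <- 0L
    while (any(!inside(av$x, av$y)) && tries < max_resample) {
      bad <- which(!inside(av$x, av$y))
      av[bad, ] <- sample_available(st$x0, st$y0, st$prev_heading, params,
                                    st$state_idx, n = length(bad))
      tries <- tries + 1L
    }
    if (any(!inside(av$x, av$y))) {
      abort(sprintf("could not place available points inside the extent for stratum %d", i))
    }
    tibble::tibble(
      stratum_id = i, brood_id = st$brood_id,
      period = period_of_day(st$day), state = st$merged,
      case = c(1L, rep(0L, n_available)),
      x = c(st$x1, av$x), y = c(st$y1, av$y),
      sl = c(st$step_m, av$sl), ta = c(st$turn_rad, av$ta))
  })

  strata$log_sl <- log(pmax(strata$sl, 0.1))
  strata$cos_ta <- cos(strata$ta)

  # covariates, grouped by brood x state so each group reads one raster set
  strata |>
    dplyr::group_by(.data$brood_id, .data$state) |>
    dplyr::group_modify(function(g, key) {
      extract_covariates(g, landscape, dist,
                         brood_rasters = rasters[[key$brood_id]],
                         state = key$state)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$stratum_id, dplyr::desc(.data$case))
}

#' Scale and center covariates
#'
#' Standardizes each requested covariate to mean 0, sd 1 (sd with n-1) over
#' the full used+available table. Movement covariates (`log_sl`, `cos_ta`)
#' are kept on their natural scale by default. A zero-variance covariate is
#' an error naming the column.
#'
#' @param table Strata table (long format).
#' @param cols Columns to standardize; defaults to every `dist_*` column plus
#'   `ndvi`, `revisit`, `residence` that is present.
#' @param scale_movement Also standardize `log_sl` and `cos_ta`?
#' @return List: `table` (standardized) and `scaling` (tibble of the means
#'   and sds applied).
#' @export
scale_center <- function(table, cols = NULL, scale_movement = FALSE) {
  if (is.null(cols)) {
    cols <- intersect(c(grep("^dist_", names(table), value = TRUE),
                        "ndvi", "revisit", "residence"), names(table))
    if (scale_movement) cols <- c(cols, intersect(c("log_sl", "cos_ta"), names(table)))
  }
  scaling <- purrr::map_dfr(cols, function(cn) {
    v <- table[[cn]]
    if (anyNA(v) || any(!is.finite(v))) abort(sprintf("covariate '%s' has non-finite values", cn))
    s <- sd(v)
    if (s == 0) abort(sprintf("covariate '%s' has zero variance; cannot scale", cn))
    tibble::tibble(term = cn, center = mean(v), scale = s)
  })
  for (i in seq_len(nrow(scaling))) {
    cn <- scaling$term[i]
    table[[cn]] <- (table[[cn]] - scaling$center[i]) / scaling$scale[i]
  }
  list(table = table, scaling = scaling)
}

#' Pairwise Pearson correlation screen
#'
#' Computes all pairwise Pearson correlations among the given covariates and
#' flags pairs with `|r|` above the threshold. Nothing is dropped
#' automatically; a warning lists the flagged pairs.
#'
#' @param table Strata (or any) table.
#' @param cols Covariate columns; defaults as in [scale_center()].
#' @param threshold Flagging threshold (default 0.7).
#' @return Tibble `var1`, `var2`, `r`, `flagged`, with the threshold recorded
#'   in attribute `"threshold"`.
#' @export
correlation_screen <- function(table, cols = NULL, threshold = 0.7) {
  if (is.null(cols)) {
    cols <- intersect(c(grep("^dist_", names(table), value = TRUE),
                        "ndvi", "revisit", "residence", "log_sl", "cos_ta"),
                      names(table))
  }
  if (length(cols) < 2) abort("need at least two covariates to screen")
  cm <- cor(as.matrix(table[cols]))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(var1 = cols[idx[, 1]], var2 = cols[idx[, 2]],
                        r = cm[idx], flagged = abs(cm[idx]) > threshold)
  attr(out, "threshold") <- threshold
  if (any(out$flagged)) {
    warn(sprintf("correlation screen: %d pair(s) exceed |r| > %g: %s",
                 sum(out$flagged), threshold,
                 paste(out$var1[out$flagged], out$var2[out$flagged],
                       sep = "~", collapse = ", ")))
  }
  out
}

#' Candidate model specifications
#'
#' The three candidate structures for one period x state x metric block:
#' a landcover model (distance to secondary roads, hardwoods, mixed
#' pine-hardwoods, open, pine, shrub/scrub, plus NDVI and the movement terms
#' cos_ta and log_sl), a recursion-only model (the single recursion
#' covariate), and a composite model (landcover + recursion + all landcover x
#' recursion interactions).
#'
#' @param period `"ground"` or `"tree"`.
#' @param state `"restricted"` or `"mobile"`.
#' @param metric `"revisit"` or `"residence"`.
#' @return List of three specs, each a list with `name`, `period`, `state`,
#'   `metric` and `terms` (character vector of model terms).
#' @export
candidate_set <- function(period, state, metric) {
  period <- match.arg(period, c("ground", "tree"))
  state <- match.arg(state, c("restricted", "mobile"))
  metric <- match.arg(metric, c("revisit", "residence"))
  landcover_main <- c("dist_roads", "dist_hardwood", "dist_mixed", "ndvi",
                      "dist_open", "dist_pine", "dist_shrub")
  movement <- c("cos_ta", "log_sl")
  specs <- list(
    list(name = "landcover", terms = c(landcover_main, movement)),
    list(name = "recursion_only", terms = metric),
    list(name = "composite",
         terms = c(landcover_main, movement, metric,
                   paste(landcover_main, metric, sep = ":"))))
  lapply(specs, function(s) c(s, list(period = period, state = state, metric = metric)))
}

ssf_design <- function(strata, terms) {
  f <- stats::reformulate(terms, intercept = FALSE)
  X <- stats::model.matrix(f, data = strata)
  if (nrow(X) != nrow(strata)) abort("model matrix dropped rows (missing covariate values?)")
  X
}

#' Fit a step-selection model
#'
#' Fits the selection coefficients of a used/available design by maximizing
#' the stratified conditional-logistic log-likelihood
#' `sum_s [ x_used' b - log sum_j exp(x_j' b) ]`
#' with Newton-Raphson (method `"conditional"`, the default; this is the
#' exact infinite-variance limit of the fixed-large-variance Poisson
#' formulation). Method `"poisson"` instead fits the explicit Poisson model
#' with stratum-specific intercepts whose variance is fixed large (10^6) via
#' glmmTMB, and is provided to verify the equivalence of the two routes.
#' Standard errors come from the inverse observed information.
#'
#' A covariate with no within-stratum contrast is inestimable; its
#' coefficient is fixed at 0 (SE `NA`). Apparent quasi-complete separation
#' (diverging coefficients) is an error naming the offending covariate.
#'
#' @param strata Long strata table (needs `stratum_id`, `case`, covariates).
#' @param terms Character vector of model terms (may include `a:b`
#'   interactions), or a spec from [candidate_set()].
#' @param method `"conditional"` or `"poisson"`.
#' @param name Model name for reporting (defaults from the spec, if given).
#' @return A `recursel_ssf_fit`: `name`, `terms`, `coefficients` (tibble:
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`), `loglik`,
#'   `K`, `n_strata`, `method`, `converged`.
#' @export
fit_ssf <- function(strata, terms, method = c("conditional", "poisson"),
                    name = NULL) {
  method <- match.arg(method)
  spec_meta <- NULL
  if (is.list(terms) && !is.null(terms$terms)) {
    name <- name %||% terms$name
    spec_meta <- terms[c("period", "state", "metric")]
    terms <- terms$terms
  }
  assert_cols(strata, c("stratum_id", "case"), "strata")
  if (!all(tapply(strata$case, strata$stratum_id, sum) == 1)) {
    abort("every stratum must contain exactly one used point (case == 1)")
  }
  X <- ssf_design(strata, terms)
  if (method == "conditional") {
    fit <- fit_clogit_newton(X, strata$case, strata$stratum_id)
  } else {
    fit <- fit_poisson_trick(X, strata$case, strata$stratum_id, strata)
  }
  structure(
    c(list(name = name %||% paste(terms, collapse = "+"), terms = terms,
           method = method, spec = spec_meta), fit),
    class = "recursel_ssf_fit")
}

fit_clogit_newton <- function(X, case, stratum, max_iter = 60, tol = 1e-10) {
  p <- ncol(X)
  sid <- match(stratum, unique(stratum))
  S <- max(sid)
  used <- which(case == 1)
  # columns with no within-stratum contrast are inestimable; fix their beta at 0
  col_active <- vapply(seq_len(p), function(j) {
    any(tapply(X[, j], sid, function(v) max(v) - min(v)) > 1e-12)
  }, logical(1))
  Xa <- X[, col_active, drop = FALSE]
  pa <- ncol(Xa)
  # exact single-covariate separation diagnostic: if the used point attains
  # the stratum max (or min) of a covariate in every stratum, its conditional
  # MLE diverges (quasi-complete separation)
  for (j in seq_len(pa)) {
    mx <- as.vector(tapply(Xa[, j], sid, max))
    mn <- as.vector(tapply(Xa[, j], sid, min))
    xu <- numeric(length(mx))
    xu[sid[used]] <- Xa[used, j]
    if (all(xu >= mx - 1e-12) || all(xu <= mn + 1e-12)) {
      abort(sprintf(paste0(
        "quasi-complete separation: '%s' is extreme for the used point in ",
        "every stratum; its selection coefficient is not estimable"),
        colnames(Xa)[j]))
    }
  }
  beta <- rep(0, pa)
  conv <- FALSE
  ll <- -Inf
  if (pa > 0) {
    obj <- function(b) {
      eta <- drop(Xa %*% b)
      mxs <- as.vector(tapply(eta, sid, max))
      denom <- drop(rowsum(exp(eta - mxs[sid]), sid))
      sum(eta[used]) - sum(log(denom) + mxs)
    }
    separation <- function() {
      j <- which.max(abs(beta))
      abort(sprintf(paste0(
        "quasi-complete separation: coefficient for '%s' diverges; ",
        "the covariate (nearly) perfectly ranks used vs available points"),
        colnames(Xa)[j]))
    }
    for (it in seq_len(max_iter)) {
      eta <- drop(Xa %*% beta)
      # per-stratum log-sum-exp with max shift
      mxs <- as.vector(tapply(eta, sid, max))
      ee <- exp(eta - mxs[sid])
      denom <- drop(rowsum(ee, sid))
      w <- ee / denom[sid]
      ll <- sum(eta[used]) - sum(log(denom) + mxs)
      grad <- colSums(Xa[used, , drop = FALSE]) - drop(crossprod(Xa, w))
      M <- rowsum(Xa * w, sid)                     # S x pa stratum means
      H <- -(crossprod(Xa * sqrt(w)) - crossprod(M))
      if (max(abs(grad)) < 1e-8) { conv <- TRUE; break }
      step <- try(solve(-H, grad), silent = TRUE)
      if (inherits(step, "try-error")) {
        abort("singular information matrix in the conditional fit (separation or collinearity)")
      }
      # step-halving keeps Newton monotone on awkward starts
      lam <- 1
      while (lam > 1e-4 && obj(beta + lam * step) < ll - 1e-10) lam <- lam / 2
      beta <- beta + lam * step
      if (max(abs(beta)) > 100) separation()
      if (max(abs(lam * step)) < tol) { conv <- TRUE; break }
    }
    if (!conv) separation()
    vcv <- try(solve(-H), silent = TRUE)
    se_a <- if (inherits(vcv, "try-error")) rep(NA_real_, pa) else sqrt(pmax(diag(vcv), 0))
  } else {
    # all covariates stratum-constant: null model
    eta <- rep(0, length(sid))
    ll <- -sum(log(tabulate(sid)))
    conv <- TRUE
    se_a <- numeric(0)
  }
  est <- rep(0, p); se <- rep(NA_real_, p)
  est[col_active] <- beta
  se[col_active] <- se_a
  list(coefficients = tibble::tibble(
         term = colnames(X), estimate = est, std.error = se,
         conf.low = est - 1.96 * se, conf.high = est + 1.96 * se),
       loglik = ll, K = p, n_strata = S, converged = conv)
}

fit_poisson_trick <- function(X, case, stratum, strata, fixed_var = 1e6) {
  if (!requireNamespace("glmmTMB", quietly = TRUE)) {
    abort("method 'poisson' needs the glmmTMB package")
  }
  df <- as.data.frame(X, check.names = FALSE)
  safe <- paste0("v", seq_len(ncol(X)))
  names(df) <- safe
  df$..case <- case
  df$..stratum <- factor(stratum)
  f <- stats::as.formula(paste("..case ~", paste(safe, collapse = " + "),
                               "+ (1 | ..stratum)"))
  m <- glmmTMB::glmmTMB(
    f, data = df, family = stats::poisson(),
    map = list(theta = factor(NA)),
    start = list(theta = log(sqrt(fixed_var))))
  co <- glmmTMB::fixef(m)$cond[-1]           # drop the global intercept
  se <- sqrt(diag(stats::vcov(m)$cond))[-1]
  list(coefficients = tibble::tibble(
         term = colnames(X), estimate = unname(co), std.error = unname(se),
         conf.low = unname(co - 1.96 * se), conf.high = unname(co + 1.96 * se)),
       loglik = as.numeric(stats::logLik(m)), K = ncol(X),
       n_strata = length(unique(stratum)),
       converged = isTRUE(m$fit$convergence == 0))
}

#' Linear predictor of a fitted step-selection model
#'
#' @param fit A `recursel_ssf_fit`.
#' @param strata Strata table with the model's covariates.
#' @return Numeric vector, one value per row of `strata`.
#' @export
predict_ssf <- function(fit, strata) {
  X <- ssf_design(strata, fit$terms)
  drop(X %*% fit$coefficients$estimate)
}

#' @export
print.recursel_ssf_fit <- function(x, ...) {
  cat(sprintf("<recursel_ssf_fit> %s (%s): K = %d, %d strata, loglik %.2f%s\n",
              x$name, x$method, x$K, x$n_strata, x$loglik,
              if (x$converged) "" else " [NOT converged]"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
tidy.recursel_ssf_fit <- function(x, ...) x$coefficients

#' @export
glance.recursel_ssf_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, K = x$K, n_strata = x$n_strata,
                 method = x$method, converged = x$converged)
}
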