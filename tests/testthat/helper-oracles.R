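# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own recursions: likelihoods by exhaustive path
# enumeration, recursion statistics by O(n^2) re-scanning with fine time
# discretization, AUC by pairwise concordance counting.

# emission density matrix computed from first principles (not via the package)
oracle_emission <- function(params, steps) {
  n <- nrow(steps)
  dens <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    sh <- (params$gamma_mean[k] / params$gamma_sd[k])^2
    sc <- params$gamma_sd[k]^2 / params$gamma_mean[k]
    g <- stats::dgamma(steps$step_m, shape = sh, scale = sc)
    v <- ifelse(is.na(steps$turn_rad), 1,
                exp(params$vm_kappa[k] * cos(steps$turn_rad - params$vm_mean[k])) /
                  (2 * pi * besselI(params$vm_kappa[k], 0)))
    dens[, k] <- g * v
  }
  dens
}

all_state_paths <- function(T, K = 3) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# log-likelihood by summing over every state path (single burst)
oracle_forward <- function(params, steps) {
  dens <- oracle_emission(params, steps)
  paths <- all_state_paths(nrow(steps))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    p <- params$initial_dist[s[1]] * dens[1, s[1]]
    for (t in seq_along(s)[-1]) {
      p <- p * params$transition[s[t - 1], s[t]] * dens[t, s[t]]
    }
    tot <- tot + p
  }
  log(tot)
}

# most probable path by exhaustive search (unique argmax assumed)
oracle_viterbi <- function(params, steps) {
  dens <- oracle_emission(params, steps)
  paths <- all_state_paths(nrow(steps))
  lp <- apply(paths, 1, function(s) {
    p <- log(params$initial_dist[s[1]]) + log(dens[1, s[1]])
    for (t in seq_along(s)[-1]) {
      p <- p + log(params$transition[s[t - 1], s[t]]) + log(dens[t, s[t]])
    }
    p
  })
  list(path = unname(paths[which.max(lp), ]), logp = max(lp))
}

# log-probability of one given path (for Viterbi dominance checks)
oracle_path_logp <- function(params, steps, s) {
  dens <- oracle_emission(params, steps)
  p <- log(params$initial_dist[s[1]]) + log(dens[1, s[1]])
  for (t in seq_along(s)[-1]) {
    p <- p + log(params$transition[s[t - 1], s[t]]) + log(dens[t, s[t]])
  }
  p
}

random_hmm_params <- function() {
  rdirichlet1 <- function() { x <- rgamma(3, 2); x / sum(x) }
  tr <- rbind(rdirichlet1(), rdirichlet1(), rdirichlet1())
  hmm_params(gamma_mean = runif(3, 10, 500), gamma_sd = runif(3, 10, 500),
             vm_mean = runif(3, -pi, pi), vm_kappa = runif(3, 0, 3),
             transition = tr, initial_dist = rdirichlet1())
}

random_steps <- function(T) {
  tibble::tibble(burst_id = "b1", step_m = rgamma(T, 2, 0.02),
                 turn_rad = c(NA, runif(T - 1, -pi, pi)))
}

# O(n^2) recursion oracle: for each focal fix, re-scan the whole track.
# Visits are runs of inside fixes (closed disc) within a burst. Entry/exit
# instants are found by scanning the adjacent boundary inter-fix segments in
# `dt`-second increments, then refining the bracketing step by root-finding
# on the distance function (uniroot) — independent of the package's analytic
# line-circle solution.
oracle_recursion <- function(fx, radii, dt = 1, max_gap_h = 1) {
  n <- nrow(fx)
  tt <- as.numeric(fx$timestamp)
  gap_h <- c(Inf, diff(tt) / 3600)
  burst <- cumsum(gap_h > max_gap_h + 1e-9 | c(TRUE, fx$day[-1] != fx$day[-n]))

  # time of the first inside instant on segment j -> j2, scanning forward
  crossing_time <- function(j, j2, cx, cy, r, first_inside) {
    t1 <- tt[j]; t2 <- tt[j2]
    f_dist <- function(t) {
      frac <- (t - t1) / (t2 - t1)
      sqrt((fx$x[j] + frac * (fx$x[j2] - fx$x[j]) - cx)^2 +
             (fx$y[j] + frac * (fx$y[j2] - fx$y[j]) - cy)^2) - r
    }
    grid <- seq(t1, t2, by = dt)
    if (grid[length(grid)] < t2) grid <- c(grid, t2)
    ins <- f_dist(grid) <= 0   # f_dist is vectorized arithmetic
    k <- if (first_inside) which(ins)[1] else rev(which(ins))[1]
    if (is.na(k)) return(NA_real_)
    if (first_inside) {
      if (k == 1) return(grid[1])
      stats::uniroot(f_dist, c(grid[k - 1], grid[k]), tol = 1e-9)$root
    } else {
      if (k == length(grid)) return(grid[length(grid)])
      stats::uniroot(f_dist, c(grid[k], grid[k + 1]), tol = 1e-9)$root
    }
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- radii[[fx$state[i]]]
    inside <- sqrt((fx$x - fx$x[i])^2 + (fx$y - fx$y[i])^2) <= r
    segs <- NULL
    a <- 1L
    while (a <= n) {
      if (!inside[a]) { a <- a + 1L; next }
      b <- a
      while (b < n && inside[b + 1L] && burst[b + 1L] == burst[b]) b <- b + 1L
      entry <- tt[a]
      if (a > 1L && burst[a - 1L] == burst[a] && !inside[a - 1L]) {
        e <- crossing_time(a - 1L, a, fx$x[i], fx$y[i], r, first_inside = TRUE)
        if (!is.na(e)) entry <- e
      }
      exit <- tt[b]
      if (b < n && burst[b + 1L] == burst[b] && !inside[b + 1L]) {
        e <- crossing_time(b, b + 1L, fx$x[i], fx$y[i], r, first_inside = FALSE)
        if (!is.na(e)) exit <- e
      }
      segs <- rbind(segs, c(entry, exit, fx$day[a]))
      a <- b + 1L
    }
    out[[i]] <- list(revisits = sum(segs[, 3] != fx$day[i]),
                     residence_h = sum(segs[, 2] - segs[, 1]) / 3600,
                     n_segments = nrow(segs))
  }
  out
}

# synthetic conditional-logistic strata with known coefficients
simulate_clogit_strata <- function(S, n_avail, beta, seed) {
  set.seed(seed)
  m <- n_avail + 1L
  p <- length(beta)
  purrr::map_dfr(seq_len(S), function(s) {
    X <- matrix(rnorm(m * p), m, p)
    eta <- drop(X %*% beta)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    used <- sample.int(m, 1, prob = w)
    out <- tibble::as_tibble(as.data.frame(X))
    names(out) <- paste0("x", seq_len(p))
    out$stratum_id <- s
    out$case <- as.integer(seq_len(m) == used)
    out
  })
}

# small synthetic scene shared by covariate/strata tests
make_test_scene <- function(seed = 11, n_days = 28, n_broods = 2,
                            n_rows = 50, n_cols = 50) {
  landscape <- generate_landscape(n_rows = n_rows, n_cols = n_cols, seed = seed)
  cfg <- sim_config(n_broods = n_broods, n_days = n_days, seed = seed,
                    censor_prob = 0)
  fixes <- simulate_broods(cfg, landscape)
  clean <- drop_roost_fixes(filter_dop(fixes))
  steps <- build_steps(clean)
  list(landscape = landscape, cfg = cfg, fixes = fixes, clean = clean,
       steps = steps)
}
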