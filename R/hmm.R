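#' Hidden Markov model parameters for step/turn data
#'
#' Parameter container for a 3-state HMM whose per-state emissions are a gamma
#' step-length distribution (parameterized by mean and sd, converted
#' internally to shape/scale) times a von Mises turning-angle distribution.
#' An optional per-state zero-mass component gives positive probability to an
#' exact zero step (GPS jitter); it is off by default.
#'
#' @param gamma_mean,gamma_sd Per-state step-length mean and sd (m), length 3.
#' @param vm_mean Per-state turning-angle mean direction (rad), length 3.
#' @param vm_kappa Per-state concentration, `>= 0`, length 3.
#' @param transition 3x3 row-stochastic transition matrix.
#' @param initial_dist Length-3 initial state distribution (each burst
#'   restarts from it).
#' @param zero_mass Optional per-state probability of an exact zero step.
#' @return A validated `recursel_hmm_params` object.
#' @export
hmm_params <- function(gamma_mean, gamma_sd, vm_mean, vm_kappa,
                       transition = matrix(1 / 3, 3, 3),
                       initial_dist = rep(1 / 3, 3),
                       zero_mass = NULL) {
  p <- structure(
    list(n_states = 3L, gamma_mean = as.numeric(gamma_mean),
         gamma_sd = as.numeric(gamma_sd), vm_mean = as.numeric(vm_mean),
         vm_kappa = as.numeric(vm_kappa), transition = transition,
         initial_dist = as.numeric(initial_dist), zero_mass = zero_mass),
    class = "recursel_hmm_params")
  validate_hmm_params(p)
  p
}

validate_hmm_params <- function(p) {
  K <- p$n_states
  for (f in c("gamma_mean", "gamma_sd", "vm_mean", "vm_kappa")) {
    if (length(p[[f]]) != K) abort(sprintf("%s must have length %d", f, K))
  }
  if (any(p$gamma_mean <= 0) || any(p$gamma_sd <= 0)) {
    abort("gamma means and sds must be positive")
  }
  if (any(p$vm_kappa < 0)) abort("von Mises concentrations must be >= 0")
  if (!is.matrix(p$transition) || any(dim(p$transition) != K) ||
      any(abs(rowSums(p$transition) - 1) > 1e-10) || any(p$transition < 0)) {
    abort("transition must be a row-stochastic KxK matrix (rows sum to 1 within 1e-10)")
  }
  if (abs(sum(p$initial_dist) - 1) > 1e-10 || any(p$initial_dist < 0)) {
    abort("initial_dist must be a probability vector")
  }
  if (!is.null(p$zero_mass) &&
      (length(p$zero_mass) != K || any(p$zero_mass < 0) || any(p$zero_mass >= 1))) {
    abort("zero_mass must be per-state probabilities in [0, 1)")
  }
  invisible(p)
}

#' Canonical 3-state starting values
#'
#' The standard 3-state initialization for brood movement: a stationary state
#' (gamma mean 27 m, sd 27 m; von Mises mean pi, concentration 0.1), a
#' restricted state (150 m / 150 m; mean 2.5, concentration 0.5), and a
#' travelling state (400 m / 1000 m; mean 0.001, concentration 0.99), with
#' persistent transitions (diagonal 0.9) and a uniform initial distribution.
#'
#' @return A `recursel_hmm_params` object.
#' @export
default_hmm_init <- function() {
  hmm_params(
    gamma_mean = c(27, 150, 400), gamma_sd = c(27, 150, 1000),
    vm_mean = c(pi, 2.5, 0.001), vm_kappa = c(0.1, 0.5, 0.99),
    transition = matrix(c(0.9, 0.05, 0.05, 0.05, 0.9, 0.05, 0.05, 0.05, 0.9),
                        3, 3, byrow = TRUE),
    initial_dist = rep(1 / 3, 3))
}

# n x K matrix of log emission densities. Missing turn angles contribute no
# turning-angle term; zero steps require a zero-mass component.
log_emission_matrix <- function(params, steps) {
  assert_cols(steps, c("step_m", "turn_rad"), "steps")
  n <- nrow(steps)
  K <- params$n_states
  zm <- params$zero_mass %||% rep(0, K)
  if (any(steps$step_m == 0) && all(zm == 0)) {
    i <- which(steps$step_m == 0)[1]
    abort(sprintf(paste0(
      "zero-length step at row %d has no finite emission density ",
      "(zero_mass = 0); jitter zero steps or set a zero-mass component"), i))
  }
  ld <- matrix(NA_real_, n, K)
  zero <- steps$step_m == 0
  has_turn <- !is.na(steps$turn_rad)
  for (k in seq_len(K)) {
    g <- dgamma(steps$step_m,
                shape = gamma_shape(params$gamma_mean[k], params$gamma_sd[k]),
                scale = gamma_scale(params$gamma_mean[k], params$gamma_sd[k]),
                log = TRUE) + log(1 - zm[k])
    g[zero] <- log(zm[k])
    v <- numeric(n)
    v[has_turn] <- dvonmises(steps$turn_rad[has_turn],
                             params$vm_mean[k], params$vm_kappa[k], log = TRUE)
    ld[, k] <- g + v
  }
  if (any(is.nan(ld))) {
    i <- which(apply(ld, 1, anyNA))[1]
    abort(sprintf("non-finite emission density at step row %d (step_m = %g)",
                  i, steps$step_m[i]))
  }
  ld
}

new_burst_flags <- function(steps) {
  n <- nrow(steps)
  c(TRUE, steps$burst_id[-1] != steps$burst_id[-n])
}

#' Simulate a step series directly from an HMM
#'
#' Draws hidden states from the Markov chain and observed step lengths /
#' turning angles from the state's gamma and von Mises emission
#' distributions. This is the exact generative counterpart of the fitted
#' model (no landscape, no patch attraction), intended for parameter-recovery
#' studies.
#'
#' @param params [hmm_params()] to generate from.
#' @param n Number of steps.
#' @param seed Integer seed.
#' @param burst_len Steps per burst (default one single burst); each burst
#'   restarts the chain from `initial_dist` and its first turn is missing.
#' @return Step series tibble: `burst_id`, `step_m`, `turn_rad`,
#'   `true_state`.
#' @export
simulate_hmm_steps <- function(params, n, seed = 1, burst_len = n) {
  validate_hmm_params(params)
  set.seed(seed)
  burst <- rep(seq_len(ceiling(n / burst_len)), each = burst_len)[seq_len(n)]
  state <- integer(n)
  step <- numeric(n)
  turn <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    new_b <- t == 1 || burst[t] != burst[t - 1]
    state[t] <- if (new_b) {
      sample.int(3, 1, prob = params$initial_dist)
    } else {
      sample.int(3, 1, prob = params$transition[state[t - 1], ])
    }
    step[t] <- rgamma(1, shape = gamma_shape(params$gamma_mean[state[t]],
                                             params$gamma_sd[state[t]]),
                      scale = gamma_scale(params$gamma_mean[state[t]],
                                          params$gamma_sd[state[t]]))
    if (!new_b) {
      turn[t] <- rvonmises(1, params$vm_mean[state[t]], params$vm_kappa[state[t]])
    }
  }
  tibble::tibble(burst_id = sprintf("sim_%04d", burst), step_m = step,
                 turn_rad = turn, true_state = state)
}

#' Forward log-likelihood of a step series
#'
#' Exact log-likelihood of the observed step/turn stream under the HMM,
#' computed by the scaled forward recursion in log space. Each burst restarts
#' from the initial distribution; bursts are treated as independent.
#'
#' @param params A [hmm_params()] object.
#' @param steps A step series from [build_steps()] (needs `burst_id`,
#'   `step_m`, `turn_rad`).
#' @return The log-likelihood (scalar).
#' @export
forward_loglik <- function(params, steps) {
  validate_hmm_params(params)
  if (nrow(steps) == 0) abort("empty step series")
  ld <- log_emission_matrix(params, steps)
  forward_loglik_cpp(ld, log(params$transition), log(params$initial_dist),
                     new_burst_flags(steps))
}

# ---- working-scale transforms -------------------------------------------
# theta = (log gmean[3], log gsd[3], vm_mean[3], log kappa[3],
#          trans logits[6] (off-diagonal, reference = diagonal),
#          init logits[2] (reference = state 1))
pack_params <- function(p) {
  tr <- p$transition
  eta_tr <- unlist(lapply(1:3, function(i) {
    off <- setdiff(1:3, i)
    log(pmax(tr[i, off], 1e-12)) - log(max(tr[i, i], 1e-12))
  }))
  eta_in <- log(pmax(p$initial_dist[2:3], 1e-12)) - log(max(p$initial_dist[1], 1e-12))
  c(log(p$gamma_mean), log(p$gamma_sd), p$vm_mean,
    log(pmax(p$vm_kappa, 1e-8)), eta_tr, eta_in)
}

unpack_params <- function(theta, zero_mass = NULL) {
  tr <- matrix(0, 3, 3)
  for (i in 1:3) {
    off <- setdiff(1:3, i)
    e <- c(0, theta[12 + (i - 1) * 2 + 1:2])          # diagonal is reference
    w <- exp(e - max(e))
    w <- w / sum(w)
    tr[i, i] <- w[1]
    tr[i, off] <- w[2:3]
  }
  e <- c(0, theta[19:20])
  w <- exp(e - max(e)); w <- w / sum(w)
  hmm_params(gamma_mean = exp(theta[1:3]), gamma_sd = exp(theta[4:6]),
             vm_mean = wrap_angle(theta[7:9]),
             vm_kappa = pmax(exp(theta[10:12]), 1e-8),
             transition = tr, initial_dist = w, zero_mass = zero_mass)
}

#' Fit the 3-state movement HMM by direct likelihood maximization
#'
#' Maximizes the forward log-likelihood by quasi-Newton (BFGS) optimization on
#' unconstrained working scales (log links for positive parameters,
#' multinomial-logit rows for the transition matrix and initial distribution),
#' with multiple restarts from multiplicatively jittered starting values.
#' Confidence intervals come from the inverse numerical Hessian on the working
#' scale, back-transformed. Fitted states are relabelled by sorting on the
#' gamma mean (ascending), which resolves label switching deterministically:
#' state 1 = stationary, 2 = restricted, 3 = travelling.
#'
#' Exact zero step lengths have no gamma density; unless `init$zero_mass` is
#' set, they are jittered by U(0, 0.1) m before fitting (reported in the
#' fit object as `n_jittered`).
#'
#' @param steps Step series from [build_steps()].
#' @param init Starting [hmm_params()]; defaults to [default_hmm_init()].
#' @param n_restarts Number of optimizer starts (first from `init` unless
#'   `jitter_all`), further starts jittered +/-30%.
#' @param seed Integer seed controlling jitter (and zero-step jitter).
#' @param jitter_all Jitter the first start too (use when `init` equals the
#'   generative truth and an honest cold start is wanted).
#' @param maxit Maximum BFGS iterations per start.
#' @return A `recursel_hmm_fit`: `params` (sorted), `loglik`, `n_obs`, `ci`
#'   (tibble of emission-parameter 95% intervals), `converged`,
#'   `n_restarts_used`, `n_jittered`, `seed`.
#' @export
fit_hmm <- function(steps, init = default_hmm_init(), n_restarts = 2,
                    seed = 1, jitter_all = FALSE, maxit = 500) {
  validate_hmm_params(init)
  if (nrow(steps) == 0) abort("empty step series")
  set.seed(seed)
  n_jittered <- 0L
  if (is.null(init$zero_mass) && any(steps$step_m == 0)) {
    z <- steps$step_m == 0
    n_jittered <- sum(z)
    steps$step_m[z] <- runif(n_jittered, 0, 0.1)
  }
  nb <- new_burst_flags(steps)
  negll <- function(theta) {
    p <- try(unpack_params(theta, init$zero_mass), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ld <- try(suppressWarnings(log_emission_matrix(p, steps)), silent = TRUE)
    if (inherits(ld, "try-error")) return(1e10)
    v <- -forward_loglik_cpp(ld, log(p$transition), log(p$initial_dist), nb)
    if (!is.finite(v)) 1e10 else v
  }
  jitter_theta <- function(theta) {
    th <- theta
    th[c(1:6, 10:12)] <- th[c(1:6, 10:12)] + log(runif(9, 0.7, 1.3))
    th[7:9] <- th[7:9] + runif(3, -0.5, 0.5)
    th[13:20] <- th[13:20] + runif(8, -0.5, 0.5)
    th
  }
  theta0 <- pack_params(init)
  best <- NULL
  n_used <- 0L
  for (r in seq_len(n_restarts)) {
    th <- if (r == 1 && !jitter_all) theta0 else jitter_theta(theta0)
    fit <- try(optim(th, negll, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    n_used <- n_used + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("all optimizer restarts failed; no HMM fit available")

  params <- unpack_params(best$par, init$zero_mass)
  # CIs from the inverse observed information on the working scale
  ci <- hmm_ci(best$par, negll, init$zero_mass)
  ord <- order(params$gamma_mean)
  fit <- structure(
    list(params = permute_states(params, ord),
         loglik = -best$value, n_obs = nrow(steps),
         ci = permute_ci(ci, ord),
         converged = best$convergence == 0,
         n_restarts_used = n_used, n_jittered = n_jittered, seed = seed),
    class = "recursel_hmm_fit")
  fit
}

permute_states <- function(p, ord) {
  hmm_params(gamma_mean = p$gamma_mean[ord], gamma_sd = p$gamma_sd[ord],
             vm_mean = p$vm_mean[ord], vm_kappa = p$vm_kappa[ord],
             transition = p$transition[ord, ord, drop = FALSE],
             initial_dist = p$initial_dist[ord],
             zero_mass = if (!is.null(p$zero_mass)) p$zero_mass[ord])
}

hmm_ci <- function(theta, negll, zero_mass) {
  h <- try(stats::optimHess(theta, negll), silent = TRUE)
  se <- rep(NA_real_, length(theta))
  if (!inherits(h, "try-error")) {
    v <- try(solve(h), silent = TRUE)
    if (!inherits(v, "try-error")) {
      d <- diag(v)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }
  th <- theta
  th[7:9] <- wrap_angle(th[7:9])   # centre the vm-mean CI on the wrapped estimate
  lo <- th - 1.96 * se
  hi <- th + 1.96 * se
  p <- unpack_params(theta, zero_mass)
  tibble::tibble(
    state = rep(1:3, times = 4),
    term = rep(c("gamma_mean", "gamma_sd", "vm_mean", "vm_kappa"), each = 3),
    estimate = c(p$gamma_mean, p$gamma_sd, p$vm_mean, p$vm_kappa),
    conf.low = c(exp(lo[1:3]), exp(lo[4:6]), lo[7:9], exp(lo[10:12])),
    conf.high = c(exp(hi[1:3]), exp(hi[4:6]), hi[7:9], exp(hi[10:12])))
}

permute_ci <- function(ci, ord) {
  ci$state <- match(ci$state, ord)
  dplyr::arrange(ci, .data$term, .data$state)
}

#' @export
print.recursel_hmm_fit <- function(x, ...) {
  cat(sprintf("<recursel_hmm_fit> 3 states, loglik %.2f on %d steps (%s)\n",
              x$loglik, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  p <- x$params
  lab <- hmm_state_labels()
  for (k in 1:3) {
    cat(sprintf("  %-11s gamma mean %7.1f m (sd %7.1f), vm mean %6.2f, kappa %5.2f\n",
                lab[k], p$gamma_mean[k], p$gamma_sd[k], p$vm_mean[k], p$vm_kappa[k]))
  }
  invisible(x)
}

hmm_state_labels <- function() c("stationary", "restricted", "travelling")

#' Decode behavioral states with the Viterbi algorithm
#'
#' Computes, per burst, the jointly most probable hidden-state path under the
#' fitted HMM (global decoding, in log space; ties broken toward the lower
#' state index). Raw states are labelled by the fit's sorted order
#' (stationary / restricted / travelling) and additionally merged to the
#' two-state scheme used downstream: stationary and restricted collapse to
#' `restricted`, travelling becomes `mobile`.
#'
#' @param fit A converged `recursel_hmm_fit` (or bare [hmm_params()]).
#' @param steps The step series the fit was (or could have been) computed on.
#' @return `steps` with three columns appended: `state_idx` (1-3), `state`
#'   (raw label) and `merged` (`restricted`/`mobile`).
#' @export
viterbi <- function(fit, steps) {
  params <- if (inherits(fit, "recursel_hmm_fit")) fit$params else fit
  validate_hmm_params(params)
  if (inherits(fit, "recursel_hmm_fit") && !isTRUE(fit$converged)) {
    warn("decoding from a non-converged fit")
  }
  dec_steps <- steps
  if (is.null(params$zero_mass) && any(dec_steps$step_m == 0)) {
    # same fallback as fit_hmm, but deterministic: an exact zero step is
    # scored at the midpoint of the jitter interval
    dec_steps$step_m[dec_steps$step_m == 0] <- 0.05
  }
  ld <- log_emission_matrix(params, dec_steps)
  path <- viterbi_cpp(ld, log(params$transition), log(params$initial_dist),
                      new_burst_flags(steps))
  steps$state_idx <- as.integer(path)
  steps$state <- hmm_state_labels()[path]
  steps$merged <- merge_states(steps$state)
  steps
}

#' Merge stationary and restricted states
#'
#' Maps the 3-state labels to the two-state scheme: `stationary` and
#' `restricted` (both short-distance, foraging-like) become `restricted`;
#' `travelling` becomes `mobile`.
#'
#' @param state Character vector of raw labels, or integers 1-3.
#' @return Character vector in `{restricted, mobile}`.
#' @export
merge_states <- function(state) {
  if (is.numeric(state)) state <- hmm_state_labels()[state]
  map <- c(stationary = "restricted", restricted = "restricted",
           travelling = "mobile")
  bad <- setdiff(unique(state), names(map))
  if (length(bad) > 0) {
    abort(sprintf("unknown state label(s): %s", paste(bad, collapse = ", ")))
  }
  unname(map[state])
}

#' Merged-state proportions
#'
#' @param merged Character vector of merged labels (`restricted`/`mobile`).
#' @return Tibble with `state` and `prop` (fractions summing to 1).
#' @export
state_proportions <- function(merged) {
  if (length(merged) == 0) abort("empty state sequence")
  tibble::tibble(state = c("restricted", "mobile")) |>
    dplyr::mutate(prop = purrr::map_dbl(.data$state, ~ mean(merged == .x)))
}

#' @export
tidy.recursel_hmm_fit <- function(x, ...) {
  ci <- x$ci
  ci$state_label <- hmm_state_labels()[ci$state]
  ci[, c("term", "state", "state_label", "estimate", "conf.low", "conf.high")]
}

#' @export
glance.recursel_hmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n_obs,
                 converged = x$converged, n_restarts_used = x$n_restarts_used)
}

#' Serialize an HMM fit to JSON
#'
#' @param fit A `recursel_hmm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_hmm_fit <- function(fit, path) {
  p <- fit$params
  jsonlite::write_json(
    list(gamma_mean = p$gamma_mean, gamma_sd = p$gamma_sd,
         vm_mean = p$vm_mean, vm_kappa = p$vm_kappa,
         transition = p$transition, initial_dist = p$initial_dist,
         loglik = fit$loglik, n_obs = fit$n_obs, converged = fit$converged,
         n_restarts_used = fit$n_restarts_used, seed = fit$seed,
         ci = fit$ci),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
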