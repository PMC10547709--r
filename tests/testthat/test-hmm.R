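test_that("forward log-likelihood matches exhaustive enumeration (property)", {
  set.seed(101)
  for (rep in 1:8) {
    p <- random_hmm_params()
    st <- random_steps(sample(2:8, 1))
    expect_equal(forward_loglik(p, st), oracle_forward(p, st), tolerance = 1e-8)
  }
})

test_that("forward likelihood handles bursts, closed forms and degenerate cases", {
  p <- default_hmm_init()
  # one observation: logsumexp over states of init * emission
  st1 <- tibble::tibble(burst_id = "b", step_m = 120, turn_rad = NA_real_)
  dens <- oracle_emission(p, st1)
  expect_equal(forward_loglik(p, st1), log(sum(p$initial_dist * dens[1, ])))
  # two bursts factorize: ll = ll(burst1) + ll(burst2)
  st2 <- random_steps(6)
  stb <- st2
  stb$burst_id <- rep(c("b1", "b2"), each = 3)
  b1 <- stb[1:3, ]; b2 <- stb[4:6, ]
  b2$turn_rad[1] <- NA                      # burst start has no turn
  stb$turn_rad[4] <- NA
  expect_equal(forward_loglik(p, stb),
               forward_loglik(p, b1) + forward_loglik(p, b2), tolerance = 1e-10)
  # identical emissions in all states: loglik independent of the transitions
  pid <- hmm_params(gamma_mean = rep(100, 3), gamma_sd = rep(50, 3),
                    vm_mean = rep(0, 3), vm_kappa = rep(1, 3),
                    transition = matrix(1 / 3, 3, 3), initial_dist = rep(1 / 3, 3))
  palt <- pid
  palt$transition <- matrix(c(0.8, 0.1, 0.1, 0.3, 0.4, 0.3, 0.05, 0.05, 0.9),
                            3, 3, byrow = TRUE)
  st <- random_steps(20)
  expect_equal(forward_loglik(pid, st), forward_loglik(palt, st), tolerance = 1e-10)
})

test_that("permuting state labels leaves the forward likelihood unchanged", {
  set.seed(33)
  p <- random_hmm_params()
  st <- random_steps(15)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))) {
    pp <- recursel:::permute_states(p, perm)
    expect_equal(forward_loglik(pp, st), forward_loglik(p, st), tolerance = 1e-10)
  }
})

test_that("a zero step without a zero-mass component fails naming the step", {
  p <- default_hmm_init()
  st <- tibble::tibble(burst_id = "b", step_m = c(10, 0, 20),
                       turn_rad = c(NA, 0.2, 0.1))
  expect_error(forward_loglik(p, st), "row 2")
  # with a zero-mass component the likelihood is finite
  pz <- p; pz$zero_mass <- c(0.1, 0.05, 0.01)
  expect_true(is.finite(forward_loglik(pz, st)))
})

test_that("Viterbi equals the exhaustive argmax and dominates random paths", {
  set.seed(77)
  for (rep in 1:6) {
    p <- random_hmm_params()
    st <- random_steps(sample(3:8, 1))
    dec <- viterbi(p, st)
    o <- oracle_viterbi(p, st)
    expect_equal(dec$state_idx, o$path)
    expect_equal(oracle_path_logp(p, st, dec$state_idx), o$logp, tolerance = 1e-10)
  }
  # dominance over 1,000 random paths
  p <- random_hmm_params()
  st <- random_steps(12)
  dec <- viterbi(p, st)
  best <- oracle_path_logp(p, st, dec$state_idx)
  rand <- replicate(1000, oracle_path_logp(p, st, sample.int(3, 12, replace = TRUE)))
  expect_true(all(best >= rand))
})

test_that("disjoint emission supports force exact decoding", {
  # states separated by orders of magnitude in step length
  p <- hmm_params(gamma_mean = c(1, 1000, 1e6), gamma_sd = c(0.1, 10, 100),
                  vm_mean = c(0, 0, 0), vm_kappa = c(0, 0, 0),
                  transition = matrix(1 / 3, 3, 3), initial_dist = rep(1 / 3, 3))
  truth <- c(1, 3, 2, 2, 1, 3)
  st <- tibble::tibble(burst_id = "b",
                       step_m = c(1, 1e6, 1000, 1000, 1, 1e6),
                       turn_rad = c(NA, runif(5, -pi, pi)))
  expect_equal(viterbi(p, st)$state_idx, truth)
})

test_that("state merging follows the stationary+restricted rule", {
  expect_equal(merge_states(c(1, 2, 3, 2)),
               c("restricted", "restricted", "mobile", "restricted"))
  expect_equal(merge_states(c("travelling", "travelling")), c("mobile", "mobile"))
  expect_error(merge_states(c("stationary", "walking")), "walking")
})

test_that("state proportions sum to one and match brute-force counts", {
  expect_equal(state_proportions(c("restricted", "mobile"))$prop, c(0.5, 0.5))
  expect_equal(state_proportions(rep("restricted", 4))$prop, c(1, 0))
  set.seed(12)
  p <- default_hmm_init()
  st <- simulate_hmm_steps(p, 400, seed = 9, burst_len = 50)
  dec <- viterbi(p, st)
  props <- state_proportions(dec$merged)
  expect_equal(sum(props$prop), 1)
  expect_equal(props$prop[props$state == "mobile"], mean(dec$state_idx == 3))
  # merged proportions are sums of raw proportions
  expect_equal(props$prop[props$state == "restricted"],
               mean(dec$state_idx == 1) + mean(dec$state_idx == 2))
})

test_that("fitting recovers generative parameters and the MLE dominates", {
  p <- default_hmm_init()
  st <- simulate_hmm_steps(p, 4000, seed = 7, burst_len = 200)
  fit <- fit_hmm(st, init = p, n_restarts = 2, seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$gamma_mean - c(27, 150, 400)) / c(27, 150, 400)), 0.1)
  # sorted-state reporting: gamma means ascending
  expect_true(!is.unsorted(fit$params$gamma_mean))
  # the fitted loglik dominates the generative parameters' loglik
  expect_gte(fit$loglik, forward_loglik(p, st))
  # CIs bracket the point estimates
  expect_true(all(fit$ci$conf.low <= fit$ci$estimate + 1e-9 &
                    fit$ci$estimate <= fit$ci$conf.high + 1e-9))
  # decoding accuracy on well-separated simulated states
  dec <- viterbi(fit, st)
  expect_gt(mean(dec$state_idx == st$true_state), 0.85)
})

test_that("approximate CI coverage holds across simulation replicates", {
  # 12 replicates x 1,500 steps at the canonical generative values; count
  # how often each gamma-mean CI covers the truth
  p <- default_hmm_init()
  truth <- c(27, 150, 400)
  hits <- matrix(NA, 12, 3)
  for (r in 1:12) {
    st <- simulate_hmm_steps(p, 1500, seed = 3000 + r, burst_len = 300)
    fit <- fit_hmm(st, init = p, n_restarts = 1, seed = r)
    ci <- fit$ci[fit$ci$term == "gamma_mean", ]
    ci <- ci[order(ci$state), ]
    hits[r, ] <- ci$conf.low <= truth & truth <= ci$conf.high
  }
  # 95% nominal; demand at least ~80% observed per parameter at this n
  expect_true(all(colMeans(hits) >= 0.8))
})

test_that("HMM fit serializes to JSON with parameters and provenance", {
  p <- default_hmm_init()
  st <- simulate_hmm_steps(p, 300, seed = 2, burst_len = 100)
  fit <- fit_hmm(st, init = p, n_restarts = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$gamma_mean, fit$params$gamma_mean, tolerance = 1e-9)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(back$seed, 5)
})
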