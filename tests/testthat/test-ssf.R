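test_that("available-point sampling honors count, state and the movement fit", {
  p <- default_hmm_init()
  set.seed(3)
  av <- sample_available(100, 200, prev_heading = 0.5, p, state = 2, n = 100)
  expect_equal(nrow(av), 100)
  # degenerate gamma (sd -> 0): all points at the same radius
  pd <- hmm_params(gamma_mean = c(27, 150, 400), gamma_sd = c(1e-6, 1e-6, 1e-6),
                   vm_mean = c(0, 0, 0), vm_kappa = c(1, 1, 1))
  avd <- sample_available(0, 0, prev_heading = 0, pd, state = 3, n = 50)
  expect_equal(sqrt(avd$x^2 + avd$y^2), rep(400, 50), tolerance = 1e-3)
  # Monte-Carlo: pooled available step lengths match the state distribution
  set.seed(4)
  big <- sample_available(0, 0, prev_heading = 1, p, state = 2, n = 10000)
  se <- 150 / sqrt(10000)
  expect_lt(abs(mean(big$sl) - 150), 3 * se)
  # missing previous heading: angles uniform, still n points
  avu <- sample_available(0, 0, prev_heading = NA, p, state = 1, n = 1000)
  expect_equal(nrow(avu), 1000)
  R <- sqrt(mean(sin(atan2(avu$y, avu$x)))^2 + mean(cos(atan2(avu$y, avu$x)))^2)
  expect_lt(R, 0.1)
})

test_that("covariate extraction does nearest-cell lookups with exact distances", {
  ls <- generate_landscape(n_rows = 30, n_cols = 30, seed = 9)
  dist <- distance_rasters(ls)
  # a point inside a pine cell has distance-to-pine 0
  pine <- which(ls$landcover == landcover_classes()[["pine"]], arr.ind = TRUE)[1, ]
  px <- ls$origin[1] + (pine[2] - 0.5) * ls$cell_size
  py <- ls$origin[2] + (pine[1] - 0.5) * ls$cell_size
  cov <- extract_covariates(tibble::tibble(x = px, y = py), ls, dist)
  expect_equal(cov$dist_pine, 0)
  expect_equal(cov$ndvi, ls$ndvi[pine[1], pine[2]])
  # a cell 4-adjacent to a road cell is 30 m from it
  rm <- ls$road_mask
  cand <- which(!rm & (rbind(rm[-1, ], FALSE) | rbind(FALSE, rm[-nrow(rm), ]) |
                         cbind(rm[, -1], FALSE) | cbind(FALSE, rm[, -ncol(rm)])),
                arr.ind = TRUE)
  expect_gt(nrow(cand), 0)
  qx <- ls$origin[1] + (cand[1, 2] - 0.5) * ls$cell_size
  qy <- ls$origin[2] + (cand[1, 1] - 0.5) * ls$cell_size
  cov2 <- extract_covariates(tibble::tibble(x = qx, y = qy), ls, dist)
  expect_equal(cov2$dist_roads, 30)
  # out-of-extent points fail
  expect_error(extract_covariates(tibble::tibble(x = -100, y = 0), ls, dist),
               "outside")
})

test_that("a landscape missing a class fails naming the class", {
  ls <- generate_landscape(n_rows = 30, n_cols = 30, seed = 9)
  ls$landcover[ls$landcover == 1L] <- 2L   # drown all water cells
  expect_error(distance_rasters(ls), "water")
})

test_that("scale_center standardizes with the n-1 convention and errors on constants", {
  tb <- tibble::tibble(dist_pine = c(1, 2, 3), ndvi = c(0, 2, 4),
                       log_sl = c(5, 6, 7))
  out <- scale_center(tb)
  expect_equal(out$table$dist_pine, c(-1, 0, 1))
  expect_equal(out$table$ndvi, c(-1, 0, 1))          # sd = 2
  expect_equal(out$table$log_sl, c(5, 6, 7))         # movement kept natural
  expect_equal(out$scaling$scale, c(1, 2))
  # idempotence on standardized input
  out2 <- scale_center(out$table)
  expect_equal(out2$table$dist_pine, out$table$dist_pine, tolerance = 1e-12)
  # movement covariates scaled on request
  outm <- scale_center(tb, scale_movement = TRUE)
  expect_equal(outm$table$log_sl, c(-1, 0, 1))
  expect_error(scale_center(tibble::tibble(ndvi = rep(2, 5))), "ndvi")
})

test_that("the correlation screen flags only truly correlated pairs", {
  set.seed(10)
  tb <- tibble::tibble(ndvi = rnorm(10000), dist_pine = rnorm(10000))
  tb$revisit <- tb$ndvi                                   # duplicate
  rep1 <- suppressWarnings(correlation_screen(tb))
  expect_equal(attr(rep1, "threshold"), 0.7)
  dup <- rep1[rep1$var1 == "dist_pine" & rep1$var2 == "revisit" |
                rep1$var1 == "ndvi" & rep1$var2 == "revisit", ]
  expect_true(any(abs(rep1$r) > 0.99 & rep1$flagged))
  # independent columns at n = 10,000: no flags
  rep2 <- correlation_screen(tb[c("ndvi", "dist_pine")])
  expect_false(any(rep2$flagged))
  expect_warning(correlation_screen(tb), "exceed")
})

test_that("the candidate set enumerates the Table-style model structures", {
  cs <- candidate_set("ground", "restricted", "revisit")
  expect_equal(vapply(cs, `[[`, character(1), "name"),
               c("landcover", "recursion_only", "composite"))
  expect_length(cs[[1]]$terms, 9)    # 7 landcover/ndvi + cos_ta + log_sl
  expect_equal(cs[[2]]$terms, "revisit")
  expect_length(cs[[3]]$terms, 17)   # 9 + 1 + 7 interactions
  cs_res <- candidate_set("tree", "mobile", "residence")
  expect_equal(cs_res[[2]]$terms, "residence")
  expect_true(all(grepl("residence", grep(":", cs_res[[3]]$terms, value = TRUE))))
})

test_that("conditional fit recovers known coefficients within 3 SE", {
  df <- simulate_clogit_strata(800, 50, beta = c(1, -0.5), seed = 21)
  fit <- fit_ssf(df, c("x1", "x2"))
  expect_true(fit$converged)
  expect_equal(fit$K, 2)
  expect_equal(fit$n_strata, 800)
  z <- abs(fit$coefficients$estimate - c(1, -0.5)) / fit$coefficients$std.error
  expect_true(all(z < 3))
  # against the independent conditional-logistic implementation (stratified
  # Cox with one event per stratum; Breslow = exact conditional likelihood)
  skip_if_not_installed("survival")
  df$time <- 1
  cf <- survival::coxph(
    survival::Surv(time, case) ~ x1 + x2 + survival::strata(stratum_id),
    data = df, method = "breslow")
  expect_equal(fit$coefficients$estimate, unname(coef(cf)), tolerance = 1e-7)
  expect_equal(fit$loglik, as.numeric(logLik(cf)), tolerance = 1e-7)
  expect_equal(fit$coefficients$std.error,
               unname(sqrt(diag(vcov(cf)))), tolerance = 1e-5)
})

test_that("the conditional and fixed-variance Poisson routes agree", {
  skip_if_not_installed("glmmTMB")
  df <- simulate_clogit_strata(400, 30, beta = c(0.8, -0.3), seed = 22)
  f1 <- fit_ssf(df, c("x1", "x2"), method = "conditional")
  f2 <- fit_ssf(df, c("x1", "x2"), method = "poisson")
  expect_lt(max(abs(f1$coefficients$estimate - f2$coefficients$estimate)), 1e-3)
  expect_equal(f1$coefficients$std.error, f2$coefficients$std.error,
               tolerance = 1e-2)
})

test_that("stratum-constant covariates get coefficient 0 and the likelihood is shift-invariant", {
  df <- simulate_clogit_strata(100, 20, beta = 0.7, seed = 23)
  set.seed(99)
  df <- df |> dplyr::group_by(stratum_id) |>
    dplyr::mutate(flat = rnorm(1)) |> dplyr::ungroup()  # constant within stratum
  fit <- fit_ssf(df, c("x1", "flat"))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "flat"], 0)
  expect_true(is.na(fit$coefficients$std.error[fit$coefficients$term == "flat"]))
  # the x1 estimate and loglik are unchanged by dropping the flat column
  fit0 <- fit_ssf(df, "x1")
  expect_equal(fit$coefficients$estimate[1], fit0$coefficients$estimate[1],
               tolerance = 1e-9)
  expect_equal(fit$loglik, fit0$loglik, tolerance = 1e-9)
  # stratum-constant shifts of the covariate (hence of the linear predictor)
  # change neither the estimate nor the likelihood
  df2 <- df |> dplyr::group_by(stratum_id) |>
    dplyr::mutate(x1 = x1 - mean(x1)) |> dplyr::ungroup()
  fitc <- fit_ssf(df2, "x1")
  expect_equal(fitc$coefficients$estimate, fit0$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(fitc$loglik, fit0$loglik, tolerance = 1e-9)
})

test_that("rescaling a covariate rescales its coefficient and keeps the loglik", {
  df <- simulate_clogit_strata(300, 30, beta = 0.6, seed = 24)
  f1 <- fit_ssf(df, "x1")
  df$x1 <- df$x1 / 2
  f2 <- fit_ssf(df, "x1")
  expect_equal(f2$coefficients$estimate, 2 * f1$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("quasi-complete separation is a diagnostic failure", {
  df <- simulate_clogit_strata(60, 10, beta = 0.5, seed = 25)
  df$perfect <- as.numeric(df$case)    # perfectly ranks used vs available
  expect_error(fit_ssf(df, c("x1", "perfect")), "separation")
})

test_that("strata built from decoded steps have 1 used + n available points", {
  scene <- make_test_scene(seed = 51, n_days = 6, n_broods = 1, n_rows = 40,
                           n_cols = 40)
  fit <- fit_hmm(scene$steps, n_restarts = 1, seed = 5)
  dec <- viterbi(fit, scene$steps)
  fx <- fix_states(scene$clean, dec)
  rst <- recursion_stats(fx)
  rasters <- build_recursion_rasters(fx, rst, scene$landscape)
  dist <- distance_rasters(scene$landscape)
  strata <- build_strata(dec, fit, scene$landscape, dist, rasters,
                         n_available = 25, seed = 2)
  counts <- strata |> dplyr::count(stratum_id)
  expect_true(all(counts$n == 26))
  expect_true(all(tapply(strata$case, strata$stratum_id, sum) == 1))
  expect_true(all(c("dist_roads", "dist_pine", "ndvi", "revisit", "residence",
                    "log_sl", "cos_ta") %in% names(strata)))
  expect_true(all(is.finite(strata$revisit)))
  expect_true(all(strata$period %in% c("ground", "tree")))
  # reproducible under the same seed
  strata2 <- build_strata(dec, fit, scene$landscape, dist, rasters,
                          n_available = 25, seed = 2)
  expect_equal(strata, strata2)
})
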