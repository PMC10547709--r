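#' Small-sample Akaike information criterion
#'
#' `AICc = -2 loglik + 2K + 2K(K+1) / (n - K - 1)`. For conditional
#' step-selection fits, `n` is the number of strata (one conditional
#' likelihood contribution each).
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-100, 4, 100) # 208 + 40/95
aicc <- function(loglik, K, n) {
  if (n <= K + 1) abort(sprintf("AICc undefined: n = %g <= K + 1 = %g", n, K + 1))
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 1) abort("need at least one model")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank-based AUC of a step-selection fit
#'
#' Area under the ROC curve of the model's linear predictor, used points as
#' positives and available points as negatives, pooled over all strata. Ties
#' count one half (Mann-Whitney convention). 0.5 means the model ranks used
#' points no better than chance; values above 0.7 indicate useful
#' discrimination.
#'
#' @param fit A `recursel_ssf_fit` (or a numeric linear predictor).
#' @param strata Strata table with `case` and the model covariates.
#' @return AUC in \[0, 1\].
#' @export
auc_ssf <- function(fit, strata) {
  score <- if (is.numeric(fit)) fit else predict_ssf(fit, strata)
  pos <- strata$case == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("AUC needs both used and available points")
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Model-selection table and coefficient report for one block
#'
#' Ranks the fits of one period x state x metric block by AICc, computes
#' delta AICc and Akaike weights (ties in AICc are broken by model name
#' order), appends the pooled AUC of each fit, and emits coefficient tables
#' (estimate, SE, 95% CI) for every model within `delta_max` AICc units of
#' the best.
#'
#' @param fits List of `recursel_ssf_fit` objects from the same strata block.
#' @param strata The strata table the fits were computed on.
#' @param delta_max Coefficient-report cutoff (default 2).
#' @return A `recursel_model_table`: list with `table` (tibble: `model`, `K`,
#'   `AICc`, `dAICc`, `w`, `logLik`, `AUC`, `n_strata`) and `coefficients`
#'   (named list of coefficient tibbles for models with `dAICc <= delta_max`).
#' @export
report_block <- function(fits, strata, delta_max = 2) {
  stopifnot(length(fits) >= 1)
  n <- fits[[1]]$n_strata
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$name, K = f$K, logLik = f$loglik,
                   AICc = aicc(f$loglik, f$K, f$n_strata),
                   AUC = auc_ssf(f, strata), n_strata = f$n_strata)
  })
  tab <- dplyr::arrange(tab, .data$AICc, .data$model)
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$w <- akaike_weights(tab$AICc)
  tab <- tab[, c("model", "K", "AICc", "dAICc", "w", "logLik", "AUC", "n_strata")]
  keep <- tab$model[tab$dAICc <= delta_max]
  coefs <- lapply(fits, function(f) f$coefficients)
  names(coefs) <- vapply(fits, function(f) f$name, character(1))
  structure(list(table = tab, coefficients = coefs[keep]),
            class = "recursel_model_table")
}

#' @export
print.recursel_model_table <- function(x, ...) {
  cat("<recursel_model_table>\n")
  print(as.data.frame(x$table), digits = 6, row.names = FALSE)
  cat(sprintf("coefficient tables emitted for: %s\n",
              paste(names(x$coefficients), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.recursel_model_table <- function(x, ...) x$table

#' Write a model table as CSV
#'
#' @param mt A `recursel_model_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(mt, path) {
  write.csv(as.data.frame(mt$table), path, row.names = FALSE)
  invisible(path)
}
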