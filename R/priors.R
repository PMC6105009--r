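PARAM_ORDER <- c("omega", "sigma2_0", "beta0", "beta1", "beta2", "beta3",
                 "beta4", "beta5", "beta6", "zeta")

#' Default estimation priors
#'
#' Independent Gaussian priors in estimation space, one row per free
#' parameter. Positive parameters (`sigma2_0`, `zeta`) are estimated on the
#' log scale. The defaults are weakly informative around the magnitudes
#' typical for log-RT data in this task family: `omega ~ N(-3, 16)`,
#' `log sigma2_0 ~ N(log 0.05, 1)`, `beta0 ~ N(6, 4)`,
#' `beta1, ..., beta6 ~ N(0, 1)`, `log zeta ~ N(log 0.01, 4)` (variances).
#' The zero-centred priors on `beta2`..`beta5` provide the shrinkage that
#' identifies the manifestation coefficients against the intercept.
#'
#' @return tibble with columns `parameter`, `transform` (`"identity"`,
#'   `"log"` or `"logit"`), `mean`, `sd` (estimation space).
#' @export
default_priors <- function() {
  tibble::tibble(
    parameter = PARAM_ORDER,
    transform = c("identity", "log", rep("identity", 7), "log"),
    mean = c(-3, log(0.05), 6, rep(0, 6), log(0.01)),
    sd = c(4, 1, 2, rep(1, 6), 2))
}

check_priors <- function(priors) {
  need <- c("parameter", "transform", "mean", "sd")
  if (!all(need %in% names(priors))) {
    abort("priors need columns parameter, transform, mean, sd")
  }
  if (!setequal(priors$parameter, PARAM_ORDER)) {
    abort(paste0("priors must cover exactly: ",
                 paste(PARAM_ORDER, collapse = ", ")))
  }
  if (any(priors$sd <= 0)) abort("prior sds must be positive")
  if (!all(priors$transform %in% c("identity", "log", "logit"))) {
    abort("transform must be identity, log or logit")
  }
  priors[match(PARAM_ORDER, priors$parameter), ]
}

to_estimation_space <- function(native, transform) {
  switch(transform,
         identity = native,
         log = log(native),
         logit = log(native / (1 - native)))
}

to_native_space <- function(est, transform) {
  switch(transform,
         identity = est,
         log = exp(est),
         logit = 1 / (1 + exp(-est)))
}
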