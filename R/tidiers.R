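#' Tidy a single-subject model fit
#'
#' One row per free parameter with the native-space MAP estimate and a
#' delta-method standard error from the inverse Hessian.
#'
#' @param x an `"hgf_fit"`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `transform`.
#' @method tidy hgf_fit
#' @export
tidy.hgf_fit <- function(x, ...) {
  pr <- x$priors[match(x$free, x$priors$parameter), ]
  se_est <- tryCatch(sqrt(diag(solve(x$hessian))),
                     error = function(e) rep(NA_real_, x$d))
  jac <- purrr::map2_dbl(x$est, pr$transform, function(e, tr) {
    switch(tr, identity = 1, log = exp(e),
           logit = { p <- 1 / (1 + exp(-e)); p * (1 - p) })
  })
  tibble::tibble(term = x$free,
                 estimate = unname(x$estimate[x$free]),
                 std.error = unname(se_est * abs(jac)),
                 transform = pr$transform)
}

#' One-row fit summary
#'
#' @param x an `"hgf_fit"`.
#' @param ... unused.
#' @return tibble with the model id, log joint, log likelihood, Laplace
#'   evidence, trial count, free-parameter count and convergence flag.
#' @method glance hgf_fit
#' @export
glance.hgf_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, log_joint = x$log_joint,
                 log_lik = x$log_lik, neg_free_energy = x$neg_free_energy,
                 n_valid = x$n_valid, n_free = x$d,
                 converged = x$convergence$converged)
}

#' Tidy an evidence matrix into long form
#'
#' @param x an `"evidence_matrix"` from [fit_cohort()].
#' @param ... unused.
#' @return tibble with `subject_id`, `model_id`, `neg_free_energy`.
#' @method tidy evidence_matrix
#' @export
tidy.evidence_matrix <- function(x, ...) {
  m <- unclass(x)
  attributes(m)[c("fits", "failures")] <- NULL
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(subject_id = rownames(m), .before = 1) |>
    tidyr::pivot_longer(-"subject_id", names_to = "model_id",
                        values_to = "neg_free_energy")
}

#' Tidy a model-selection result
#'
#' @param x a `"bms_result"`.
#' @param ... unused.
#' @return the per-model tibble (`model_id`, `alpha`, `pp`, `xp`, `pxp`).
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) x$models

#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = nrow(x$models),
                 bor = x$bor,
                 best_model = x$models$model_id[which.max(x$models$pxp)],
                 best_pxp = max(x$models$pxp))
}

#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$summary

#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(model_id = x$model_id,
                 n = max(x$summary$n), n_failed = x$n_failed,
                 min_r = min(x$summary$r, na.rm = TRUE))
}

#' @method tidy model_recovery
#' @export
tidy.model_recovery <- function(x, ...) x$results

#' @method tidy ppc_report
#' @export
tidy.ppc_report <- function(x, ...) x$subjects

#' @method glance ppc_report
#' @export
glance.ppc_report <- function(x, ...) x$effects

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$model_id, ", ", max(x$summary$n),
      " subjects (", x$n_failed, " failed fits)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
print.model_recovery <- function(x, ...) {
  cat("<model_recovery> ", x$n_cohorts, " cohorts x ", x$cohort_size,
      " subjects per generator\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("<ppc_report> ", x$model_id, ", ", nrow(x$subjects), " subjects\n",
      sep = "")
  print(x$effects)
  invisible(x)
}
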