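# Fitting works in estimation space: each parameter is mapped through its
# prior's transform (identity/log/logit), given an independent Gaussian
# prior there, and the joint posterior is maximised by quasi-Newton (BFGS)
# from the prior mean plus seeded perturbed restarts.

fit_data_pieces <- function(data, learn_template) {
  if (!"valid" %in% names(data)) data <- preprocess_rts(data)
  if (sum(data$valid) < 1) abort("no valid trials to fit")
  u <- encode_inputs(data)
  m <- manifestation_vectors(data)
  log_rt <- ifelse(data$valid, data$log_rt, 0)
  list(u = u, m = m, log_rt = log_rt, valid = data$valid,
       n_valid = sum(data$valid), lt = learn_template)
}

negloglik_native <- function(native, pieces, spec) {
  lt <- pieces$lt
  rt_neg_loglik_cpp(
    pieces$u$u_color, pieces$u$u_shape, native[["omega"]],
    native[["sigma2_0"]], lt$mu2_0, spec$n_levels, spec$precfb, lt$kappa,
    lt$mu3_0, lt$sigma3_0, lt$theta, lt$clamp,
    unname(native[c("beta0", "beta1", "beta2", "beta3", "beta4", "beta5",
                    "beta6")]),
    native[["zeta"]], spec$relpe, spec$irrelbias,
    pieces$m$m_colorful, pieces$m$m_grey, pieces$m$m_square,
    pieces$m$m_triangle, pieces$m$outcome_code, pieces$log_rt, pieces$valid)
}

#' Log joint density of parameters and data under one model
#'
#' The response log-likelihood of the observed log reaction times (learning
#' model run over all trials, likelihood summed over valid trials only) plus
#' the Gaussian log-prior terms in estimation space.
#'
#' @param params named numeric vector of all ten parameters in native space
#'   (`omega`, `sigma2_0`, `beta0`..`beta6`, `zeta`).
#' @param data a trial table with task columns and `rt_ms`/`responded` (run
#'   through [preprocess_rts()] if `valid` is absent).
#' @param model_id model id string.
#' @param priors prior specification as in [default_priors()].
#' @param learn_template a [learn_params()] supplying the fixed structural
#'   constants (`mu2_0`, `kappa`, level-3 initials, `theta`, clamp).
#' @return scalar log joint; `-Inf` (with attribute `invalid = TRUE`) when
#'   the trajectories are numerically invalid.
#' @export
log_joint <- function(params, data, model_id, priors = default_priors(),
                      learn_template = learn_params()) {
  priors <- check_priors(priors)
  spec <- parse_model_id(model_id)
  params <- unlist(params)[PARAM_ORDER]
  pieces <- fit_data_pieces(data, learn_template)
  nll <- negloglik_native(params, pieces, spec)
  if (!is.finite(nll)) {
    return(structure(-Inf, invalid = TRUE))
  }
  est <- purrr::map2_dbl(params, priors$transform, to_estimation_space)
  sum(dnorm(est, priors$mean, priors$sd, log = TRUE)) - nll
}

central_gradient <- function(fn, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    h <- eps * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

#' Fit one model to one subject by MAP estimation
#'
#' Maximises the log joint in estimation space with BFGS from the prior mean
#' plus `n_starts - 1` seeded perturbed starting points (each perturbed by
#' `perturb_sd` prior standard deviations), keeps the best optimum, and
#' computes the Laplace-approximate log model evidence (negative free
#' energy) from the numerical Hessian at the optimum.
#'
#' @inheritParams log_joint
#' @param fixed optional named numeric vector of parameters pinned at native
#'   values and excluded from estimation.
#' @param n_starts number of optimisation starts.
#' @param seed integer seed for the start perturbations (fits are
#'   deterministic given it).
#' @param perturb_sd start perturbation scale in prior standard deviations.
#' @param control passed to [stats::optim()].
#' @param grad_tol gradient-norm threshold above which a convergence warning
#'   is issued.
#' @return an object of class `"hgf_fit"`; see [tidy()] and [glance()]
#'   methods.
#' @export
map_fit <- function(data, model_id, priors = default_priors(), fixed = NULL,
                    n_starts = 5, seed = 1L, perturb_sd = 1,
                    learn_template = learn_params(),
                    control = list(maxit = 2000, reltol = 1e-10),
                    grad_tol = 1e-5) {
  priors <- check_priors(priors)
  spec <- parse_model_id(model_id)
  pieces <- fit_data_pieces(data, learn_template)
  if (!is.null(fixed) &&
      (!all(names(fixed) %in% PARAM_ORDER) || is.null(names(fixed)))) {
    abort("`fixed` must be a named vector of known parameters")
  }
  free <- setdiff(PARAM_ORDER, names(fixed))
  if (length(free) == 0) abort("at least one parameter must be free")
  pf <- priors[match(free, priors$parameter), ]

  native_of <- function(est_free) {
    nat <- setNames(numeric(length(PARAM_ORDER)), PARAM_ORDER)
    nat[names(fixed)] <- unlist(fixed)[names(fixed)]
    nat[free] <- purrr::map2_dbl(est_free, pf$transform, to_native_space)
    nat
  }
  BIG <- 1e12
  objective <- function(est_free) {
    nll <- negloglik_native(native_of(est_free), pieces, spec)
    if (!is.finite(nll)) return(BIG)
    val <- nll - sum(dnorm(est_free, pf$mean, pf$sd, log = TRUE))
    if (!is.finite(val)) BIG else val
  }

  starts <- matrix(rep(pf$mean, n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    z <- withr::with_seed(as.integer(seed),
                          matrix(rnorm((n_starts - 1) * length(free)),
                                 nrow = n_starts - 1))
    starts[-1, ] <- starts[-1, , drop = FALSE] +
      perturb_sd * z * matrix(rep(pf$sd, n_starts - 1), nrow = n_starts - 1,
                              byrow = TRUE)
  }
  runs <- purrr::map(seq_len(n_starts), function(i) {
    tryCatch(optim(starts[i, ], objective, method = "BFGS",
                   control = control),
             error = function(e) NULL)
  })
  runs <- purrr::compact(runs)
  values <- purrr::map_dbl(runs, "value")
  if (length(runs) == 0 || all(values >= BIG)) {
    abort("all optimisation starts failed or were numerically invalid")
  }
  best <- runs[[which.min(values)]]
  est_hat <- setNames(best$par, free)
  hess <- optimHess(best$par, objective)
  hess <- (hess + t(hess)) / 2
  dimnames(hess) <- list(free, free)
  grad_norm <- sqrt(sum(central_gradient(objective, best$par)^2))
  converged <- grad_norm <= grad_tol
  if (!converged) {
    warn(paste0("gradient norm ", format(grad_norm, digits = 3),
                " above tolerance at the best optimum (", model_id, ")"))
  }
  lj <- -best$value
  nat_hat <- native_of(best$par)
  ll <- -negloglik_native(nat_hat, pieces, spec)
  le <- laplace_evidence(lj, hess)
  structure(
    list(model_id = model_id, estimate = nat_hat, est = est_hat,
         fixed = fixed, free = free, hessian = hess, log_joint = lj,
         log_lik = ll, neg_free_energy = le$value,
         hessian_adjusted = le$adjusted, n_valid = pieces$n_valid,
         d = length(free),
         convergence = list(converged = converged, grad_norm = grad_norm,
                            start_values = -values,
                            value_spread = diff(range(-values)),
                            optim_code = best$convergence),
         priors = priors, learn_template = learn_template, seed = seed),
    class = "hgf_fit")
}

laplace_evidence <- function(log_joint, hessian, eig_floor = 1e-6) {
  d <- NROW(hessian)
  if (d == 0) return(list(value = log_joint, adjusted = FALSE))
  ev <- eigen(hessian, symmetric = TRUE, only.values = TRUE)$values
  adjusted <- any(ev < eig_floor)
  ev <- pmax(ev, eig_floor)
  list(value = log_joint + d / 2 * log(2 * pi) - 0.5 * sum(log(ev)),
       adjusted = adjusted)
}

#' Laplace-approximate log model evidence of a fit
#'
#' `log_joint(MAP) + d/2 log(2*pi) - 1/2 log det(H)`, with `H` the Hessian of
#' the negative log joint at the optimum and `d` the number of free
#' parameters. Non-positive-definite Hessians are handled by flooring the
#' eigenvalues at `eig_floor` (a warning is issued and flagged).
#'
#' @param fit an `"hgf_fit"` object.
#' @param eig_floor eigenvalue floor.
#' @return scalar approximate log model evidence.
#' @export
neg_free_energy <- function(fit, eig_floor = 1e-6) {
  stopifnot(inherits(fit, "hgf_fit"))
  le <- laplace_evidence(fit$log_joint, fit$hessian, eig_floor)
  if (le$adjusted) {
    warn("Hessian not positive definite; eigenvalues floored")
  }
  le$value
}

#' @export
print.hgf_fit <- function(x, ...) {
  cat("<hgf_fit> ", x$model_id, "\n", sep = "")
  cat("  log joint ", format(x$log_joint, digits = 6), ", evidence (Laplace) ",
      format(x$neg_free_energy, digits = 6), ", ", x$n_valid,
      " valid trials\n", sep = "")
  print(round(x$estimate, 4))
  invisible(x)
}

#' Fit a cohort over a model space
#'
#' Fits every model to every subject and collects the Laplace log evidences
#' in a subjects-by-models matrix, the input to [run_bms()]. Per-cell
#' failures are recorded, not fatal; failed cells are `NA`.
#'
#' @param data long trial table with a `subject_id` column (task columns plus
#'   `rt_ms`, `responded`).
#' @param models character vector of model ids; defaults to the full
#'   16-model space.
#' @param priors,n_starts,learn_template,control passed to [map_fit()].
#' @param seed master seed; per-cell fit seeds are derived from it.
#' @param keep_fits retain the individual `"hgf_fit"` objects as an
#'   attribute (can be large).
#' @return matrix of class `"evidence_matrix"` (rows subjects, columns
#'   models) with attributes `fits` (if kept) and `failures`.
#' @export
fit_cohort <- function(data, models = model_space(),
                       priors = default_priors(), n_starts = 5, seed = 1L,
                       learn_template = learn_params(),
                       control = list(maxit = 2000, reltol = 1e-10),
                       keep_fits = TRUE) {
  if (!"subject_id" %in% names(data)) abort("`data` needs a `subject_id`")
  subjects <- unique(data$subject_id)
  L <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(as.character(subjects), models))
  cell_seeds <- withr::with_seed(
    as.integer(seed),
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(subjects) * length(models)),
           nrow = length(subjects)))
  fits <- if (keep_fits) {
    setNames(vector("list", length(subjects)), as.character(subjects))
  }
  failures <- list()
  for (i in seq_along(subjects)) {
    sub_data <- dplyr::filter(data, .data$subject_id == subjects[i])
    if (keep_fits) fits[[i]] <- setNames(vector("list", length(models)),
                                         models)
    for (j in seq_along(models)) {
      fit <- tryCatch(
        map_fit(sub_data, models[j], priors = priors, n_starts = n_starts,
                seed = cell_seeds[i, j], learn_template = learn_template,
                control = control),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          subject_id = subjects[i], model_id = models[j],
          message = conditionMessage(fit))
      } else {
        L[i, j] <- fit$neg_free_energy
        if (keep_fits) fits[[i]][[j]] <- fit
      }
    }
  }
  structure(L, fits = fits,
            failures = if (length(failures)) dplyr::bind_rows(failures) else
              tibble::tibble(subject_id = character(), model_id = character(),
                             message = character()),
            class = c("evidence_matrix", "matrix", "array"))
}
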