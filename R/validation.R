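# Credibility checks: parameter recovery, model recovery, and posterior-
# predictive replication of the raw reaction-time effects on simulated
# cohorts.

#' Generating population for synthetic cohorts
#'
#' Per-subject true parameters are drawn independently from Gaussians
#' (optionally truncated below). The defaults centre the cohort on
#' magnitudes typical of log-RT data in this task family: slow but nonzero
#' volatility (`omega` around -2), intercept near `log(520 ms)`, a positive
#' prediction-error slowing `beta1`, small positive idiosyncratic
#' manifestation biases, a positive outcome effect (slower circles), and
#' log-RT noise variance `zeta = 0.04`.
#'
#' @param ... per-parameter overrides, each `c(mean, sd)` or
#'   `c(mean, sd, lower)`.
#' @return tibble with columns `parameter`, `mean`, `sd`, `lower`.
#' @export
recovery_population <- function(...) {
  pop <- tibble::tibble(
    parameter = PARAM_ORDER,
    mean = c(-2, 0.05, 6.25, 0.2, 0.03, 0.03, 0.03, 0.03, 0.07, 0.04),
    sd = c(0.3, 0, 0.15, 0.1, 0.02, 0.02, 0.02, 0.02, 0.05, 0),
    lower = c(-Inf, 1e-6, -Inf, -Inf, 0, 0, 0, 0, -Inf, 1e-6))
  dots <- list(...)
  for (nm in names(dots)) {
    i <- match(nm, pop$parameter)
    if (is.na(i)) abort(paste0("unknown parameter '", nm, "'"))
    v <- dots[[nm]]
    pop$mean[i] <- v[1]
    if (length(v) > 1) pop$sd[i] <- v[2]
    if (length(v) > 2) pop$lower[i] <- v[3]
  }
  pop
}

draw_parameters <- function(n, population) {
  draws <- purrr::pmap(population, function(parameter, mean, sd, lower) {
    x <- rnorm(n, mean, sd)
    for (i in seq_len(50)) {
      bad <- x < lower
      if (!any(bad)) break
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    pmax(x, lower)
  })
  out <- tibble::as_tibble(setNames(draws, population$parameter))
  out$subject_id <- sprintf("S%03d", seq_len(n))
  dplyr::relocate(out, "subject_id")
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject true parameters from `population`, generates one task
#' sequence per subject (the first relevant dimension alternates across
#' subjects, mirroring counterbalancing), and simulates reaction times from
#' `model_id`.
#'
#' @param n_subjects cohort size.
#' @param model_id generating model id.
#' @param task_config an [isp_config()]; its seed field is ignored
#'   (per-subject seeds derive from `seed`).
#' @param population a [recovery_population()].
#' @param seed master seed.
#' @return list with `data` (long trial table with `subject_id`) and
#'   `true_params` (tibble of generating values incl. `beta_irrelevance`).
#' @export
simulate_cohort <- function(n_subjects, model_id = "2HGF-RelPE+IrrelBias",
                            task_config = isp_config(),
                            population = recovery_population(), seed = 1L) {
  seeds <- withr::with_seed(as.integer(seed), {
    list(params = sample.int(.Machine$integer.max - 1L, 1),
         task = sample.int(.Machine$integer.max - 1L, n_subjects),
         noise = sample.int(.Machine$integer.max - 1L, n_subjects))
  })
  truth <- withr::with_seed(seeds$params, draw_parameters(n_subjects,
                                                          population))
  truth$beta_irrelevance <- beta_irrelevance(truth$beta2, truth$beta3,
                                             truth$beta4, truth$beta5)
  spec <- parse_model_id(model_id)
  data <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    cfg <- task_config
    cfg$first_relevant_dimension <- c("color", "shape")[(i - 1) %% 2 + 1]
    cfg$seed <- seeds$task[i]
    task <- generate_task(cfg)
    lp <- learn_params(omega = truth$omega[i], sigma2_0 = truth$sigma2_0[i])
    rp <- resp_params(beta0 = truth$beta0[i], beta1 = truth$beta1[i],
                      beta2 = truth$beta2[i], beta3 = truth$beta3[i],
                      beta4 = truth$beta4[i], beta5 = truth$beta5[i],
                      beta6 = truth$beta6[i], zeta = truth$zeta[i])
    sim <- simulate_subject(task, model_id, lp, rp, seed = seeds$noise[i])
    dplyr::mutate(tibble::as_tibble(sim), subject_id = truth$subject_id[i],
                  .before = 1)
  })
  list(data = data, true_params = truth, model_id = model_id, seed = seed)
}

#' Parameter recovery study
#'
#' Simulates a cohort from known parameters, refits the same model to every
#' synthetic subject, and summarises recovery per parameter (Pearson
#' correlation, bias, RMSE), including the composite
#' [beta_irrelevance()].
#'
#' @inheritParams simulate_cohort
#' @param priors,n_starts passed to [map_fit()].
#' @return object of class `"recovery_report"`: list with `summary` (tibble:
#'   `term`, `r`, `bias`, `rmse`, `n`), `values` (long tibble of true and
#'   recovered values), `n_failed`, `model_id`, `seed`.
#' @export
parameter_recovery <- function(n_subjects = 40,
                               model_id = "2HGF-RelPE+IrrelBias",
                               task_config = isp_config(),
                               population = recovery_population(), seed = 1L,
                               priors = default_priors(), n_starts = 2) {
  sim <- simulate_cohort(n_subjects, model_id, task_config, population, seed)
  L <- fit_cohort(sim$data, models = model_id, priors = priors,
                  n_starts = n_starts, seed = seed)
  fits <- attr(L, "fits")
  est <- purrr::imap_dfr(fits, function(fl, sid) {
    f <- fl[[model_id]]
    if (is.null(f)) return(tibble::tibble())
    out <- tibble::as_tibble(as.list(f$estimate))
    out$beta_irrelevance <- beta_irrelevance(f$estimate[["beta2"]],
                                             f$estimate[["beta3"]],
                                             f$estimate[["beta4"]],
                                             f$estimate[["beta5"]])
    dplyr::mutate(out, subject_id = sid, .before = 1)
  })
  n_failed <- n_subjects - nrow(est)
  terms <- c(PARAM_ORDER, "beta_irrelevance")
  values <- dplyr::inner_join(
    tidyr::pivot_longer(sim$true_params, dplyr::all_of(terms),
                        names_to = "term", values_to = "true"),
    tidyr::pivot_longer(est, dplyr::all_of(terms), names_to = "term",
                        values_to = "recovered"),
    by = c("subject_id", "term"))
  summary <- values |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      r = if (sd(.data$true) > 0 && sd(.data$recovered) > 0)
        cor(.data$true, .data$recovered) else NA_real_,
      bias = mean(.data$recovered - .data$true),
      rmse = sqrt(mean((.data$recovered - .data$true)^2)),
      n = dplyr::n(), .groups = "drop")
  structure(list(summary = summary, values = values, n_failed = n_failed,
                 model_id = model_id, seed = seed),
            class = "recovery_report")
}

#' Model recovery study
#'
#' For each generating model, simulates `n_cohorts` cohorts, fits each over
#' `fit_models`, runs random-effects model selection, and records which
#' model wins by protected exceedance probability.
#'
#' @param generators character vector of generating model ids (>= 2 for a
#'   confusion analysis; 1 is allowed).
#' @param n_cohorts cohorts per generator.
#' @param cohort_size subjects per cohort.
#' @param fit_models model space fitted to every cohort.
#' @inheritParams simulate_cohort
#' @param priors,n_starts passed to [map_fit()].
#' @param n_samples Monte-Carlo samples for the exceedance probabilities.
#' @return object of class `"model_recovery"`: list with `results` (tibble:
#'   `generator`, `cohort`, `winner`, `pxp_winner`), `confusion` (tibble of
#'   counts, rows summing to `n_cohorts`), and the settings.
#' @export
model_recovery <- function(generators = c("2HGF-RelPE+IrrelBias", "2HGF-BL"),
                           n_cohorts = 10, cohort_size = 20,
                           fit_models = model_space(learning = "2HGF"),
                           task_config = isp_config(),
                           population = recovery_population(), seed = 1L,
                           priors = default_priors(), n_starts = 2,
                           n_samples = 2e5) {
  if (length(generators) < 1) abort("need at least one generator")
  grid <- tidyr::expand_grid(generator = generators,
                             cohort = seq_len(n_cohorts))
  grid$seed <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L,
                                           nrow(grid)))
  results <- purrr::pmap_dfr(grid, function(generator, cohort, seed) {
    sim <- simulate_cohort(cohort_size, generator, task_config, population,
                           seed)
    L <- fit_cohort(sim$data, models = fit_models, priors = priors,
                    n_starts = n_starts, seed = seed, keep_fits = FALSE)
    bms <- run_bms(L, n_samples = n_samples, seed = seed)
    w <- which.max(bms$models$pxp)
    tibble::tibble(generator = generator, cohort = cohort,
                   winner = bms$models$model_id[w],
                   pxp_winner = bms$models$pxp[w])
  })
  confusion <- results |>
    dplyr::count(.data$generator, .data$winner) |>
    tidyr::pivot_wider(names_from = "winner", values_from = "n",
                       values_fill = 0L)
  structure(list(results = results, confusion = confusion,
                 generators = generators, fit_models = fit_models,
                 n_cohorts = n_cohorts, cohort_size = cohort_size,
                 seed = seed),
            class = "model_recovery")
}

#' Posterior-predictive replication of the raw effects
#'
#' Simulates one behaviour table per subject from fitted parameters and
#' reruns the raw analyses (expectedness contrast, outcome contrast,
#' time-bin learning curve, aberrant salience score) on the simulated data,
#' reporting effect directions and the correlation between simulated and
#' observed aberrant salience scores.
#'
#' @param fits named list (by subject id) of `"hgf_fit"` objects, all for
#'   the same model (e.g. one column of [fit_cohort()]'s `fits` attribute).
#' @param data the observed long trial table the fits came from.
#' @param seed master seed for the simulation noise.
#' @return object of class `"ppc_report"`: list with `subjects` (per-subject
#'   observed and simulated summaries), `effects` (one-row tibble of mean
#'   simulated contrasts and the AS-score correlation), `model_id`.
#' @export
posterior_predictive_check <- function(fits, data, seed = 1L) {
  if (is.null(names(fits))) abort("`fits` must be named by subject id")
  model_id <- fits[[1]]$model_id
  noise_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max - 1L,
                                             length(fits)))
  if (!"valid" %in% names(data)) data <- preprocess_rts(data)
  sim_data <- purrr::imap_dfr(fits, function(f, sid) {
    task <- as_isp_task(dplyr::filter(data, .data$subject_id == sid))
    e <- f$estimate
    sim <- simulate_subject(
      task, model_id,
      learn_params(omega = e[["omega"]], sigma2_0 = e[["sigma2_0"]]),
      resp_params(beta0 = e[["beta0"]], beta1 = e[["beta1"]],
                  beta2 = e[["beta2"]], beta3 = e[["beta3"]],
                  beta4 = e[["beta4"]], beta5 = e[["beta5"]],
                  beta6 = e[["beta6"]], zeta = e[["zeta"]]),
      seed = noise_seeds[match(sid, names(fits))])
    dplyr::mutate(tibble::as_tibble(sim), subject_id = sid, .before = 1)
  })
  sim_data <- preprocess_rts(sim_data)
  summarise_side <- function(d, prefix) {
    em <- expectedness_means(d)
    tb <- timebin_means(d)
    oc <- d |>
      dplyr::filter(.data$valid) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(coin_minus_circle =
                         mean(.data$log_rt[.data$outcome == "coin"]) -
                         mean(.data$log_rt[.data$outcome == "circle"]),
                       .groups = "drop")
    slope <- tb |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(bin_slope = mean(.data$mean_log_rt[.data$bin == 4],
                                        na.rm = TRUE) -
                         mean(.data$mean_log_rt[.data$bin == 1],
                              na.rm = TRUE),
                       .groups = "drop")
    as <- aberrant_salience_raw(d)
    out <- em |>
      dplyr::transmute(.data$subject_id,
                       expect_effect = .data$mean_unexpected -
                         .data$mean_expected) |>
      dplyr::left_join(oc, by = "subject_id") |>
      dplyr::left_join(slope, by = "subject_id") |>
      dplyr::left_join(as, by = "subject_id")
    dplyr::rename_with(out, ~ paste0(prefix, .x), -"subject_id")
  }
  subjects <- dplyr::inner_join(summarise_side(data, "obs_"),
                                summarise_side(sim_data, "sim_"),
                                by = "subject_id")
  effects <- tibble::tibble(
    sim_expect_effect = mean(subjects$sim_expect_effect),
    sim_coin_minus_circle = mean(subjects$sim_coin_minus_circle),
    sim_bin_slope = mean(subjects$sim_bin_slope),
    as_correlation = cor(subjects$obs_as_score_ms, subjects$sim_as_score_ms))
  structure(list(subjects = subjects, effects = effects,
                 model_id = model_id, seed = seed, sim_data = sim_data),
            class = "ppc_report")
}
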