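#' Learning parameters for the hierarchical Gaussian filter branches
#'
#' Both branches (color, shape) share one parameter set. The free parameters
#' of all variants are `omega` (log-volatility of the level-2 random walk)
#' and `sigma2_0` (initial level-2 variance). Three-level variants add a
#' volatility level with coupling `kappa`, initial state (`mu3_0`,
#' `sigma3_0`) and constant step variance `theta`; these are fixed by default
#' and configurable.
#'
#' @param omega level-2 log-volatility.
#' @param sigma2_0 initial level-2 variance (> 0).
#' @param mu2_0 initial level-2 mean (0 gives a symmetric 0.5 first prediction).
#' @param kappa level-2/level-3 coupling (> 0, 3-level variants only).
#' @param mu3_0,sigma3_0 initial level-3 mean and variance.
#' @param theta constant level-3 step variance.
#' @param variant one of `"2HGF"`, `"2HGFprecfb"`, `"3HGF"`, `"3HGFprecfb"`,
#'   or `NULL` to take the variant from the model id at run time.
#' @param clamp bound on the logistic argument guarding against overflow.
#' @return list of class `"learn_params"`.
#' @export
learn_params <- function(omega = -3, sigma2_0 = 0.05, mu2_0 = 0, kappa = 1,
                         mu3_0 = 1, sigma3_0 = 0.1, theta = exp(-6),
                         variant = NULL, clamp = 36) {
  if (sigma2_0 <= 0) abort("`sigma2_0` must be positive")
  if (kappa <= 0) abort("`kappa` must be positive")
  if (sigma3_0 <= 0 || theta <= 0) abort("level-3 variances must be positive")
  if (!is.null(variant)) variant <- match.arg(variant, LEARNING_VARIANTS)
  structure(list(omega = omega, sigma2_0 = sigma2_0, mu2_0 = mu2_0,
                 kappa = kappa, mu3_0 = mu3_0, sigma3_0 = sigma3_0,
                 theta = theta, variant = variant, clamp = clamp),
            class = "learn_params")
}

#' First-level precision of a binary prediction
#'
#' The precision (inverse variance) of a Bernoulli prediction with mean
#' `mu1hat`: `1 / (mu1hat * (1 - mu1hat))`. It attains its minimum of 4 at
#' `mu1hat = 0.5` and grows symmetrically towards infinity near 0 and 1.
#' This quantity is the package's operational definition of a cue feature's
#' subjective relevance.
#'
#' @param mu1hat prediction(s) strictly between 0 and 1.
#' @return precision(s), `>= 4`.
#' @export
#' @examples
#' precision_of_prediction(0.5) # 4
#' precision_of_prediction(0.8) # 6.25
precision_of_prediction <- function(mu1hat) {
  if (!all(is.finite(mu1hat)) || any(mu1hat <= 0) || any(mu1hat >= 1)) {
    abort("`mu1hat` must lie strictly in (0, 1)")
  }
  1 / (mu1hat * (1 - mu1hat))
}

#' Relevance weights of the two cue features
#'
#' Each feature's first-level precision normalised by the sum over both
#' features. A feature's irrelevance weight is the other feature's relevance
#' weight.
#'
#' @param pi1hat_color,pi1hat_shape first-level precisions (each `>= 4`).
#' @return tibble with columns `rel_color` and `rel_shape` summing to 1.
#' @export
relevance_weights <- function(pi1hat_color, pi1hat_shape) {
  if (any(pi1hat_color < 4 - 1e-9) || any(pi1hat_shape < 4 - 1e-9)) {
    abort("first-level precisions must be >= 4")
  }
  rel_color <- pi1hat_color / (pi1hat_color + pi1hat_shape)
  tibble::tibble(rel_color = rel_color, rel_shape = 1 - rel_color)
}

#' One filter step for a single branch
#'
#' Reference implementation of the per-trial update used by
#' [run_two_branch()]; exposed for inspection and testing. The level-2
#' posterior mean moves by the first-level prediction error divided by the
#' updated level-2 precision; in 3-level variants the level-3 volatility
#' estimate widens the level-2 prediction variance and is itself updated by
#' the volatility prediction error.
#'
#' @param state list with `mu2`, `sigma2` and (3-level) `mu3`, `sigma3`.
#' @param u binary input (0 or 1).
#' @param params a [learn_params()]; `params$variant` (or 2-level plain if
#'   `NULL`) selects the update.
#' @param rel_weight the branch's prediction-time relevance weight, used only
#'   by precision-feedback variants, where the first-level prediction error
#'   in the mean update is scaled by `2 * rel_weight` (1 at equal precision).
#' @return updated `state`, with the trial's `mu1hat`, `pi1hat` and `delta1`
#'   appended.
#' @export
hgf_branch_step <- function(state, u, params, rel_weight = NULL) {
  stopifnot(u %in% c(0, 1))
  variant <- params$variant %||% "2HGF"
  n_levels <- if (grepl("^3", variant)) 3L else 2L
  precfb <- grepl("precfb", variant, fixed = TRUE)
  vstep <- if (n_levels == 3L) exp(params$kappa * state$mu3 + params$omega)
           else exp(params$omega)
  sigma2hat <- state$sigma2 + vstep
  a <- max(min(state$mu2, params$clamp), -params$clamp)
  mu1hat <- 1 / (1 + exp(-a))
  pi1hat <- precision_of_prediction(mu1hat)
  delta1 <- u - mu1hat
  pi2 <- 1 / sigma2hat + 1 / pi1hat
  w <- if (precfb) {
    if (is.null(rel_weight)) abort("precision feedback needs `rel_weight`")
    2 * rel_weight
  } else 1
  mu2_old <- state$mu2
  state$mu2 <- state$mu2 + w * delta1 / pi2
  state$sigma2 <- max(1 / pi2, 1e-12)
  if (state$sigma2 <= 0) abort("level-2 variance became non-positive")
  if (n_levels == 3L) {
    w2 <- vstep / sigma2hat
    delta2 <- (state$sigma2 + (state$mu2 - mu2_old)^2) / sigma2hat - 1
    pi3 <- 1 / (state$sigma3 + params$theta) +
      params$kappa^2 / 2 * w2 * (w2 + (2 * w2 - 1) * delta2)
    pi3 <- max(pi3, 1e-6)
    state$mu3 <- state$mu3 + params$kappa / (2 * pi3) * w2 * delta2
    state$sigma3 <- 1 / pi3
  }
  state$mu1hat <- mu1hat
  state$pi1hat <- pi1hat
  state$delta1 <- delta1
  state
}

#' Encode task trials as binary branch inputs
#'
#' Each branch tracks an undirected association between one feature and the
#' outcome. The reference pairing (configurable, direction arbitrary) codes
#' `u_color = 1` for colorful-with-coin or grey-with-circle, and
#' `u_shape = 1` for triangle-with-coin or square-with-circle.
#'
#' @param task an `"isp_task"` tibble.
#' @param flip_color,flip_shape invert the respective pairing.
#' @return tibble with integer columns `u_color` and `u_shape`.
#' @export
encode_inputs <- function(task, flip_color = FALSE, flip_shape = FALSE) {
  u_color <- as.integer((task$color == "colorful") == (task$outcome == "coin"))
  u_shape <- as.integer((task$shape == "triangle") == (task$outcome == "coin"))
  if (flip_color) u_color <- 1L - u_color
  if (flip_shape) u_shape <- 1L - u_shape
  tibble::tibble(u_color = u_color, u_shape = u_shape)
}

#' Run the two-branch filter over a task sequence
#'
#' Runs one binary hierarchical Gaussian filter per cue feature over the
#' encoded trial inputs. The branches share parameters. Relevance weights are
#' computed from the prediction-time first-level precisions of both branches,
#' so on every trial they depend only on inputs up to the previous trial; in
#' precision-feedback variants they additionally scale the level-2 mean
#' updates (see [hgf_branch_step()]).
#'
#' @param task an `"isp_task"` tibble (or any tibble with `color`, `shape`,
#'   `outcome` columns).
#' @param params a [learn_params()].
#' @param variant learning variant; defaults to `params$variant` or
#'   `"2HGF"`.
#' @param flip_color,flip_shape passed to [encode_inputs()].
#' @return a tibble of class `"hgf_trajectories"` with per-trial columns
#'   `u_color`, `u_shape`, `mu1hat_*`, `pi1hat_*`, `delta1_*`, `rel_color`,
#'   `rel_shape`.
#' @export
run_two_branch <- function(task, params = learn_params(), variant = NULL,
                           flip_color = FALSE, flip_shape = FALSE) {
  variant <- variant %||% params$variant %||% "2HGF"
  variant <- match.arg(variant, LEARNING_VARIANTS)
  u <- encode_inputs(task, flip_color, flip_shape)
  res <- hgf_filter_cpp(
    u$u_color, u$u_shape, params$omega, params$sigma2_0, params$mu2_0,
    if (grepl("^3", variant)) 3L else 2L,
    grepl("precfb", variant, fixed = TRUE),
    params$kappa, params$mu3_0, params$sigma3_0, params$theta, params$clamp)
  if (!res$ok) {
    abort(paste0("filter failed numerically at trial ", res$bad_trial))
  }
  out <- tibble::tibble(
    trial = seq_len(nrow(u)), u_color = u$u_color, u_shape = u$u_shape,
    mu1hat_color = res$mu1hat_color, pi1hat_color = res$pi1hat_color,
    delta1_color = res$delta1_color, mu1hat_shape = res$mu1hat_shape,
    pi1hat_shape = res$pi1hat_shape, delta1_shape = res$delta1_shape,
    rel_color = res$rel_color, rel_shape = res$rel_shape)
  attr(out, "params") <- params
  attr(out, "variant") <- variant
  attr(out, "floored") <- res$floored
  class(out) <- c("hgf_trajectories", class(out))
  out
}

#' Pivot trajectories to the long per-branch layout
#'
#' One row per trial and branch, convenient for serialisation and plotting.
#'
#' @param traj an `"hgf_trajectories"` tibble.
#' @return long tibble with columns `trial`, `branch`, `u`, `mu1hat`,
#'   `pi1hat`, `delta1`, `rel_color`, `rel_shape`.
#' @export
trajectories_long <- function(traj) {
  tidyr::pivot_longer(
    tibble::as_tibble(traj),
    cols = c("u_color", "u_shape", "mu1hat_color", "mu1hat_shape",
             "pi1hat_color", "pi1hat_shape", "delta1_color", "delta1_shape"),
    names_to = c(".value", "branch"),
    names_pattern = "(u|mu1hat|pi1hat|delta1)_(color|shape)")
}
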