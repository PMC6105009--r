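#' Response-model parameters
#'
#' Coefficients of the linear model for mean log reaction time:
#' an intercept `beta0`; `beta1` on the mean unsigned first-level prediction
#' error of the two features (relevance-weighted in RelPE variants);
#' manifestation coefficients `beta2`..`beta5` (colorful, grey, square,
#' triangle), entering with a minus sign and, in IrrelBias variants, scaled
#' by their feature's irrelevance weight; `beta6` on the outcome
#' (circle coded 1, coin 0, so positive `beta6` means slower circle
#' responses); and the Gaussian noise variance `zeta` on the log-RT scale.
#'
#' @param beta0,beta1,beta2,beta3,beta4,beta5,beta6 coefficients.
#' @param zeta noise variance (> 0 for likelihoods; 0 allowed for noiseless
#'   simulation).
#' @param variant one of `"BL"`, `"RelPE"`, `"IrrelBias"`,
#'   `"RelPE+IrrelBias"`, or `NULL` to take it from the model id at run time.
#' @return list of class `"resp_params"`.
#' @export
resp_params <- function(beta0 = 6.25, beta1 = 0.2, beta2 = 0, beta3 = 0,
                        beta4 = 0, beta5 = 0, beta6 = 0.07, zeta = 0.04,
                        variant = NULL) {
  if (zeta < 0) abort("`zeta` must be non-negative")
  if (!is.null(variant)) variant <- match.arg(variant, RESPONSE_VARIANTS)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 beta4 = beta4, beta5 = beta5, beta6 = beta6, zeta = zeta,
                 variant = variant),
            class = "resp_params")
}

#' Manifestation indicator vectors and outcome coding for a task
#'
#' @param task a task tibble with `color`, `shape`, `outcome` columns.
#' @return tibble with indicator columns `m_colorful`, `m_grey`, `m_square`,
#'   `m_triangle` (each feature's pair sums to 1 per trial) and
#'   `outcome_code` (circle = 1, coin = 0).
#' @export
manifestation_vectors <- function(task) {
  tibble::tibble(
    m_colorful = as.numeric(task$color == "colorful"),
    m_grey = as.numeric(task$color == "grey"),
    m_square = as.numeric(task$shape == "square"),
    m_triangle = as.numeric(task$shape == "triangle"),
    outcome_code = as.numeric(task$outcome == "circle"))
}

#' Predicted mean log reaction time per trial
#'
#' Baseline (BL):
#' `beta0 + beta1 * (|d_color| + |d_shape|) / 2 - (beta2*m_colorful +
#' beta3*m_grey) - (beta4*m_square + beta5*m_triangle) + beta6 * outcome`.
#' RelPE replaces the prediction-error term with the relevance-weighted mean
#' `(rel_color*|d_color| + rel_shape*|d_shape|) / 2` (the /2 divisor is kept
#' although the weights sum to 1). IrrelBias multiplies each feature's
#' manifestation term by that feature's irrelevance weight (= the other
#' feature's relevance weight). The full model applies both.
#'
#' @param traj trajectories from [run_two_branch()].
#' @param task the task tibble the trajectories were computed on.
#' @param params a [resp_params()].
#' @param variant response variant; defaults to `params$variant` or `"BL"`.
#' @return numeric vector of predicted mean log RTs, one per trial.
#' @export
predict_logrt <- function(traj, task, params, variant = NULL) {
  variant <- variant %||% params$variant %||% "BL"
  variant <- match.arg(variant, RESPONSE_VARIANTS)
  if (nrow(traj) != nrow(task)) {
    abort("trajectories and task differ in length")
  }
  m <- manifestation_vectors(task)
  relpe <- variant %in% c("RelPE", "RelPE+IrrelBias")
  irrelbias <- variant %in% c("IrrelBias", "RelPE+IrrelBias")
  adc <- abs(traj$delta1_color)
  ads <- abs(traj$delta1_shape)
  pe <- if (relpe) (traj$rel_color * adc + traj$rel_shape * ads) / 2
        else (adc + ads) / 2
  bias_color <- params$beta2 * m$m_colorful + params$beta3 * m$m_grey
  bias_shape <- params$beta4 * m$m_square + params$beta5 * m$m_triangle
  if (irrelbias) {
    bias_color <- traj$rel_shape * bias_color  # irrel_color = rel_shape
    bias_shape <- traj$rel_color * bias_shape
  }
  params$beta0 + params$beta1 * pe - bias_color - bias_shape +
    params$beta6 * m$outcome_code
}

#' Gaussian log-likelihood of observed log reaction times
#'
#' Sum over valid trials of the normal log-density of the observed log RT at
#' the predicted mean with variance `zeta`; other trials contribute nothing.
#'
#' @param log_rt observed log RTs (may contain `NA` on invalid trials).
#' @param predictions predicted mean log RTs, same length.
#' @param zeta noise variance (> 0).
#' @param valid logical vector of trials to include; defaults to
#'   non-missing `log_rt`.
#' @return scalar log-likelihood.
#' @export
response_loglik <- function(log_rt, predictions, zeta, valid = NULL) {
  if (length(log_rt) != length(predictions)) {
    abort("`log_rt` and `predictions` differ in length")
  }
  if (!is.finite(zeta) || zeta <= 0) abort("`zeta` must be positive")
  valid <- valid %||% !is.na(log_rt)
  if (length(valid) != length(log_rt)) abort("`valid` has the wrong length")
  sum(dnorm(log_rt[valid], predictions[valid], sqrt(zeta), log = TRUE))
}

#' Composite manifestation-bias parameter
#'
#' Collapses the four manifestation coefficients into a single idiosyncratic
#' bias measure: the mean of the absolute within-feature differences,
#' `(|beta2 - beta3| + |beta4 - beta5|) / 2`. Non-negative, and zero exactly
#' when both within-feature pairs are equal.
#'
#' @param beta2,beta3 color-manifestation coefficients (colorful, grey).
#' @param beta4,beta5 shape-manifestation coefficients (square, triangle).
#' @return scalar (vectorised over inputs).
#' @export
#' @examples
#' beta_irrelevance(0.10, 0.00, 0.06, 0.02) # 0.07
beta_irrelevance <- function(beta2, beta3, beta4, beta5) {
  (abs(beta2 - beta3) + abs(beta4 - beta5)) / 2
}
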