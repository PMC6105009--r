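COLOR_LEVELS <- c("colorful", "grey")
SHAPE_LEVELS <- c("square", "triangle")

manifestation_levels <- function(dimension) {
  switch(dimension, color = COLOR_LEVELS, shape = SHAPE_LEVELS,
         abort(paste0("unknown dimension '", dimension, "'")))
}

other_dimension <- function(dimension) {
  if (dimension == "color") "shape" else "color"
}

#' Task configuration for the implicit salience paradigm
#'
#' The default design: 160 trials in 20-trial blocks; on every trial a cue
#' with one color manifestation (colorful/grey) and one shape manifestation
#' (square/triangle) is followed by a coin (reward, worth `coin_value`) or a
#' circle (neutral). One dimension is relevant: one of its manifestations is
#' followed by the coin with probability `contingency`, the other with
#' 1 - `contingency`, and which one reverses every block. The other dimension
#' is uninformative (50/50). The relevant dimension itself switches once,
#' after `switch_trial` trials. Coin and circle each occur on half the trials.
#'
#' With `exact_counts = TRUE` (default) every block realises the design
#' frequencies exactly: per 20-trial block the rewarded relevant manifestation
#' is shown 10 times (8 coin, 2 circle), the other 10 times (2 coin,
#' 8 circle), and each irrelevant manifestation is split 5/5 within each
#' outcome type; trial order within a block is a seeded permutation. With
#' `exact_counts = FALSE` manifestations and outcomes are drawn independently
#' per trial at the scheduled probabilities.
#'
#' @param n_trials total number of trials; must be divisible by
#'   `block_length`.
#' @param block_length trials per contingency block.
#' @param contingency probability in (0.5, 1] that the currently rewarded
#'   relevant manifestation is followed by the coin.
#' @param switch_trial last trial of the first relevance half; the relevant
#'   dimension flips on the next trial. Defaults to `n_trials / 2`.
#' @param first_relevant_dimension `"color"` or `"shape"`.
#' @param coin_value value in Euro of one coin outcome.
#' @param exact_counts realise design frequencies exactly per block.
#' @param seed integer seed for the trial-order permutation (and, without
#'   exact counts, the outcome draws). `NULL` uses the current RNG state.
#' @return a list of class `"isp_config"`.
#' @export
isp_config <- function(n_trials = 160L, block_length = 20L, contingency = 0.8,
                       switch_trial = NULL,
                       first_relevant_dimension = c("color", "shape"),
                       coin_value = 0.10, exact_counts = TRUE, seed = NULL) {
  first_relevant_dimension <- match.arg(first_relevant_dimension)
  n_trials <- as.integer(n_trials)
  block_length <- as.integer(block_length)
  if (n_trials <= 0 || block_length <= 0 || n_trials %% block_length != 0) {
    abort("`n_trials` must be a positive multiple of `block_length`")
  }
  if (!(contingency > 0.5 && contingency <= 1)) {
    abort("`contingency` must lie in (0.5, 1]")
  }
  switch_trial <- as.integer(switch_trial %||% (n_trials / 2L))
  if (switch_trial %% block_length != 0 || switch_trial <= 0 ||
      switch_trial > n_trials) {
    abort("`switch_trial` must fall on a block boundary within the task")
  }
  structure(
    list(n_trials = n_trials, block_length = block_length,
         contingency = contingency, switch_trial = switch_trial,
         first_relevant_dimension = first_relevant_dimension,
         coin_value = coin_value, exact_counts = isTRUE(exact_counts),
         seed = seed),
    class = "isp_config")
}

block_schedule <- function(config) {
  n_blocks <- config$n_trials %/% config$block_length
  switch_block <- config$switch_trial %/% config$block_length
  first <- config$first_relevant_dimension
  tibble::tibble(
    block = seq_len(n_blocks),
    relevant_dimension = ifelse(.data$block <= switch_block, first,
                                other_dimension(first)),
    # which manifestation the coin follows at p = contingency; alternates
    # deterministically block to block
    rewarded_manifestation = purrr::map2_chr(
      .data$relevant_dimension, .data$block,
      ~ manifestation_levels(.x)[(.y - 1L) %% 2L + 1L]))
}

generate_block <- function(config, relevant_dimension, rewarded) {
  L <- config$block_length
  rel_levels <- manifestation_levels(relevant_dimension)
  irr_levels <- manifestation_levels(other_dimension(relevant_dimension))
  unrewarded <- setdiff(rel_levels, rewarded)
  if (config$exact_counts) {
    n_half <- L %/% 2L
    n_rc <- config$contingency * n_half  # rewarded-manifestation coin count
    if (L %% 2L != 0 || abs(n_rc - round(n_rc)) > 1e-9 || n_half %% 2L != 0) {
      abort(paste0(
        "exact counts need an even block length with contingency * ",
        "block_length / 2 integral and block_length divisible by 4"))
    }
    n_rc <- as.integer(round(n_rc))
    rel_manif <- c(rep(rewarded, n_half), rep(unrewarded, n_half))
    outcome <- c(rep("coin", n_rc), rep("circle", n_half - n_rc),
                 rep("coin", n_half - n_rc), rep("circle", n_rc))
    # each irrelevant manifestation appears equally often within each
    # outcome type, so its conditional coin frequency is exactly 1/2
    irr_manif <- character(L)
    for (o in c("coin", "circle")) {
      idx <- which(outcome == o)
      lab <- rep(irr_levels, length.out = length(idx))
      irr_manif[idx] <- lab[sample.int(length(idx))]
    }
    ord <- sample.int(L)
    rel_manif <- rel_manif[ord]; outcome <- outcome[ord]
    irr_manif <- irr_manif[ord]
  } else {
    rel_manif <- sample(rel_levels, L, replace = TRUE)
    p_coin <- ifelse(rel_manif == rewarded, config$contingency,
                     1 - config$contingency)
    outcome <- ifelse(runif(L) < p_coin, "coin", "circle")
    irr_manif <- sample(irr_levels, L, replace = TRUE)
  }
  color <- if (relevant_dimension == "color") rel_manif else irr_manif
  shape <- if (relevant_dimension == "shape") rel_manif else irr_manif
  tibble::tibble(color = color, shape = shape, outcome = outcome)
}

#' Generate a task sequence for the implicit salience paradigm
#'
#' @param config an [isp_config()].
#' @return a tibble of class `"isp_task"`, one row per trial, with columns
#'   `trial`, `block`, `half`, `color`, `shape`, `outcome`,
#'   `relevant_dimension`, `rewarded_manifestation` and `expected`
#'   (`"expected"` if the outcome followed the scheduled 80% contingency of
#'   the relevant dimension, `"unexpected"` otherwise). The configuration is
#'   attached as attribute `"config"`.
#' @export
#' @examples
#' task <- generate_task(isp_config(seed = 1))
#' table(task$outcome)
generate_task <- function(config = isp_config()) {
  stopifnot(inherits(config, "isp_config"))
  build <- function() {
    sched <- block_schedule(config)
    trials <- purrr::pmap_dfr(sched, function(block, relevant_dimension,
                                              rewarded_manifestation) {
      dplyr::mutate(
        generate_block(config, relevant_dimension, rewarded_manifestation),
        block = block, relevant_dimension = relevant_dimension,
        rewarded_manifestation = rewarded_manifestation)
    })
    trials$trial <- seq_len(nrow(trials))
    trials$half <- ifelse(trials$trial <= config$switch_trial, 1L, 2L)
    rel_manif <- ifelse(trials$relevant_dimension == "color", trials$color,
                        trials$shape)
    trials$expected <- ifelse(
      (rel_manif == trials$rewarded_manifestation) ==
        (trials$outcome == "coin"),
      "expected", "unexpected")
    dplyr::select(trials, "trial", "block", "half", "color", "shape",
                  "outcome", "relevant_dimension", "rewarded_manifestation",
                  "expected")
  }
  out <- if (is.null(config$seed)) build() else
    withr::with_seed(as.integer(config$seed), build())
  attr(out, "config") <- config
  class(out) <- c("isp_task", class(out))
  out
}

#' Simulate a synthetic subject's reaction times
#'
#' Runs the chosen learning model over the task, maps the trajectories to a
#' predicted mean log reaction time under the chosen response model, adds
#' zero-mean Gaussian noise with variance `zeta`, and exponentiates to
#' milliseconds.
#'
#' @param task an `"isp_task"` tibble from [generate_task()].
#' @param model_id model id, e.g. `"2HGF-RelPE+IrrelBias"` (see
#'   [model_space()]).
#' @param learn_params learning parameters from [learn_params()]; a variant
#'   set there must agree with `model_id`.
#' @param resp_params response parameters from [resp_params()]; `zeta = 0`
#'   gives noiseless predictions.
#' @param seed integer seed for the noise draws; `NULL` uses the current RNG.
#' @param miss_rate probability per trial of a missing response (its `rt_ms`
#'   is `NA`).
#' @return the task tibble with columns `rt_ms` and `responded` appended;
#'   attribute `"model_id"` records the generator.
#' @export
simulate_subject <- function(task, model_id, learn_params, resp_params,
                             seed = NULL, miss_rate = 0) {
  stopifnot(inherits(task, "isp_task"))
  spec <- parse_model_id(model_id)
  if (!is.null(learn_params$variant) && learn_params$variant != spec$learning) {
    abort("learning-parameter variant disagrees with `model_id`")
  }
  if (!is.null(resp_params$variant) && resp_params$variant != spec$response) {
    abort("response-parameter variant disagrees with `model_id`")
  }
  if (resp_params$zeta < 0) abort("`zeta` must be non-negative")
  if (miss_rate < 0 || miss_rate >= 1) abort("`miss_rate` must be in [0, 1)")
  traj <- run_two_branch(task, learn_params, variant = spec$learning)
  pred <- predict_logrt(traj, task, resp_params, variant = spec$response)
  draw <- function() {
    log_rt <- pred + rnorm(nrow(task), 0, sqrt(resp_params$zeta))
    responded <- runif(nrow(task)) >= miss_rate
    list(log_rt = log_rt, responded = responded)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  out <- dplyr::mutate(tibble::as_tibble(task),
                       rt_ms = ifelse(d$responded, exp(d$log_rt), NA_real_),
                       responded = d$responded)
  attr(out, "config") <- attr(task, "config")
  attr(out, "model_id") <- model_id
  class(out) <- c("isp_task", class(out))
  out
}
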