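test_that("default design realises the printed frequencies exactly", {
  task <- default_task()
  cfg <- attr(task, "config")
  expect_s3_class(task, "isp_task")
  expect_equal(nrow(task), 160)
  expect_equal(sum(task$outcome == "coin") * cfg$coin_value, 8)

  per_block <- dplyr::group_by(tibble::as_tibble(task), block)
  counts <- dplyr::summarise(
    per_block,
    n = dplyr::n(),
    coins = sum(outcome == "coin"),
    rel_manif_coin = mean(
      outcome[ifelse(relevant_dimension == "color", color, shape) ==
                rewarded_manifestation] == "coin"),
    n_expected = sum(expected == "expected"))
  expect_true(all(counts$n == 20))
  expect_true(all(counts$coins == 10))
  expect_equal(counts$rel_manif_coin, rep(0.8, 8))
  expect_true(all(counts$n_expected == 16))

  # each irrelevant manifestation is followed by coin on exactly half of
  # its presentations within every block
  irr <- dplyr::mutate(
    tibble::as_tibble(task),
    irr_manif = ifelse(relevant_dimension == "color", shape, color))
  irr_rates <- dplyr::summarise(
    dplyr::group_by(irr, block, irr_manif),
    p_coin = mean(outcome == "coin"), .groups = "drop")
  expect_true(all(irr_rates$p_coin == 0.5))
})

test_that("relevant dimension switches after half the task and the rewarded
           manifestation alternates every block", {
  task <- default_task()
  expect_true(all(task$relevant_dimension[1:80] ==
                    task$relevant_dimension[1]))
  expect_true(all(task$relevant_dimension[81:160] !=
                    task$relevant_dimension[1]))
  sched <- dplyr::distinct(tibble::as_tibble(task), block,
                           rewarded_manifestation)
  expect_equal(nrow(sched), 8)
  expect_true(all(sched$rewarded_manifestation[seq(1, 7, 2)] !=
                    sched$rewarded_manifestation[seq(2, 8, 2)]))
})

test_that("trial order is a seeded permutation: counts invariant, order not", {
  a <- generate_task(isp_config(seed = 1))
  b <- generate_task(isp_config(seed = 1))
  c <- generate_task(isp_config(seed = 2))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  # the design margins are fixed; only the within-block order is reshuffled
  margins <- function(t) {
    t <- dplyr::mutate(
      tibble::as_tibble(t),
      rel_manif = ifelse(relevant_dimension == "color", color, shape),
      irr_manif = ifelse(relevant_dimension == "color", shape, color))
    list(
      dplyr::count(t, block, rel_manif, outcome) |>
        dplyr::arrange(block, rel_manif, outcome),
      dplyr::count(t, block, irr_manif, outcome) |>
        dplyr::arrange(block, irr_manif, outcome))
  }
  expect_equal(margins(a), margins(c), ignore_attr = "config")
})

test_that("bernoulli mode draws outcomes at the scheduled probabilities", {
  cfg <- isp_config(n_trials = 4000, block_length = 20, switch_trial = 2000,
                    exact_counts = FALSE, seed = 5)
  task <- generate_task(cfg)
  rel_manif <- ifelse(task$relevant_dimension == "color", task$color,
                      task$shape)
  p_hat <- mean(task$outcome[rel_manif == task$rewarded_manifestation] ==
                  "coin")
  expect_lt(abs(p_hat - 0.8), 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(isp_config(n_trials = 150, block_length = 20), "multiple")
  expect_error(isp_config(contingency = 0.5), "0.5")
  expect_error(isp_config(contingency = 1.2), "0.5")
  expect_error(isp_config(switch_trial = 75), "block boundary")
  expect_error(generate_task(isp_config(contingency = 0.83)), "integral")
})

test_that("noiseless simulation reproduces the predicted mean log RT", {
  task <- default_task()
  lp <- learn_params(omega = -2, sigma2_0 = 0.05)
  rp <- resp_params(zeta = 0)
  sim <- simulate_subject(task, "2HGF-RelPE", lp, rp, seed = 1)
  traj <- run_two_branch(task, lp)
  pred <- predict_logrt(traj, task, rp, variant = "RelPE")
  expect_equal(sim$rt_ms, exp(pred))
  expect_true(all(sim$responded))
})

test_that("a positive outcome coefficient slows circle responses", {
  sim <- sim_subject(beta6 = 0.1, beta1 = 0, beta2 = 0, beta4 = 0,
                     zeta = 0.01)
  expect_lt(mean(sim$rt_ms[sim$outcome == "coin"]),
            mean(sim$rt_ms[sim$outcome == "circle"]))
})

test_that("simulated log RTs are centred on the model prediction", {
  task <- default_task()
  lp <- learn_params(omega = -2, sigma2_0 = 0.05)
  rp <- resp_params(beta1 = 0.3, beta6 = 0.07, zeta = 0.04)
  pred <- predict_logrt(run_two_branch(task, lp), task, rp,
                        variant = "RelPE+IrrelBias")
  sims <- sapply(1:300, function(s) {
    log(simulate_subject(task, "2HGF-RelPE+IrrelBias", lp, rp,
                         seed = s)$rt_ms)
  })
  mc_se <- sqrt(0.04 / 300)
  expect_lt(max(abs(rowMeans(sims) - pred)), 5 * mc_se)
})

test_that("simulation validates parameters and miss rate", {
  task <- default_task()
  lp <- learn_params()
  expect_error(simulate_subject(task, "2HGF-BL", lp,
                                resp_params(zeta = -1)), "non-negative")
  expect_error(simulate_subject(task, "2HGF-BL",
                                learn_params(variant = "3HGF"),
                                resp_params()), "disagrees")
  sim <- simulate_subject(task, "2HGF-BL", lp, resp_params(), seed = 3,
                          miss_rate = 0.2)
  expect_gt(sum(!sim$responded), 0)
  expect_true(all(is.na(sim$rt_ms[!sim$responded])))
})
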