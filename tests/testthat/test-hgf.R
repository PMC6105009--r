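test_that("first-level precision has its minimum of 4 at 0.5 and is
           symmetric", {
  expect_equal(precision_of_prediction(0.5), 4)
  expect_equal(precision_of_prediction(0.8), 6.25)
  p <- runif(20, 0.01, 0.99)
  expect_equal(precision_of_prediction(p), precision_of_prediction(1 - p))
  expect_true(all(precision_of_prediction(p) >= 4))
  expect_error(precision_of_prediction(0), "0, 1")
  expect_error(precision_of_prediction(1), "0, 1")
})

test_that("relevance weights normalise the two precisions", {
  expect_equal(relevance_weights(4, 4),
               tibble::tibble(rel_color = 0.5, rel_shape = 0.5))
  w <- relevance_weights(6.25, 4)
  expect_equal(w$rel_color, 6.25 / 10.25)
  pis <- matrix(4 + rexp(40), ncol = 2)
  w <- relevance_weights(pis[, 1], pis[, 2])
  expect_equal(w$rel_color + w$rel_shape, rep(1, 20))
  expect_error(relevance_weights(3.9, 4), ">= 4")
})

test_that("single branch step matches hand computation from a flat prior", {
  st <- hgf_branch_step(list(mu2 = 0, sigma2 = 0.05), u = 1,
                        learn_params(omega = -2))
  expect_equal(st$mu1hat, 0.5)
  expect_equal(st$pi1hat, 4)
  expect_equal(st$delta1, 0.5)
  pi2 <- 1 / (0.05 + exp(-2)) + 1 / 4
  expect_equal(st$mu2, 0.5 / pi2)
  expect_equal(st$sigma2, 1 / pi2)
})

test_that("compiled filter reproduces the plain-R oracle for all variants", {
  task <- default_task()
  u <- encode_inputs(task)
  for (variant in c("2HGF", "2HGFprecfb", "3HGF", "3HGFprecfb")) {
    traj <- run_two_branch(task, learn_params(omega = -2, sigma2_0 = 0.1),
                           variant = variant)
    orc <- oracle_filter(u$u_color, u$u_shape, omega = -2, sigma2_0 = 0.1,
                         variant = variant)
    expect_equal(traj$mu1hat_color, orc$mu1hat_c, tolerance = 1e-12)
    expect_equal(traj$mu1hat_shape, orc$mu1hat_s, tolerance = 1e-12)
    expect_equal(traj$delta1_color, orc$delta1_c, tolerance = 1e-12)
    expect_equal(traj$rel_color, orc$rel_c, tolerance = 1e-12)
    expect_equal(traj$pi1hat_shape, orc$pi1hat_s, tolerance = 1e-12)
  }
})

test_that("compiled filter matches iterating the exported single step", {
  task <- default_task()
  u <- encode_inputs(task)
  params <- learn_params(omega = -2.5, sigma2_0 = 0.05, variant = "2HGF")
  traj <- run_two_branch(task, params)
  st <- list(mu2 = 0, sigma2 = 0.05)
  for (k in 1:20) {
    st <- hgf_branch_step(st, u$u_color[k], params)
    expect_equal(traj$mu1hat_color[k], st$mu1hat, tolerance = 1e-12)
  }
})

test_that("beliefs approach certainty monotonically under constant input", {
  task <- default_task()
  task$outcome <- ifelse(task$color == "colorful", "coin", "circle")
  traj <- run_two_branch(task, learn_params(omega = -2, sigma2_0 = 0.05))
  expect_true(all(diff(traj$mu1hat_color) > 0))
  expect_lt(max(traj$mu1hat_color), 1)
  expect_gt(dplyr::last(traj$mu1hat_color), 0.95)
})

test_that("frozen learner keeps flat beliefs and half-sized errors", {
  task <- default_task()
  traj <- run_two_branch(task, learn_params(omega = -40, sigma2_0 = 1e-12))
  expect_equal(traj$mu1hat_color, rep(0.5, 160), tolerance = 1e-6)
  expect_equal(traj$delta1_color, traj$u_color - 0.5, tolerance = 1e-6)
  expect_equal(traj$rel_color, rep(0.5, 160), tolerance = 1e-6)
})

test_that("relabelling the reference pairing mirrors beliefs and preserves
           precisions and relevance", {
  task <- default_task()
  params <- learn_params(omega = -2, sigma2_0 = 0.05)
  a <- run_two_branch(task, params)
  b <- run_two_branch(task, params, flip_color = TRUE)
  expect_equal(b$mu1hat_color, 1 - a$mu1hat_color, tolerance = 1e-12)
  expect_equal(b$pi1hat_color, a$pi1hat_color, tolerance = 1e-12)
  expect_equal(b$rel_color, a$rel_color, tolerance = 1e-12)
  expect_equal(b$mu1hat_shape, a$mu1hat_shape, tolerance = 1e-12)
})

test_that("precision feedback reduces to the plain filter when the branches
           stay equally precise", {
  task <- default_task()
  task$shape <- ifelse(task$color == "colorful", "triangle", "square")
  u <- encode_inputs(task)
  expect_identical(u$u_color, u$u_shape)  # symmetric inputs, rel stays 0.5
  params <- learn_params(omega = -2, sigma2_0 = 0.05)
  plain <- run_two_branch(task, params, variant = "2HGF")
  fb <- run_two_branch(task, params, variant = "2HGFprecfb")
  expect_equal(fb$rel_color, rep(0.5, 160), tolerance = 1e-12)
  expect_equal(fb$mu1hat_color, plain$mu1hat_color, tolerance = 1e-12)
  expect_equal(fb$mu1hat_shape, plain$mu1hat_shape, tolerance = 1e-12)
})

test_that("a perfectly predictive feature attracts the relevance weight", {
  task <- default_task()
  task$outcome <- ifelse(task$shape == "triangle", "coin", "circle")
  withr::with_seed(9, {
    task$color <- sample(c("colorful", "grey"), 160, TRUE)
  })
  traj <- run_two_branch(task, learn_params(omega = -2, sigma2_0 = 0.05))
  expect_gt(mean(traj$rel_shape[141:160]), mean(traj$rel_color[141:160]))
  expect_gt(mean(traj$rel_shape[141:160]), 0.7)
})

test_that("first trial starts symmetric", {
  traj <- run_two_branch(default_task(), learn_params())
  expect_equal(traj$mu1hat_color[1], 0.5)
  expect_equal(traj$mu1hat_shape[1], 0.5)
  expect_equal(traj$rel_color[1], 0.5)
  expect_equal(traj$pi1hat_color[1], 4)
})

test_that("long layout carries one row per trial and branch", {
  long <- trajectories_long(run_two_branch(default_task(), learn_params()))
  expect_equal(nrow(long), 320)
  expect_setequal(unique(long$branch), c("color", "shape"))
  expect_true(all(c("u", "mu1hat", "pi1hat", "delta1") %in% names(long)))
})
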