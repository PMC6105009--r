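# Exact K = 2 references: with a flat Dirichlet(1, 1) prior the posterior
# over the frequency r of model 1 is p(r) ~ prod_n (r a_n + (1 - r) b_n)
# with a_n, b_n the per-subject normalised evidences; moments by quadrature.
exact_pp_k2 <- function(L) {
  a <- exp(L[, 1] - apply(L, 1, max))
  b <- exp(L[, 2] - apply(L, 1, max))
  m <- function(r) vapply(r, function(ri) prod(ri * a + (1 - ri) * b),
                          numeric(1))
  z <- integrate(m, 0, 1, rel.tol = 1e-10)$value
  integrate(function(r) r * m(r), 0, 1, rel.tol = 1e-10)$value / z
}

test_that("identical evidences give uniform frequencies and certain null", {
  L <- matrix(rnorm(10), 10, 3)
  L <- L[, c(1, 1, 1)]  # same column three times
  colnames(L) <- c("a", "b", "c")
  res <- run_bms(L, n_samples = 1e5, seed = 2)
  expect_equal(unname(res$models$pp), rep(1 / 3, 3), tolerance = 1e-8)
  expect_gt(res$bor, 0.5)  # null favoured; exact value ~0.84 at n = 10
  expect_equal(unname(res$models$pxp), rep(1 / 3, 3), tolerance = 0.02)
})

test_that("a unanimously dominant model reaches the analytic fixed point", {
  n <- 9
  L <- cbind(m1 = rep(0, n), m2 = rep(-30, n), m3 = rep(-30, n))
  fit <- rfx_bms(L)
  expect_equal(unname(fit$alpha), c(1 + n, 1, 1), tolerance = 1e-6)
  expect_equal(unname(fit$pp[1]), (1 + n) / (3 + n), tolerance = 1e-6)
  ep <- exceedance_and_protected(fit, n_samples = 2e5, seed = 4)
  expect_gt(ep$xp[1], 0.99)
  expect_lt(ep$bor, 0.01)
  expect_gt(ep$pxp[1], 0.99)
})

test_that("with well-separated evidences the variational frequencies match
           exact quadrature to two decimals", {
  withr::with_seed(17, {
    gaps <- c(4.5, 3.6, -3.2, 5.1, 4.0, -4.4, 3.8, 5.6) +
      rnorm(8, 0, 0.2)
  })
  L <- cbind(m1 = gaps, m2 = 0)
  fit <- rfx_bms(L)
  expect_equal(unname(fit$pp[1]), exact_pp_k2(L), tolerance = 0.01)
})

test_that("two-model exceedance matches the Beta closed form", {
  L <- cbind(m1 = c(3, 4, -2, 5, 3, 4), m2 = 0)
  fit <- rfx_bms(L)
  xp_exact <- 1 - pbeta(0.5, fit$alpha[1], fit$alpha[2])
  n_samples <- 4e5
  ep <- exceedance_and_protected(fit, n_samples = n_samples, seed = 11)
  mc_se <- sqrt(xp_exact * (1 - xp_exact) / n_samples)
  expect_lt(abs(ep$xp[1] - xp_exact), 4 * mc_se + 1e-6)
})

test_that("adding a per-subject constant to the evidences changes nothing", {
  withr::with_seed(23, L <- matrix(rnorm(24, sd = 2), 8, 3))
  colnames(L) <- c("a", "b", "c")
  shifted <- L + rnorm(8, 100, 10)
  f1 <- rfx_bms(L)
  f2 <- rfx_bms(shifted)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-8)
  expect_equal(f1$F1 - f1$F0, f2$F1 - f2$F0, tolerance = 1e-6)
})

test_that("an overwhelming prior concentration pins frequencies to uniform", {
  L <- cbind(m1 = rep(3, 6), m2 = 0)
  fit <- rfx_bms(L, alpha0 = 1e6)
  expect_equal(unname(fit$pp), c(0.5, 0.5), tolerance = 1e-4)
})

test_that("family aggregation sums member frequencies under a family-uniform
           prior", {
  withr::with_seed(31, L <- matrix(rnorm(32, sd = 1.5), 8, 4))
  colnames(L) <- c("a1", "a2", "b1", "b2")
  part <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  fam <- family_bms(L, part, n_samples = 1e5, seed = 7)
  fit <- rfx_bms(L, alpha0 = c(0.5, 0.5, 0.5, 0.5))
  expect_equal(fam$pp, unname(c(fit$pp[1] + fit$pp[2],
                                fit$pp[3] + fit$pp[4])), tolerance = 1e-8)
  expect_equal(sum(fam$pp), 1, tolerance = 1e-10)
  expect_equal(sum(fam$xp), 1, tolerance = 1e-10)
})

test_that("default families partition the sixteen-model space", {
  fams <- default_families()
  for (p in fams) {
    ids <- unlist(p, use.names = FALSE)
    expect_setequal(ids, model_space())
    expect_equal(anyDuplicated(ids), 0)
  }
  expect_equal(lengths(fams$response), setNames(rep(4L, 4),
                                                names(fams$response)))
})

test_that("invalid inputs are rejected", {
  L <- cbind(a = c(1, 2), b = c(0, 0))
  expect_error(rfx_bms(L[, 1, drop = FALSE]), ">= 2")
  expect_error(rfx_bms(cbind(a = c(1, NA), b = c(0, 0))), "finite")
  expect_error(rfx_bms(L, alpha0 = 0), "positive")
  expect_error(exceedance_and_protected(rfx_bms(L), n_samples = 100),
               "1e4|at least")
  expect_error(family_bms(L, list(A = "a")), "disjoint")
  expect_error(family_bms(L, list(A = c("a", "b"), B = "b")), "disjoint")
  expect_error(run_bms(cbind(a = c(1, NA), b = c(0, 0))), "NA")
})

test_that("the evidence-matrix report feeds model selection end to end", {
  withr::with_seed(37, L <- matrix(rnorm(12), 4, 3))
  colnames(L) <- c("a", "b", "c")
  class(L) <- c("evidence_matrix", "matrix", "array")
  res <- run_bms(L, n_samples = 1e5, seed = 3,
                 families = list(split = list(AB = c("a", "b"), C = "c")))
  expect_s3_class(res, "bms_result")
  expect_equal(sum(res$models$pp), 1, tolerance = 1e-10)
  expect_equal(nrow(res$families), 2)
  expect_output(print(res), "bms_result")
})
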