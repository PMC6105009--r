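test_that("validity respects the inclusive exclusion bounds", {
  d <- tibble::tibble(rt_ms = c(149, 150, 800, 1500, 1501, NA),
                      responded = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- preprocess_rts(d)
  expect_equal(out$valid, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$log_rt, ifelse(out$valid, log(d$rt_ms), NA_real_))
  d2 <- d; d2$responded[3] <- FALSE
  expect_false(preprocess_rts(d2)$valid[3])
  expect_error(preprocess_rts(tibble::tibble(rt_ms = -5)), "negative")
  expect_error(preprocess_rts(tibble::tibble(x = 1)), "rt_ms")
})

test_that("expectedness means follow the hand computation per subject", {
  d <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 4),
    expected = rep(c("expected", "expected", "unexpected", "unexpected"), 2),
    rt_ms = c(300, 400, 500, 700, 310, 330, 600, 800),
    responded = TRUE)
  out <- expectedness_means(d)
  expect_equal(out$subject_id, c("a", "b"))
  expect_equal(out$mean_expected, c(mean(log(c(300, 400))),
                                    mean(log(c(310, 330)))))
  expect_equal(out$mean_unexpected, c(mean(log(c(500, 700))),
                                      mean(log(c(600, 800)))))
  expect_equal(out$n_expected, c(2L, 2L))
  d$rt_ms[3:4] <- NA
  d$responded[3:4] <- FALSE
  expect_warning(expectedness_means(d), "zero valid")
})

test_that("time bins pair consecutive expected events within block and
           outcome condition", {
  # one block, 8 expected coin events at known times plus distractor rows
  d <- tibble::tibble(
    trial = 1:20, block = 1,
    expected = rep(c("expected", "unexpected"), c(16, 4)),
    outcome = c(rep(c("coin", "circle"), 8), rep("circle", 4)),
    rt_ms = 200 + (1:20) * 10, responded = TRUE)
  out <- timebin_means(d)
  coin <- dplyr::filter(out, condition == "coin")
  expect_equal(coin$bin, 1:4)
  # coin events sit on trials 1,3,5,...,15; bins pair them in trial order
  coin_rts <- 200 + seq(1, 15, 2) * 10
  expect_equal(coin$mean_log_rt,
               as.numeric(tapply(log(coin_rts), rep(1:4, each = 2), mean)))
  expect_equal(coin$n, rep(2L, 4))
})

test_that("time bins cover the full design and flag empty cells", {
  sim <- sim_subject(seed = 81)
  out <- timebin_means(sim)
  expect_equal(nrow(out), 8)  # 2 conditions x 4 bins
  expect_equal(sum(out$n), 128)  # 16 expected x 8 blocks
  expect_true(all(out$n == 16))
  sim2 <- preprocess_rts(sim)
  # invalidate every expected coin event: its bins become empty
  sim2$valid[sim2$expected == "expected" & sim2$outcome == "coin"] <- FALSE
  expect_warning(out2 <- timebin_means(sim2), "empty")
  expect_equal(dplyr::filter(out2, condition == "coin")$n, rep(0L, 4))
})

test_that("the raw salience score averages the per-half manifestation
           contrasts in ms", {
  task <- default_task()
  rt <- numeric(160)
  h1 <- task$half == 1  # color relevant first: shape is irrelevant
  rt[h1 & task$shape == "square"] <- 300
  rt[h1 & task$shape == "triangle"] <- 350
  rt[!h1 & task$color == "colorful"] <- 400
  rt[!h1 & task$color == "grey"] <- 420
  d <- dplyr::mutate(tibble::as_tibble(task), rt_ms = rt, responded = TRUE)
  expect_equal(aberrant_salience_raw(d)$as_score_ms, (50 + 20) / 2)
  d$rt_ms[h1 & task$shape == "square"] <- NA
  d$responded[h1 & task$shape == "square"] <- FALSE
  expect_error(aberrant_salience_raw(d), "zero valid")
})

test_that("salience score is zero for unbiased and invariant to sign", {
  task <- default_task()
  d <- dplyr::mutate(tibble::as_tibble(task), rt_ms = 500, responded = TRUE)
  expect_equal(aberrant_salience_raw(d)$as_score_ms, 0)
  # swapping which manifestation is slower leaves the score unchanged
  rt_a <- ifelse(task$shape == "square", 480, 520)
  rt_b <- ifelse(task$shape == "square", 520, 480)
  score <- function(r) aberrant_salience_raw(
    dplyr::mutate(tibble::as_tibble(task), rt_ms = r, responded = TRUE)
  )$as_score_ms
  expect_equal(score(rt_a), score(rt_b))
})

test_that("group comparisons wrap the standard tests", {
  withr::with_seed(91, {
    a <- rnorm(15, 1)
    b <- rnorm(20, 0, 2)
  })
  tt <- t.test(a, b, var.equal = FALSE)
  out <- group_compare(a, b, "welch")
  expect_equal(out$statistic, unname(tt$statistic)^2)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, unname(tt$parameter))
  expect_equal(out$estimate, mean(a) - mean(b))
  expect_equal(out$p_value, tt$p.value)

  ot <- group_compare(a, kind = "one_sample_t", alternative = "greater")
  rt <- t.test(a, mu = 0, alternative = "greater")
  expect_equal(ot$statistic, unname(rt$statistic))
  expect_equal(ot$p_value, rt$p.value)

  sp <- group_compare(1:10, (1:10)^2, "spearman")
  expect_equal(sp$estimate, 1)

  expect_error(group_compare(1, 1:5, "welch"), ">= 2")
  expect_error(group_compare(rep(1, 5), rep(2, 5), "welch"), "zero variance")
  expect_error(group_compare(rep(0, 4), kind = "one_sample_t"), "zero")
  expect_error(group_compare(1:2, 2:3, "spearman"), ">= 3")
})

test_that("the subject summary joins both raw analyses", {
  data <- dplyr::bind_rows(
    dplyr::mutate(sim_subject(seed = 95), subject_id = "s1"),
    dplyr::mutate(sim_subject(seed = 96), subject_id = "s2"))
  out <- subject_summary(data)
  expect_equal(nrow(out), 2)
  expect_true(all(c("mean_expected", "mean_unexpected", "as_score_ms") %in%
                    names(out)))
  expect_true(all(is.finite(out$as_score_ms)))
})
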