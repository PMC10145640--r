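test_that("day-1/day-2 counts tabulate and conserve the drop-off histogram", {
  tk <- data.frame(host_id = c("A", "A", "A", "B"),
                   stage = c("nymph", "nymph", "nymph", "larva"),
                   observed_day = c(0.5, 1.5, 1.5, 3.5),
                   species = "ricinus", stringsAsFactors = FALSE)
  cnt <- day12_counts(tk)
  get <- function(h, s, d) cnt$count[cnt$host_id == h & cnt$stage == s &
                                       cnt$day == d]
  expect_identical(get("A", "nymph", 1), 1L)
  expect_identical(get("A", "nymph", 2), 2L)
  expect_identical(get("B", "larva", 1), 0L)  # zero-filled
  expect_identical(nrow(cnt), 2L * 4L * 2L)
  # empty input with an explicit host universe: all-zero, right shape
  hosts <- data.frame(host_id = c("A", "B", "C"))
  cnt0 <- day12_counts(tk[0, ], hosts)
  expect_identical(nrow(cnt0), 3L * 4L * 2L)
  expect_true(all(cnt0$count == 0))
  # conservation against the simulator histogram
  co <- simulate_cohort(sim_config(seed = 12))
  cc <- day12_counts(co$ticks, co$hosts)
  tk_r <- ricinus(co)
  expect_identical(sum(cc$count[cc$day == 1]), sum(tk_r$observed_day == 0.5))
  expect_identical(sum(cc$count[cc$day == 2]), sum(tk_r$observed_day == 1.5))
})

test_that("degenerate random effect and dispersion reduce to a Poisson GLM", {
  co <- simulate_cohort(sim_config(seed = 13))
  cnt <- day12_counts(co$ticks, co$hosts)
  ag <- day12_test(cnt, method = "agq", fix = list(sigma = 0, theta = 1e7))
  df <- as.data.frame(cnt)
  df$stage <- factor(df$stage, c("larva", "nymph", "female", "male"))
  df$day <- factor(df$day)
  g <- glm(count ~ day * stage, poisson(), data = df)
  expect_equal(unname(ag$coefficients), unname(coef(g)), tolerance = 1e-4)
})

test_that("adaptive quadrature and Laplace agree on well-separated data", {
  co <- simulate_cohort(sim_config(seed = 14, day1_suppression_prob = 0.5,
                                   frailty_sd = 0.5))
  cnt <- day12_counts(co$ticks, co$hosts)
  la <- day12_test(cnt, method = "laplace")
  gh <- day12_test(cnt, method = "agq", nodes = 15)
  expect_lt(max(abs(gh$ratios$rate_ratio / la$ratios$rate_ratio - 1)), 0.02)
  expect_lt(abs(gh$sigma / la$sigma - 1), 0.05)
})

test_that("rate ratios are invariant to host relabelling", {
  co <- simulate_cohort(sim_config(seed = 15, day1_suppression_prob = 0.4))
  cnt <- day12_counts(co$ticks, co$hosts)
  la <- day12_test(cnt)
  relab <- setNames(sample(sprintf("X%02d", 1:57)), unique(cnt$host_id))
  cnt2 <- cnt; cnt2$host_id <- relab[cnt$host_id]
  la2 <- day12_test(cnt2)
  expect_equal(la$ratios$rate_ratio, la2$ratios$rate_ratio, tolerance = 1e-6)
})

test_that("subadult pooling and input validation behave", {
  co <- simulate_cohort(sim_config(seed = 16, day1_suppression_prob = 0.5))
  cnt <- day12_counts(co$ticks, co$hosts)
  ts <- day12_test(cnt, grouping = "subadult")
  expect_identical(as.character(ts$ratios$group),
                   c("subadult", "female", "male"))
  expect_gt(ts$ratios$rate_ratio[ts$ratios$group == "subadult"], 1)
  zero <- cnt; zero$count <- 0L
  expect_error(day12_test(zero), "zero")
  one <- cnt[cnt$host_id == cnt$host_id[1], ]
  expect_error(day12_test(one), "two hosts")
})

test_that("suppression of non-males leaves the male day effect quiet", {
  male_sig <- sub_sig <- 0L
  n_seed <- 20
  for (s in seq_len(n_seed)) {
    co <- simulate_cohort(sim_config(seed = 1300 + s,
                                     day1_suppression_prob = 0.5))
    tst <- day12_test(day12_counts(co$ticks, co$hosts))
    p <- setNames(tst$ratios$p, as.character(tst$ratios$group))
    rr <- setNames(tst$ratios$rate_ratio, as.character(tst$ratios$group))
    if (p["male"] < 0.05 && rr["male"] > 1) male_sig <- male_sig + 1L
    if (p["nymph"] < 0.05 && rr["nymph"] > 1) sub_sig <- sub_sig + 1L
  }
  expect_lt(male_sig, sub_sig)
  expect_gt(sub_sig / n_seed, 0.8)
})
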