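test_that("latent bookkeeping and reproducibility hold", {
  co <- simulate_cohort(sim_config(seed = 5))
  tk <- co$ticks
  expect_true(all(abs(tk$latent_backward_time + tk$latent_forward_time -
                        tk$latent_whole_time) < 1e-9))
  expect_true(all(tk$observed_day == ceiling(tk$latent_forward_time) - 0.5))
  expect_true(all(tk$observed_day > 0))
  co2 <- simulate_cohort(sim_config(seed = 5))
  expect_identical(co$ticks, co2$ticks)
  co3 <- simulate_cohort(sim_config(seed = 6))
  expect_false(identical(co$ticks, co3$ticks))
  # seasons follow the host schedule; hexagonus rare and nymph-staged
  expect_true(all(tk$season %in% c("spring", "summer", "autumn")))
  hex <- tk[tk$species == "hexagonus", ]
  expect_true(all(hex$stage == "nymph"))
  expect_lt(nrow(hex) / nrow(tk), 0.03)
})

test_that("capture position is uniform over the attachment spell", {
  co <- simulate_cohort(small_config(seed = 31, n_hosts = 50,
                                     mean_nymph = 150, mean_larva = 150))
  u <- co$ticks$latent_forward_time / co$ticks$latent_whole_time
  expect_gt(length(u), 1e4)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("memoryless shape gives unbiased-looking forward times", {
  cfg <- small_config(seed = 32, shape = 1, n_hosts = 60, mean_nymph = 1600,
                      mean_larva = 0)
  co <- simulate_cohort(cfg)
  lam <- cfg$scale["nymph", "spring"]
  v <- co$ticks$latent_forward_time
  expect_gt(length(v), 5e4)
  expect_equal(mean(v), lam, tolerance = 4 * sd(v) / sqrt(length(v)))
})

test_that("length bias shows up as the shape-only mean ratio", {
  co <- simulate_cohort(small_config(seed = 33, n_hosts = 60,
                                     mean_nymph = 900, mean_larva = 900))
  tk <- co$ticks
  expect_gt(nrow(tk), 5e4)
  emp <- mean(tk$latent_whole_time) / mean(tk$latent_forward_time)
  # sampled whole times are length-biased; their mean over twice the forward
  # mean is the shape-only ratio, here computed by quadrature
  k <- 4.5; lam <- small_config(1)$scale["nymph", "spring"]
  et <- quad(function(t) t * weib_pdf(t, k, lam))
  elb <- quad(function(t) t^2 * weib_pdf(t, k, lam)) / et
  expect_equal(mean(tk$latent_whole_time[tk$stage == "nymph"]),
               elb, tolerance = 0.02 * elb)
  expect_equal(emp, 2, tolerance = 0.03)  # E[T*] = 2 E[V] by uniform position
})

test_that("per-cell counts are calibrated when frailty is off", {
  cfg <- small_config(seed = 34, n_hosts = 200, mean_nymph = 25,
                      mean_larva = 10)
  co <- simulate_cohort(cfg)
  for (st in c("nymph", "larva")) {
    n_st <- vapply(co$hosts$host_id, function(h)
      sum(co$ticks$host_id == h & co$ticks$stage == st), 0)
    mu <- cfg$abundance_mean[st, "spring"]
    expect_lt(abs(mean(n_st) - mu), 3 * sd(n_st) / sqrt(length(n_st)))
  }
})

test_that("stationary-process and direct length-biased samplers agree in law", {
  cfg1 <- small_config(seed = 35, n_hosts = 40, mean_nymph = 300,
                       mean_larva = 0)
  a <- simulate_cohort(cfg1, method = "stationary")$ticks
  b <- simulate_cohort(cfg1, method = "lengthbias")$ticks
  expect_gt(min(nrow(a), nrow(b)), 1e4)
  expect_gt(suppressWarnings(
    ks.test(a$latent_whole_time[1:1e4], b$latent_whole_time[1:1e4])$p.value),
    0.01)
  expect_gt(suppressWarnings(
    ks.test(a$latent_forward_time[1:1e4], b$latent_forward_time[1:1e4])$p.value),
    0.01)
})

test_that("day-1 suppression moves the prescribed fraction of day-1 records", {
  recs <- data.frame(host_id = "H01", stage = rep(c("nymph", "male"), each = 1e4),
                     observed_day = 0.5, species = "ricinus",
                     stringsAsFactors = FALSE)
  expect_identical(apply_day1_suppression(recs, 0), recs)
  all_moved <- apply_day1_suppression(recs, 1)
  expect_true(all(all_moved$observed_day[all_moved$stage == "nymph"] == 1.5))
  expect_true(all(all_moved$observed_day[all_moved$stage == "male"] == 0.5))
  set.seed(9)
  half <- apply_day1_suppression(recs, 0.5)
  moved <- sum(half$observed_day[half$stage == "nymph"] == 1.5)
  bounds <- qbinom(c(0.005, 0.995), 1e4, 0.5)
  expect_gt(moved, bounds[1]); expect_lt(moved, bounds[2])
  expect_identical(nrow(half), nrow(recs))
  expect_error(apply_day1_suppression(recs, 1.5), "prob")
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(sim_config(capture_schedule = data.frame()), "empty")
  expect_error(sim_config(n_hosts = 3), "disagrees")
  bad <- default_sched <- sim_config(seed = 1)$capture_schedule
  bad$season[1] <- "winter"
  expect_error(sim_config(capture_schedule = bad), "season")
  ab <- matrix(-1, 4, 3, dimnames = list(c("larva", "nymph", "female", "male"),
                                         c("spring", "summer", "autumn")))
  expect_error(sim_config(abundance_mean = ab), ">= 0")
  expect_error(sim_config(shape = c(2, 3)), "single")
  expect_error(sim_config(seed = NULL), "seed")
})
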