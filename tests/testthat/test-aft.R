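# Recovery fixture shared by several blocks: shape 3, cell scales spanning
# roughly 4-12 days, paper-like size (57 hosts, ~4700 ticks).
recovery_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      scale <- matrix(c(4, 5, 9, 12,
                        4.5, 5.5, 10, 11,
                        5, 6, 8, 10),
                      nrow = 4,
                      dimnames = list(c("larva", "nymph", "female", "male"),
                                      c("spring", "summer", "autumn")))
      cfg <- sim_config(shape = 3, scale = scale, frailty_sd = 0,
                        hexagonus_fraction = 0, seed = 424)
      val <<- list(cfg = cfg, cohort = simulate_cohort(cfg))
    }
    val
  }
})

test_that("profile-likelihood fit recovers shape and cell scales from simulation", {
  rc <- recovery_cohort()
  tk <- rc$cohort$ticks
  expect_gt(nrow(tk), 3000)
  fit <- fraft(observed_day ~ stage * season, data = tk, cluster = host_id)
  expect_true(fit$converged)
  expect_true(fit$robust)
  expect_lt(abs(fit$shape - 3) / 3, 0.10)
  # every cell log-scale within 3 robust SEs of the truth
  cells <- unique(tk[, c("stage", "season")])
  tt <- delete.response(fit$terms)
  X <- model.matrix(tt, model.frame(tt, cells, xlev = fit$xlevels))
  est <- drop(X %*% coef(fit))
  p <- length(coef(fit))
  se <- sqrt(diag(X %*% fit$vcov[1:p, 1:p] %*% t(X)))
  truth <- log(rc$cfg$scale[cbind(as.character(cells$stage),
                                  as.character(cells$season))])
  expect_true(all(abs(est - truth) < 3 * se))
  # whole-scale group means near the true lambda * Gamma(1 + 1/k)
  gm <- group_means(fit)
  truth_t <- whole_mean(3, rc$cfg$scale[cbind(as.character(gm$stage),
                                              as.character(gm$season))])
  se_t <- (log(gm$whole_upper) - log(gm$whole_lower)) / (2 * qnorm(0.975))
  expect_true(all(abs(log(gm$whole_mean) - log(truth_t)) < 3 * se_t))
})

test_that("point estimates ignore cluster labels; the sandwich does not", {
  rc <- recovery_cohort()
  tk <- ricinus(rc$cohort)
  tk <- tk[tk$season == "spring", ]
  f1 <- fraft(observed_day ~ stage, data = tk, cluster = host_id)
  set.seed(8)
  tk2 <- tk
  tk2$host_id <- sample(tk$host_id)   # relabel, breaking real clustering
  f2 <- fraft(observed_day ~ stage, data = tk2, cluster = host_id)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-8)
  expect_lt(abs(f1$shape - f2$shape), 1e-8)
  expect_gt(max(abs(f1$vcov - f2$vcov)), 1e-10)
})

test_that("weighted day-bin aggregation reproduces the per-record fit", {
  rc <- recovery_cohort()
  tk <- ricinus(rc$cohort)
  tk <- tk[tk$season == "summer", ]
  f1 <- fraft(observed_day ~ stage, data = tk)
  agg <- aggregate(list(count = tk$observed_day),
                   by = list(stage = tk$stage, observed_day = tk$observed_day),
                   FUN = length)
  f2 <- fraft(observed_day ~ stage, data = agg, weights = count)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$shape, f2$shape, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("midpoint and interval-censored conventions agree on day-scale data", {
  rc <- recovery_cohort()
  tk <- ricinus(rc$cohort)
  fm <- fraft(observed_day ~ stage * season, data = tk)
  fi <- fraft(observed_day ~ stage * season, data = tk,
              convention = "interval")
  expect_lt(abs(fm$shape - fi$shape) / fm$shape, 0.05)
  expect_lt(max(abs(coef(fm) - coef(fi))), 0.1)
})

test_that("profile likelihood is unimodal and bracket-invariant", {
  fx <- study_fixtures()
  bins <- fx$daybins
  bins$observed_day <- bins$day - 0.5
  shapes <- vapply(list(c(0.3, 30), c(1, 20), c(2, 10)), function(rg)
    fraft(observed_day ~ stage, data = bins, weights = count,
          shape_range = rg)$shape, 0)
  expect_lt(max(shapes) - min(shapes), 1e-6)
  # profile curve concave around the optimum on a grid
  pl <- vapply(seq(log(2), log(9), length.out = 25), function(s)
    fraft(observed_day ~ stage, data = bins, weights = count,
          shape = exp(s))$loglik, 0)
  expect_identical(sum(diff(sign(diff(pl))) != 0), 1L)
})

test_that("a fixed memoryless shape collapses whole and observed means", {
  rc <- recovery_cohort()
  tk <- ricinus(rc$cohort)
  fit <- fraft(observed_day ~ stage, data = tk, shape = 1)
  expect_true(fit$shape_fixed)
  gm <- group_means(fit)
  expect_equal(gm$whole_mean, gm$observed_mean, tolerance = 1e-10)
  expect_equal(unique(round(gm$mean_ratio, 10)), 1)
})

test_that("confidence intervals for cell means and the mean ratio are calibrated", {
  k_true <- 3; lam_true <- 6
  n_rep <- 400
  cover_mean <- cover_ratio <- logical(n_rep)
  set.seed(314)
  for (r in seq_len(n_rep)) {
    v <- ceiling(rforward(350, k_true, lam_true)) - 0.5
    df <- data.frame(observed_day = v)
    fit <- fraft(observed_day ~ 1, data = df)
    pr <- predict(fit, newdata = data.frame(dummy = 1),
                  type = "whole_mean", se.fit = TRUE)
    lo <- exp(log(pr$fit) - 1.96 * pr$se.fit)
    hi <- exp(log(pr$fit) + 1.96 * pr$se.fit)
    cover_mean[r] <- lo <= whole_mean(k_true, lam_true) &&
      whole_mean(k_true, lam_true) <= hi
    ci <- mean_ratio_ci(fit$shape, fit$shape_se)
    cover_ratio[r] <- ci$lower <= mean_ratio(k_true) &&
      mean_ratio(k_true) <= ci$upper
  }
  expect_gt(mean(cover_mean), 0.90); expect_lt(mean(cover_mean), 0.98)
  expect_gt(mean(cover_ratio), 0.90); expect_lt(mean(cover_ratio), 0.98)
})

test_that("cluster-robust SEs exceed naive SEs under shared-host duration effects", {
  worse <- 0L
  for (s in 1:20) {
    co <- simulate_cohort(small_config(seed = 500 + s, n_hosts = 25,
                                       mean_nymph = 40, mean_larva = 0,
                                       duration_frailty_sd = 0.4))
    fit <- fraft(observed_day ~ 1, data = co$ticks, cluster = host_id)
    if (sqrt(fit$vcov[1, 1]) < sqrt(fit$naive_vcov[1, 1])) worse <- worse + 1L
  }
  expect_lte(worse, 2L)
})

test_that("degenerate inputs are rejected and merging preserves rows", {
  expect_error(fraft(observed_day ~ 1, data = data.frame(observed_day = numeric(0))),
               "no usable")
  expect_error(fraft(observed_day ~ 1,
                     data = data.frame(observed_day = rep(1.5, 30))),
               "identifiable")
  expect_error(fraft(observed_day ~ 1,
                     data = data.frame(observed_day = c(-0.5, 1.5))),
               "positive")
  df <- data.frame(observed_day = c(0.5, 1.5, 2.5, 0.5))
  m <- merge_day12(df)
  expect_equal(m$observed_day, c(1, 1, 2.5, 1))
  expect_identical(nrow(m), nrow(df))
  expect_error(fraft(observed_day ~ stage,
                     data = data.frame(observed_day = 0.5, stage = "imago")),
               "unknown stage")
})

test_that("residuals and simulate follow the fitted law", {
  rc <- recovery_cohort()
  tk <- ricinus(rc$cohort)
  fit <- fraft(observed_day ~ stage, data = tk)
  r <- residuals(fit, type = "cox-snell")
  expect_true(all(r >= 0))
  # binned observations: mean of -log S is near 1 under the model
  expect_equal(mean(r), 1, tolerance = 0.1)
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(dim(sims), c(nrow(tk), 2L))
  expect_true(all(sims > 0))
  sims2 <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(sims, sims2)
})
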