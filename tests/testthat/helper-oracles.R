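# Independent oracles used across tests: quadrature of the closed forms and
# a rejection sampler for the length-biased law. These deliberately avoid the
# package's own evaluation paths.

quad <- function(f, lower = 0, upper = Inf, ...) {
  integrate(f, lower, upper, rel.tol = 1e-10, abs.tol = 1e-12, ...)$value
}

# raw Weibull density written out, not via dwhole()
weib_pdf <- function(t, k, lam) (k / lam) * (t / lam)^(k - 1) * exp(-(t / lam)^k)

# acceptance-rejection draw from t * f(t) / E[T] using a Weibull envelope
# with inflated scale; envelope constant found numerically
rbiased_reject <- function(n, k, lam) {
  et <- quad(function(t) t * weib_pdf(t, k, lam))
  target <- function(t) t * weib_pdf(t, k, lam) / et
  genv <- function(t) weib_pdf(t, k, lam * 1.6)
  grid <- seq(1e-3, lam * 6, length.out = 4000)
  M <- max(target(grid) / genv(grid)) * 1.05
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * M * 1.2)
    x <- lam * 1.6 * rweibull(m, k, 1)
    keep <- runif(m) < target(x) / (M * genv(x))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# compact per-cell cohort for fast fits: two stages, one season
small_config <- function(seed, shape = 4.5, n_hosts = 20, mean_nymph = 30,
                         mean_larva = 20, frailty_sd = 0,
                         duration_frailty_sd = 0, ...) {
  ab <- matrix(0, 4, 3, dimnames = list(c("larva", "nymph", "female", "male"),
                                        c("spring", "summer", "autumn")))
  ab["nymph", "spring"] <- mean_nymph
  ab["larva", "spring"] <- mean_larva
  sched <- data.frame(capture_week = rep(1:5, length.out = n_hosts),
                      season = "spring")
  sim_config(capture_schedule = sched, abundance_mean = ab, shape = shape,
             frailty_sd = frailty_sd,
             duration_frailty_sd = duration_frailty_sd,
             hexagonus_fraction = 0, seed = seed, ...)
}

ricinus <- function(cohort) {
  cohort$ticks[cohort$ticks$species == "ricinus", , drop = FALSE]
}
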