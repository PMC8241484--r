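test_that("baseline detectability is logit-linear in covariates", {
  p <- detection_params(p0_intercept = qlogis(0.2), sigma = 5)
  expect_equal(baseline_p0(p), 0.2)
  expect_equal(baseline_p0(p, gps = 1), 0.2) # beta_gps = 0
  p2 <- detection_params(qlogis(0.2), 5, beta_gps = -0.5, beta_tracks = 0.3)
  expect_equal(baseline_p0(p2, gps = 1), plogis(qlogis(0.2) - 0.5))
  expect_equal(baseline_p0(p2, tracks = 2, gps = 1),
               plogis(qlogis(0.2) + 0.6 - 0.5))
  expect_error(baseline_p0(p2, tracks = NA), "missing")
})

test_that("half-normal detection decays as the closed form and motivates the 6-sigma buffer", {
  expect_equal(detection_prob(0.3, 0, 5), 0.3)
  expect_equal(detection_prob(0.3, 5, 5), 0.3 * exp(-1 / 2))
  expect_equal(detection_prob(0.3, 30, 5), 0.3 * exp(-18))
  expect_lt(detection_prob(1, 30, 5), 2e-8) # negligible beyond 6 sigma
  d <- seq(0, 50, by = 2.5)
  expect_true(all(diff(detection_prob(0.2, d, 8)) < 0))
})

test_that("observation log-likelihood equals the direct binomial computation", {
  st <- make_tiny_study()
  pars <- tiny_params()
  n <- dim(st$y)[1]; Tn <- st$horizon
  ac <- matrix(5L, n, Tn)
  z <- matrix(2L, n, Tn)
  z[2, 3] <- 3L; st$y[2, , 3] <- 0L # culled individual undetected at death
  ll <- observation_loglik(st$y, ac, z, pars$detection, st$detectors,
                          st$habitat, gps = st$gps, prev = st$prev)
  # independent accumulation detector by detector
  dd <- st$detectors$detectors
  manual <- 0
  for (i in seq_len(n)) for (t in seq_len(Tn)) {
    if (z[i, t] != 2) next
    d <- sqrt((dd$x - st$habitat$cells$x[5])^2 +
                (dd$y - st$habitat$cells$y[5])^2)
    p0 <- plogis(qlogis(0.1) + 0.3 * st$prev[i, t] - 0.2 * st$gps[i, t])
    pv <- p0 * exp(-d^2 / 200)
    manual <- manual + sum(dbinom(st$y[i, , t], dd$K, pv, log = TRUE))
  }
  expect_equal(ll, manual, tolerance = 1e-12)
})

test_that("positive counts while not alive are impossible, and certain zeros are free", {
  st <- make_tiny_study()
  pars <- tiny_params()
  n <- dim(st$y)[1]; Tn <- st$horizon
  ac <- matrix(5L, n, Tn)
  z <- matrix(1L, n, Tn) # nobody alive, but y has positive counts
  expect_identical(observation_loglik(st$y, ac, z, pars$detection,
                                      st$detectors, st$habitat), -Inf)
  y0 <- array(0L, dim = dim(st$y))
  zero_p <- detection_params(p0_intercept = -700, sigma = 10) # p0 = 0
  expect_equal(observation_loglik(y0, ac, matrix(2L, n, Tn), zero_p,
                                  st$detectors, st$habitat), 0)
})

test_that("local evaluation with a radius covering the grid equals full evaluation", {
  st <- make_tiny_study()
  pars <- tiny_params()
  n <- dim(st$y)[1]; Tn <- st$horizon
  set.seed(5)
  ac <- matrix(sample.int(9, n * Tn, replace = TRUE), n, Tn)
  z <- matrix(2L, n, Tn)
  full <- observation_loglik(st$y, ac, z, pars$detection, st$detectors,
                             st$habitat, gps = st$gps, prev = st$prev,
                             local_radius = Inf)
  loc <- observation_loglik(st$y, ac, z, pars$detection, st$detectors,
                            st$habitat, gps = st$gps, prev = st$prev,
                            local_radius = 200)
  expect_equal(loc, full, tolerance = 1e-12)
})

test_that("compiled observation kernels agree with the R reference", {
  st <- make_tiny_study()
  pars <- tiny_params()
  prep <- opscr:::.prepare_fit(st, fit_config())
  n <- prep$n; Tn <- prep$Tn
  set.seed(6)
  ac <- matrix(sample.int(9, n * Tn, replace = TRUE), n, Tn)
  z <- matrix(2L, n, Tn)
  E2 <- opscr:::emission_alive_cpp(
    ac, prep$d2cd, prep$yflat, prep$K, prep$county,
    pars$detection$p0_intercept, prep$detcov, numeric(0),
    pars$detection$beta_prev, pars$detection$beta_gps, prep$gps, prep$prev,
    pars$detection$sigma, Inf)
  manual <- sapply(seq_len(Tn), function(t) sapply(seq_len(n), function(i)
    opscr:::.obs_ll_row(st, pars$detection, i, t, ac[i, t])))
  expect_equal(E2, matrix(manual, n, Tn), tolerance = 1e-10)
  alive <- matrix(1L, n, Tn)
  tot <- opscr:::obs_ll_cpp(
    ac, alive, prep$d2cd, prep$yflat, prep$K, prep$county,
    pars$detection$p0_intercept, prep$detcov, numeric(0),
    pars$detection$beta_prev, pars$detection$beta_gps, prep$gps, prep$prev,
    pars$detection$sigma, Inf)
  expect_equal(tot, sum(E2), tolerance = 1e-10)
})

test_that("simulated counts respect gating, saturate, and match binomial moments", {
  st <- make_tiny_study()
  n <- 3; Tn <- 3
  ac <- matrix(5L, n, Tn)
  dead <- matrix(1L, n, Tn)
  pars <- detection_params(qlogis(0.3), 8)
  expect_true(all(simulate_observations(ac, dead, pars, st$detectors,
                                        st$habitat) == 0))
  sat <- detection_params(p0_intercept = 750, sigma = 1e6) # p0 = 1
  ysat <- simulate_observations(ac, matrix(2L, n, Tn), sat, st$detectors,
                                st$habitat)
  expect_true(all(st$detectors$detectors$K == 4))
  expect_true(all(ysat == 4L))
  # moment check: mean of y over replicates ~ K p within 3 MC SE
  set.seed(7)
  one <- matrix(2L, 1, 1)
  p <- detection_prob(0.3, 0, 8) # AC cell 5 sits on detector 5's centre
  reps <- replicate(1e4, simulate_observations(matrix(5L, 1, 1), one, pars,
                                               st$detectors,
                                               st$habitat)[1, 5, 1])
  K <- st$detectors$detectors$K[5]
  se <- sqrt(K * p * (1 - p) / 1e4)
  expect_lt(abs(mean(reps) - K * p), 3 * se)
})

test_that("previous-detection covariate flags any earlier season", {
  y <- array(0L, c(2, 3, 4))
  y[1, 2, 2] <- 1L
  pv <- prev_detected(y)
  expect_equal(pv[1, ], c(0L, 0L, 1L, 1L))
  expect_equal(pv[2, ], rep(0L, 4))
})
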