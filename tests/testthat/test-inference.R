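test_that("joint log-likelihood matches a pencil-and-paper composition", {
  st <- make_tiny_study()
  pars <- tiny_params()
  n <- dim(st$y)[1]; Tn <- st$horizon
  z <- rbind(c(2L, 2L, 2L),   # "a": alive throughout
             c(2L, 2L, 3L),   # "b": culled between seasons 2 and 3
             c(1L, 1L, 1L))   # augmented: never recruited
  ac <- rbind(c(1L, 2L, 2L), c(9L, 9L, 9L), c(4L, 4L, 5L))
  ll <- joint_loglik(pars, z, ac, st)
  dem <- pars$demographic
  manual <- 0
  # demographic terms (collar covariate of "a" is 1 in season 2)
  manual <- manual + log(0.5) +
    log(transition_distribution(2, dem, 2, gps = 1)[2]) +
    log(transition_distribution(2, dem, 3, gps = 0)[2])
  manual <- manual + log(0.5) +
    log(transition_distribution(2, dem, 2, gps = 0)[2]) +
    log(transition_distribution(2, dem, 3, gps = 0)[3])
  manual <- manual + log(0.5) + 2 * log(1 - 0.2)
  # movement terms
  for (i in 1:3) {
    manual <- manual +
      log(initial_ac_distribution(st$habitat, pars$movement)[ac[i, 1]]) +
      log(movement_kernel(ac[i, 1], st$habitat, pars$movement)[ac[i, 2]]) +
      log(movement_kernel(ac[i, 2], st$habitat, pars$movement)[ac[i, 3]])
  }
  manual <- manual + observation_loglik(st$y, ac, z, pars$detection,
                                        st$detectors, st$habitat,
                                        gps = st$gps, prev = st$prev)
  expect_equal(ll, manual, tolerance = 1e-10)
})

test_that("histories violating evidence or the observation gate are impossible", {
  st <- make_tiny_study()
  pars <- tiny_params()
  ok_z <- rbind(c(2L, 2L, 2L), c(2L, 2L, 3L), c(1L, 1L, 1L))
  ac <- matrix(5L, 3, 3)
  expect_true(is.finite(joint_loglik(pars, ok_z, ac, st)))
  # "b" alive in season 3 contradicts its legal recovery
  bad <- ok_z; bad[2, 3] <- 2L
  expect_identical(joint_loglik(pars, bad, ac, st), -Inf)
  # "a" unborn while detected
  bad2 <- ok_z; bad2[1, 1] <- 1L
  expect_identical(joint_loglik(pars, bad2, ac, st), -Inf)
})

test_that("duplicating an individual doubles its joint contribution", {
  st <- make_tiny_study()
  pars <- tiny_params()
  z1 <- matrix(c(2L, 2L, 2L), 1)
  ac1 <- matrix(c(1L, 2L, 2L), 1)
  sub <- st
  sub$y <- st$y[1, , , drop = FALSE]
  sub$gps <- st$gps[1, , drop = FALSE]
  sub$prev <- st$prev[1, , drop = FALSE]
  sub$conmask <- st$conmask[1, , , drop = FALSE]
  sub$group <- st$group[1]
  one <- joint_loglik(pars, z1, ac1, sub)
  dup <- sub
  dup$y <- st$y[c(1, 1), , , drop = FALSE]
  dup$gps <- st$gps[c(1, 1), , drop = FALSE]
  dup$prev <- st$prev[c(1, 1), , drop = FALSE]
  dup$conmask <- st$conmask[c(1, 1), , , drop = FALSE]
  dup$group <- st$group[c(1, 1)]
  two <- joint_loglik(pars, z1[c(1, 1), , drop = FALSE],
                      ac1[c(1, 1), , drop = FALSE], dup)
  expect_equal(two, 2 * one, tolerance = 1e-10)
})

test_that("forward marginal equals exhaustive enumeration over state paths", {
  st <- make_tiny_study()
  pars <- tiny_params()
  set.seed(18)
  ac <- matrix(sample.int(9, 9, replace = TRUE), 3, 3)
  fwd <- marginal_loglik_forward(pars, ac, st)
  enum <- enumerate_marginal(pars, ac, st)
  expect_equal(fwd, enum, tolerance = 1e-10)
})

test_that("degenerate evidence reduces the marginal to the single legal path", {
  st <- make_tiny_study()
  pars <- tiny_params()
  # no deaths possible and certain inclusion: alive throughout
  sure <- model_parameters(
    demographic_params(psi = 1 - 1e-12, gamma = 0.2, h0 = -700, w0 = -700),
    pars$movement, pars$detection)
  ac <- matrix(5L, 3, 3)
  fwd <- marginal_loglik_forward(sure, ac, st)
  z2 <- matrix(2L, 3, 3)
  st2 <- st
  st2$conmask[2, , ] <- TRUE # lift the recovery mask for this comparison
  fwd2 <- marginal_loglik_forward(sure, ac, st2)
  expect_equal(fwd2, joint_loglik(sure, z2, ac, st2), tolerance = 1e-9)
})

test_that("compiled forward filter agrees with the R marginal", {
  st <- make_tiny_study()
  pars <- tiny_params()
  prep <- opscr:::.prepare_fit(st, fit_config())
  set.seed(19)
  ac <- matrix(sample.int(9, prep$n * prep$Tn, replace = TRUE), prep$n)
  E2 <- opscr:::emission_alive_cpp(
    ac, prep$d2cd, prep$yflat, prep$K, prep$county,
    pars$detection$p0_intercept, prep$detcov, numeric(0),
    pars$detection$beta_prev, pars$detection$beta_gps, prep$gps, prep$prev,
    pars$detection$sigma, Inf)
  h0m <- matrix(pars$demographic$h0, 1, prep$Tn)
  w0m <- matrix(pars$demographic$w0, 1, prep$Tn)
  gm <- matrix(pars$demographic$gamma, 1, prep$Tn)
  lf <- opscr:::forward_ll_cpp(E2, prep$anyY, prep$conmask, prep$gps,
                               prep$group, pars$demographic$psi, gm, h0m, w0m,
                               pars$demographic$beta_h_gps,
                               pars$demographic$beta_w_gps)
  # subtract the movement terms from the R marginal to isolate the state part
  move <- 0
  for (i in 1:3) {
    move <- move +
      log(initial_ac_distribution(st$habitat, pars$movement)[ac[i, 1]]) +
      log(movement_kernel(ac[i, 1], st$habitat, pars$movement)[ac[i, 2]]) +
      log(movement_kernel(ac[i, 2], st$habitat, pars$movement)[ac[i, 3]])
  }
  fwd <- marginal_loglik_forward(pars, ac, st)
  expect_equal(sum(lf), fwd - move, tolerance = 1e-8)
})

test_that("FFBS draws respect evidence masks and transition legality", {
  st <- make_tiny_study()
  pars <- tiny_params()
  prep <- opscr:::.prepare_fit(st, fit_config())
  ac <- matrix(5L, prep$n, prep$Tn)
  E2 <- opscr:::emission_alive_cpp(
    ac, prep$d2cd, prep$yflat, prep$K, prep$county,
    pars$detection$p0_intercept, prep$detcov, numeric(0),
    pars$detection$beta_prev, pars$detection$beta_gps, prep$gps, prep$prev,
    pars$detection$sigma, Inf)
  h0m <- matrix(pars$demographic$h0, 1, prep$Tn)
  w0m <- matrix(pars$demographic$w0, 1, prep$Tn)
  gm <- matrix(pars$demographic$gamma, 1, prep$Tn)
  set.seed(20)
  for (r in 1:50) {
    z <- opscr:::ffbs_cpp(E2, prep$anyY, prep$conmask, prep$gps, prep$group,
                          pars$demographic$psi, gm, h0m, w0m,
                          pars$demographic$beta_h_gps,
                          pars$demographic$beta_w_gps)
    expect_true(all(st$conmask[cbind(rep(1:3, 3), rep(1:3, each = 3),
                                     as.integer(z))]))
    expect_false(any(z[, 1] == 2 & z[, 2] == 1))
  }
})

test_that("split-chain Rhat behaves at its reference points", {
  set.seed(21)
  base <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  # identical chains: statistic at (essentially) one
  r_same <- gelman_rubin(list(base, base))
  expect_true(all(abs(r_same - 1) < 0.01))
  # disjoint supports: far above the convergence criterion
  r_far <- gelman_rubin(list(base, base + 50))
  expect_true(all(r_far > 5))
  # independent textbook evaluation on random normal chains
  chains <- list(matrix(rnorm(1000), ncol = 1),
                 matrix(rnorm(1000), ncol = 1))
  r <- gelman_rubin(chains)
  splits <- list(chains[[1]][1:500, 1], chains[[1]][501:1000, 1],
                 chains[[2]][1:500, 1], chains[[2]][501:1000, 1])
  n <- 500
  W <- mean(sapply(splits, var))
  B <- n * var(sapply(splits, mean))
  expect_equal(unname(r), sqrt(((n - 1) / n * W + B / n) / W),
               tolerance = 1e-12)
  # constant chains report unity, single chains are an error
  cst <- matrix(1, 100, 1)
  expect_equal(unname(gelman_rubin(list(cst, cst))), 1)
  expect_error(gelman_rubin(list(base)), "two chains")
})

test_that("collar contrasts from degenerate posteriors reproduce fixed differences", {
  mk_fit <- function(h0, w0, bh, bw) {
    d <- cbind(h0_g1 = rep(h0, 50), w0_g1 = w0, beta_h_gps = bh,
               beta_w_gps = bw, Nsuper = 10)
    structure(list(draws = list(d, d), param_names = colnames(d)),
              class = "opscr_fit")
  }
  f0 <- mk_fit(qlogis(0.10), qlogis(0.25), 0, 0)
  c0 <- derive_collar_contrasts(f0)
  expect_equal(c0$diff_pp_median, c(0, 0, 0))
  # the published cause-specific medians: overall difference 16 pp
  f1 <- mk_fit(qlogis(0.10), qlogis(0.25),
               qlogis(0.07) - qlogis(0.10), qlogis(0.12) - qlogis(0.25))
  c1 <- derive_collar_contrasts(f1)
  expect_equal(c1$diff_pp_median[c1$measure == "overall"], 16)
  expect_equal(c1$diff_pp_median[c1$measure == "other"], 13)
  expect_equal(c1$diff_pp_median[c1$measure == "legal"], 3)
  expect_equal(c1$noncollared_median, c(0.10, 0.25, 0.35))
  expect_equal(c1$collared_median, c(0.07, 0.12, 0.19))
  expect_error(derive_collar_contrasts(f1, group = 9), "unknown group")
})

test_that("contrast summaries equal brute-force recomputation from raw chains", {
  set.seed(22)
  d1 <- cbind(h0_g1 = rnorm(200, -2, 0.3), w0_g1 = rnorm(200, -1, 0.3),
              beta_h_gps = rnorm(200, -0.4, 0.2),
              beta_w_gps = rnorm(200, -1, 0.3), Nsuper = 10)
  d2 <- d1 + 0.01
  fit <- structure(list(draws = list(d1, d2), param_names = colnames(d1)),
                   class = "opscr_fit")
  ct <- derive_collar_contrasts(fit)
  all_d <- rbind(d1, d2)
  dpp <- 100 * (plogis(all_d[, "w0_g1"]) -
                  plogis(all_d[, "w0_g1"] + all_d[, "beta_w_gps"]))
  expect_equal(ct$diff_pp_median[ct$measure == "other"], median(dpp))
  expect_equal(ct$diff_pp_lo[ct$measure == "other"],
               unname(quantile(dpp, 0.025)))
})

test_that("a short MCMC run is bit-reproducible under its seed", {
  st <- generate_study(study_config("tiny"), seed = 23)
  cfg <- fit_config(chains = 2, iterations = 60, burn = 30, seed = 24,
                    sigma_max = 5)
  f1 <- suppressWarnings(run_mcmc(st, cfg))
  f2 <- suppressWarnings(run_mcmc(st, cfg))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(run_mcmc(st, fit_config(chains = 2, iterations = 60,
                                                burn = 30, seed = 25,
                                                sigma_max = 5)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior draws respect parameter constraints", {
  st <- generate_study(study_config("tiny"), seed = 26)
  f <- suppressWarnings(run_mcmc(st, fit_config(chains = 2, iterations = 150,
                                               burn = 50, seed = 27,
                                               sigma_max = 5)))
  d <- as.matrix(f)
  expect_true(all(d[, "sigma"] > 0 & d[, "sigma"] <= 5))
  expect_true(all(d[, "tau"] > 0 & d[, "tau"] <= 100))
  expect_true(all(d[, "psi_g1"] > 0 & d[, "psi_g1"] < 1))
  expect_true(all(d[, "gamma_g1"] >= 0 & d[, "gamma_g1"] <= 1))
  h <- plogis(d[, "h0_g1"]); w <- plogis(d[, "w0_g1"])
  expect_true(all(h + w < 1))
  hc <- plogis(d[, "h0_g1"] + d[, "beta_h_gps"])
  wc <- plogis(d[, "w0_g1"] + d[, "beta_w_gps"])
  expect_true(all(hc + wc < 1))
})

test_that("a season-specific fit runs and names its intercepts by season", {
  st <- generate_study(study_config("tiny"), seed = 28)
  f <- suppressWarnings(run_mcmc(st, fit_config(chains = 2, iterations = 80,
                                               burn = 40, seed = 29,
                                               sigma_max = 5,
                                               time_varying = TRUE)))
  expect_true(all(c("h0_g1_t2", "h0_g1_t3", "gamma_g1_t2") %in%
                    f$param_names))
  ct <- derive_collar_contrasts(f, season = 2)
  expect_equal(nrow(ct), 3)
  expect_error(derive_collar_contrasts(f), "season")
})
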