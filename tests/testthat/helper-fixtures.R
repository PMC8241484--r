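# Shared fixtures: a small hand-built study with known geometry and
# evidence, plus a brute-force path-enumeration oracle for the forward
# algorithm.

make_tiny_habitat <- function() {
  build_habitat_grid(c(0, 60, 0, 60), cell_size = 20,
                     covariate = function(x, y) (x + y) / 120,
                     buffer_width = 0)
}

# 2 observed individuals over T = 3 seasons on a 3x3 habitat, one legal
# recovery, one collar spell, one augmented pseudo-individual
make_tiny_study <- function() {
  habitat <- make_tiny_habitat()
  detectors <- build_detector_grid(c(0, 60, 0, 60), detector_size = 20,
                                   subdetector_size = 10, habitat = habitat)
  records <- data.frame(
    individual_id = c("a", "a", "a", "b"),
    season = c(1L, 1L, 2L, 2L),
    x = c(12, 18, 32, 52), y = c(12, 12, 28, 48))
  collars <- data.frame(individual_id = "a", season = 2L, gps = 1L)
  recoveries <- data.frame(individual_id = "b", season = 3L,
                           cause = "legal", x = 50, y = 50)
  build_study(habitat, detectors, records, horizon = 3L, M = 3L,
              collars = collars, recoveries = recoveries)
}

tiny_params <- function() {
  model_parameters(
    demographic_params(psi = 0.5, gamma = 0.2, h0 = qlogis(0.1),
                       w0 = qlogis(0.2), beta_h_gps = -0.3,
                       beta_w_gps = -0.5),
    movement_params(tau = 15, b_dens = 0.3),
    detection_params(p0_intercept = qlogis(0.1), sigma = 10,
                     beta_prev = 0.3, beta_gps = -0.2))
}

# sum over all 4^T latent state paths of exp(joint log-probability) for a
# fixed AC path; independent of the forward-algorithm implementation
enumerate_marginal <- function(params, ac, study) {
  n <- nrow(ac); Tn <- ncol(ac)
  dem <- params$demographic
  total <- 0
  for (i in seq_len(n)) {
    paths <- as.matrix(expand.grid(rep(list(1:4), Tn)))
    li <- 0
    for (r in seq_len(nrow(paths))) {
      zi <- paths[r, ]
      pr <- initial_distribution(dem)[zi[1]]
      for (t in 2:Tn)
        pr <- pr * transition_distribution(zi[t - 1], dem, t,
                                           study$gps[i, t])[zi[t]]
      if (pr <= 0) next
      if (any(!study$conmask[cbind(i, seq_len(Tn), zi)])) next
      z1 <- matrix(zi, 1, Tn)
      oll <- observation_loglik(study$y[i, , , drop = FALSE],
                                ac[i, , drop = FALSE], z1,
                                params$detection, study$detectors,
                                study$habitat,
                                gps = study$gps[i, , drop = FALSE],
                                prev = study$prev[i, , drop = FALSE])
      if (!is.finite(oll)) next
      li <- li + pr * exp(oll)
    }
    if (li <= 0) return(-Inf)
    total <- total + log(li)
    reg <- study$region_of_group[study$group[i]]
    total <- total +
      log(initial_ac_distribution(study$habitat, params$movement,
                                  reg)[ac[i, 1]])
    for (t in 2:Tn)
      total <- total + log(movement_kernel(ac[i, t - 1], study$habitat,
                                           params$movement, reg)[ac[i, t]])
  }
  total
}
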