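#' Bundle the three submodel parameter sets
#'
#' @param demographic a [demographic_params()].
#' @param movement a [movement_params()].
#' @param detection a [detection_params()].
#' @return a list of class `model_parameters`.
#' @export
model_parameters <- function(demographic, movement, detection) {
  stopifnot(inherits(demographic, "demographic_params"),
            inherits(movement, "movement_params"),
            inherits(detection, "detection_params"))
  structure(list(demographic = demographic, movement = movement,
                 detection = detection), class = "model_parameters")
}

# observation log-likelihood of one (individual, season) row given an AC cell
.obs_ll_row <- function(study, detpar, i, t, cell, local_radius = Inf) {
  dd <- study$detectors$detectors
  cov <- .det_covariates(study$detectors, t)
  lp0 <- detpar$p0_intercept[dd$county] + detpar$beta_tracks * cov$tracks +
    detpar$beta_roads * cov$roads + detpar$beta_snow * cov$snow +
    detpar$beta_prev * study$prev[i, t] + detpar$beta_gps * study$gps[i, t]
  d2 <- (dd$x - study$habitat$cells$x[cell])^2 +
    (dd$y - study$habitat$cells$y[cell])^2
  yv <- study$y[i, , t]
  use <- yv > 0 | d2 <= local_radius^2
  p <- plogis(lp0[use]) * exp(-d2[use] / (2 * detpar$sigma^2))
  sum(dbinom(yv[use], dd$K[use], p, log = TRUE))
}

#' Joint log-likelihood of parameters and latent variables
#'
#' Sum of the demographic transition log-probabilities (respecting the hard
#' evidence masks, which contribute `-Inf` when violated), the movement
#' log-probabilities of the activity-centre paths, and the binomial
#' observation log-likelihood.  A plain-R single-stratum reference used as a
#' pencil-and-paper oracle for the compiled sampler kernels; constraint
#' violations return `-Inf` rather than throwing, so MCMC logic can treat
#' them as rejections.
#'
#' @param params a [model_parameters()].
#' @param z integer `n x T` latent state matrix.
#' @param ac integer `n x T` matrix of habitat cell indices.
#' @param study an `opscr_study`.
#' @param local_radius observation evaluation radius, km.
#' @return scalar log-likelihood, possibly `-Inf`.
#' @export
joint_loglik <- function(params, z, ac, study, local_radius = Inf) {
  tryCatch(.joint_loglik_impl(params, z, ac, study, local_radius),
           opscr_infeasible_hazard = function(e) -Inf)
}

.joint_loglik_impl <- function(params, z, ac, study, local_radius = Inf) {
  n <- nrow(z); Tn <- ncol(z)
  dem <- params$demographic
  ll <- 0
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      if (!study$conmask[i, t, z[i, t]]) return(-Inf)
      pr <- if (t == 1) initial_distribution(dem)[z[i, 1]] else
        transition_distribution(z[i, t - 1], dem, t,
                                study$gps[i, t])[z[i, t]]
      if (pr <= 0) return(-Inf)
      ll <- ll + log(pr)
    }
    reg <- study$region_of_group[study$group[i]]
    ll <- ll + log(initial_ac_distribution(study$habitat, params$movement,
                                           reg)[ac[i, 1]])
    if (Tn >= 2) for (t in 2:Tn)
      ll <- ll + log(movement_kernel(ac[i, t - 1], study$habitat,
                                     params$movement, reg)[ac[i, t]])
  }
  ll + observation_loglik(study$y, ac, z, params$detection, study$detectors,
                          study$habitat, gps = study$gps, prev = study$prev,
                          local_radius = local_radius)
}

#' Forward-algorithm marginal log-likelihood over latent states
#'
#' Marginalizes the four-state sequences `z` out of [joint_loglik()] exactly,
#' per individual, for a fixed activity-centre path; the exactness oracle for
#' the sampled-state scheme.  The movement terms (which do not involve `z`)
#' are included so that `exp(marginal)` equals the sum of `exp(joint)` over
#' all legal state paths.
#'
#' @inheritParams joint_loglik
#' @param ac integer `n x T` matrix of habitat cell indices.
#' @return scalar marginal log-likelihood.
#' @export
marginal_loglik_forward <- function(params, ac, study, local_radius = Inf) {
  tryCatch(.marginal_forward_impl(params, ac, study, local_radius),
           opscr_infeasible_hazard = function(e) -Inf)
}

.marginal_forward_impl <- function(params, ac, study, local_radius = Inf) {
  n <- nrow(ac); Tn <- ncol(ac)
  dem <- params$demographic
  total <- 0
  anyY <- vapply(seq_len(Tn),
                 function(t) rowSums(study$y[, , t, drop = FALSE] > 0) > 0,
                 logical(n))
  anyY <- matrix(anyY, nrow = n)
  for (i in seq_len(n)) {
    lem <- function(t) {
      e <- c(if (anyY[i, t]) -Inf else 0,
             .obs_ll_row(study, params$detection, i, t, ac[i, t],
                         local_radius),
             if (anyY[i, t]) -Inf else 0,
             if (anyY[i, t]) -Inf else 0)
      e[!study$conmask[i, t, ]] <- -Inf
      e
    }
    lfilt <- log(initial_distribution(dem)) + lem(1)
    ll <- max(lfilt)
    if (!is.finite(ll)) return(-Inf)
    lfilt <- lfilt - ll
    if (Tn >= 2) for (t in 2:Tn) {
      lpred <- vapply(1:4, function(sp) {
        terms <- vapply(1:4, function(s) {
          pr <- transition_distribution(s, dem, t, study$gps[i, t])[sp]
          if (pr <= 0) -Inf else lfilt[s] + log(pr)
        }, numeric(1))
        m <- max(terms)
        if (!is.finite(m)) -Inf else m + log(sum(exp(terms - m)))
      }, numeric(1))
      lfilt <- lpred + lem(t)
      m <- max(lfilt)
      if (!is.finite(m)) return(-Inf)
      ll <- ll + m
      lfilt <- lfilt - m
    }
    total <- total + ll + log(sum(exp(lfilt)))
    reg <- study$region_of_group[study$group[i]]
    total <- total + log(initial_ac_distribution(study$habitat,
                                                 params$movement,
                                                 reg)[ac[i, 1]])
    if (Tn >= 2) for (t in 2:Tn)
      total <- total + log(movement_kernel(ac[i, t - 1], study$habitat,
                                           params$movement, reg)[ac[i, t]])
  }
  total
}
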