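#' Detection parameters
#'
#' The half-normal detection model: the probability of detecting an
#' individual at a detector decays with the squared distance between the
#' detector centre and the individual's activity centre,
#' `p = p0 * exp(-d^2 / (2 sigma^2))`, with the baseline `p0` logit-linear in
#' detector covariates (search effort, road access, snow), previous-detection
#' status and the collar covariate.
#'
#' @param p0_intercept logit-scale baseline intercept(s); one value per
#'   county.
#' @param sigma half-normal scale, km.
#' @param beta_tracks,beta_roads,beta_snow logit-scale slopes on the
#'   standardized detector covariates.
#' @param beta_prev logit-scale effect of having been detected in any
#'   earlier season.
#' @param beta_gps logit-scale effect of wearing a GPS collar.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(p0_intercept, sigma, beta_tracks = 0,
                             beta_roads = 0, beta_snow = 0, beta_prev = 0,
                             beta_gps = 0) {
  stopifnot(all(is.finite(p0_intercept)), is.finite(sigma), sigma > 0,
            is.finite(beta_tracks), is.finite(beta_roads),
            is.finite(beta_snow), is.finite(beta_prev), is.finite(beta_gps))
  structure(list(p0_intercept = p0_intercept, sigma = sigma,
                 beta_tracks = beta_tracks, beta_roads = beta_roads,
                 beta_snow = beta_snow, beta_prev = beta_prev,
                 beta_gps = beta_gps),
            class = "detection_params")
}

#' Baseline detection probability at a detector
#'
#' @param params a [detection_params()].
#' @param county county id of the detector (indexes `p0_intercept`).
#' @param tracks,roads,snow standardized detector covariate values.
#' @param prev binary previous-detection covariate.
#' @param gps binary collar covariate.
#' @return baseline probability `p0` in (0, 1).  Missing covariate values are
#'   an error; nothing is imputed.
#' @export
baseline_p0 <- function(params, county = 1, tracks = 0, roads = 0, snow = 0,
                        prev = 0, gps = 0) {
  vals <- c(tracks, roads, snow, prev, gps)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("missing or non-finite detection covariate value")
  plogis(params$p0_intercept[county] + params$beta_tracks * tracks +
           params$beta_roads * roads + params$beta_snow * snow +
           params$beta_prev * prev + params$beta_gps * gps)
}

#' Half-normal detection probability
#'
#' @param p0 baseline detection probability at distance zero.
#' @param distance activity centre to detector distance, km (vectorized).
#' @param sigma half-normal scale, km.
#' @return `p0 * exp(-distance^2 / (2 sigma^2))`.
#' @export
detection_prob <- function(p0, distance, sigma) {
  stopifnot(all(distance >= 0), sigma > 0)
  p0 * exp(-distance^2 / (2 * sigma^2))
}

# detector-season covariate slice as a list(tracks, roads, snow) of vectors;
# zeros when the grid carries no covariates
.det_covariates <- function(detectors, t) {
  J <- nrow(detectors$detectors)
  out <- list(tracks = numeric(J), roads = numeric(J), snow = numeric(J))
  if (!is.null(detectors$covariates)) {
    nm <- dimnames(detectors$covariates)[[3]]
    for (k in intersect(names(out), nm)) out[[k]] <- detectors$covariates[, t, k]
  }
  out
}

#' Observation log-likelihood (reference implementation)
#'
#' Sum of binomial log-probabilities `y[i,j,t] ~ Binomial(K_j, p[i,j,t] *
#' I(z[i,t] = 2))` over individuals, detectors and seasons.  Detectors with
#' zero counts farther than `local_radius` from the activity centre are
#' skipped (their `log(1 - p)` term is below machine precision at the default
#' six-sigma radius); positive counts are always evaluated exactly.  Any
#' positive count while the individual is not alive yields `-Inf`.
#'
#' This plain-R implementation is the correctness oracle for the compiled
#' kernel used inside [run_mcmc()].
#'
#' @param y integer array `n x J x T` of subdetector counts.
#' @param ac integer matrix `n x T` of 1-based habitat cell indices.
#' @param z integer matrix `n x T` of state codes.
#' @param params a [detection_params()].
#' @param detectors a `detector_grid`.
#' @param habitat a `habitat_grid`.
#' @param gps,prev optional `n x T` binary matrices (default all zero).
#' @param local_radius evaluation radius, km (default `Inf` = full
#'   evaluation).
#' @return total log-likelihood (scalar; may be `-Inf`).
#' @export
observation_loglik <- function(y, ac, z, params, detectors, habitat,
                               gps = NULL, prev = NULL, local_radius = Inf) {
  n <- dim(y)[1]; J <- dim(y)[2]; Tn <- dim(y)[3]
  stopifnot(all(dim(ac) == c(n, Tn)), all(dim(z) == c(n, Tn)),
            J == nrow(detectors$detectors), local_radius > 0)
  if (any(y > rep(detectors$detectors$K, each = n)))
    stop("y exceeds the subdetector count K of its detector")
  if (is.null(gps)) gps <- matrix(0L, n, Tn)
  if (is.null(prev)) prev <- matrix(0L, n, Tn)
  dd <- detectors$detectors
  ll <- 0
  for (t in seq_len(Tn)) {
    cov <- .det_covariates(detectors, t)
    lp0 <- params$p0_intercept[dd$county] + params$beta_tracks * cov$tracks +
      params$beta_roads * cov$roads + params$beta_snow * cov$snow
    for (i in seq_len(n)) {
      yv <- y[i, , t]
      if (z[i, t] != 2) {
        if (any(yv > 0)) return(-Inf)
        next
      }
      cx <- habitat$cells$x[ac[i, t]]
      cy <- habitat$cells$y[ac[i, t]]
      d2 <- (dd$x - cx)^2 + (dd$y - cy)^2
      use <- yv > 0 | d2 <= local_radius^2
      if (!any(use)) next
      p <- plogis(lp0[use] + params$beta_prev * prev[i, t] +
                    params$beta_gps * gps[i, t]) *
        exp(-d2[use] / (2 * params$sigma^2))
      ll <- ll + sum(dbinom(yv[use], dd$K[use], p, log = TRUE))
      if (!is.finite(ll)) return(-Inf)
    }
  }
  ll
}

#' Simulate subdetector counts
#'
#' Generator counterpart of the observation model:
#' `y[i,j,t] ~ Binomial(K_j, p[i,j,t])` while alive, zero otherwise.  The
#' previous-detection covariate is accumulated sequentially from the
#' simulated counts of earlier seasons.
#'
#' @inheritParams observation_loglik
#' @return integer array `n x J x T` of counts.
#' @export
simulate_observations <- function(ac, z, params, detectors, habitat,
                                  gps = NULL) {
  n <- nrow(ac); Tn <- ncol(ac)
  dd <- detectors$detectors
  J <- nrow(dd)
  if (is.null(gps)) gps <- matrix(0L, n, Tn)
  y <- array(0L, dim = c(n, J, Tn))
  prev <- integer(n)
  for (t in seq_len(Tn)) {
    cov <- .det_covariates(detectors, t)
    lp0 <- params$p0_intercept[dd$county] + params$beta_tracks * cov$tracks +
      params$beta_roads * cov$roads + params$beta_snow * cov$snow
    for (i in seq_len(n)) {
      if (z[i, t] != 2) next
      cx <- habitat$cells$x[ac[i, t]]
      cy <- habitat$cells$y[ac[i, t]]
      d2 <- (dd$x - cx)^2 + (dd$y - cy)^2
      p <- plogis(lp0 + params$beta_prev * prev[i] +
                    params$beta_gps * gps[i, t]) *
        exp(-d2 / (2 * params$sigma^2))
      y[i, , t] <- rbinom(J, dd$K, p)
    }
    prev <- pmax(prev, as.integer(rowSums(y[, , t, drop = FALSE]) > 0))
  }
  y
}

#' Previous-detection covariate from a count array
#'
#' `prev[i, t]` is 1 when individual `i` was detected in any season strictly
#' before `t`.
#'
#' @param y integer array `n x J x T`.
#' @return integer matrix `n x T`.
#' @export
prev_detected <- function(y) {
  n <- dim(y)[1]; Tn <- dim(y)[3]
  det <- vapply(seq_len(Tn), function(t) rowSums(y[, , t, drop = FALSE]) > 0,
                logical(n))
  det <- matrix(det, nrow = n)
  prev <- matrix(0L, n, Tn)
  if (Tn >= 2) for (t in 2:Tn)
    prev[, t] <- as.integer(prev[, t - 1] | det[, t - 1])
  prev
}
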