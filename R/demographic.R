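#' Demographic parameters of the four-state population process
#'
#' The latent state of each (possibly augmented) individual follows a
#' categorical Markov chain over four states: 1 unborn, 2 alive, 3 dead from
#' legal culling (held one season), 4 dead from other causes or earlier
#' (absorbing).  Cause-specific mortality is logit-linear in the binary
#' collar covariate: `logit(h) = h0_t + beta_h_gps * GPS` and
#' `logit(w) = w0_t + beta_w_gps * GPS`, with survival `phi = 1 - h - w`.
#'
#' @param psi inclusion probability at the first season, in (0, 1).
#' @param gamma per-season recruitment probability; scalar or length-`T`
#'   vector (entry `t` drives the transition into season `t`).
#' @param h0 logit-scale legal-culling mortality intercept(s) of non-collared
#'   individuals; scalar or length-`T` vector.
#' @param w0 logit-scale other-cause mortality intercept(s); scalar or
#'   length-`T` vector.
#' @param beta_h_gps,beta_w_gps logit-scale collar effects on the two
#'   mortality causes, shared across strata.
#' @return an object of class `demographic_params`.
#' @export
demographic_params <- function(psi, gamma, h0, w0, beta_h_gps = 0,
                               beta_w_gps = 0) {
  stopifnot(psi > 0, psi < 1, all(gamma >= 0), all(gamma <= 1),
            all(is.finite(h0)), all(is.finite(w0)),
            is.finite(beta_h_gps), is.finite(beta_w_gps))
  structure(list(psi = psi, gamma = gamma, h0 = h0, w0 = w0,
                 beta_h_gps = beta_h_gps, beta_w_gps = beta_w_gps),
            class = "demographic_params")
}

.param_at <- function(x, t) if (length(x) == 1) x else x[t]

#' Cause-specific mortality and survival probabilities
#'
#' @param params a [demographic_params()].
#' @param season season index `t` (selects season-specific intercepts).
#' @param gps binary collar covariate (0/1).
#' @return list with `h` (legal culling), `w` (other causes) and
#'   `phi = 1 - h - w`.  Errors with condition class
#'   `opscr_infeasible_hazard` when `h + w >= 1`, which MCMC proposal logic
#'   treats as a rejection.
#' @export
mortality_probs <- function(params, season = 1, gps = 0) {
  stopifnot(gps %in% c(0, 1))
  h <- plogis(.param_at(params$h0, season) + params$beta_h_gps * gps)
  w <- plogis(.param_at(params$w0, season) + params$beta_w_gps * gps)
  if (h + w >= 1)
    stop(structure(class = c("opscr_infeasible_hazard", "error", "condition"),
                   list(message = sprintf(
                     "infeasible hazards: h + w = %.4f >= 1 at season %d, gps = %d",
                     h + w, season, gps), call = sys.call(-1))))
  list(h = h, w = w, phi = 1 - h - w)
}

#' One-step transition distribution of the demographic chain
#'
#' @param current current state code in 1..4.
#' @inheritParams mortality_probs
#' @return probability vector over the four states (sums to one).
#' @export
transition_distribution <- function(current, params, season, gps = 0) {
  stopifnot(current %in% 1:4, season >= 2)
  if (current == 1) {
    g <- .param_at(params$gamma, season)
    c(1 - g, g, 0, 0)
  } else if (current == 2) {
    mp <- mortality_probs(params, season, gps)
    c(0, mp$phi, mp$h, mp$w)
  } else {
    c(0, 0, 0, 1) # both dead states absorb into state 4
  }
}

#' Initial state distribution
#'
#' @param params a [demographic_params()] (only `psi` is used).
#' @return probability vector `(1 - psi, psi, 0, 0)`.
#' @export
initial_distribution <- function(params) {
  c(1 - params$psi, params$psi, 0, 0)
}

#' Allowed-state masks from dead recoveries, detections and collar records
#'
#' Translates hard evidence into per-individual, per-season sets of legal
#' latent states: a legal cull recovered in season `t` forces state 3 at `t`,
#' state 4 afterwards, and alive at `t - 1`; a reported other-cause death
#' forces state 4 at `t` analogously; a season with any detection forces
#' state 2 (culled individuals are not detectable in the season of death);
#' a collar deployment window implies the individual was alive at capture
#' (the season before the window starts) and recruited throughout it.
#'
#' @param recoveries data.frame (`individual_id`, `season`, `cause` in
#'   `"legal"`/`"other"`), or `NULL`; at most one row per individual.
#' @param horizon number of monitoring seasons `T`.
#' @param individuals character vector fixing row order of the mask.
#' @param detections optional data.frame (`individual_id`, `season`) of
#'   seasons with at least one detection.
#' @param collars optional data.frame (`individual_id`, `season`, `gps`).
#' @param complete_legal_reporting when `TRUE`, the absence of a cull
#'   recovery is itself evidence: state 3 is disallowed except in the season
#'   of a recorded legal recovery, reflecting a monitoring regime in which
#'   every legal culling event is reported.  The default (`FALSE`) leaves
#'   unevidenced seasons unconstrained.
#' @return logical array `n x T x 4`; `TRUE` marks an allowed state.
#' @export
state_constraints_from_recoveries <- function(recoveries, horizon, individuals,
                                              detections = NULL,
                                              collars = NULL,
                                              complete_legal_reporting = FALSE) {
  n <- length(individuals)
  mask <- array(TRUE, dim = c(n, horizon, 4),
                dimnames = list(individuals, NULL, NULL))
  if (complete_legal_reporting) mask[, , 3] <- FALSE
  det_seasons <- vector("list", n)
  names(det_seasons) <- individuals
  if (!is.null(detections) && nrow(detections)) {
    for (r in seq_len(nrow(detections))) {
      id <- as.character(detections$individual_id[r])
      t <- detections$season[r]
      if (!id %in% individuals) next
      if (t < 1 || t > horizon) stop("detection season ", t, " outside horizon")
      mask[id, t, c(1, 3, 4)] <- FALSE
      det_seasons[[id]] <- c(det_seasons[[id]], t)
    }
  }
  if (!is.null(collars) && nrow(collars)) {
    act <- collars[collars$gps == 1, , drop = FALSE]
    for (id in unique(as.character(act$individual_id))) {
      if (!id %in% individuals) next
      ts <- sort(act$season[as.character(act$individual_id) == id])
      # collared, so recruited before the deployment window
      mask[id, ts, 1] <- FALSE
      # alive at capture, the season before each deployment run starts
      starts <- ts[c(TRUE, diff(ts) > 1)]
      for (s0 in starts) {
        if (s0 >= 2) mask[id, s0 - 1, c(1, 3, 4)] <- FALSE
        else mask[id, 1, c(1, 3, 4)] <- FALSE
      }
    }
  }
  if (!is.null(recoveries) && nrow(recoveries)) {
    if (anyDuplicated(recoveries$individual_id))
      stop("an individual has more than one dead recovery")
    for (r in seq_len(nrow(recoveries))) {
      id <- as.character(recoveries$individual_id[r])
      t <- recoveries$season[r]
      cause <- as.character(recoveries$cause[r])
      if (!id %in% individuals) next
      if (t < 1 || t > horizon) stop("recovery season ", t, " outside horizon")
      if (!cause %in% c("legal", "other"))
        stop("unknown recovery cause '", cause, "'")
      late <- det_seasons[[id]][det_seasons[[id]] >= t]
      if (length(late))
        stop("individual ", id, " detected in season ", min(late),
             " at or after its recovery in season ", t,
             ": inconsistent history")
      dead_state <- if (cause == "legal") 3L else 4L
      mask[id, t, ] <- FALSE
      mask[id, t, dead_state] <- TRUE
      if (t < horizon) for (tt in (t + 1):horizon) {
        mask[id, tt, ] <- FALSE
        mask[id, tt, 4] <- TRUE
      }
      if (t >= 2) mask[id, t - 1, c(1, 3, 4)] <- FALSE
      if (t >= 3) for (tt in seq_len(t - 2)) mask[id, tt, c(3, 4)] <- FALSE
    }
  }
  bad <- which(apply(mask, c(1, 2), sum) == 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("no legal state remains for individual ",
         individuals[bad[1, 1]], " in season ", bad[1, 2])
  mask
}

#' Forward-simulate one state path
#'
#' Generator counterpart of the demographic chain; used by the synthetic-study
#' module and the generator-fidelity tests.
#'
#' @inheritParams mortality_probs
#' @param horizon number of seasons.
#' @param gps binary vector of length `horizon` (recycled if scalar).
#' @return integer state vector of length `horizon`.
#' @export
simulate_state_path <- function(params, horizon, gps = 0) {
  gps <- rep(gps, length.out = horizon)
  z <- integer(horizon)
  z[1] <- sample.int(4, 1, prob = initial_distribution(params))
  if (horizon >= 2) for (t in 2:horizon) {
    z[t] <- sample.int(4, 1,
                       prob = transition_distribution(z[t - 1], params, t,
                                                      gps[t]))
  }
  z
}
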